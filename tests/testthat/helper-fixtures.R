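# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately written as plain loops / set scans, never calling
# the package functions they check.

make_expr <- function(values, unit = "FPKM", species = "sp",
                      organ_of = NULL) {
  if (is.null(organ_of))
    organ_of <- stats::setNames(colnames(values), colnames(values))
  expression_matrix(values, unit, species, organ_of)
}

rand_counts <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  m <- matrix(rpois(n_genes * n_samples, 50), n_genes,
              dimnames = list(genes, samples))
  m[1L, colSums(m) == 0] <- 1L
  make_expr(m * 1.0, "COUNTS")
}

rand_hits <- function(n_queries = 10, n_subjects = 10, n_hits = 40,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(query = sample(sprintf("q%02d", seq_len(n_queries)), n_hits,
                            replace = TRUE),
             subject = sample(sprintf("s%02d", seq_len(n_subjects)), n_hits,
                              replace = TRUE),
             pct_identity = round(runif(n_hits, 20, 100), 1),
             align_len = sample(50:500, n_hits, replace = TRUE),
             evalue = 10^-sample(0:100, n_hits, replace = TRUE),
             bitscore = round(runif(n_hits, 30, 500), 1),
             stringsAsFactors = FALSE)
}

# ordering comparator implementing the stated tie-break chain
hit_better <- function(a, b) {
  if (a$bitscore != b$bitscore) return(a$bitscore > b$bitscore)
  if (a$evalue != b$evalue) return(a$evalue < b$evalue)
  if (a$pct_identity != b$pct_identity) return(a$pct_identity > b$pct_identity)
  a$subject < b$subject
}

brute_best_hit <- function(hits, exclude_self = TRUE) {
  if (exclude_self) hits <- hits[hits$query != hits$subject, , drop = FALSE]
  out <- list()
  for (q in sort(unique(hits$query))) {
    rows <- hits[hits$query == q, , drop = FALSE]
    best <- rows[1L, ]
    if (nrow(rows) > 1L)
      for (i in 2:nrow(rows))
        if (hit_better(rows[i, ], best)) best <- rows[i, ]
    out[[q]] <- data.frame(focal_gene = q, reference_gene = best$subject,
                           bitscore = best$bitscore, evalue = best$evalue,
                           pct_identity = best$pct_identity,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

brute_unique <- function(pairs) {
  # group by reference gene, keep the best by bitscore -> evalue ->
  # identity -> smallest focal id
  keep <- logical(nrow(pairs))
  for (s in unique(pairs$reference_gene)) {
    idx <- which(pairs$reference_gene == s)
    best <- idx[1L]
    for (i in idx[-1L]) {
      a <- pairs[i, ]; b <- pairs[best, ]
      better <- if (a$bitscore != b$bitscore) a$bitscore > b$bitscore
        else if (a$evalue != b$evalue) a$evalue < b$evalue
        else if (a$pct_identity != b$pct_identity)
          a$pct_identity > b$pct_identity
        else a$focal_gene < b$focal_gene
      if (better) best <- i
    }
    keep[best] <- TRUE
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$focal_gene), , drop = FALSE]
}

brute_reciprocal <- function(hits_ab, hits_ba) {
  fwd <- brute_best_hit(hits_ab)
  rev <- brute_best_hit(hits_ba)
  keep <- logical(nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    j <- which(rev$focal_gene == fwd$reference_gene[i])
    keep[i] <- length(j) == 1L && rev$reference_gene[j] == fwd$focal_gene[i]
  }
  fwd[keep, , drop = FALSE]
}

# double loop over genes x organs applying both OSG rules literally
brute_osgs <- function(focal_vec, ref_mat, pairs, reference_max = 0.5,
                       focal_min = 1.0, excluded = character()) {
  organs <- setdiff(colnames(ref_mat), excluded)
  res <- character()
  expr <- numeric()
  for (i in seq_len(nrow(pairs))) {
    f <- pairs$focal_gene[i]; r <- pairs$reference_gene[i]
    eliminated <- FALSE
    for (o in organs) if (ref_mat[r, o] > reference_max) eliminated <- TRUE
    if (!eliminated && focal_vec[f] > focal_min) {
      res <- c(res, f); expr <- c(expr, focal_vec[f])
    }
  }
  res[order(-expr, res)]
}

# exhaustive hypergeometric upper tail by subset enumeration
brute_hyper <- function(k, K, n, N) {
  genes <- seq_len(N)
  annotated <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2L, function(s) sum(s %in% annotated))
  mean(hits >= k)
}

# literal BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, p[o[j]] * m / j), 0)
    q[o[i]] <- min(vals)
  }
  q
}
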