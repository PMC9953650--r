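# Shared / organ-only partitions of expressed genes through a homolog map,
# plus self-contained over-representation analysis (hypergeometric + BH).

#' Partition expressed genes of two organs through a homolog map
#'
#' A homolog pair is shared-expressed iff both sides are in their respective
#' expressed sets; expressed focal genes not in any shared pair (including
#' genes without a homolog) are focal-only, and symmetrically for the
#' reference side.
#'
#' @param focal_expressed character vector of expressed focal gene ids.
#' @param reference_expressed character vector of expressed reference gene
#'   ids.
#' @param map injective \code{HomologMap} (\code{UNIQUE} or
#'   \code{RECIPROCAL} mode).
#' @return an \code{OverlapPartition}: list with \code{shared_pairs}
#'   (data.frame \code{focal_gene}, \code{reference_gene}),
#'   \code{focal_only}, \code{reference_only} and \code{counts}.
#' @export
partition_expressed <- function(focal_expressed, reference_expressed, map) {
  stopifnot(inherits(map, "HomologMap"))
  p <- map$pairs
  if (anyDuplicated(p$focal_gene) || anyDuplicated(p$reference_gene))
    stop("partition_expressed requires an injective homolog map ",
         "(use restrict_unique or reciprocal_map)")
  focal_expressed <- unique(as.character(focal_expressed))
  reference_expressed <- unique(as.character(reference_expressed))
  shared <- p[p$focal_gene %in% focal_expressed &
                p$reference_gene %in% reference_expressed,
              c("focal_gene", "reference_gene"), drop = FALSE]
  rownames(shared) <- NULL
  focal_only <- setdiff(focal_expressed, shared$focal_gene)
  reference_only <- setdiff(reference_expressed, shared$reference_gene)
  structure(list(shared_pairs = shared, focal_only = focal_only,
                 reference_only = reference_only,
                 counts = c(shared = nrow(shared),
                            focal_only = length(focal_only),
                            reference_only = length(reference_only))),
            class = "OverlapPartition")
}

#' @export
print.OverlapPartition <- function(x, ...) {
  cat(sprintf("OverlapPartition: %d shared pairs, %d focal-only, %d reference-only\n",
              x$counts["shared"], x$counts["focal_only"],
              x$counts["reference_only"]))
  invisible(x)
}

#' Read a GMT annotation file
#'
#' Standard tab-separated gene-set format: term id, description, then gene
#' ids. Empty sets are dropped; duplicated term ids are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a \code{description}
#'   attribute (named character vector term -> description).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L], " has no genes")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicated term id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  structure(sets, description = desc)
}

#' Write gene sets as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the term id).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id]))
      descriptions[[id]] else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with \code{K} annotated genes in a
#' background of \code{N} and a query of size \code{n}:
#' \eqn{p = \sum_{i=k}^{\min(K,n)} {K \choose i}{N-K \choose n-i} / {N \choose n}}.
#'
#' @param k observed overlap.
#' @param K annotated genes in background.
#' @param n query size.
#' @param N background size.
#' @return upper-tail probability in (0, 1].
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n), k <= min(K, n))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)} on the sorted scale,
#' mapped back to the input order. Implemented directly (not delegated) so
#' the step-up rule itself is under test.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  scaled <- pvals[o] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(scaled))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Over-representation analysis of a gene set
#'
#' One-sided hypergeometric test per annotation term, with BH adjustment
#' across all tested terms. Annotation sets are intersected with the
#' background before testing; terms with fewer than \code{min_set_size}
#' background genes are skipped as noise (flag-controlled). Terms with zero
#' overlap are still reported.
#'
#' @param query character vector of gene ids, a subset of \code{background}.
#' @param annotation named list of gene sets (see \code{\link{read_gmt}}).
#' @param background character vector of background gene ids.
#' @param min_set_size minimal in-background term size (default 3).
#' @return data.frame with columns \code{term_id}, \code{description},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{q}, sorted by
#'   ascending p.
#' @export
enrich <- function(query, annotation, background, min_set_size = 3L) {
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  if (!length(background)) stop("empty background")
  if (!length(query)) stop("empty query")
  extra <- setdiff(query, background)
  if (length(extra))
    stop("query gene(s) not in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  desc <- attr(annotation, "description")
  sets <- lapply(annotation, function(s) intersect(s, background))
  keep <- lengths(sets) >= min_set_size
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  N <- length(background)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1L))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(term_id = names(sets),
                    description = if (!is.null(desc))
                      unname(desc[names(sets)]) else names(sets),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p), q = unname(q),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
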