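# One-to-one homolog maps from pairwise protein-alignment hit tables
# (12-column tabular format, BLAST outfmt-6 dialect).

#' Parse a tabular alignment hit file
#'
#' Reads tab-separated rows with at least the 12 standard columns (query,
#' subject, identity, length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore); extra columns are ignored and lines starting with
#' \code{#} are skipped.
#'
#' @param path hit file path.
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{pct_identity}, \code{align_len}, \code{evalue}, \code{bitscore}.
#' @export
parse_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(query = character(), subject = character(),
                      pct_identity = numeric(), align_len = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed hit row (fewer than 12 columns) at line ",
         lineno[which(nf < 12L)[1L]])
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  hits <- data.frame(query = get(1L), subject = get(2L),
                     pct_identity = as.numeric(get(3L)),
                     align_len = as.integer(get(4L)),
                     evalue = as.numeric(get(11L)),
                     bitscore = as.numeric(get(12L)),
                     stringsAsFactors = FALSE)
  bad <- !is.finite(hits$bitscore) | !is.finite(hits$evalue) |
    !is.finite(hits$pct_identity)
  if (any(bad))
    stop("malformed numeric field at line ", lineno[which(bad)[1L]])
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "bitscore") %in% colnames(hits)))
  if (is.null(hits$evalue)) hits$evalue <- 0
  if (is.null(hits$pct_identity)) hits$pct_identity <- 100
  if (nrow(hits)) {
    if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
      stop("pct_identity outside [0,100]")
    if (any(hits$evalue < 0)) stop("negative evalue")
    if (any(hits$bitscore <= 0)) stop("bitscore must be positive")
  }
  invisible(hits)
}

# Deterministic hit ordering: best first. Chain: max bitscore, min evalue,
# max identity, lexicographically smallest subject id.
.hit_order <- function(hits) {
  order(-hits$bitscore, hits$evalue, -hits$pct_identity, hits$subject,
        method = "radix")
}

.new_homolog_map <- function(pairs, mode) {
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, mode = mode), class = "HomologMap")
}

#' @export
print.HomologMap <- function(x, ...) {
  cat(sprintf("HomologMap [%s]: %d pairs\n", x$mode, nrow(x$pairs)))
  invisible(x)
}

#' Number of pairs in a homolog map
#' @param x a \code{HomologMap}.
#' @export
length.HomologMap <- function(x) nrow(x$pairs)

#' One-way best-hit homolog map
#'
#' Per query, retains the single hit with the maximal bitscore; ties are
#' broken by minimal evalue, then maximal percent identity, then the
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param hits data.frame of alignment hits (see \code{\link{parse_hits}});
#'   the \code{evalue} and \code{pct_identity} columns default to 0 and 100
#'   when absent.
#' @param exclude_self drop hits whose query equals their subject (shared
#'   id namespace); default \code{TRUE}.
#' @param min_bitscore,max_evalue optional hit filters applied before
#'   selection; no floor/ceiling by default.
#' @return a \code{HomologMap} with \code{mode = "BEST_HIT"}; \code{pairs}
#'   has columns \code{focal_gene}, \code{reference_gene}, \code{bitscore},
#'   \code{evalue}, \code{pct_identity}.
#' @export
best_hit_map <- function(hits, exclude_self = TRUE, min_bitscore = 0,
                         max_evalue = Inf) {
  hits <- validate_hits(hits)
  if (is.null(hits$evalue)) hits$evalue <- 0
  if (is.null(hits$pct_identity)) hits$pct_identity <- 100
  keep <- hits$bitscore >= min_bitscore & hits$evalue <= max_evalue
  if (exclude_self) keep <- keep & hits$query != hits$subject
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits))
    return(.new_homolog_map(data.frame(focal_gene = character(),
                                       reference_gene = character(),
                                       bitscore = numeric(), evalue = numeric(),
                                       pct_identity = numeric(),
                                       stringsAsFactors = FALSE), "BEST_HIT"))
  hits <- hits[.hit_order(hits), , drop = FALSE]
  best <- hits[!duplicated(hits$query), , drop = FALSE]
  best <- best[order(best$query, method = "radix"), , drop = FALSE]
  .new_homolog_map(data.frame(focal_gene = best$query,
                              reference_gene = best$subject,
                              bitscore = best$bitscore, evalue = best$evalue,
                              pct_identity = best$pct_identity,
                              stringsAsFactors = FALSE), "BEST_HIT")
}

#' Restrict a best-hit map to unique (injective) pairs
#'
#' When several focal genes share one reference gene, only the pair with the
#' highest bitscore survives (same tie-break chain as
#' \code{\link{best_hit_map}}, with the smallest focal id as the final
#' tie-break), so the result maps distinct focal genes to distinct reference
#' genes.
#'
#' @param map a \code{HomologMap} in \code{BEST_HIT} mode (a \code{UNIQUE}
#'   map passes through unchanged).
#' @return a \code{HomologMap} with \code{mode = "UNIQUE"}.
#' @export
restrict_unique <- function(map) {
  stopifnot(inherits(map, "HomologMap"))
  if (!map$mode %in% c("BEST_HIT", "UNIQUE"))
    stop("restrict_unique expects a BEST_HIT map")
  p <- map$pairs
  o <- order(-p$bitscore, p$evalue, -p$pct_identity, p$focal_gene,
             method = "radix")
  p <- p[o, , drop = FALSE]
  p <- p[!duplicated(p$reference_gene), , drop = FALSE]
  p <- p[order(p$focal_gene, method = "radix"), , drop = FALSE]
  .new_homolog_map(p, "UNIQUE")
}

#' Reciprocal (bilateral) best-hit map
#'
#' A pair \code{(a, b)} is retained iff \code{b} is \code{a}'s best hit in
#' the forward table and \code{a} is \code{b}'s best hit in the reverse
#' table. The result is injective by construction.
#'
#' @param hits_ab forward hit table (focal queries vs reference subjects).
#' @param hits_ba reverse hit table (reference queries vs focal subjects).
#' @param exclude_self as in \code{\link{best_hit_map}}.
#' @return a \code{HomologMap} with \code{mode = "RECIPROCAL"}.
#' @export
reciprocal_map <- function(hits_ab, hits_ba, exclude_self = TRUE) {
  fwd <- best_hit_map(hits_ab, exclude_self = exclude_self)$pairs
  rev <- best_hit_map(hits_ba, exclude_self = exclude_self)$pairs
  rev_of <- stats::setNames(rev$reference_gene, rev$focal_gene)
  mutual <- !is.na(rev_of[fwd$reference_gene]) &
    rev_of[fwd$reference_gene] == fwd$focal_gene
  mutual[is.na(mutual)] <- FALSE
  .new_homolog_map(fwd[mutual, , drop = FALSE], "RECIPROCAL")
}

#' Read / write homolog map TSV
#'
#' The on-disk format has columns \code{focal_gene}, \code{reference_gene},
#' \code{bitscore}, \code{mode} (plus \code{evalue}, \code{pct_identity}
#' when available).
#'
#' @param map a \code{HomologMap}.
#' @param path TSV path.
#' @return \code{write_homolog_map} returns \code{path} invisibly;
#'   \code{read_homolog_map} returns a \code{HomologMap}.
#' @export
write_homolog_map <- function(map, path) {
  df <- map$pairs
  df$mode <- map$mode
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_homolog_map
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("focal_gene", "reference_gene", "bitscore", "mode")
  if (!all(need %in% colnames(df)))
    stop("homolog map file must have columns ", paste(need, collapse = ", "))
  mode <- unique(df$mode)
  if (length(mode) != 1L) stop("mixed modes in homolog map file")
  if (is.null(df$evalue)) df$evalue <- 0
  if (is.null(df$pct_identity)) df$pct_identity <- 100
  .new_homolog_map(df[, c("focal_gene", "reference_gene", "bitscore",
                          "evalue", "pct_identity")], mode)
}

#' Lookup table focal gene -> reference gene
#' @param map a \code{HomologMap}.
#' @return named character vector.
#' @export
map_pairs <- function(map) {
  stats::setNames(map$pairs$reference_gene, map$pairs$focal_gene)
}
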