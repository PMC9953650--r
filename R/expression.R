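.EXPR_UNITS <- c("COUNTS", "TPM", "FPKM", "RPKM")

#' Expression matrix with unit, species and organ annotation
#'
#' The basic container of the package: a gene x sample matrix of non-negative
#' expression values, tagged with a unit (\code{COUNTS}, \code{TPM},
#' \code{FPKM} or \code{RPKM}), a species identifier and a sample-to-organ
#' label map. FPKM and RPKM are the same numeric scale here and differ only
#' by tag; a warning is emitted by downstream comparisons when they are mixed.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); all entries must be finite and >= 0.
#' @param unit one of \code{"COUNTS"}, \code{"TPM"}, \code{"FPKM"},
#'   \code{"RPKM"}.
#' @param species species identifier string.
#' @param organ_of named character vector mapping every sample id to an organ
#'   label; names must cover \code{colnames(values)}.
#' @return an object of class \code{ExpressionMatrix}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expression_matrix(m, "FPKM", "styela", c(s1 = "endostyle", s2 = "endostyle"))
#' @export
expression_matrix <- function(values, unit, species, organ_of) {
  unit <- match.arg(toupper(unit), .EXPR_UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids")
  if (any(!is.finite(values)))
    stop("non-finite expression values")
  if (any(values < 0))
    stop("negative expression values")
  organ_of <- unlist(organ_of)
  missing_lab <- setdiff(colnames(values), names(organ_of))
  if (length(missing_lab))
    stop("samples without an organ label: ", paste(missing_lab, collapse = ", "))
  organ_of <- organ_of[colnames(values)]
  if (unit == "TPM") {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      stop("TPM columns must sum to 1e6 (rel. tol 1e-6); offending sample(s): ",
           paste(colnames(values)[bad], collapse = ", "))
  }
  structure(list(values = values, unit = unit, species = species,
                 organ_of = organ_of),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$species, x$unit))
  cat("organs:", paste(unique(x$organ_of), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Organ labels of an expression matrix
#' @param m an \code{ExpressionMatrix}.
#' @return character vector of distinct organ labels, in order of appearance.
#' @export
organs <- function(m) unique(unname(m$organ_of))

#' Aggregate replicate samples of each organ
#'
#' Collapses the sample columns of an expression matrix to one column per
#' organ. The study's comparisons operate on per-organ values; when an organ
#' has replicate samples they are combined by \code{rule}: \code{mean}
#' (default, arithmetic mean), \code{any} (maximum, so a gene passes a
#' threshold if any replicate does) or \code{all} (minimum).
#'
#' @param m an \code{ExpressionMatrix}.
#' @param rule aggregation rule, one of \code{"mean"}, \code{"any"},
#'   \code{"all"}.
#' @return numeric matrix, genes x organs.
#' @export
aggregate_organs <- function(m, rule = c("mean", "any", "all")) {
  rule <- match.arg(rule)
  orgs <- organs(m)
  f <- switch(rule, mean = rowMeans,
              any = function(x) apply(x, 1L, max),
              all = function(x) apply(x, 1L, min))
  out <- vapply(orgs, function(o) {
    cols <- which(unname(m$organ_of) == o)
    sub <- m$values[, cols, drop = FALSE]
    if (ncol(sub) == 1L) sub[, 1L] else f(sub)
  }, numeric(nrow(m$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(rownames(m$values), orgs))
  out
}

#' Read an expression table with its organ map
#'
#' Expects a UTF-8 TSV whose first column is \code{gene_id} and whose
#' remaining columns are samples, plus a two-column TSV (\code{sample_id},
#' \code{organ}) assigning every sample to an organ.
#'
#' @param path expression TSV path.
#' @param unit unit tag of the stored values.
#' @param species species identifier.
#' @param organ_map_path organ map TSV path.
#' @return an \code{ExpressionMatrix}.
#' @export
read_expression_table <- function(path, unit, species, organ_map_path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene_id column plus >=1 sample")
  gene_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num))
    stop("non-numeric expression column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  mat <- as.matrix(vals)
  rownames(mat) <- gene_ids
  om <- utils::read.delim(organ_map_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "organ") %in% colnames(om)))
    stop("organ map must have columns sample_id, organ")
  organ_of <- stats::setNames(as.character(om$organ), as.character(om$sample_id))
  expression_matrix(mat, unit, species, organ_of)
}

#' Write an expression table (and optionally its organ map)
#' @param m an \code{ExpressionMatrix}.
#' @param path output TSV path.
#' @param organ_map_path optional path for the sample/organ map TSV.
#' @return invisibly, \code{path}.
#' @export
write_expression_table <- function(m, path, organ_map_path = NULL) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(organ_map_path)) {
    om <- data.frame(sample_id = names(m$organ_of), organ = unname(m$organ_of))
    utils::write.table(om, organ_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene effective lengths
#' @param path TSV with columns \code{gene_id}, \code{length_bp}.
#' @return named numeric vector of lengths in bases.
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(df)))
    stop("lengths file must have columns gene_id, length_bp")
  len <- stats::setNames(as.numeric(df$length_bp), as.character(df$gene_id))
  if (any(!is.finite(len)) || any(len <= 0)) stop("gene lengths must be positive")
  len
}

.check_lengths <- function(m, lengths) {
  missing <- setdiff(rownames(m$values), names(lengths))
  if (length(missing))
    stop("missing gene length(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...")
  L <- lengths[rownames(m$values)]
  if (any(!is.finite(L)) || any(L <= 0)) stop("gene lengths must be positive")
  L
}

#' Convert raw counts to TPM
#'
#' Per sample, \eqn{TPM_g = 10^6 (c_g / L_g) / \sum_j (c_j / L_j)} with
#' \eqn{L_g} the gene's effective transcript (exon) length. Columns of the
#' result sum to 1e6 by construction.
#'
#' @param m \code{ExpressionMatrix} with unit \code{COUNTS}.
#' @param lengths named vector of effective lengths covering all genes of
#'   \code{m}.
#' @return \code{ExpressionMatrix} with unit \code{TPM}.
#' @export
counts_to_tpm <- function(m, lengths) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "COUNTS") stop("counts_to_tpm requires unit COUNTS, got ", m$unit)
  L <- .check_lengths(m, lengths)
  rate <- m$values / L
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero))
    stop("all-zero count column(s): ", paste(colnames(m$values)[zero], collapse = ", "))
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  expression_matrix(tpm, "TPM", m$species, m$organ_of)
}

#' Convert raw counts to FPKM (or RPKM)
#'
#' Per sample, \eqn{FPKM_g = 10^9 c_g / (L_g N)} with \eqn{N} the column
#' total. RPKM is numerically identical and selected by \code{tag}.
#'
#' @inheritParams counts_to_tpm
#' @param tag output unit tag, \code{"FPKM"} (default) or \code{"RPKM"}.
#' @return \code{ExpressionMatrix} with the requested unit tag.
#' @export
counts_to_fpkm <- function(m, lengths, tag = c("FPKM", "RPKM")) {
  tag <- match.arg(tag)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "COUNTS") stop("counts_to_fpkm requires unit COUNTS, got ", m$unit)
  L <- .check_lengths(m, lengths)
  N <- colSums(m$values)
  zero <- N == 0
  if (any(zero))
    stop("all-zero count column(s): ", paste(colnames(m$values)[zero], collapse = ", "))
  fpkm <- sweep(m$values / L, 2L, N, "/") * 1e9
  expression_matrix(fpkm, tag, m$species, m$organ_of)
}

#' Sum single-cell counts into one pseudobulk sample
#'
#' Applies per-gene summation over all cells (the row-wise sum of the
#' cell x gene matrix transposed to genes x cells), yielding a one-sample
#' counts matrix ready for \code{\link{counts_to_tpm}}.
#'
#' @param cells non-negative integer matrix, genes x cell barcodes, with gene
#'   rownames.
#' @param sample_id id for the single output column.
#' @param organ organ label for the output sample.
#' @param species species identifier.
#' @return \code{ExpressionMatrix} with unit \code{COUNTS} and one sample.
#' @export
pseudobulk <- function(cells, sample_id = "pseudobulk", organ = "pseudobulk",
                       species = "unknown") {
  if (!is.matrix(cells) || !is.numeric(cells) || ncol(cells) < 1L || nrow(cells) < 1L)
    stop("`cells` must be a non-empty numeric genes x cells matrix")
  if (is.null(rownames(cells))) stop("`cells` must have gene rownames")
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  sums <- matrix(rowSums(cells), ncol = 1L,
                 dimnames = list(rownames(cells), sample_id))
  expression_matrix(sums, "COUNTS", species,
                    stats::setNames(organ, sample_id))
}

#' Expressed-gene set of an organ (or the whole matrix)
#'
#' A gene is expressed when its aggregated expression over the selected
#' samples is strictly greater than \code{threshold} (the study's cut-offs
#' are phrased "larger than", so boundary values are excluded).
#'
#' @param m an \code{ExpressionMatrix}.
#' @param threshold positive expression cut-off (strict).
#' @param organ organ label to restrict to, or \code{"ALL"} for every sample.
#' @param rule replicate aggregation rule, see \code{\link{aggregate_organs}}.
#' @return character vector of expressed gene ids, in matrix row order.
#' @export
expressed_genes <- function(m, threshold, organ = "ALL",
                            rule = c("mean", "any", "all")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is.numeric(threshold) || threshold < 0)
    stop("`threshold` must be a non-negative number")
  if (identical(organ, "ALL")) {
    cols <- seq_len(ncol(m$values))
  } else {
    if (!organ %in% m$organ_of)
      stop("unknown organ label: ", organ)
    cols <- which(unname(m$organ_of) == organ)
  }
  sub <- m$values[, cols, drop = FALSE]
  agg <- switch(rule,
                mean = rowMeans(sub),
                any = apply(sub, 1L, max),
                all = apply(sub, 1L, min))
  rownames(m$values)[agg > threshold]
}
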