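# Replicate-level quality control: inter-sample correlation and PCA.

#' Inter-sample Pearson correlation
#'
#' Pearson correlation between sample columns, by default on the
#' log(x + pseudocount) scale (the conventional variance-stabilising choice
#' for expression data; raw mode is available). Constant columns have an
#' undefined coefficient and are reported as \code{NA} with a warning.
#'
#' @param m an \code{ExpressionMatrix} with at least two samples.
#' @param log_transform apply \code{log(x + pseudocount)} first (default
#'   \code{TRUE}).
#' @param pseudocount added before the log (default 1).
#' @return symmetric correlation matrix with unit diagonal, samples in
#'   matrix column order.
#' @export
sample_correlation <- function(m, log_transform = TRUE, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2L) stop("need at least two samples")
  x <- if (log_transform) log(m$values + pseudocount) else m$values
  const <- apply(x, 2L, function(col) max(col) == min(col))
  if (any(const))
    warning("constant sample column(s), coefficients undefined: ",
            paste(colnames(x)[const], collapse = ", "))
  cc <- suppressWarnings(stats::cor(x, method = "pearson"))
  idx <- which(!const)
  cc[cbind(idx, idx)] <- 1
  cc
}

#' Principal-component scores of samples
#'
#' Scores come from the singular value decomposition of the gene-centered
#' (optionally log-scaled) matrix with samples as observations. Component
#' signs are fixed by forcing each component's largest-magnitude gene
#' loading positive, so outputs are reproducible across platforms.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param n_components number of components (at most
#'   \code{min(samples - 1, genes)}).
#' @param log_transform apply \code{log(x + 1)} first (default \code{TRUE}).
#' @return list with \code{scores} (samples x components matrix, columns
#'   \code{PC1..PCk}), \code{explained_variance} (non-increasing fractions
#'   summing to <= 1) and \code{loadings} (genes x components).
#' @export
pca_scores <- function(m, n_components = 2L, log_transform = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- if (log_transform) log(m$values + 1) else m$values
  ns <- ncol(x)
  maxc <- min(ns - 1L, nrow(x))
  if (n_components > maxc)
    stop("n_components must be <= min(#samples - 1, #genes) = ", maxc)
  centered <- x - rowMeans(x)           # center each gene across samples
  sv <- svd(t(centered), nu = n_components, nv = n_components)
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  loadings <- sv$v
  dimnames(loadings) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  total_var <- sum(centered^2)
  ev <- if (total_var > 0) sv$d[seq_len(n_components)]^2 / total_var
        else rep(0, n_components)
  list(scores = scores, explained_variance = ev, loadings = loadings)
}
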