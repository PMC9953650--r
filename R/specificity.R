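# Organ-specific gene (OSG) calling: focal-organ genes expressed above a
# floor whose homolog stays below a ceiling in every reference organ.

#' OSG calling configuration
#'
#' Houses the two expression cut-offs of the screen: a candidate is
#' eliminated when its reference homolog exceeds \code{reference_max}
#' (strictly) in any non-excluded reference organ, and survivors must exceed
#' \code{focal_min} (strictly) in the focal organ. Defaults are the study
#' values 0.5 and 1.0 on the FPKM/RPKM scale.
#'
#' @param reference_max expression ceiling in every reference organ
#'   (default 0.5).
#' @param focal_min expression floor in the focal organ (default 1.0).
#' @param excluded_reference_organs reference organ labels exempt from the
#'   ceiling (e.g. the reference species' own copy of the focal organ).
#' @return an \code{osg_config} list.
#' @export
osg_config <- function(reference_max = 0.5, focal_min = 1.0,
                       excluded_reference_organs = character()) {
  if (!is.numeric(reference_max) || reference_max < 0)
    stop("reference_max must be >= 0")
  if (!is.numeric(focal_min) || focal_min <= 0)
    stop("focal_min must be > 0")
  structure(list(reference_max = reference_max, focal_min = focal_min,
                 excluded_reference_organs = as.character(excluded_reference_organs)),
            class = "osg_config")
}

#' Call organ-specific genes against a reference organ panel
#'
#' Candidates are the focal genes present in the homolog map (unmapped genes
#' cannot be screened and are reported separately as \code{unscreened}).
#' A candidate is eliminated if its reference homolog's aggregated expression
#' is strictly above \code{cfg$reference_max} in any reference organ outside
#' \code{cfg$excluded_reference_organs}; of the survivors, those with
#' focal-organ aggregated expression strictly above \code{cfg$focal_min} are
#' the OSGs, ordered by descending focal expression (gene id breaks ties).
#'
#' Focal (FPKM) and reference (RPKM) values are compared on their raw scales;
#' a warning is emitted when the two unit tags differ.
#'
#' @param focal \code{ExpressionMatrix} of the focal species.
#' @param focal_organ organ label of the focal organ in \code{focal}.
#' @param reference \code{ExpressionMatrix} of the reference species' organ
#'   panel.
#' @param map \code{HomologMap}, focal side drawn from \code{focal} gene ids.
#' @param cfg an \code{\link{osg_config}}.
#' @param rule replicate aggregation rule (see
#'   \code{\link{aggregate_organs}}).
#' @return an \code{OSGResult}: list with \code{osgs} (ordered gene ids),
#'   \code{evidence} (data.frame with per-gene focal expression, maximum
#'   reference-organ expression and its organ, reference homolog id),
#'   \code{unscreened} (focal genes without a homolog), \code{counts}
#'   (candidates / eliminated / survivors / osgs) and \code{config}.
#' @export
call_osgs <- function(focal, focal_organ, reference, map,
                      cfg = osg_config(), rule = c("mean", "any", "all")) {
  rule <- match.arg(rule)
  stopifnot(inherits(focal, "ExpressionMatrix"),
            inherits(reference, "ExpressionMatrix"),
            inherits(map, "HomologMap"), inherits(cfg, "osg_config"))
  if (!nrow(map$pairs)) stop("empty homolog map")
  if (!focal_organ %in% focal$organ_of)
    stop("focal organ not present in focal matrix: ", focal_organ)
  if (focal$unit != reference$unit)
    warning("comparing mixed units on raw scales: focal ", focal$unit,
            " vs reference ", reference$unit)

  focal_expr_all <- aggregate_organs(focal, rule)[, focal_organ]
  ref_agg <- aggregate_organs(reference, rule)
  ref_organs <- setdiff(colnames(ref_agg), cfg$excluded_reference_organs)
  if (!length(ref_organs)) stop("no reference organs left after exclusion")
  ref_agg <- ref_agg[, ref_organs, drop = FALSE]

  pairs <- map$pairs[map$pairs$focal_gene %in% rownames(focal$values), ,
                     drop = FALSE]
  unscreened <- setdiff(rownames(focal$values), pairs$focal_gene)
  in_ref <- pairs$reference_gene %in% rownames(ref_agg)
  if (!all(in_ref))
    stop("reference homolog(s) absent from reference matrix: ",
         paste(utils::head(pairs$reference_gene[!in_ref], 5L), collapse = ", "))

  ref_sub <- ref_agg[pairs$reference_gene, , drop = FALSE]
  max_idx <- max.col(ref_sub, ties.method = "first")
  max_ref <- ref_sub[cbind(seq_len(nrow(ref_sub)), max_idx)]
  focal_expr <- focal_expr_all[pairs$focal_gene]

  eliminated <- max_ref > cfg$reference_max
  survivor <- !eliminated
  is_osg <- survivor & focal_expr > cfg$focal_min

  ev <- data.frame(gene_id = pairs$focal_gene,
                   reference_gene = pairs$reference_gene,
                   focal_expr = unname(focal_expr),
                   max_ref_expr = unname(max_ref),
                   ref_organ_of_max = colnames(ref_sub)[max_idx],
                   stringsAsFactors = FALSE)
  ev <- ev[is_osg, , drop = FALSE]
  ev <- ev[order(-ev$focal_expr, ev$gene_id, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL

  structure(list(osgs = ev$gene_id, evidence = ev,
                 unscreened = unscreened,
                 counts = c(candidates = nrow(pairs),
                            eliminated = sum(eliminated),
                            survivors = sum(survivor),
                            osgs = nrow(ev)),
                 config = cfg),
            class = "OSGResult")
}

#' @export
print.OSGResult <- function(x, ...) {
  cat(sprintf("OSGResult: %d OSGs from %d candidates (%d eliminated by reference ceiling, %d unscreened)\n",
              x$counts["osgs"], x$counts["candidates"], x$counts["eliminated"],
              length(x$unscreened)))
  invisible(x)
}

#' Write an OSG result table
#' @param x an \code{OSGResult}.
#' @param path TSV path (columns \code{gene_id}, \code{reference_gene},
#'   \code{focal_expr}, \code{max_ref_expr}, \code{ref_organ_of_max}).
#' @export
write_osg_table <- function(x, path) {
  utils::write.table(x$evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
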