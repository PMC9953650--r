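# Projection of OSGs onto a target species' organ panel (similarity ratio)
# and tissue-enriched-gene similarity index against an organ atlas.

#' Per-organ similarity ratio of projected OSG homologs
#'
#' The denominator is the number of OSGs that have a homolog in the target
#' species; per target organ, the numerator counts mapped homologs whose
#' aggregated expression is strictly above \code{threshold} (TPM > 1 by
#' default). The ratio numerator/denominator is the organ's similarity to
#' the focal organ.
#'
#' @param osgs an \code{OSGResult} (or plain character vector of OSG ids).
#' @param map_to_target \code{HomologMap} whose focal side are OSG ids and
#'   whose reference side are target-species gene ids.
#' @param target \code{ExpressionMatrix} of the target organ panel (a warning
#'   is emitted when its unit is not TPM).
#' @param threshold strict expression cut-off (default 1.0).
#' @param rule replicate aggregation rule.
#' @return a \code{SimilarityProfile}: data.frame with columns \code{organ},
#'   \code{ratio}, \code{expressed_count}, \code{mapped_total}, sorted by
#'   descending ratio; attributes \code{threshold}, \code{unit},
#'   \code{unmapped} (OSGs without a target homolog).
#' @export
similarity_ratio <- function(osgs, map_to_target, target, threshold = 1.0,
                             rule = c("mean", "any", "all")) {
  rule <- match.arg(rule)
  osg_ids <- if (inherits(osgs, "OSGResult")) osgs$osgs else as.character(osgs)
  stopifnot(inherits(map_to_target, "HomologMap"),
            inherits(target, "ExpressionMatrix"))
  if (target$unit != "TPM")
    warning("target matrix unit is ", target$unit, ", expected TPM")
  pairs <- map_to_target$pairs
  pairs <- pairs[pairs$focal_gene %in% osg_ids, , drop = FALSE]
  unmapped <- setdiff(osg_ids, pairs$focal_gene)
  if (!nrow(pairs))
    stop("no OSG has a target homolog: similarity ratio undefined")
  missing <- setdiff(pairs$reference_gene, rownames(target$values))
  if (length(missing))
    stop("target homolog(s) absent from target matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  agg <- aggregate_organs(target, rule)[pairs$reference_gene, , drop = FALSE]
  expressed <- colSums(agg > threshold)
  prof <- data.frame(organ = colnames(agg),
                     ratio = unname(expressed) / nrow(pairs),
                     expressed_count = unname(expressed),
                     mapped_total = nrow(pairs),
                     stringsAsFactors = FALSE)
  prof <- prof[order(-prof$ratio, prof$organ, method = "radix"), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, threshold = threshold, unit = target$unit,
            unmapped = unmapped,
            class = c("SimilarityProfile", "data.frame"))
}

#' Call tissue-enriched genes in a consensus expression atlas
#'
#' A gene is enriched in tissue \code{t} when its expression there is at
#' least \code{fold} times its maximum over all other tissues ("at least a
#' four-fold" makes the boundary inclusive, unlike the strict expression
#' thresholds elsewhere) and at least \code{floor}. When the maximum over
#' the other tissues is zero, the fold condition is vacuous and only the
#' floor applies. Under this max-versus-rest rule a gene is enriched in at
#' most one tissue (for \code{fold} > 1).
#'
#' @param atlas \code{ExpressionMatrix} with one consensus column per tissue
#'   (organ labels are the tissue names; replicate columns per tissue are
#'   averaged first).
#' @param fold enrichment fold (default 4, must be > 1).
#' @param floor minimal expression in the enriched tissue (default 1, atlas
#'   units); guards the zero-background case.
#' @return a \code{TissueEnrichedSets}: named list of gene-id vectors, one
#'   per tissue, with attributes \code{fold} and \code{floor}.
#' @export
call_tissue_enriched <- function(atlas, fold = 4, floor = 1) {
  stopifnot(inherits(atlas, "ExpressionMatrix"))
  if (fold <= 1) stop("`fold` must be > 1")
  vals <- aggregate_organs(atlas, "mean")
  if (ncol(vals) < 2L) stop("atlas needs at least two tissues")
  tissues <- colnames(vals)
  # per gene: max and second max across tissues
  mx_idx <- max.col(vals, ties.method = "first")
  mx <- vals[cbind(seq_len(nrow(vals)), mx_idx)]
  tmp <- vals
  tmp[cbind(seq_len(nrow(vals)), mx_idx)] <- -Inf
  second <- apply(tmp, 1L, max)
  enriched <- mx >= floor & (second <= 0 | mx >= fold * second)
  # ties for the maximum across >=2 tissues can never satisfy fold > 1
  # unless second == 0, which the condition above already handles
  sets <- lapply(tissues, function(t)
    rownames(vals)[enriched & tissues[mx_idx] == t])
  names(sets) <- tissues
  structure(sets, fold = fold, floor = floor,
            class = c("TissueEnrichedSets", "list"))
}

#' Similarity index of a focal organ against atlas tissue-enriched sets
#'
#' Per tissue, the positives are enriched genes whose focal-species homolog
#' is expressed strictly above \code{threshold} (FPKM > 5 by default) in the
#' focal organ. The denominator is either the number of enriched genes with
#' a focal homolog (\code{"MAPPED"}, default) or the full enriched-set size
#' (\code{"FULL_SET"}). Tissues with an empty denominator get \code{NA}, not
#' zero.
#'
#' @param enriched a \code{TissueEnrichedSets} (or named list of gene sets).
#' @param map_to_focal \code{HomologMap} whose focal side are atlas gene ids
#'   and whose reference side are focal-species gene ids.
#' @param focal \code{ExpressionMatrix} of the focal species (a warning is
#'   emitted when its unit is not FPKM).
#' @param focal_organ organ label of the focal organ.
#' @param threshold strict expression cut-off (default 5.0).
#' @param denominator_mode \code{"MAPPED"} or \code{"FULL_SET"}.
#' @param rule replicate aggregation rule.
#' @return a \code{SimilarityIndexProfile}: data.frame with columns
#'   \code{tissue}, \code{index}, \code{positive_count}, \code{denominator},
#'   sorted by descending index (NAs last); attributes \code{threshold} and
#'   \code{denominator_mode}.
#' @export
similarity_index <- function(enriched, map_to_focal, focal, focal_organ,
                             threshold = 5.0,
                             denominator_mode = c("MAPPED", "FULL_SET"),
                             rule = c("mean", "any", "all")) {
  denominator_mode <- match.arg(denominator_mode)
  rule <- match.arg(rule)
  stopifnot(inherits(map_to_focal, "HomologMap"),
            inherits(focal, "ExpressionMatrix"))
  if (focal$unit != "FPKM")
    warning("focal matrix unit is ", focal$unit, ", expected FPKM")
  if (!focal_organ %in% focal$organ_of)
    stop("focal organ not present in focal matrix: ", focal_organ)
  focal_expr <- aggregate_organs(focal, rule)[, focal_organ]
  homolog_of <- map_pairs(map_to_focal)
  rows <- lapply(names(enriched), function(t) {
    genes <- enriched[[t]]
    hom <- homolog_of[genes]
    hom <- hom[!is.na(hom) & hom %in% names(focal_expr)]
    pos <- sum(focal_expr[hom] > threshold)
    denom <- if (denominator_mode == "MAPPED") length(hom) else length(genes)
    data.frame(tissue = t,
               index = if (denom > 0) pos / denom else NA_real_,
               positive_count = pos, denominator = denom,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof <- prof[order(-prof$index, prof$tissue, method = "radix",
                     na.last = TRUE), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, threshold = threshold, denominator_mode = denominator_mode,
            class = c("SimilarityIndexProfile", "data.frame"))
}

#' Write a similarity profile/index TSV
#' @param x a \code{SimilarityProfile} or \code{SimilarityIndexProfile}.
#' @param path TSV path (columns \code{organ_or_tissue},
#'   \code{ratio_or_index}, \code{numerator}, \code{denominator}).
#' @export
write_profile <- function(x, path) {
  df <- data.frame(organ_or_tissue = x[[1L]], ratio_or_index = x[[2L]],
                   numerator = x[[3L]], denominator = x[[4L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
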