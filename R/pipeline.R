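# Orchestration: one config drives OSG calling, target projection, atlas
# index, overlap + enrichment and QC, with a machine-readable run report.

#' Build / load a run configuration
#'
#' Accepts a YAML file path or an equivalent nested list. Required blocks:
#' \code{focal} (path, organ_map, unit, species, organ), \code{reference}
#' (path, organ_map, unit, species), \code{hits} (paths:
#' \code{focal_reference}, optionally \code{reference_focal},
#' \code{focal_target}, \code{atlas_focal}), \code{out_dir}. Optional:
#' \code{target}, \code{atlas} blocks, \code{thresholds} (defaults:
#' reference_max 0.5, focal_min 1, projection 1, index 5, expressed 1,
#' fold 4, floor 1), \code{homolog_mode} (\code{unique} default,
#' \code{best} or \code{reciprocal}), \code{denominator_mode},
#' \code{excluded_reference_organs}, \code{overlap_reference_organ},
#' \code{annotation_gmt}, \code{rule}, \code{seed}.
#'
#' @param x YAML path or list.
#' @return validated \code{run_config} list.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("run config must be a YAML file or a list")
  defaults <- list(reference_max = 0.5, focal_min = 1, projection = 1,
                   index = 5, expressed = 1, fold = 4, floor = 1)
  cfg$thresholds <- utils::modifyList(defaults,
                                      as.list(cfg$thresholds %||% list()))
  cfg$homolog_mode <- cfg$homolog_mode %||% "unique"
  cfg$denominator_mode <- cfg$denominator_mode %||% "MAPPED"
  cfg$rule <- cfg$rule %||% "mean"
  cfg$excluded_reference_organs <-
    as.character(cfg$excluded_reference_organs %||% character())
  for (blk in c("focal", "reference"))
    if (is.null(cfg[[blk]])) stop("run config missing block: ", blk)
  if (is.null(cfg$out_dir)) stop("run config missing out_dir")
  if (is.null(cfg$focal[["organ"]])) stop("run config missing focal$organ")
  if (any(unlist(cfg$thresholds) < 0)) stop("thresholds must be >= 0")
  # every referenced input path must exist before any computation
  paths <- c(cfg$focal$path, cfg$focal$organ_map,
             cfg$reference$path, cfg$reference$organ_map,
             cfg$target$path, cfg$target$organ_map,
             cfg$atlas$path, cfg$atlas$organ_map,
             unlist(cfg$hits), cfg$annotation_gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_block <- function(blk) {
  read_expression_table(blk$path, blk$unit, blk$species %||% "unknown",
                        blk$organ_map)
}

#' Run the full comparison pipeline
#'
#' Executes, in order: input loading, homolog-map construction from the hit
#' tables, OSG calling, target-panel similarity ratios (when a target block
#' is configured), atlas tissue-enrichment and similarity index (when an
#' atlas block is configured), expressed-gene overlap partition (when
#' \code{overlap_reference_organ} is set) with optional over-representation
#' analysis, and replicate QC. Every stage's table is written under
#' \code{out_dir} and a JSON report records input checksums, thresholds,
#' stage counts and the package version. Any stage error aborts with the
#' failing stage named.
#'
#' @param cfg a \code{\link{run_config}} (or YAML path / list coercible to
#'   one).
#' @param verbose log stage progress to stderr.
#' @return the run report, invisibly (also written as
#'   \code{out_dir/report.json}).
#' @export
run_all <- function(cfg, verbose = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  say <- function(...) if (verbose) message("[xorgan] ", ...)
  stage <- "setup"
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("xorgan")),
                 thresholds = cfg$thresholds,
                 homolog_mode = cfg$homolog_mode,
                 denominator_mode = cfg$denominator_mode,
                 rule = cfg$rule)
  run_stage <- function(name, expr) {
    stage <<- name
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline failed in stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  ## inputs ---------------------------------------------------------------
  inputs <- c(focal = cfg$focal$path, reference = cfg$reference$path,
              target = cfg$target$path, atlas = cfg$atlas$path,
              unlist(cfg$hits))
  report$input_md5 <- as.list(tools::md5sum(inputs))
  focal <- run_stage("load_focal", .load_block(cfg$focal))
  reference <- run_stage("load_reference", .load_block(cfg$reference))
  target <- if (!is.null(cfg$target))
    run_stage("load_target", .load_block(cfg$target))
  atlas <- if (!is.null(cfg$atlas))
    run_stage("load_atlas", .load_block(cfg$atlas))

  ## homology -------------------------------------------------------------
  map_fr <- run_stage("homology", {
    fwd <- parse_hits(cfg$hits$focal_reference)
    if (cfg$homolog_mode == "reciprocal") {
      if (is.null(cfg$hits$reference_focal))
        stop("reciprocal mode needs hits$reference_focal")
      reciprocal_map(fwd, parse_hits(cfg$hits$reference_focal))
    } else if (cfg$homolog_mode == "unique") {
      restrict_unique(best_hit_map(fwd))
    } else best_hit_map(fwd)
  })
  write_homolog_map(map_fr, file.path(out, "map_focal_reference.tsv"))
  report$homolog_pairs <- nrow(map_fr$pairs)

  ## specificity ----------------------------------------------------------
  osg <- run_stage("osg", call_osgs(
    focal, cfg$focal[["organ"]], reference, map_fr,
    osg_config(cfg$thresholds$reference_max, cfg$thresholds$focal_min,
               cfg$excluded_reference_organs),
    rule = cfg$rule))
  write_osg_table(osg, file.path(out, "osg.tsv"))
  report$osg <- as.list(osg$counts)
  report$osg$unscreened <- length(osg$unscreened)

  ## projection -----------------------------------------------------------
  if (!is.null(target)) {
    ratio <- run_stage("similarity_ratio", {
      map_ft <- restrict_unique(best_hit_map(parse_hits(cfg$hits$focal_target)))
      similarity_ratio(osg, map_ft, target,
                       threshold = cfg$thresholds$projection,
                       rule = cfg$rule)
    })
    write_profile(ratio, file.path(out, "similarity_ratio.tsv"))
    report$similarity_ratio <- stats::setNames(as.list(ratio$ratio),
                                               ratio$organ)
    report$projection_mapped_total <- ratio$mapped_total[1L]
  }
  if (!is.null(atlas)) {
    enr <- run_stage("tissue_enriched",
                     call_tissue_enriched(atlas, fold = cfg$thresholds$fold,
                                          floor = cfg$thresholds$floor))
    write_gmt(unclass(enr)[lengths(enr) > 0], file.path(out, "enriched_sets.gmt"))
    report$enriched_counts <- as.list(lengths(enr))
    index <- run_stage("similarity_index", {
      map_af <- restrict_unique(best_hit_map(parse_hits(cfg$hits$atlas_focal)))
      similarity_index(enr, map_af, focal, cfg$focal[["organ"]],
                       threshold = cfg$thresholds$index,
                       denominator_mode = cfg$denominator_mode,
                       rule = cfg$rule)
    })
    write_profile(index, file.path(out, "similarity_index.tsv"))
    report$similarity_index <- stats::setNames(as.list(index$index),
                                               index$tissue)
  }

  ## overlap --------------------------------------------------------------
  if (!is.null(cfg$overlap_reference_organ)) {
    part <- run_stage("overlap", {
      fx <- expressed_genes(focal, cfg$thresholds$expressed,
                            cfg$focal[["organ"]], rule = cfg$rule)
      rx <- expressed_genes(reference, cfg$thresholds$expressed,
                            cfg$overlap_reference_organ, rule = cfg$rule)
      inj <- if (map_fr$mode == "BEST_HIT") restrict_unique(map_fr) else map_fr
      partition_expressed(fx, rx, inj)
    })
    utils::write.table(part$shared_pairs,
                       file.path(out, "overlap_shared.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(part$focal_only, file.path(out, "overlap_focal_only.txt"))
    writeLines(part$reference_only,
               file.path(out, "overlap_reference_only.txt"))
    report$overlap <- as.list(part$counts)
    if (!is.null(cfg$annotation_gmt)) {
      enr_tab <- run_stage("enrichment", {
        anno <- read_gmt(cfg$annotation_gmt)
        bg <- intersect(rownames(focal$values), unique(unlist(anno)))
        q <- intersect(part$focal_only, bg)
        if (length(q)) enrich(q, anno, bg) else NULL
      })
      if (!is.null(enr_tab))
        utils::write.table(enr_tab, file.path(out, "enrich_focal_only.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      report$enrichment_terms <- if (is.null(enr_tab)) 0L else nrow(enr_tab)
    }
  }

  ## qc -------------------------------------------------------------------
  if (ncol(focal$values) >= 2L) {
    qc <- run_stage("qc", {
      cc <- sample_correlation(focal)
      k <- min(2L, ncol(focal$values) - 1L, nrow(focal$values))
      list(cor = cc, pca = pca_scores(focal, k))
    })
    utils::write.table(qc$cor, file.path(out, "qc_correlation.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(data.frame(sample = rownames(qc$pca$scores),
                                  qc$pca$scores, check.names = FALSE),
                       file.path(out, "qc_pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$qc_min_correlation <- min(qc$cor, na.rm = TRUE)
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done")
  invisible(report)
}
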