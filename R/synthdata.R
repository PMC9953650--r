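# Synthetic two-species multi-organ datasets with planted ground truth:
# planted OSGs with margins around the calling thresholds, planted per-organ
# expressed fractions in the target panel, planted >=4-fold tissue-enriched
# atlas sets, and alignment hit tables whose best hits recover the true map.

.default_reference_organs <- c("oral_siphon", "atrial_siphon",
  "neural_complex", "heart", "ovary", "pharynx", "stomach",
  "proximal_intestine", "middle_intestine", "distal_intestine", "endostyle")

.default_target_organs <- c("gill", "head_kidney", "brain", "tail", "spleen",
  "skin", "muscle", "liver", "heart", "thymus", "thyroid", "eye")

.default_atlas_tissues <- c("thyroid", "parathyroid", "stomach",
  "salivary_gland", "choroid", "fallopian_tube", "skin", "bone_marrow",
  "retina", "brain", "liver", "lung", "kidney", "heart_muscle",
  "skeletal_muscle", "pancreas", "spleen", "thymus", "testis", "ovary",
  "placenta", "prostate", "colon", "duodenum", "esophagus",
  "urinary_bladder", "adipose_tissue")

#' Simulation configuration
#'
#' Defaults state the simulated world once: a focal species with one organ
#' (three replicates), an 11-organ reference panel whose own copy of the
#' focal organ is exempt from the elimination ceiling, a 12-organ target
#' panel, and a 27-tissue consensus atlas with 50 planted enriched genes per
#' tissue. Planted organ-specific genes carry at least a two-fold margin on
#' either side of the calling thresholds (focal floor 1.0, reference ceiling
#' 0.5), so noiseless recovery is exact and noisy recovery is controlled.
#'
#' @param n_genes_focal,n_genes_reference,n_genes_target gene counts per
#'   species.
#' @param focal_organ focal organ label.
#' @param focal_replicates replicate samples of the focal organ.
#' @param reference_organs,target_organs,atlas_tissues organ/tissue label
#'   vectors.
#' @param excluded_reference_organ reference organ exempt from the OSG
#'   elimination ceiling (the reference species' homologous organ).
#' @param ortholog_fraction fraction of focal genes with a one-to-one
#'   homolog in each partner species.
#' @param n_planted_osgs number of planted organ-specific genes.
#' @param baseline_meanlog,baseline_sdlog log-normal background expression
#'   parameters (FPKM-like scale).
#' @param focal_high_range planted OSG focal expression range (min must
#'   exceed twice the focal floor of 1.0).
#' @param reference_low_max ceiling for planted OSG homologs in
#'   non-excluded reference organs (must stay below half the 0.5 ceiling...
#'   i.e. at most 0.3 by default, strictly below 0.5).
#' @param expressed_fraction_of named vector, target organ -> probability
#'   that a mapped planted-OSG homolog is expressed there.
#' @param n_enriched_per_tissue planted enriched genes per atlas tissue.
#' @param n_atlas_background non-enriched atlas genes.
#' @param enrich_fold_margin planted fold separation (> 4).
#' @param atlas_mapped_fraction fraction of enriched atlas genes with a
#'   focal homolog.
#' @param index_positive_fraction probability that a mapped enriched gene's
#'   focal homolog is expressed above the FPKM 5 index threshold.
#' @param noise_sd multiplicative log-normal noise sd on expression values
#'   (0 = noiseless, the default).
#' @param n_decoys decoy alignment hits per query in emitted hit tables.
#' @param seed integer seed driving every draw through one generator stream.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_genes_focal = 6000L, n_genes_reference = 6000L,
                       n_genes_target = 6000L,
                       focal_organ = "endostyle", focal_replicates = 3L,
                       reference_organs = .default_reference_organs,
                       target_organs = .default_target_organs,
                       atlas_tissues = .default_atlas_tissues,
                       excluded_reference_organ = "endostyle",
                       ortholog_fraction = 0.8,
                       n_planted_osgs = 150L,
                       baseline_meanlog = 1, baseline_sdlog = 1.2,
                       focal_high_range = c(5, 50),
                       reference_low_max = 0.3,
                       expressed_fraction_of = NULL,
                       n_enriched_per_tissue = 50L,
                       n_atlas_background = 600L,
                       enrich_fold_margin = 6,
                       atlas_mapped_fraction = 0.75,
                       index_positive_fraction = 0.5,
                       noise_sd = 0,
                       n_decoys = 3L,
                       seed = 1L) {
  if (is.null(expressed_fraction_of)) {
    expressed_fraction_of <- stats::setNames(
      c(0.70, 0.65, 0.60, 0.30, 0.45, 0.35, 0.25, 0.30, 0.40, 0.50,
        0.55, 0.45)[seq_along(target_organs)], target_organs)
  }
  cfg <- list(n_genes_focal = as.integer(n_genes_focal),
              n_genes_reference = as.integer(n_genes_reference),
              n_genes_target = as.integer(n_genes_target),
              focal_organ = focal_organ,
              focal_replicates = as.integer(focal_replicates),
              reference_organs = reference_organs,
              target_organs = target_organs,
              atlas_tissues = atlas_tissues,
              excluded_reference_organ = excluded_reference_organ,
              ortholog_fraction = ortholog_fraction,
              n_planted_osgs = as.integer(n_planted_osgs),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              focal_high_range = focal_high_range,
              reference_low_max = reference_low_max,
              expressed_fraction_of = expressed_fraction_of,
              n_enriched_per_tissue = as.integer(n_enriched_per_tissue),
              n_atlas_background = as.integer(n_atlas_background),
              enrich_fold_margin = enrich_fold_margin,
              atlas_mapped_fraction = atlas_mapped_fraction,
              index_positive_fraction = index_positive_fraction,
              noise_sd = noise_sd,
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (ortholog_fraction <= 0 || ortholog_fraction > 1)
      stop("ortholog_fraction must lie in (0, 1]")
    if (any(expressed_fraction_of < 0 | expressed_fraction_of > 1))
      stop("expressed fractions must lie in [0, 1]")
    if (!setequal(names(expressed_fraction_of), target_organs))
      stop("expressed_fraction_of must be named by the target organs")
    # margins must respect the canonical calling thresholds (focal floor 1.0,
    # reference ceiling 0.5, projection threshold 1.0, fold 4)
    if (focal_high_range[1L] <= 2 * 1.0)
      stop("focal_high_range minimum must exceed 2x the focal floor (1.0)")
    if (reference_low_max >= 0.5)
      stop("reference_low_max must stay strictly below the 0.5 ceiling")
    if (enrich_fold_margin <= 4)
      stop("enrich_fold_margin must exceed the 4-fold calling rule")
    n_mapped <- floor(ortholog_fraction * min(n_genes_focal, n_genes_reference))
    if (n_planted_osgs > n_mapped)
      stop("n_planted_osgs exceeds the number of mapped focal genes")
    if (!excluded_reference_organ %in% reference_organs)
      stop("excluded_reference_organ must be a reference organ label")
    if (length(target_organs) < 1L || length(atlas_tissues) < 2L)
      stop("need >=1 target organ and >=2 atlas tissues")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  invisible(cfg)
}

.lnoise <- function(x, sd) {
  if (sd == 0) return(x)
  x * exp(stats::rnorm(length(x), 0, sd))
}

#' Simulate a full two-species comparison dataset
#'
#' Emits, deterministically for a fixed seed: a focal-species expression
#' matrix (FPKM, one organ, replicated), a reference organ panel (RPKM), a
#' target organ panel (TPM, columns summing to 1e6 exactly), a consensus
#' atlas, alignment hit tables in both directions for the focal/reference
#' link plus one-way tables for the target and atlas links, and a
#' \code{SimTruth} record of everything planted.
#'
#' Planted OSGs exceed the focal floor with margin and stay below the
#' reference ceiling with margin in all non-excluded reference organs (the
#' excluded organ is planted high, so recovery genuinely requires the
#' exclusion). Non-planted mapped genes violate one rule each: half are
#' focal-low (<= 0.5), half reference-high (>= 1 in some organ). Mapped
#' planted-OSG homologs in each target organ are expressed (well above
#' TPM 1) independently with the configured per-organ probability, and the
#' realized draw is recorded. Atlas enriched sets satisfy the four-fold rule
#' at the configured margin; the atlas itself is noise-free so planted sets
#' are recovered exactly at any noise level.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{focal}, \code{reference}, \code{target},
#'   \code{atlas} (\code{ExpressionMatrix}), \code{hits} (list of hit
#'   data.frames: \code{focal_reference}, \code{reference_focal},
#'   \code{focal_target}, \code{atlas_focal}) and \code{truth}
#'   (\code{SimTruth}).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  focal_genes <- sprintf("SCg%05d", seq_len(cfg$n_genes_focal))
  ref_genes <- sprintf("CRg%05d", seq_len(cfg$n_genes_reference))
  tgt_genes <- sprintf("DRg%05d", seq_len(cfg$n_genes_target))

  ## --- orthology: focal <-> reference -----------------------------------
  n_fr <- floor(cfg$ortholog_fraction *
                  min(cfg$n_genes_focal, cfg$n_genes_reference))
  map_fr <- data.frame(
    focal_gene = sample(focal_genes, n_fr),
    reference_gene = sample(ref_genes, n_fr),
    stringsAsFactors = FALSE)

  planted <- sort(sample(map_fr$focal_gene, cfg$n_planted_osgs))
  nonplanted <- setdiff(map_fr$focal_gene, planted)
  focal_low <- sample(nonplanted, floor(length(nonplanted) / 2))
  ref_high <- setdiff(nonplanted, focal_low)

  ## --- orthology: focal -> target (all planted OSGs mapped) -------------
  n_ft <- min(floor(cfg$ortholog_fraction * cfg$n_genes_focal),
              cfg$n_genes_target)
  ft_focal <- union(planted,
                    sample(focal_genes, max(n_ft - length(planted), 0L)))
  ft_focal <- ft_focal[seq_len(min(length(ft_focal), cfg$n_genes_target))]
  map_ft <- data.frame(focal_gene = ft_focal,
                       reference_gene = sample(tgt_genes, length(ft_focal)),
                       stringsAsFactors = FALSE)

  ## --- focal matrix (FPKM, one organ, replicates) -----------------------
  base_focal <- stats::rlnorm(cfg$n_genes_focal, cfg$baseline_meanlog,
                              cfg$baseline_sdlog)
  names(base_focal) <- focal_genes
  base_focal[planted] <- stats::runif(length(planted),
                                      cfg$focal_high_range[1L],
                                      cfg$focal_high_range[2L])
  base_focal[focal_low] <- stats::runif(length(focal_low), 0, 0.5)

  ## --- atlas + atlas -> focal map ---------------------------------------
  n_enr <- cfg$n_enriched_per_tissue * length(cfg$atlas_tissues)
  atlas_genes <- sprintf("HSg%05d", seq_len(n_enr + cfg$n_atlas_background))
  enr_ids <- atlas_genes[seq_len(n_enr)]
  enriched_sets <- split(enr_ids,
                         rep(cfg$atlas_tissues, each = cfg$n_enriched_per_tissue))
  enriched_sets <- enriched_sets[cfg$atlas_tissues]
  atlas_vals <- matrix(0, nrow = length(atlas_genes),
                       ncol = length(cfg$atlas_tissues),
                       dimnames = list(atlas_genes, cfg$atlas_tissues))
  for (ti in seq_along(cfg$atlas_tissues)) {
    g <- enriched_sets[[ti]]
    v <- stats::runif(length(g), 20, 60)
    others <- matrix(stats::runif(length(g) * (ncol(atlas_vals) - 1L)),
                     nrow = length(g)) * (v / cfg$enrich_fold_margin)
    atlas_vals[g, -ti] <- others
    atlas_vals[g, ti] <- v
  }
  bg_ids <- atlas_genes[-seq_len(n_enr)]
  if (length(bg_ids)) {
    b <- stats::rlnorm(length(bg_ids), cfg$baseline_meanlog,
                       cfg$baseline_sdlog)
    atlas_vals[bg_ids, ] <- b * matrix(
      stats::runif(length(bg_ids) * ncol(atlas_vals), 0.5, 1.5),
      nrow = length(bg_ids))
  }
  atlas <- expression_matrix(atlas_vals, "FPKM", "homo_sapiens",
                             stats::setNames(cfg$atlas_tissues,
                                             cfg$atlas_tissues))

  # focal homologs of enriched atlas genes come from focal genes whose
  # planted focal value is unconstrained (not planted OSGs, not focal-low)
  pool_af <- setdiff(focal_genes, c(planted, focal_low))
  n_af <- floor(cfg$atlas_mapped_fraction * n_enr)
  if (n_af > length(pool_af))
    stop("not enough unconstrained focal genes for the atlas map; ",
         "reduce atlas_mapped_fraction or n_enriched_per_tissue")
  mapped_enr <- sort(sample(enr_ids, n_af))
  map_af <- data.frame(focal_gene = mapped_enr,
                       reference_gene = sample(pool_af, n_af),
                       stringsAsFactors = FALSE)
  # plant the focal expression of those homologs around the FPKM 5 index cut
  idx_pos <- stats::runif(n_af) < cfg$index_positive_fraction
  base_focal[map_af$reference_gene[idx_pos]] <-
    stats::runif(sum(idx_pos), 10, 50)
  base_focal[map_af$reference_gene[!idx_pos]] <-
    stats::runif(sum(!idx_pos), 0, 2)
  realized_index_positive <- split(map_af$focal_gene[idx_pos],
    factor(rep(cfg$atlas_tissues, each = cfg$n_enriched_per_tissue),
           levels = cfg$atlas_tissues)[match(map_af$focal_gene[idx_pos],
                                             enr_ids)])

  focal_samples <- paste0(cfg$focal_organ, "_rep", seq_len(cfg$focal_replicates))
  focal_vals <- matrix(rep(base_focal, cfg$focal_replicates),
                       ncol = cfg$focal_replicates,
                       dimnames = list(focal_genes, focal_samples))
  focal_vals[] <- .lnoise(focal_vals, cfg$noise_sd)
  focal <- expression_matrix(focal_vals, "FPKM", "styela_clava",
                             stats::setNames(rep(cfg$focal_organ,
                                                 cfg$focal_replicates),
                                             focal_samples))

  ## --- reference matrix (RPKM, one sample per organ) --------------------
  ref_vals <- matrix(stats::rlnorm(cfg$n_genes_reference *
                                     length(cfg$reference_organs),
                                   cfg$baseline_meanlog, cfg$baseline_sdlog),
                     nrow = cfg$n_genes_reference,
                     dimnames = list(ref_genes, cfg$reference_organs))
  ref_of <- stats::setNames(map_fr$reference_gene, map_fr$focal_gene)
  nonexcl <- setdiff(cfg$reference_organs, cfg$excluded_reference_organ)
  # planted OSG partners: low everywhere except the excluded organ, which is
  # planted high so that recovery requires the exclusion
  pp <- ref_of[planted]
  ref_vals[pp, nonexcl] <- stats::runif(length(pp) * length(nonexcl), 0,
                                        cfg$reference_low_max)
  ref_vals[pp, cfg$excluded_reference_organ] <-
    stats::runif(length(pp), 1, 10)
  # reference-high decoys: at least one non-excluded organ clearly above 0.5
  rh <- ref_of[ref_high]
  hot_organ <- sample(nonexcl, length(rh), replace = TRUE)
  ref_vals[cbind(match(rh, ref_genes),
                 match(hot_organ, cfg$reference_organs))] <-
    stats::runif(length(rh), 1, 5)
  ref_vals[] <- .lnoise(ref_vals, cfg$noise_sd)
  reference <- expression_matrix(ref_vals, "RPKM", "ciona_robusta",
                                 stats::setNames(cfg$reference_organs,
                                                 cfg$reference_organs))

  ## --- target matrix (TPM, exact column sums) ---------------------------
  tgt_vals <- matrix(stats::rlnorm(cfg$n_genes_target *
                                     length(cfg$target_organs),
                                   5, cfg$baseline_sdlog),
                     nrow = cfg$n_genes_target,
                     dimnames = list(tgt_genes, cfg$target_organs))
  tgt_of <- stats::setNames(map_ft$reference_gene, map_ft$focal_gene)
  osg_tgt <- tgt_of[planted]
  realized_expressed <- vector("list", length(cfg$target_organs))
  names(realized_expressed) <- cfg$target_organs
  for (org in cfg$target_organs) {
    f <- cfg$expressed_fraction_of[[org]]
    on <- stats::runif(length(osg_tgt)) < f
    tgt_vals[osg_tgt[on], org] <- stats::runif(sum(on), 5, 50)
    tgt_vals[osg_tgt[!on], org] <- stats::runif(sum(!on), 0.01, 0.2)
    realized_expressed[[org]] <- unname(names(osg_tgt)[on])  # focal OSG ids
  }
  tgt_vals[] <- .lnoise(tgt_vals, cfg$noise_sd)
  # renormalize the background genes so each column sums to exactly 1e6
  # while the planted homolog values stay untouched
  planted_rows <- match(osg_tgt, tgt_genes)
  for (j in seq_len(ncol(tgt_vals))) {
    planted_sum <- sum(tgt_vals[planted_rows, j])
    bg_sum <- sum(tgt_vals[-planted_rows, j])
    tgt_vals[-planted_rows, j] <- tgt_vals[-planted_rows, j] *
      (1e6 - planted_sum) / bg_sum
  }
  target <- expression_matrix(tgt_vals, "TPM", "danio_rerio",
                              stats::setNames(cfg$target_organs,
                                              cfg$target_organs))

  ## --- hit tables --------------------------------------------------------
  hits <- list(
    focal_reference = simulate_hits(map_fr, cfg$n_decoys,
                                    subject_pool = ref_genes),
    reference_focal = simulate_hits(
      data.frame(focal_gene = map_fr$reference_gene,
                 reference_gene = map_fr$focal_gene,
                 stringsAsFactors = FALSE),
      cfg$n_decoys, subject_pool = focal_genes),
    focal_target = simulate_hits(map_ft, cfg$n_decoys,
                                 subject_pool = tgt_genes),
    atlas_focal = simulate_hits(map_af, cfg$n_decoys,
                                subject_pool = focal_genes))

  truth <- structure(list(
    planted_osg_ids = planted,
    map_focal_reference = map_fr,
    map_focal_target = map_ft,
    map_atlas_focal = map_af,
    expressed_fraction_of = cfg$expressed_fraction_of,
    realized_expressed = realized_expressed,
    enriched_sets = enriched_sets,
    realized_index_positive = realized_index_positive,
    excluded_reference_organ = cfg$excluded_reference_organ,
    config = cfg), class = "SimTruth")

  list(focal = focal, reference = reference, target = target, atlas = atlas,
       hits = hits, truth = truth)
}

#' Fabricate alignment hit tables around a known truth map
#'
#' Every true pair is emitted with the highest bitscore among its query's
#' hits; decoy hits (random subjects) get strictly lower bitscores and
#' larger e-values, so \code{\link{best_hit_map}} on the output recovers the
#' truth map exactly.
#'
#' @param true_map data.frame with columns \code{focal_gene} (query) and
#'   \code{reference_gene} (subject), or \code{query}/\code{subject}.
#' @param n_decoys decoy hits per query.
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   stream (as inside \code{\link{simulate_dataset}}).
#' @param subject_pool subject ids decoys are drawn from (defaults to the
#'   truth map's subjects).
#' @return hit data.frame as returned by \code{\link{parse_hits}}.
#' @export
simulate_hits <- function(true_map, n_decoys = 0L, seed = NULL,
                          subject_pool = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (all(c("query", "subject") %in% colnames(true_map)))
    true_map <- data.frame(focal_gene = true_map$query,
                           reference_gene = true_map$subject,
                           stringsAsFactors = FALSE)
  nq <- nrow(true_map)
  if (is.null(subject_pool)) subject_pool <- unique(true_map$reference_gene)
  true_bit <- stats::runif(nq, 200, 500)
  rows <- data.frame(query = true_map$focal_gene,
                     subject = true_map$reference_gene,
                     pct_identity = stats::runif(nq, 60, 99),
                     align_len = sample(100:900, nq, replace = TRUE),
                     evalue = 10^-stats::runif(nq, 50, 180),
                     bitscore = true_bit,
                     stringsAsFactors = FALSE)
  if (n_decoys > 0L && nq > 0L && length(subject_pool) > 1L) {
    nd <- nq * n_decoys
    qi <- rep(seq_len(nq), each = n_decoys)
    # decoys sampled with replacement; a decoy duplicating its query's true
    # subject is harmless (lower bitscore) and mimics secondary HSPs
    decoys <- data.frame(query = true_map$focal_gene[qi],
                         subject = sample(subject_pool, nd, replace = TRUE),
                         pct_identity = stats::runif(nd, 30, 80),
                         align_len = sample(50:600, nd, replace = TRUE),
                         evalue = 10^-stats::runif(nd, 5, 40),
                         bitscore = true_bit[qi] * stats::runif(nd, 0.4, 0.95),
                         stringsAsFactors = FALSE)
    rows <- rbind(rows, decoys)
  }
  rownames(rows) <- NULL
  rows
}

#' Write a hit table in 12-column tabular alignment format
#' @param hits hit data.frame (six retained fields).
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(hits$query, hits$subject,
                   sprintf("%.3f", hits$pct_identity), hits$align_len,
                   0L, 0L, 1L, hits$align_len, 1L, hits$align_len,
                   format(hits$evalue, scientific = TRUE, digits = 3),
                   sprintf("%.1f", hits$bitscore))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits the four expression matrices (with organ maps), the four hit
#' tables, the planted enriched sets as GMT, and \code{truth.json}.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_expression_table(sim$focal, p("focal.tsv"), p("focal_organs.tsv"))
  write_expression_table(sim$reference, p("reference.tsv"),
                         p("reference_organs.tsv"))
  write_expression_table(sim$target, p("target.tsv"), p("target_organs.tsv"))
  write_expression_table(sim$atlas, p("atlas.tsv"), p("atlas_organs.tsv"))
  write_hits(sim$hits$focal_reference, p("hits_focal_reference.tsv"))
  write_hits(sim$hits$reference_focal, p("hits_reference_focal.tsv"))
  write_hits(sim$hits$focal_target, p("hits_focal_target.tsv"))
  write_hits(sim$hits$atlas_focal, p("hits_atlas_focal.tsv"))
  write_gmt(sim$truth$enriched_sets, p("enriched_truth.gmt"))
  truth <- unclass(sim$truth)
  truth$config <- NULL
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate a negative-binomial count matrix with gene lengths
#'
#' Convenience generator for the COUNTS pathway (unit-conversion and
#' pseudobulk testing): counts are negative-binomial around a log-normal
#' per-gene mean, lengths uniform in [300, 5000].
#'
#' @param n_genes,n_samples dimensions.
#' @param mu_meanlog,mu_sdlog log-normal mean parameters.
#' @param size negative-binomial dispersion (size parameter).
#' @param organ organ label applied to all samples.
#' @param seed optional integer seed.
#' @return list with \code{counts} (an \code{ExpressionMatrix}, unit
#'   COUNTS) and \code{lengths} (named vector).
#' @export
simulate_counts <- function(n_genes = 200L, n_samples = 4L, mu_meanlog = 3,
                            mu_sdlog = 1, size = 10, organ = "organ",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  mu <- stats::rlnorm(n_genes, mu_meanlog, mu_sdlog)
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = size),
                   nrow = n_genes, dimnames = list(genes, samples))
  # guard the all-zero-column degenerate case
  zero <- colSums(counts) == 0
  counts[1L, zero] <- 1L
  m <- expression_matrix(counts * 1.0, "COUNTS", "sim",
                         stats::setNames(rep(organ, n_samples), samples))
  lengths <- stats::setNames(sample(300:5000, n_genes, replace = TRUE), genes)
  list(counts = m, lengths = lengths)
}
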