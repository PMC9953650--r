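# The planted-truth generator. Small configs keep runtimes low; the
# full-size defaults are exercised once in the acceptance suite.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_genes_focal = 600, n_genes_reference = 600,
             n_genes_target = 600, n_planted_osgs = 40,
             atlas_tissues = paste0("T", 1:5), n_enriched_per_tissue = 10,
             n_atlas_background = 100, seed = seed, ...)
}

test_that("sim_config validates margins against the calling thresholds", {
  expect_error(small_cfg(focal_high_range = c(1.5, 50)), "focal_high_range")
  expect_error(small_cfg(reference_low_max = 0.6), "reference_low_max")
  expect_error(small_cfg(enrich_fold_margin = 3), "enrich_fold_margin")
  expect_error(small_cfg(ortholog_fraction = 0), "ortholog_fraction")
  expect_error(small_cfg(n_planted_osgs = 1e5), "n_planted_osgs")
  expect_error(small_cfg(excluded_reference_organ = "nope"),
               "excluded_reference_organ")
})

test_that("fixed seeds reproduce; different seeds differ", {
  s1 <- simulate_dataset(small_cfg(seed = 4))
  s2 <- simulate_dataset(small_cfg(seed = 4))
  expect_identical(s1, s2)
  s3 <- simulate_dataset(small_cfg(seed = 5))
  expect_false(identical(s1$truth$realized_expressed,
                         s3$truth$realized_expressed))
})

test_that("matrices carry the stated units and TPM columns sum exactly", {
  sim <- simulate_dataset(small_cfg(seed = 2, noise_sd = 0.2))
  expect_identical(sim$focal$unit, "FPKM")
  expect_identical(sim$reference$unit, "RPKM")
  expect_identical(sim$target$unit, "TPM")
  expect_true(all(abs(colSums(sim$target$values) - 1e6) < 1))
  expect_equal(length(organs(sim$reference)), 11L)
  expect_equal(length(organs(sim$target)), 12L)
})

test_that("noiseless planted OSGs are recovered exactly through the hits", {
  for (seed in c(3, 17)) {
    sim <- simulate_dataset(small_cfg(seed = seed))
    map <- restrict_unique(best_hit_map(sim$hits$focal_reference))
    res <- suppressWarnings(call_osgs(
      sim$focal, "endostyle", sim$reference, map,
      osg_config(excluded_reference_organs =
                   sim$truth$excluded_reference_organ)))
    expect_setequal(res$osgs, sim$truth$planted_osg_ids)
    # without the exclusion the planted-high excluded organ blocks recovery
    res_noex <- suppressWarnings(call_osgs(sim$focal, "endostyle",
                                           sim$reference, map, osg_config()))
    expect_length(res_noex$osgs, 0L)
  }
})

test_that("expressed_fraction 1 forces a similarity ratio of exactly 1", {
  fr <- stats::setNames(c(1, rep(0.5, 11)),
    c("gill", "head_kidney", "brain", "tail", "spleen", "skin", "muscle",
      "liver", "heart", "thymus", "thyroid", "eye"))
  sim <- simulate_dataset(small_cfg(seed = 6, expressed_fraction_of = fr))
  map_ft <- restrict_unique(best_hit_map(sim$hits$focal_target))
  prof <- similarity_ratio(sim$truth$planted_osg_ids, map_ft, sim$target)
  expect_equal(prof$ratio[prof$organ == "gill"], 1.0)
  # every organ's ratio equals its realized fraction exactly (noiseless)
  for (o in prof$organ)
    expect_equal(prof$ratio[prof$organ == o],
                 length(sim$truth$realized_expressed[[o]]) /
                   length(sim$truth$planted_osg_ids))
})

test_that("planted enriched sets are recovered exactly from the atlas", {
  sim <- simulate_dataset(small_cfg(seed = 8, noise_sd = 0.3))
  sets <- call_tissue_enriched(sim$atlas)
  expect_equal(lapply(sets, sort), lapply(sim$truth$enriched_sets, sort),
               ignore_attr = TRUE)
})

test_that("simulate_hits round-trips the truth map through best_hit_map", {
  set.seed(10)
  tm <- data.frame(focal_gene = sprintf("q%02d", 1:20),
                   reference_gene = sprintf("s%02d", sample(1:50, 20)))
  for (nd in c(0L, 5L, 10L)) {
    hits <- simulate_hits(tm, n_decoys = nd, seed = 100 + nd,
                          subject_pool = sprintf("s%02d", 1:50))
    expect_equal(nrow(hits), 20L * (1L + nd))
    got <- best_hit_map(hits)$pairs
    expect_equal(got$reference_gene[match(tm$focal_gene, got$focal_gene)],
                 tm$reference_gene)
  }
  # reciprocal tables for a symmetric truth recover it
  rev_tm <- data.frame(focal_gene = tm$reference_gene,
                       reference_gene = tm$focal_gene)
  rm <- reciprocal_map(simulate_hits(tm, 4, seed = 1,
                                     subject_pool = sprintf("s%02d", 1:50)),
                       simulate_hits(rev_tm, 4, seed = 2,
                                     subject_pool = sprintf("q%02d", 1:20)))
  expect_setequal(paste(rm$pairs$focal_gene, rm$pairs$reference_gene),
                  paste(tm$focal_gene, tm$reference_gene))
})

test_that("hit tables round-trip through the 12-column format", {
  tm <- data.frame(focal_gene = c("a", "b"), reference_gene = c("X", "Y"))
  hits <- simulate_hits(tm, 2, seed = 3, subject_pool = c("X", "Y", "Z"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- parse_hits(f)
  expect_equal(back$query, hits$query)
  expect_equal(back$subject, hits$subject)
  expect_equal(back$bitscore, round(hits$bitscore, 1))
})

test_that("write_dataset emits a loadable, consistent directory", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(seed = 12))
  write_dataset(sim, dir)
  focal <- read_expression_table(file.path(dir, "focal.tsv"), "FPKM",
                                 "styela_clava",
                                 file.path(dir, "focal_organs.tsv"))
  expect_equal(focal$values, sim$focal$values, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$planted_osg_ids, sim$truth$planted_osg_ids)
  gmt <- read_gmt(file.path(dir, "enriched_truth.gmt"))
  expect_equal(unclass(gmt), sim$truth$enriched_sets, ignore_attr = TRUE)
})
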