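# Similarity ratio, tissue-enrichment calling and similarity index.

tpm_matrix <- function(vals) {
  # pad with one filler gene so every column sums to exactly 1e6
  filler <- 1e6 - colSums(vals)
  stopifnot(all(filler > 0))
  rbind(vals, filler = filler)
}

test_that("similarity_ratio counts strict exceedances over mapped OSGs", {
  set.seed(1)
  n <- 100
  osg_ids <- sprintf("f%03d", 1:n)
  tgt_ids <- sprintf("t%03d", 1:n)
  pairs <- data.frame(query = osg_ids, subject = tgt_ids, pct_identity = 90,
                      align_len = 100L, evalue = 1e-30,
                      bitscore = runif(n, 100, 200))
  vals <- cbind(gill = c(runif(72, 2, 50), runif(28, 0, 0.5)),
                liver = rep(0.2, n),
                brain = runif(n, 2, 50))
  rownames(vals) <- tgt_ids
  target <- make_expr(tpm_matrix(vals), "TPM")
  prof <- similarity_ratio(osg_ids, best_hit_map(pairs), target)
  expect_equal(prof$ratio[prof$organ == "gill"], 0.72)
  expect_equal(prof$ratio[prof$organ == "brain"], 1.0)
  expect_equal(prof$ratio[prof$organ == "liver"], 0.0)
  expect_true(all(prof$mapped_total == n))
  expect_equal(prof$expressed_count / prof$mapped_total, prof$ratio)

  # antitone in threshold
  prof_hi <- similarity_ratio(osg_ids, best_hit_map(pairs), target,
                              threshold = 10)
  expect_true(all(prof_hi$ratio[order(prof_hi$organ)] <=
                    prof$ratio[order(prof$organ)]))

  # unmapped OSGs excluded from the denominator, reported in attributes
  prof2 <- similarity_ratio(c(osg_ids, "fX"), best_hit_map(pairs), target)
  expect_true(all(prof2$mapped_total == n))
  expect_identical(attr(prof2, "unmapped"), "fX")

  expect_error(similarity_ratio("unmapped_gene", best_hit_map(pairs), target),
               "no OSG")
})

test_that("similarity_ratio matches a brute-force per-organ count", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:60, 1)
    osg_ids <- sprintf("f%03d", 1:n); tgt_ids <- sprintf("t%03d", 1:n)
    pairs <- data.frame(query = osg_ids, subject = tgt_ids,
                        pct_identity = 90, align_len = 100L, evalue = 1e-30,
                        bitscore = runif(n, 100, 200))
    vals <- matrix(rlnorm(n * 3, 0, 1.5), n,
                   dimnames = list(tgt_ids, c("oA", "oB", "oC")))
    target <- make_expr(tpm_matrix(vals), "TPM")
    prof <- similarity_ratio(osg_ids, best_hit_map(pairs), target)
    for (o in c("oA", "oB", "oC")) {
      cnt <- 0L
      for (g in tgt_ids) if (vals[g, o] > 1) cnt <- cnt + 1L
      expect_equal(prof$expressed_count[prof$organ == o], cnt)
      expect_equal(prof$ratio[prof$organ == o], cnt / n)
    }
  }
})

test_that("call_tissue_enriched applies the inclusive four-fold rule", {
  vals <- rbind(g_boundary = c(40, 10, 5),    # exactly 4x -> enriched (inclusive)
                g_below    = c(39, 10, 1),    # 3.9x -> nowhere
                g_zero     = c(2, 0, 0),      # zero background: floor only
                g_flat     = c(7, 7, 7))
  colnames(vals) <- c("T1", "T2", "T3")
  atlas <- make_expr(vals)
  sets <- call_tissue_enriched(atlas)
  expect_setequal(sets$T1, c("g_boundary", "g_zero"))
  expect_length(sets$T2, 0)
  expect_length(sets$T3, 0)

  # floor 5 removes the zero-background gene
  sets5 <- call_tissue_enriched(atlas, floor = 5)
  expect_identical(sets5$T1, "g_boundary")

  # disjoint across tissues by the max-versus-rest rule
  expect_equal(anyDuplicated(unlist(sets)), 0L)

  # nested under a larger fold
  set.seed(3)
  rmat <- matrix(rlnorm(200 * 5, 2, 1.5), 200,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("T", 1:5)))
  ratlas <- make_expr(rmat)
  s4 <- call_tissue_enriched(ratlas, fold = 4)
  s8 <- call_tissue_enriched(ratlas, fold = 8)
  for (t in names(s4)) expect_true(all(s8[[t]] %in% s4[[t]]))

  expect_error(call_tissue_enriched(make_expr(vals[, 1, drop = FALSE])),
               "two tissues")
  expect_error(call_tissue_enriched(atlas, fold = 1), "fold")
})

test_that("similarity_index honours both denominator conventions", {
  # 20 enriched genes, 15 mapped, 9 with focal expression above 5
  enr <- list(thyroid = sprintf("h%02d", 1:20))
  mapped <- sprintf("h%02d", 1:15)
  pairs <- data.frame(query = mapped, subject = sprintf("f%02d", 1:15),
                      pct_identity = 90, align_len = 100L, evalue = 1e-30,
                      bitscore = 100 + 1:15)
  focal_vals <- c(runif(9, 6, 50), runif(6, 0, 5))
  focal <- make_expr(matrix(focal_vals, ncol = 1L,
                            dimnames = list(sprintf("f%02d", 1:15), "e1")),
                     organ_of = c(e1 = "endostyle"))
  si <- similarity_index(enr, best_hit_map(pairs), focal, "endostyle")
  expect_equal(si$index, 0.60)
  expect_equal(si$denominator, 15L)
  si_full <- similarity_index(enr, best_hit_map(pairs), focal, "endostyle",
                              denominator_mode = "FULL_SET")
  expect_equal(si_full$index, 0.45)
  expect_equal(si_full$denominator, 20L)

  # extremes and the empty-denominator convention
  all_on <- focal; all_on$values[] <- 100
  expect_equal(similarity_index(enr, best_hit_map(pairs), all_on,
                                "endostyle")$index, 1.0)
  all_off <- focal; all_off$values[] <- 0
  expect_equal(similarity_index(enr, best_hit_map(pairs), all_off,
                                "endostyle")$index, 0.0)
  enr2 <- c(enr, list(ghost = "h99"))  # no mapped homolog
  si2 <- similarity_index(enr2, best_hit_map(pairs), focal, "endostyle")
  expect_true(is.na(si2$index[si2$tissue == "ghost"]))

  # antitone in threshold
  lo <- similarity_index(enr, best_hit_map(pairs), focal, "endostyle",
                         threshold = 1)
  expect_true(si$index <= lo$index)
})
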