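# Unit handling, IO, pseudobulk and expressed-gene extraction.

test_that("expression table round-trips through TSV with organ labels", {
  m <- make_expr(matrix(c(1.5, 0.2, 3, 4), 2,
                        dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                 organ_of = c(s1 = "endostyle", s2 = "gill"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  om <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, tsv, om)
  back <- read_expression_table(tsv, "FPKM", "sp", om)
  expect_equal(back$values, m$values)
  expect_equal(back$organ_of, m$organ_of)
  expect_identical(back$unit, "FPKM")
})

test_that("invalid expression inputs are rejected", {
  vals <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(make_expr(vals * 1.0), "duplicated gene")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  om <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\tx"), tsv)
  writeLines(c("sample_id\torgan", "s1\ta", "s2\tb"), om)
  expect_error(read_expression_table(tsv, "FPKM", "sp", om), "non-numeric")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t-4"), tsv)
  expect_error(read_expression_table(tsv, "FPKM", "sp", om), "negative")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tsv)
  writeLines(c("sample_id\torgan", "s1\ta"), om)
  expect_error(read_expression_table(tsv, "FPKM", "sp", om),
               "without an organ label")

  # TPM tag demands columns summing to 1e6
  expect_error(make_expr(matrix(c(1, 2), 1,
                                dimnames = list("g1", c("s1", "s2"))), "TPM"),
               "sum to 1e6")
})

test_that("counts_to_tpm matches hand-evaluated examples and errors", {
  m <- make_expr(matrix(c(10, 30), 2, dimnames = list(c("g1", "g2"), "s1")),
                 "COUNTS")
  tpm <- counts_to_tpm(m, c(g1 = 1000, g2 = 2000))
  # rates 0.01 and 0.015 -> 4e5 / 6e5
  expect_equal(unname(tpm$values[, 1L]), c(4e5, 6e5))

  even <- counts_to_tpm(make_expr(matrix(c(10, 20), 2,
                                         dimnames = list(c("g1", "g2"), "s1")),
                                  "COUNTS"),
                        c(g1 = 500, g2 = 1000))
  expect_equal(unname(even$values[, 1L]), c(5e5, 5e5))

  expect_error(counts_to_tpm(m, c(g1 = 1000)), "missing gene length")
  zero <- make_expr(matrix(c(0, 0), 2, dimnames = list(c("g1", "g2"), "sA")),
                    "COUNTS")
  expect_error(counts_to_tpm(zero, c(g1 = 10, g2 = 10)), "sA")
  expect_error(counts_to_tpm(tpm, c(g1 = 10, g2 = 10)), "COUNTS")
})

test_that("counts_to_fpkm matches hand evaluation and honours the RPKM tag", {
  m <- make_expr(matrix(c(10, 90), 2, dimnames = list(c("g1", "g2"), "s1")),
                 "COUNTS")
  fpkm <- counts_to_fpkm(m, c(g1 = 500, g2 = 500))
  # 10 * 1e9 / (500 * 100) = 2e5; 90 * 1e9 / (500 * 100) = 1.8e6
  expect_equal(unname(fpkm$values[, 1L]), c(2e5, 1.8e6))
  expect_identical(fpkm$unit, "FPKM")
  rpkm <- counts_to_fpkm(m, c(g1 = 500, g2 = 500), tag = "RPKM")
  expect_identical(rpkm$unit, "RPKM")
  expect_equal(rpkm$values, fpkm$values)

  # 1 kb gene carrying 10 of N = 1e6 reads -> FPKM 10
  lib <- make_expr(matrix(c(10, 1e6 - 10), 2,
                          dimnames = list(c("g1", "filler"), "s1")), "COUNTS")
  expect_equal(unname(counts_to_fpkm(lib, c(g1 = 1000, filler = 1000))$values["g1", 1L]),
               10)
})

test_that("TPM/FPKM identities hold on random count matrices", {
  set.seed(42)
  for (rep in 1:20) {
    sim <- rand_counts(sample(20:100, 1), sample(2:6, 1))
    lens <- stats::setNames(sample(200:3000, nrow(sim$values), replace = TRUE),
                            rownames(sim$values))
    tpm <- counts_to_tpm(sim, lens)
    expect_true(all(abs(colSums(tpm$values) - 1e6) < 1e-6 * 1e6))
    # scale invariance per column
    scaled <- sim
    scaled$values <- sweep(sim$values, 2L, runif(ncol(sim$values), 0.5, 4), "*")
    expect_equal(counts_to_tpm(scaled, lens)$values, tpm$values,
                 tolerance = 1e-12)
    # TPM == FPKM renormalized to 1e6
    fpkm <- counts_to_fpkm(sim, lens)
    renorm <- sweep(fpkm$values, 2L, colSums(fpkm$values), "/") * 1e6
    expect_equal(renorm, tpm$values, tolerance = 1e-9)
  }
})

test_that("pseudobulk sums cells, conserves totals and commutes with TPM", {
  cells <- matrix(c(1, 0, 2, 0, 3, 1), 2, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  pb <- pseudobulk(cells)
  expect_equal(unname(pb$values[, 1L]), c(3, 4))
  expect_equal(sum(pb$values), sum(cells))

  single <- pseudobulk(cells[, 1L, drop = FALSE])
  expect_equal(unname(single$values[, 1L]), unname(cells[, 1L]))

  lens <- c(g1 = 500, g2 = 1500)
  direct <- counts_to_tpm(pb, lens)
  manual <- make_expr(matrix(rowSums(cells), ncol = 1L,
                             dimnames = list(rownames(cells), "pseudobulk")),
                      "COUNTS")
  expect_equal(direct$values, counts_to_tpm(manual, lens)$values)

  expect_error(pseudobulk(cells[, 0, drop = FALSE]), "non-empty")
  expect_error(pseudobulk(cells - 0.5), "integer")
})

test_that("expressed_genes applies strict thresholds and aggregation rules", {
  m <- make_expr(matrix(c(1.5, 1.0, 0.2), 3,
                        dimnames = list(c("g1", "g2", "g3"), "s1")))
  expect_identical(expressed_genes(m, 1), "g1")  # boundary g2 excluded
  expect_setequal(expressed_genes(m, 0), c("g1", "g2", "g3"))

  two <- make_expr(matrix(c(0.5, 3.5), 1,
                          dimnames = list("g1", c("s1", "s2"))),
                   organ_of = c(s1 = "endo", s2 = "endo"))
  expect_identical(expressed_genes(two, 1, "endo", rule = "mean"), "g1")
  expect_identical(expressed_genes(two, 1, "endo", rule = "all"), character())
  expect_identical(expressed_genes(two, 1, "endo", rule = "any"), "g1")
  expect_error(expressed_genes(two, 1, "gill"), "unknown organ")

  # antitone in threshold
  set.seed(7)
  r <- rand_counts(50, 3)
  for (pair in list(c(1, 5), c(10, 40), c(0.5, 60))) {
    lo <- expressed_genes(r, pair[1L])
    hi <- expressed_genes(r, pair[2L])
    expect_true(all(hi %in% lo))
  }
})
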