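test_that("RPKM follows the unit definition at assay-scale depths", {
  counts <- matrix(c(10, 0, 250), 3, 1,
                   dimnames = list(c("gA", "gB", "gC"), "s0"))
  x <- make_quant_experiment(counts, lengths = c(1000, 2000, 48667),
                             library_size = 1e6, timepoints = 0)
  # gC at an assay-scale depth of 50 million reads
  x$samples$library_size <- c(1e6)
  r1 <- compute_rpkm(x)
  expect_equal(r1$values["gA", 1], 10)
  expect_equal(r1$values["gB", 1], 0)
  x$samples$library_size <- 50e6
  r2 <- compute_rpkm(x)
  expect_equal(r2$values["gC", 1], 250 / (48.667 * 50), tolerance = 1e-12)
})

test_that("RPKM is invariant to joint count/depth rescaling and errors are hard", {
  set.seed(11)
  counts <- matrix(rpois(8, 50), 4, 2,
                   dimnames = list(paste0("g", 1:4), c("s0", "s1")))
  x <- make_quant_experiment(counts, lengths = c(500, 1500, 30000, 80000),
                             library_size = c(2e6, 3e6),
                             timepoints = c(0, 2.5))
  base <- compute_rpkm(x)
  k <- 7
  y <- x
  y$values[, 2] <- y$values[, 2] * k
  y$samples$library_size[2] <- y$samples$library_size[2] * k
  expect_equal(compute_rpkm(y)$values, base$values)

  # missing length names the gene; zero library size refuses
  bad <- x
  bad$annotation <- bad$annotation[bad$annotation$gene_id != "g3", ]
  expect_error(compute_rpkm(bad), "g3")
  bad2 <- x
  bad2$samples$library_size[1] <- 0
  expect_error(bru_experiment(bad2$values, bad2$samples, bad2$annotation,
                              "counts"), "library_size")
})

test_that("scaling multiplies by the (condition, timepoint) factor", {
  counts <- matrix(c(4, 4, 2, 2.8, 2, 1), 1, 6,
                   dimnames = list("g1", paste0("s", 1:6)))
  samples <- data.frame(
    sample_id = paste0("s", 1:6),
    condition = rep(c("control", "kd"), each = 3),
    timepoint = rep(c(0, 0.5, 2.5), 2), replicate = 1L)
  x <- bru_experiment(counts, samples, state = "rpkm")
  unit <- scaling_factor_table(data.frame(
    condition = rep(c("control", "kd"), each = 3),
    timepoint = rep(c(0, 0.5, 2.5), 2), factor = 1))
  expect_identical(apply_scaling(x, unit)$values, x$values)

  fac <- scaling_factor_table(data.frame(
    condition = rep(c("control", "kd"), each = 3),
    timepoint = rep(c(0, 0.5, 2.5), 2),
    factor = c(1, 0.5, 0.37, 1, 1, 1)))
  s <- apply_scaling(x, fac)
  expect_equal(s$values[1, 2], 2.0)                 # 4 x 0.5
  expect_equal(s$values[1, 3], 2 * 0.37)
  expect_equal(s$state, "scaled_rpkm")

  missing <- scaling_factor_table(data.frame(
    condition = "control", timepoint = c(0, 0.5, 2.5), factor = c(1, .5, .4)))
  expect_error(apply_scaling(x, missing), "kd")
})

test_that("scaling commutes with gene subsetting", {
  set.seed(3)
  vals <- matrix(runif(12), 4, 3,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  samples <- data.frame(sample_id = paste0("s", 1:3), condition = "control",
                        timepoint = c(0, 0.5, 2.5), replicate = 1L)
  fac <- scaling_factor_table(data.frame(
    condition = "control", timepoint = c(0, 0.5, 2.5),
    factor = c(1, 0.8, 0.42)))
  x <- bru_experiment(vals, samples, state = "rpkm")
  keep <- c("g2", "g4")
  a <- subset_genes(apply_scaling(x, fac), keep)
  b <- apply_scaling(subset_genes(x, keep), fac)
  expect_identical(a$values, b$values)
})

test_that("baseline ratios, exclusions and replicate averaging behave", {
  vals <- matrix(c(4, 0, 0.28,   2, 1, 0.14,   4, 2, 0.28), 3, 3,
                 dimnames = list(c("g1", "g2", "g3"), c("b", "t1", "t2")))
  samples <- data.frame(sample_id = c("b", "t1", "t2"),
                        condition = "control",
                        timepoint = c(0, 2.5, 24.5), replicate = 1L)
  x <- bru_experiment(vals, samples, state = "scaled_rpkm")
  rt <- relative_to_baseline(x)
  expect_equal(rt$ratios$ratio[rt$ratios$gene_id == "g1" &
                                 rt$ratios$timepoint == 2.5], 0.5)
  expect_equal(rt$ratios$ratio[rt$ratios$gene_id == "g3" &
                                 rt$ratios$timepoint == 24.5], 1.0)
  expect_equal(rt$excluded$gene_id, "g2")
  expect_equal(rt$excluded$reason, "baseline_zero")
  # retained + excluded partition the input gene set
  expect_setequal(c(unique(rt$ratios$gene_id), rt$excluded$gene_id),
                  rownames(vals))

  # replicate_mean averages the per-replicate ratios
  vals2 <- cbind(vals, b2 = c(2, 1, 0.28), t12 = c(2, 1, 0.28))
  samples2 <- rbind(samples, data.frame(
    sample_id = c("b2", "t12"), condition = "control",
    timepoint = c(0, 2.5), replicate = 2L))
  x2 <- bru_experiment(vals2, samples2, state = "scaled_rpkm")
  rm_ <- relative_to_baseline(x2, "replicate_mean")
  got <- rm_$ratios$ratio[rm_$ratios$gene_id == "g1" &
                            rm_$ratios$timepoint == 2.5]
  expect_equal(got, mean(c(2 / 4, 2 / 2)))
})

test_that("complete-case filter drops genes undetected in any listed condition", {
  vals <- matrix(c(1, 1,   2, 0,   3, 4,   5, 6), 2, 4,
                 dimnames = list(c("g1", "g2"),
                                 c("c0", "c24", "k0", "k24")))
  samples <- data.frame(sample_id = colnames(vals),
                        condition = rep(c("control", "kd"), each = 2),
                        timepoint = rep(c(0, 24.5), 2), replicate = 1L)
  x <- bru_experiment(vals, samples, state = "rpkm")
  expect_setequal(filter_complete_cases(x, c("control", "kd")), "g1")
  expect_setequal(filter_complete_cases(x, "kd"), c("g1", "g2"))
  expect_setequal(filter_complete_cases(x, character()), c("g1", "g2"))
})

test_that("timepoint aliases resolve to labelled hours", {
  expect_equal(normalize_timepoint(c("0", "30min", "2h30", "6h30", "24h30")),
               c(0, 0.5, 2.5, 6.5, 24.5))
  expect_equal(normalize_timepoint(c(0, 0.5, 24.5)), c(0, 0.5, 24.5))
  expect_error(normalize_timepoint("next tuesday"), "unrecognised")
})
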