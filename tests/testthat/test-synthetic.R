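test_that("cohort generation is deterministic and matches its configuration", {
  cfg <- cohort_config(n_genes = 500, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  sim_a <- simulate_timecourse(a)
  sim_b <- simulate_timecourse(b)
  expect_identical(sim_a$experiment$values, sim_b$experiment$values)
  expect_identical(sim_a$factors, sim_b$factors)

  # genes are laid out without overlap on each chromosome
  ann <- a$annotation
  for (ch in unique(ann$chrom)) {
    e <- ann[ann$chrom == ch, ]
    e <- e[order(e$start), ]
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("sampled lengths and damage status track the configured model", {
  cfg <- cohort_config(n_genes = 10000, seed = 5)
  co <- generate_cohort(cfg)
  expect_lt(abs(median(co$truth$length) / exp(cfg$length_meanlog) - 1), 0.05)

  # damaged fraction converges to the closed-form expectation
  pr <- prob_damaged(co$truth$length, lesion_params(dose = cfg$dose))
  expect_lt(abs(mean(co$truth$damaged) - mean(pr)),
            3 * sqrt(sum(pr * (1 - pr))) / nrow(co$truth))

  # no damage without irradiation
  co0 <- generate_cohort(cohort_config(n_genes = 400, seed = 5, dose = 0))
  expect_false(any(co0$truth$damaged))
  expect_false(any(co0$truth$kinetics_truth == "fast"))

  # truth labels are internally consistent
  expect_true(all(co$truth$kinetics_truth[co$truth$damaged] == "fast"))
  expect_true(all(co$truth$response_truth[co$truth$damaged] == "repressed"))
  expect_true(all(co$truth$kinetics_truth[co$truth$trans_repressed] == "slow"))
})

test_that("noiseless scaling factors restore the planted signal exactly", {
  # depth normalisation erases the global change; if the reported factors
  # are the true cohort totals, the scaled ratios must equal the planted
  # per-class kinetic shapes bit-for-bit (up to float rounding)
  cfg <- cohort_config(n_genes = 300, seed = 9, count_noise = "none")
  sim <- simulate_uv_experiment(cfg)
  scaled <- apply_scaling(compute_rpkm(sim$experiment), sim$factors)
  rt <- relative_to_baseline(scaled, "replicate_mean")
  m <- ratio_matrix(rt, "control")
  tr <- sim$truth[match(rownames(m), sim$truth$gene_id), ]
  fast <- tr$kinetics_truth == "fast"
  slow <- tr$kinetics_truth == "slow"
  none <- tr$response_truth == "unchanged"
  expect_equal(unname(m[fast, "0.5"]), rep(cfg$cis_floor, sum(fast)),
               tolerance = 1e-9)
  expect_equal(unname(m[slow, "0.5"]), rep(cfg$trans_level_0p5, sum(slow)),
               tolerance = 1e-9)
  expect_equal(unname(m[slow, "2.5"]), rep(cfg$trans_floor, sum(slow)),
               tolerance = 1e-9)
  expect_equal(unname(m[none, "24.5"]), rep(1, sum(none)), tolerance = 1e-9)
  expect_equal(unname(m[fast | slow, "24.5"]),
               rep(cfg$recovery_control, sum(fast | slow)), tolerance = 1e-9)
  # knockdown recovery carries the planted dependency effect
  mk <- ratio_matrix(rt, "knockdown_A")
  eff <- unname(cfg$dependency_effects[tr$dependency_truth])
  rep_g <- tr$response_truth == "repressed"
  expect_equal(unname(mk[rep_g, "24.5"]),
               (cfg$recovery_control * eff)[rep_g], tolerance = 1e-9)
})

test_that("planted peaks are recovered exactly by filtering plus intersection", {
  cfg <- cohort_config(n_genes = 400, seed = 13)
  co <- generate_cohort(cfg)
  pk <- generate_peaks(co$annotation, target_fraction = 0.62, seed = 13)
  kept <- filter_peaks(pk$peaks)
  ext <- extend_upstream(co$annotation, 5000)
  hits <- intersect_targets(ext, kept)
  expect_setequal(names(hits)[hits], pk$target_genes)
  expect_equal(mean(hits), 0.62, tolerance = 0.01)

  # no targets planted -> all false; failing attributes -> all filtered out
  pk0 <- generate_peaks(co$annotation, target_fraction = 0, seed = 13)
  hits0 <- intersect_targets(ext, filter_peaks(pk0$peaks))
  expect_false(any(hits0))
  pk_fe5 <- pk$peaks
  pk_fe5$fold_enrichment <- 5
  expect_false(any(intersect_targets(ext, filter_peaks(pk_fe5))))
})

test_that("count noise degrades label recovery monotonically", {
  agree <- vapply(c(0, 0.6), function(sd_log) {
    cfg <- cohort_config(
      n_genes = 600, seed = 31, n_replicates = 1,
      count_noise = if (sd_log == 0) "poisson" else "lognormal_poisson",
      overdispersion_sd = sd_log)
    run <- run_pipeline(cfg)
    m <- merge(run$truth, run$response, by = "gene_id")
    mean(m$response_truth == m$response)
  }, 0)
  expect_gt(agree[1], agree[2])
})

test_that("fast fraction rises with the planted damaged fraction", {
  fast_frac <- vapply(c(2, 10, 40), function(dose) {
    cfg <- cohort_config(n_genes = 1500, seed = 4, dose = dose,
                         count_noise = "none")
    co <- generate_cohort(cfg)
    sim <- simulate_timecourse(co)
    run <- run_pipeline(sim)
    k <- run$response$kinetics[run$response$response == "repressed"]
    mean(k == "fast")
  }, 0)
  expect_true(all(diff(fast_frac) > 0))
})

test_that("synthetic inputs survive a TSV round trip unchanged", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_genes = 120, seed = 2, count_noise = "none")
  sim <- simulate_uv_experiment(cfg)
  pk <- generate_peaks(sim$annotation, seed = 2)
  paths <- write_synthetic_inputs(sim, dir, peaks = pk)
  run_mem <- run_pipeline(sim, peaks = pk)
  run_file <- run_pipeline_files(paths[["counts"]], paths[["samples"]],
                                 paths[["factors"]], paths[["annotation"]],
                                 paths[["peaks"]])
  expect_equal(run_file$response$response, run_mem$response$response)
  expect_equal(run_file$summary$dependency, run_mem$summary$dependency)
  expect_equal(run_file$overlaps$targets_vs_repressed$p_value,
               run_mem$overlaps$targets_vs_repressed$p_value)
})
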