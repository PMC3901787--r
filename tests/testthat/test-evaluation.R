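# Summary tables, bias, the bootstrap recovery test and adjusted means.

test_that("summary tables report exact arithmetic means when unrounded", {
  withr::with_seed(21, {
    cells <- matrix(runif(12, 1, 100), 3, 4,
                    dimnames = list(c("TC", "A", "B"), c("L", "ML", "MH", "H")))
    tab <- summary_table(cells, quantity = "FO", rounding = "none")
    expect_equal(row_means(tab), rowMeans(cells), tolerance = 1e-9)
    expect_equal(col_means(tab), colMeans(cells), tolerance = 1e-9)
  })
})

test_that("paper rounding is half-up at the conventional granularity", {
  expect_equal(round_half_up(3587.5), 3588)
  expect_equal(round_half_up(1.155, 2), 1.16)
  expect_equal(round_half_up(-2.5), -3)
  cells <- matrix(c(3587.5, 3582.4, 3555.5, 3561.2), 1, 4,
                  dimnames = list("TC", c("a", "b", "c", "d")))
  fo <- summary_table(cells, quantity = "FO", rounding = "paper")
  expect_equal(unname(row_means(fo)), 3570)      # 3571.65 -> nearest 10
  expect_equal(unname(col_means(fo))[1], 3588)   # nearest 1 for diet means
  rec <- summary_table(matrix(c(1.10, 1.20, 1.29, 1.05), 1, 4,
                              dimnames = list("ADL", c("L", "ML", "MH", "H"))),
                       quantity = "recovery", rounding = "paper")
  expect_equal(unname(row_means(rec)), 1.16)
})

test_that("recovery and estimate tables aggregate per-cell estimates", {
  tr <- simulate_trial(noise_free_config(recovery = 1.16, seed = 12))
  est <- marker_estimates(tr)
  rec <- recovery_table(est, diet_order = tr$diets$diet_id)
  expect_equal(unname(rec$cells), matrix(1.16, 3, 4), tolerance = 1e-9)
  expect_equal(unname(row_means(rec)), rep(1.16, 3), tolerance = 1e-9)

  fo <- estimates_table(est, "FO", diet_order = tr$diets$diet_id)
  expect_equal(rownames(fo$cells)[1], "TC")
  # FO rows are TC/1.16 for every marker
  for (m in c("ADL", "APL", "ADIA")) {
    expect_equal(fo$cells[m, ], fo$cells["TC", ] / 1.16, tolerance = 1e-9)
  }
  # a perfect marker collapses every method row onto total collection
  tr1 <- simulate_trial(noise_free_config(recovery = 1, seed = 12))
  fo1 <- estimates_table(marker_estimates(tr1), "FO")
  for (m in c("ADL", "APL", "ADIA")) {
    expect_equal(fo1$cells[m, ], fo1$cells["TC", ], tolerance = 1e-9)
  }
})

test_that("an empty diet-marker cell is an informative error", {
  tr <- simulate_trial(sim_config(seed = 13))
  est <- marker_estimates(tr)
  dropped <- est[!(est$marker_name == "ADL" & est$diet_id == "L"), ]
  expect_error(recovery_table(dropped, diet_order = tr$diets$diet_id),
               "diet L x marker ADL", class = "markerdig_validation_error")
})

test_that("FO bias on noise-free data equals 100 * (1/R - 1) exactly", {
  for (R in c(0.8, 1.16, 1.3)) {
    tr <- simulate_trial(noise_free_config(recovery = R, seed = 14))
    fo <- estimates_table(marker_estimates(tr), "FO")
    b <- bias_summary(fo)
    expect_equal(b$bias_pct, rep(100 * (1 / R - 1), 3), tolerance = 1e-9)
  }
  # markers identical to TC have zero bias
  tr1 <- simulate_trial(noise_free_config(recovery = 1, seed = 14))
  b1 <- bias_summary(estimates_table(marker_estimates(tr1), "FO"))
  expect_equal(b1$bias_pct, rep(0, 3), tolerance = 1e-9)
})

test_that("bootstrap recovery test behaves at the edges and rejects R = 1.16", {
  r <- recovery_vs_one_test(rep(1, 10), n_resamples = 1000, seed = 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$p_two_sided, 1)

  r0 <- recovery_vs_one_test(rep(1.2, 10), n_resamples = 1000, seed = 1)
  expect_equal(r0$p_two_sided, 0)

  tr <- simulate_trial(sim_config(seed = 3))
  est <- marker_estimates(tr)
  adl <- est$recovery[est$marker_name == "ADL"]
  expect_equal(length(adl), 24)
  t1 <- recovery_vs_one_test(adl, n_resamples = 2000, seed = 3)
  expect_lt(t1$p_two_sided, 0.05)
  expect_gt(t1$ci_low, 1)
  # deterministic given the seed
  t2 <- recovery_vs_one_test(adl, n_resamples = 2000, seed = 3)
  expect_identical(t1, t2)

  expect_error(recovery_vs_one_test(c(1, 1.1), seed = 1),
               class = "markerdig_validation_error")
  expect_error(recovery_vs_one_test(rep(1, 5), n_resamples = 10, seed = 1),
               class = "markerdig_validation_error")
})

test_that("adjusted means equal arithmetic means on balanced data", {
  tr <- simulate_trial(noise_free_config(recovery = 1, seed = 15))
  est <- marker_estimates(tr)
  one <- est[est$marker_name == "ADL", ]
  adj <- fit_adjusted_means(one, "dmd_est")
  arith <- tapply(one$dmd_est, one$diet_id, mean)
  expect_equal(adj$adjusted_mean, as.numeric(arith[adj$diet_id]), tolerance = 1e-9)
})

test_that("adjusted means remove period effects that arithmetic means absorb", {
  design <- make_youden_design(8, 3, 4, seed = 2)
  diet_eff <- c(L = 500, ML = 550, MH = 540, H = 565)
  period_eff <- c(P1 = 0, P2 = 90, P3 = -60)
  df <- design
  df$y <- diet_eff[df$diet_id] + period_eff[df$period_id]
  # losing one L cell in P2 unbalances periods within that diet
  df_unbal <- df[-which(df$diet_id == "L" & df$period_id == "P2")[1], ]
  arith <- tapply(df_unbal$y, df_unbal$diet_id, mean)
  adj <- fit_adjusted_means(df_unbal, "y")
  adj_v <- setNames(adj$adjusted_mean, adj$diet_id)
  # adjusted differences recover the configured diet differences exactly
  expect_equal(adj_v[["ML"]] - adj_v[["L"]], 50, tolerance = 1e-9)
  expect_equal(adj_v[["H"]] - adj_v[["MH"]], 25, tolerance = 1e-9)
  # the arithmetic contrast absorbs the missing period effect (off by 16)
  expect_gt(abs((arith[["ML"]] - arith[["L"]]) - 50), 10)
})

test_that("degenerate adjusted-mean inputs are handled", {
  single <- tibble::tibble(diet_id = "L", y = c(1, 2, 3))
  expect_equal(fit_adjusted_means(single, "y")$adjusted_mean, 2)
  confounded <- tibble::tibble(
    diet_id = rep(c("A", "B"), each = 3),
    period_id = rep(c("P1", "P2"), each = 3),
    y = c(1, 2, 3, 4, 5, 6)
  )
  expect_error(fit_adjusted_means(confounded, "y"),
               class = "markerdig_validation_error")
})

test_that("analyze_trial writes a deterministic artifact set", {
  tr <- simulate_trial(sim_config(seed = 16))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  analyze_trial(tr, out_dir = d1, seed = 16, n_resamples = 1000)
  analyze_trial(tr, out_dir = d2, seed = 16, n_resamples = 1000)
  files <- c("estimates.csv", "recovery_table.csv", "fo_table.csv",
             "dmd_table.csv", "bias.csv", "tests.csv", "report.md")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
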