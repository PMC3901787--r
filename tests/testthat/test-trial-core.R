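# Trial validation, the Youden checker, CSV round-trips, and the
# per-cell estimate pipeline on a hand-computed fixture.

test_that("the hand-built two-cow trial reproduces hand arithmetic", {
  est <- marker_estimates(hand_trial())
  expect_equal(nrow(est), 2)
  c1 <- est[est$animal_id == "C1", ]
  expect_equal(c1$dmi, 7740)
  expect_equal(c1$m_fd, 43)
  expect_equal(c1$recovery, 93 * 3760 / (43 * 7740))
  expect_equal(c1$fo_est, 332820 / 93)
  expect_equal(c1$dmd_est, 1000 * 50 / 93)
  expect_equal(c1$dmd_obs, 1000 * (1 - 3760 / 7740))

  c2 <- est[est$animal_id == "C2", ]
  expect_equal(c2$dmi, 9000)
  expect_equal(c2$m_fd, 400000 / 9000)
  expect_equal(c2$recovery, 90 * 4000 / 400000)  # 0.9
  expect_equal(c2$fo_est, 400000 / 90)
  expect_equal(c2$dmd_est, 1000 * (1 - (400000 / 9000) / 90))
})

test_that("a missing ort record means nothing was refused", {
  tr <- hand_trial()
  # C1 has zero orts and no ort assay: the ort term must drop out cleanly
  expect_false(any(startsWith(tr$assays$material_id, "ort:C1")))
  est <- marker_estimates(tr)
  expect_equal(est$m_fd[est$animal_id == "C1"], 43)
  # but refused orts without an ort assay is a reference error
  tr2 <- hand_trial()
  tr2$assays <- tr2$assays[tr2$assays$material_id != "ort:C2:P1", ]
  expect_error(marker_estimates(tr2), class = "markerdig_reference_error")
})

test_that("trial validation rejects malformed records", {
  tr <- hand_trial()
  bad_intake <- tr$intake
  bad_intake$ort_mass_g_dm[3] <- bad_intake$offered_mass_g_dm[3] + 1
  expect_error(
    marker_trial(tr$design, tr$diets, bad_intake, tr$fecal, tr$assays),
    class = "markerdig_validation_error"
  )
  neg <- tr$fecal
  neg$fecal_dm_g[1] <- -5
  expect_error(
    marker_trial(tr$design, tr$diets, tr$intake, neg, tr$assays),
    class = "markerdig_validation_error"
  )
  dangling <- tr$design
  dangling$diet_id[1] <- "NOPE"
  expect_error(
    marker_trial(dangling, tr$diets, tr$intake, tr$fecal, tr$assays),
    class = "markerdig_reference_error"
  )
  bad_diets <- tr$diets
  bad_diets$adf[1] <- bad_diets$ndf[1] + 10
  expect_error(
    marker_trial(tr$design, bad_diets, tr$intake, tr$fecal, tr$assays),
    class = "markerdig_validation_error"
  )
})

test_that("implausible fecal output (>= DMI) warns but does not fail", {
  tr <- hand_trial()
  heavy <- tr$fecal
  heavy$fecal_dm_g <- 3000  # 15000 g total vs 7740/9000 g DMI
  expect_warning(
    marker_trial(tr$design, tr$diets, tr$intake, heavy, tr$assays),
    "fecal output at or above DMI"
  )
})

test_that("the Youden checker enforces both design properties", {
  ok <- make_youden_design(8, 3, 4, seed = 1)
  expect_true(check_youden_design(ok))
  # unequal diet counts within a period
  uneq <- ok
  i <- which(uneq$period_id == "P1")[1:2]
  uneq$diet_id[i] <- uneq$diet_id[i[1]]
  expect_error(check_youden_design(uneq), class = "markerdig_validation_error")
  # an animal repeating a diet across periods
  rep_ <- ok
  a <- rep_$animal_id[1]
  rows <- which(rep_$animal_id == a)
  swap_partner <- which(rep_$period_id == rep_$period_id[rows[2]] &
                          rep_$diet_id == rep_$diet_id[rows[1]])[1]
  rep_$diet_id[c(rows[2], swap_partner)] <- rep_$diet_id[c(swap_partner, rows[2])]
  expect_error(check_youden_design(rep_), class = "markerdig_validation_error")
})

test_that("write then read is the identity to 1e-9", {
  tr <- simulate_trial(sim_config(seed = 7))
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  tr2 <- read_trial(dir)
  expect_equal(tr2$design, tr$design)
  expect_equal(tr2$intake$offered_mass_g_dm, tr$intake$offered_mass_g_dm, tolerance = 1e-9)
  expect_equal(tr2$intake$ort_mass_g_dm, tr$intake$ort_mass_g_dm, tolerance = 1e-9)
  expect_equal(tr2$fecal$fecal_dm_g, tr$fecal$fecal_dm_g, tolerance = 1e-9)
  expect_equal(tr2$assays$value_g_per_kg_dm, tr$assays$value_g_per_kg_dm, tolerance = 1e-9)
  expect_equal(tr2$truth$true_fo, tr$truth$true_fo, tolerance = 1e-9)
  # both replicates survive and the accepted concentration is their mean
  p <- assay_panels(tr2$assays)
  expect_equal(p$n_rep, rep(2L, nrow(p)))
  byhand <- tapply(tr2$assays$value_g_per_kg_dm,
                   paste(tr2$assays$material_id, tr2$assays$marker_name, sep = "|"),
                   mean)
  expect_equal(p$concentration, as.numeric(byhand[paste(p$material_id, p$marker_name, sep = "|")]))
  # and the full estimate pipeline agrees across the round-trip
  expect_equal(marker_estimates(tr2), marker_estimates(tr), tolerance = 1e-9)
})

test_that("empty record tables write headers-only files and read back", {
  tr <- hand_trial()
  empty <- marker_trial(tr$design, tr$diets, tr$intake[0, ], tr$fecal[0, ], tr$assays[0, ])
  dir <- withr::local_tempdir()
  write_trial(empty, dir)
  expect_equal(length(readLines(file.path(dir, "intake.csv"))), 1)
  tr2 <- read_trial(dir)
  expect_equal(nrow(tr2$intake), 0)
  expect_equal(nrow(tr2$assays), 0)
})

test_that("a missing column is a schema error naming the column", {
  tr <- simulate_trial(sim_config(seed = 3))
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  intake <- readr::read_csv(file.path(dir, "intake.csv"), show_col_types = FALSE)
  readr::write_csv(intake[setdiff(names(intake), "ort_mass_g_dm")],
                   file.path(dir, "intake.csv"))
  expect_error(read_trial(dir), "ort_mass_g_dm", class = "markerdig_schema_error")
  expect_error(read_trial(withr::local_tempdir()), class = "markerdig_schema_error")
})

test_that("as-fed masses convert to DM via the DM content", {
  expect_equal(as_fed_to_dm(1000, 885), 885)
  expect_equal(as_fed_to_dm(c(100, 200), c(900, 850)), c(90, 170))
  expect_error(as_fed_to_dm(100, 1200), class = "markerdig_validation_error")
})
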