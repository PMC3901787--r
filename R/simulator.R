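# Seeded simulator of a replicated Youden-square digestion trial with
# known ground truth. The default configuration emulates a 4-diet x
# 3-period x 8-cow trial: two blocks of four cows (594 +/- 35.5 kg),
# restricted feeding at 20 g DM/kg body weight, a 5-d total collection,
# bermudagrass-hay diets spanning 79-164 g CP/kg with diet-specific true
# DMD, three internal markers (ADL, APL, ADIA) with marker-specific true
# fecal recoveries, small partial refusals, and duplicate assays carrying
# multiplicative noise subject to the 5%-CV rerun rule.

#' Default diet parameters for the simulator
#'
#' Four bermudagrass-hay diets graded by crude protein (L, ML, MH, H) with
#' nutrient composition, total-collection DMD used as simulation truth
#' (g/kg DM), offered-hay marker concentrations (g/kg DM) and refusal
#' behavior. Values mirror [hay_composition], [reference_marker_conc] and
#' [reference_total_collection]; the refusal distribution (mean fraction
#' 0.05, SD 0.02) is a convention, since restricted feeding is designed to
#' minimize refusal and ort amounts are rarely reported.
#'
#' @return A tibble with one row per diet.
#' @export
default_diet_params <- function() {
  tibble::tibble(
    diet_id = c("L", "ML", "MH", "H"),
    cp = c(79, 111, 131, 164),
    ndf = c(768, 712, 690, 740),
    adf = c(428, 348, 332, 370),
    total_ash = c(61, 87, 88, 81),
    dm = c(885, 872, 867, 875),
    true_dmd = c(504, 550, 538, 564),
    refusal_mean = 0.05,
    refusal_sd = 0.02,
    ADL = c(43, 32, 32, 38),
    APL = c(26, 24, 22, 25),
    ADIA = c(25, 32, 27, 20)
  )
}

#' Default marker parameters for the simulator
#'
#' True fecal recoveries per marker (ADL 1.16, APL 1.06, ADIA 1.03 — the
#' diet-averaged recoveries observed for these markers in bermudagrass-fed
#' cattle), duplicate-assay CV, and refusal selectivity (ratio of ort to
#' offered concentration; 1 means non-selective refusal).
#'
#' @param assay_cv Duplicate assay coefficient of variation (fraction).
#'   Default 0.025.
#' @return A tibble with one row per marker.
#' @export
default_marker_params <- function(assay_cv = 0.025) {
  tibble::tibble(
    marker_name = c("ADL", "APL", "ADIA"),
    true_recovery = c(1.16, 1.06, 1.03),
    assay_cv = assay_cv,
    selectivity = 1
  )
}

#' Simulator configuration
#'
#' Collects every knob of [simulate_trial()] with defaults matching the
#' reference trial layout: 8 animals in 2 blocks, 3 periods, 4 diets, body
#' weight ~ Normal(594, 35.5) kg drawn once per animal, 20 g DM offered
#' per kg body weight per day, 5 collection days.
#'
#' @param n_animals,n_periods,n_diets Trial dimensions. `n_diets` must
#'   divide `n_animals` and `n_periods` cannot exceed `n_diets`.
#' @param body_weight_mean,body_weight_sd Body-weight distribution, kg.
#' @param feeding_rate Hay offered, g DM per kg body weight per day.
#' @param collection_days Length of the total-collection window, d.
#' @param diet_params Tibble as returned by [default_diet_params()]; must
#'   have `n_diets` rows.
#' @param marker_params Tibble as returned by [default_marker_params()].
#' @param assay_cv Convenience override applied to every marker's
#'   `assay_cv` when not `NULL`.
#' @param seed Integer seed; the same config and seed reproduce the trial
#'   byte-for-byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 8, n_periods = 3, n_diets = 4,
                       body_weight_mean = 594, body_weight_sd = 35.5,
                       feeding_rate = 20, collection_days = 5,
                       diet_params = default_diet_params(),
                       marker_params = default_marker_params(),
                       assay_cv = NULL, seed = 1) {
  if (!is.null(assay_cv)) marker_params$assay_cv <- assay_cv
  cfg <- list(
    n_animals = n_animals, n_periods = n_periods, n_diets = n_diets,
    body_weight_mean = body_weight_mean, body_weight_sd = body_weight_sd,
    feeding_rate = feeding_rate, collection_days = collection_days,
    diet_params = tibble::as_tibble(diet_params),
    marker_params = tibble::as_tibble(marker_params),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_animals %% cfg$n_diets != 0) {
    abort_validation("n_diets must divide n_animals (equal diet replicates per period)")
  }
  if (cfg$n_periods > cfg$n_diets) {
    abort_validation("infeasible design: n_periods cannot exceed n_diets")
  }
  if (nrow(cfg$diet_params) != cfg$n_diets) {
    abort_validation("diet_params must have one row per diet")
  }
  require_cols(cfg$diet_params, c("diet_id", "true_dmd", "refusal_mean", "refusal_sd"), "diet_params")
  require_cols(cfg$marker_params, c("marker_name", "true_recovery", "assay_cv", "selectivity"), "marker_params")
  missing_conc <- setdiff(cfg$marker_params$marker_name, names(cfg$diet_params))
  if (length(missing_conc) > 0) {
    abort_validation(sprintf(
      "diet_params lacks a concentration column for marker(s): %s",
      paste(missing_conc, collapse = ", ")
    ))
  }
  rf <- cfg$diet_params$refusal_mean
  if (any(rf < 0 | rf >= 1)) abort_validation("refusal_mean must lie in [0, 1)")
  if (any(cfg$marker_params$assay_cv < 0)) abort_validation("assay_cv must be >= 0")
  if (any(cfg$marker_params$true_recovery <= 0)) abort_validation("true_recovery must be > 0")
  td <- cfg$diet_params$true_dmd
  if (any(td <= 0 | td >= 1000)) abort_validation("true_dmd must lie in (0, 1000) g/kg")
  if (cfg$feeding_rate <= 0 || cfg$collection_days < 1) {
    abort_validation("feeding_rate must be positive and collection_days >= 1")
  }
  invisible(cfg)
}

#' Generate a randomized Youden-square design
#'
#' Builds a balanced crossover assignment: each block of `n_diets` animals
#' receives `n_periods` rows of a randomized cyclic Latin square of order
#' `n_diets`, so every diet appears once per period within each block
#' (hence `n_animals / n_diets` times per period overall) and no animal
#' repeats a diet. With `n_periods == n_diets` the design degenerates to a
#' full Latin square per block.
#'
#' @param n_animals,n_periods,n_diets Design dimensions; `n_diets` must
#'   divide `n_animals` and `n_periods <= n_diets`.
#' @param seed Integer seed controlling the randomization (diet labels,
#'   period offsets and animal columns are independently permuted per
#'   block).
#' @param diet_ids Diet labels; defaults to L/ML/MH/H for four diets, else
#'   `D1..Dn`.
#' @return A design tibble (`animal_id`, `block`, `period_id`, `diet_id`)
#'   passing [check_youden_design()].
#' @export
make_youden_design <- function(n_animals = 8, n_periods = 3, n_diets = 4,
                               seed = 1, diet_ids = NULL) {
  if (n_animals %% n_diets != 0) {
    abort_validation("n_diets must divide n_animals")
  }
  if (n_periods > n_diets) {
    abort_validation("infeasible design: n_periods cannot exceed n_diets")
  }
  if (is.null(diet_ids)) {
    diet_ids <- if (n_diets == 4) c("L", "ML", "MH", "H") else paste0("D", seq_len(n_diets))
  }
  stopifnot(length(diet_ids) == n_diets)
  n_blocks <- n_animals %/% n_diets
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_blocks), function(b) {
      labels <- sample(diet_ids)
      offsets <- sample(seq_len(n_diets), n_periods)   # distinct rows of the square
      cols <- sample(seq_len(n_diets))                  # animal columns
      grid <- expand.grid(p = seq_len(n_periods), a = seq_len(n_diets))
      tibble::tibble(
        animal_id = paste0("C", (b - 1) * n_diets + grid$a),
        block = paste0("B", b),
        period_id = paste0("P", grid$p),
        diet_id = labels[((offsets[grid$p] + cols[grid$a]) %% n_diets) + 1]
      )
    })
    design <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$period_id, .data$animal_id)
    check_youden_design(design)
    design
  })
}

# Draw one duplicate assay pair for a true concentration: independent
# multiplicative Gaussian errors (truncated at zero), redrawn until the
# pair passes the duplicate-CV rule -- the in-silico analogue of rerunning
# failed duplicates.
draw_duplicates <- function(true_value, cv, cv_limit = 0.05, max_tries = 1000) {
  if (cv == 0 || true_value == 0) {
    return(c(true_value, true_value))
  }
  for (i in seq_len(max_tries)) {
    v <- true_value * stats::rnorm(2, mean = 1, sd = cv)
    if (any(v <= 0)) next
    if (duplicate_cv_check(v, cv_limit)$pass) return(v)
  }
  abort_validation("could not draw a duplicate pair passing the CV rule; assay_cv too large")
}

#' Simulate a complete feeding trial with known truth
#'
#' Generates a trial under `config`: body weights once per animal; per
#' animal-period a daily offered mass (`feeding_rate` x body weight), a
#' refusal fraction drawn from the diet's truncated-normal refusal
#' distribution, true fecal output from the diet's true DMD
#' (`FO = DMI * (1 - DMD/1000)`, so digested mass plus FO equals DMI
#' exactly), and, per marker, a true fecal concentration implied by the
#' configured recovery (`m_fc = R * marker consumed / FO`). Duplicate
#' assays of offered hay (per animal-period, mirroring per-feeding hay
#' sampling), orts and feces then receive independent multiplicative
#' Gaussian noise with the marker's `assay_cv`, with failing duplicate
#' pairs redrawn under the 5% CV rule. With `assay_cv = 0`, no refusal and
#' recovery 1 the marker equations recover truth exactly.
#'
#' @param config A [sim_config()].
#' @return A `marker_trial` whose `truth` component holds one row per
#'   animal-period: `true_dmi`, `true_fo`, `true_dmd` and one
#'   `true_recovery_<marker>` column per marker.
#' @export
simulate_trial <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  design <- make_youden_design(cfg$n_animals, cfg$n_periods, cfg$n_diets,
                               seed = cfg$seed, diet_ids = cfg$diet_params$diet_id)
  dp <- cfg$diet_params
  mp <- cfg$marker_params
  days <- cfg$collection_days

  withr::with_seed(cfg$seed + 1L, {
    animals <- sort(unique(design$animal_id))
    bw <- stats::setNames(
      stats::rnorm(length(animals), cfg$body_weight_mean, cfg$body_weight_sd),
      animals
    )
    if (any(bw <= 0)) abort_validation("drew a non-positive body weight; check config")

    cells <- design
    di <- match(cells$diet_id, dp$diet_id)
    refusal <- stats::rnorm(nrow(cells), dp$refusal_mean[di], dp$refusal_sd[di])
    refusal <- pmin(pmax(refusal, 0), 0.9)

    offered_daily <- unname(cfg$feeding_rate * bw[cells$animal_id])
    ort_daily <- refusal * offered_daily
    q_of <- days * offered_daily
    q_or <- days * ort_daily
    dmi <- q_of - q_or
    true_dmd <- dp$true_dmd[di]
    true_fo <- dmi * (1 - true_dmd / 1000)

    intake <- tidyr::crossing(
      dplyr::mutate(cells, .off = offered_daily, .ort = ort_daily),
      day = seq_len(days)
    ) |>
      dplyr::transmute(
        animal_id = .data$animal_id, period_id = .data$period_id,
        day = .data$day,
        offered_mass_g_dm = .data$.off, ort_mass_g_dm = .data$.ort
      ) |>
      dplyr::arrange(.data$animal_id, .data$period_id, .data$day)

    fecal <- tidyr::crossing(
      dplyr::mutate(cells, .fo = true_fo / days),
      day = seq_len(days)
    ) |>
      dplyr::transmute(
        animal_id = .data$animal_id, period_id = .data$period_id,
        day = .data$day, fecal_dm_g = .data$.fo
      ) |>
      dplyr::arrange(.data$animal_id, .data$period_id, .data$day)

    # assays, in documented draw order: cell by cell, marker by marker,
    # material order hay -> ort -> feces
    assay_rows <- vector("list", nrow(cells) * nrow(mp) * 3L)
    k <- 0L
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(nrow(mp))) {
        mk <- mp$marker_name[j]
        cv <- mp$assay_cv[j]
        m_of_true <- dp[[mk]][di[i]]
        m_or_true <- m_of_true * mp$selectivity[j]
        consumed <- m_of_true * q_of[i] - m_or_true * q_or[i]
        m_fc_true <- mp$true_recovery[j] * consumed / true_fo[i]

        add <- function(role, true_value) {
          v <- draw_duplicates(true_value, cv)
          k <<- k + 1L
          assay_rows[[k]] <<- tibble::tibble(
            material_id = material_id(role, cells$animal_id[i], cells$period_id[i]),
            marker_name = mk, rep_index = c(1L, 2L), value_g_per_kg_dm = v
          )
        }
        add("hay", m_of_true)
        if (q_or[i] > 0) add("ort", m_or_true)
        add("feces", m_fc_true)
      }
    }
    assays <- dplyr::bind_rows(assay_rows[seq_len(k)])

    truth <- tibble::tibble(
      animal_id = cells$animal_id, period_id = cells$period_id,
      diet_id = cells$diet_id,
      body_weight_kg = unname(bw[cells$animal_id]),
      true_dmi = dmi, true_fo = true_fo, true_dmd = true_dmd
    )
    for (j in seq_len(nrow(mp))) {
      truth[[paste0("true_recovery_", mp$marker_name[j])]] <- mp$true_recovery[j]
    }

    diets <- dp |>
      dplyr::select(-"refusal_mean", -"refusal_sd") |>
      dplyr::relocate("diet_id", "cp", "ndf", "adf", "total_ash", "dm", "true_dmd")

    marker_trial(design = design, diets = diets, intake = intake,
                 fecal = fecal, assays = assays, truth = truth)
  })
}
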