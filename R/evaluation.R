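# Trial-level summaries: diet x marker recovery tables, FO/DMD estimate
# tables against total collection, relative-bias summaries, a bootstrap
# test of recovery = 1, and OLS-adjusted (least-squares) diet means.

#' Construct a diet-by-method summary table
#'
#' The common shape of trial report tables: one row per method or marker,
#' one column per diet, with a row mean (over diets) appended to each row
#' and a column mean (over methods) appended to each column. Cells are
#' stored at full precision; report-style rounding is applied only when
#' means are extracted with `rounding = "paper"`:
#' recoveries to 2 decimals, DMD to the nearest g/kg, fecal output to the
#' nearest 10 g for row (method) means and the nearest g for column (diet)
#' means, all half-up — matching how such tables are conventionally
#' printed.
#'
#' @param cells Numeric matrix with methods/markers as rownames and diets
#'   as colnames.
#' @param quantity One of `"none"`, `"recovery"`, `"FO"`, `"DMD"`;
#'   selects the paper rounding granularity.
#' @param rounding `"none"` (full precision) or `"paper"`.
#' @param row_means Optional externally supplied row means (e.g. the
#'   model-adjusted means printed in a report, which need not equal the
#'   arithmetic means of the printed cells). Defaults to the arithmetic
#'   row means.
#' @return An object of class `summary_table`.
#' @seealso [row_means()], [col_means()], [bias_summary()]
#' @export
summary_table <- function(cells, quantity = c("none", "recovery", "FO", "DMD"),
                          rounding = c("none", "paper"), row_means = NULL) {
  quantity <- match.arg(quantity)
  rounding <- match.arg(rounding)
  cells <- as.matrix(cells)
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    abort_validation("summary_table cells need row (method) and column (diet) names")
  }
  if (!is.null(row_means)) {
    if (length(row_means) != nrow(cells)) {
      abort_validation("row_means must have one value per row")
    }
    row_means <- stats::setNames(as.numeric(row_means), rownames(cells))
  } else {
    row_means <- rowMeans(cells)
  }
  structure(
    list(cells = cells, quantity = quantity, rounding = rounding,
         row_means_raw = row_means, col_means_raw = colMeans(cells)),
    class = "summary_table"
  )
}

# (row_unit, col_unit, cell_digits) of paper-style rounding per quantity
rounding_units <- function(quantity) {
  switch(quantity,
    recovery = list(row = 0.01, col = 0.01, digits = 2),
    FO = list(row = 10, col = 1, digits = 0),
    DMD = list(row = 1, col = 1, digits = 0),
    none = list(row = 0, col = 0, digits = NA)
  )
}

#' @rdname summary_table
#' @param x A `summary_table`.
#' @return `row_means()` and `col_means()` return named numeric vectors,
#'   rounded per the table's quantity when its rounding rule is `"paper"`.
#' @export
row_means <- function(x) {
  stopifnot(inherits(x, "summary_table"))
  m <- x$row_means_raw
  if (x$rounding == "paper") m <- round_to_unit(m, rounding_units(x$quantity)$row)
  m
}

#' @rdname summary_table
#' @export
col_means <- function(x) {
  stopifnot(inherits(x, "summary_table"))
  m <- x$col_means_raw
  if (x$rounding == "paper") m <- round_to_unit(m, rounding_units(x$quantity)$col)
  m
}

#' @export
as.data.frame.summary_table <- function(x, ...) {
  cells <- x$cells
  if (x$rounding == "paper") {
    # cells print at the row (method) granularity: FO nearest 10 g,
    # DMD nearest g/kg, recoveries 2 decimals
    cells <- round_to_unit(cells, rounding_units(x$quantity)$row)
  }
  df <- data.frame(item = rownames(cells), cells, mean = unname(row_means(x)),
                   row.names = NULL, check.names = FALSE)
  avg <- data.frame(item = "Average", t(col_means(x)), mean = NA_real_,
                    check.names = FALSE)
  rbind(df, avg)
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("<summary_table: %s, rounding = %s>\n", x$quantity, x$rounding))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' Diet-by-marker fecal recovery table
#'
#' Each cell is the mean fecal recovery over animals for one diet and one
#' marker; the row mean over diets is the marker's overall recovery.
#'
#' @param estimates Output of [marker_estimates()].
#' @param rounding `"none"` or `"paper"` (recoveries to 2 decimals).
#' @param diet_order Column order; defaults to order of first appearance.
#' @return A `summary_table` with markers as rows and diets as columns.
#' @export
recovery_table <- function(estimates, rounding = c("none", "paper"),
                           diet_order = NULL) {
  rounding <- match.arg(rounding)
  diet_order <- diet_order %||% unique(estimates$diet_id)
  markers <- unique(estimates$marker_name)
  cells <- matrix(NA_real_, length(markers), length(diet_order),
                  dimnames = list(markers, diet_order))
  agg <- estimates |>
    dplyr::group_by(.data$marker_name, .data$diet_id) |>
    dplyr::summarise(value = mean(.data$recovery), .groups = "drop")
  cells[cbind(agg$marker_name, agg$diet_id)] <- agg$value
  if (anyNA(cells)) {
    i <- which(is.na(cells), arr.ind = TRUE)[1, ]
    abort_validation(sprintf(
      "no recovery estimates for diet %s x marker %s",
      colnames(cells)[i[2]], rownames(cells)[i[1]]
    ))
  }
  summary_table(cells, quantity = "recovery", rounding = rounding)
}

#' Fecal output / DMD estimate table versus total collection
#'
#' One row per method — total collection (`TC`) first, then each marker —
#' and one column per diet; each cell is the mean over animals of that
#' method's estimate for that diet. The row means are the method means and
#' the column means the diet means reported in trial summaries.
#'
#' @param estimates Output of [marker_estimates()].
#' @param quantity `"FO"` (g DM over the collection) or `"DMD"` (g/kg).
#' @param rounding `"none"` or `"paper"`.
#' @param diet_order Column order; defaults to order of first appearance.
#' @return A `summary_table`.
#' @export
estimates_table <- function(estimates, quantity = c("FO", "DMD"),
                            rounding = c("none", "paper"), diet_order = NULL) {
  quantity <- match.arg(quantity)
  rounding <- match.arg(rounding)
  diet_order <- diet_order %||% unique(estimates$diet_id)
  obs_col <- if (quantity == "FO") "fo_obs" else "dmd_obs"
  est_col <- if (quantity == "FO") "fo_est" else "dmd_est"

  tc <- estimates |>
    dplyr::distinct(.data$animal_id, .data$period_id, .data$diet_id,
                    value = .data[[obs_col]]) |>
    dplyr::group_by(.data$diet_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  mk <- estimates |>
    dplyr::group_by(.data$marker_name, .data$diet_id) |>
    dplyr::summarise(value = mean(.data[[est_col]]), .groups = "drop")

  markers <- unique(estimates$marker_name)
  cells <- matrix(NA_real_, 1 + length(markers), length(diet_order),
                  dimnames = list(c("TC", markers), diet_order))
  cells["TC", tc$diet_id] <- tc$value
  cells[cbind(mk$marker_name, mk$diet_id)] <- mk$value
  if (anyNA(cells)) {
    i <- which(is.na(cells), arr.ind = TRUE)[1, ]
    abort_validation(sprintf(
      "missing %s estimate for diet %s x method %s",
      quantity, colnames(cells)[i[2]], rownames(cells)[i[1]]
    ))
  }
  summary_table(cells, quantity = quantity, rounding = rounding)
}

#' Relative bias of marker methods against total collection
#'
#' For each non-reference row of a summary table, the percent deviation of
#' its method mean from the total-collection method mean:
#' `100 * (marker mean - TC mean) / TC mean`. Uses the table's row means —
#' externally supplied (printed) means when the table was built with them,
#' arithmetic means otherwise.
#'
#' @param table A `summary_table` containing a `"TC"` row.
#' @return A tibble with columns `method` and `bias_pct`.
#' @export
bias_summary <- function(table) {
  stopifnot(inherits(table, "summary_table"))
  rm_ <- table$row_means_raw
  if (!"TC" %in% names(rm_)) {
    abort_validation("bias_summary needs a summary table with a TC row")
  }
  tc <- rm_[["TC"]]
  if (tc == 0) abort_validation("TC mean is zero; relative bias undefined")
  others <- setdiff(names(rm_), "TC")
  tibble::tibble(
    method = others,
    bias_pct = unname(100 * (rm_[others] - tc) / tc)
  )
}

#' Bootstrap test of mean fecal recovery against 1
#'
#' A nonparametric replacement for the classical t-test that the marker
#' ratio differs from 1: percentile bootstrap of the mean of the
#' per-animal recoveries, with a two-sided p-value
#' `2 * min(P(boot mean <= 1), P(boot mean >= 1))`. Deterministic given
#' the seed. With all values identical the CI degenerates to the point
#' value and p is 1 when that value equals 1 and 0 otherwise.
#'
#' @param recoveries Numeric vector of at least 3 per-animal recoveries
#'   for one marker.
#' @param n_resamples Number of bootstrap resamples, at least 1000.
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return A list with `mean`, `ci_low`, `ci_high`, `p_two_sided`,
#'   `n`, `n_resamples`.
#' @export
recovery_vs_one_test <- function(recoveries, n_resamples = 2000, seed = 1,
                                 conf_level = 0.95) {
  n <- length(recoveries)
  if (n < 3) abort_validation("at least 3 recovery values are required")
  if (n_resamples < 1000) abort_validation("use at least 1000 bootstrap resamples")
  m <- mean(recoveries)
  if (all(recoveries == recoveries[1])) {
    return(list(mean = m, ci_low = m, ci_high = m,
                p_two_sided = if (m == 1) 1 else 0,
                n = n, n_resamples = as.integer(n_resamples)))
  }
  boot <- withr::with_seed(seed, {
    idx <- sample.int(n, n * n_resamples, replace = TRUE)
    colMeans(matrix(recoveries[idx], nrow = n))
  })
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(boot <= 1), mean(boot >= 1))
  list(mean = m, ci_low = ci[1], ci_high = ci[2],
       p_two_sided = min(p, 1), n = n, n_resamples = as.integer(n_resamples))
}

#' Least-squares (model-adjusted) diet means
#'
#' Ordinary-least-squares adjustment of diet means for period and block
#' effects — the fixed-effects analogue of the least-squares means
#' conventionally reported for crossover trials. On perfectly balanced
#' data the adjusted means coincide with the arithmetic diet means; in an
#' incomplete (Youden) layout they correct for whatever period/block
#' imbalance the incompleteness induces.
#'
#' @param data Data frame with a numeric response and a `diet_id` column;
#'   `period_id` and `block` are used as additive adjustment factors when
#'   present (a `block` column may instead be supplied through `design`).
#' @param response Name of the response column.
#' @param design Optional design table used to join `block` by
#'   `animal_id`.
#' @return A tibble with columns `diet_id` and `adjusted_mean`.
#' @export
fit_adjusted_means <- function(data, response, design = NULL) {
  data <- tibble::as_tibble(data)
  require_cols(data, c("diet_id", response), "fit_adjusted_means data")
  if (!is.null(design) && !"block" %in% names(data) && "block" %in% names(design)) {
    data <- dplyr::left_join(
      data, dplyr::distinct(design, .data$animal_id, .data$block),
      by = "animal_id"
    )
  }
  diets <- unique(data$diet_id)
  if (length(diets) == 1) {
    return(tibble::tibble(diet_id = diets,
                          adjusted_mean = mean(data[[response]])))
  }
  terms <- "diet_id"
  for (fac in c("period_id", "block")) {
    if (fac %in% names(data) && length(unique(data[[fac]])) > 1) {
      terms <- c(terms, fac)
    }
  }
  data$.y <- data[[response]]
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort_validation(sprintf(
      "rank-deficient design: aliased coefficient(s) %s",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ))
  }
  # a noise-free trial fits exactly; summary.lm's perfect-fit warning is
  # expected there, not actionable
  em <- withCallingHandlers(
    emmeans::emmeans(fit, "diet_id"),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- as.data.frame(em)
  out <- tibble::tibble(diet_id = as.character(s$diet_id), adjusted_mean = s$emmean)
  out[match(diets, out$diet_id), ]
}

#' Run the full marker analysis of a trial
#'
#' Computes per-cell marker estimates, the recovery and FO/DMD summary
#' tables, relative FO/DMD bias of each marker against total collection,
#' and the bootstrap recovery-vs-1 test per marker. When `out_dir` is
#' given, writes `estimates.csv`, `recovery_table.csv`, `fo_table.csv`,
#' `dmd_table.csv`, `bias.csv`, `tests.csv` and a markdown `report.md`;
#' outputs are byte-identical across re-runs with the same inputs and
#' seed.
#'
#' @param trial A `marker_trial`.
#' @param out_dir Optional output directory.
#' @param seed Seed for the bootstrap tests.
#' @param rounding `"none"` or `"paper"` table rounding.
#' @param n_resamples Bootstrap resamples per marker test.
#' @return Invisibly, a list with `estimates`, `recovery`, `fo`, `dmd`,
#'   `bias` and `tests`.
#' @export
analyze_trial <- function(trial, out_dir = NULL, seed = 1,
                          rounding = c("none", "paper"), n_resamples = 2000) {
  rounding <- match.arg(rounding)
  est <- marker_estimates(trial)
  diet_order <- trial$diets$diet_id
  rec <- recovery_table(est, rounding = rounding, diet_order = diet_order)
  fo <- estimates_table(est, "FO", rounding = rounding, diet_order = diet_order)
  dmd <- estimates_table(est, "DMD", rounding = rounding, diet_order = diet_order)
  bias <- dplyr::full_join(
    dplyr::rename(bias_summary(fo), fo_bias_pct = "bias_pct"),
    dplyr::rename(bias_summary(dmd), dmd_bias_pct = "bias_pct"),
    by = "method"
  )
  markers <- unique(est$marker_name)
  tests <- dplyr::bind_rows(lapply(seq_along(markers), function(i) {
    r <- est$recovery[est$marker_name == markers[i]]
    if (length(r) < 3) {
      # too few cells for resampling inference; report the mean only
      return(tibble::tibble(marker_name = markers[i], mean_recovery = mean(r),
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_two_sided = NA_real_, n = length(r)))
    }
    t <- recovery_vs_one_test(r, n_resamples = n_resamples, seed = seed + i)
    tibble::tibble(marker_name = markers[i], mean_recovery = t$mean,
                   ci_low = t$ci_low, ci_high = t$ci_high,
                   p_two_sided = t$p_two_sided, n = t$n)
  }))
  res <- list(estimates = est, recovery = rec, fo = fo, dmd = dmd,
              bias = bias, tests = tests)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(est, file.path(out_dir, "estimates.csv"), progress = FALSE)
    readr::write_csv(as.data.frame(rec), file.path(out_dir, "recovery_table.csv"), progress = FALSE)
    readr::write_csv(as.data.frame(fo), file.path(out_dir, "fo_table.csv"), progress = FALSE)
    readr::write_csv(as.data.frame(dmd), file.path(out_dir, "dmd_table.csv"), progress = FALSE)
    readr::write_csv(bias, file.path(out_dir, "bias.csv"), progress = FALSE)
    readr::write_csv(tests, file.path(out_dir, "tests.csv"), progress = FALSE)
    writeLines(render_report(res, seed = seed, rounding = rounding),
               file.path(out_dir, "report.md"))
  }
  invisible(res)
}

# Minimal fixed-width markdown table; avoids a formatting dependency.
md_table <- function(df, digits = 2) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, format = "f", digits = digits) else as.character(x)
  }
  body <- as.data.frame(lapply(df, fmt), check.names = FALSE)
  header <- paste0("| ", paste(names(body), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(body)), collapse = "|"), "|")
  rows <- apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

render_report <- function(res, seed, rounding) {
  c(
    "# Marker-based digestibility analysis",
    "",
    sprintf("- cells analyzed: %d", nrow(dplyr::distinct(res$estimates, .data$animal_id, .data$period_id))),
    sprintf("- markers: %s", paste(unique(res$estimates$marker_name), collapse = ", ")),
    sprintf("- bootstrap seed: %d; table rounding: %s", seed, rounding),
    "",
    "## Fecal recovery (g/g)",
    "",
    md_table(as.data.frame(res$recovery), digits = 3),
    "",
    "## Fecal output (g DM per collection)",
    "",
    md_table(as.data.frame(res$fo), digits = 0),
    "",
    "## Dry matter digestibility (g/kg)",
    "",
    md_table(as.data.frame(res$dmd), digits = 0),
    "",
    "## Relative bias vs total collection (%)",
    "",
    md_table(res$bias, digits = 2),
    "",
    "## Bootstrap test of recovery = 1",
    "",
    md_table(res$tests, digits = 4)
  )
}
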