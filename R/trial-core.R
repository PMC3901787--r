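# Trial container, validation and CSV I/O.
#
# A trial is five tables:
#   diets  - one row per diet: nutrient composition (g/kg DM), DM (g/kg
#            as-fed), optional simulated true DMD, one column per marker
#            concentration.
#   design - animal_id, block, period_id, diet_id (the Youden-square
#            assignment).
#   intake - per animal x period x day: hay offered and orts refused, g DM.
#   assays - per material x marker x replicate: concentration, g/kg DM.
#   fecal  - per animal x period x day: fecal DM excreted, g.
#
# Assay materials are keyed by strings: "hay:<animal>:<period>" for hay
# offered to one animal-period, "diet:<diet_id>" for a pooled diet-level
# hay assay, "ort:<animal>:<period>" and "feces:<animal>:<period>".

TRIAL_FILES <- c(
  diets = "diets.csv", design = "design.csv", intake = "intake.csv",
  assays = "assays.csv", fecal = "fecal.csv"
)

#' Assemble and validate a feeding trial
#'
#' Bundles the five trial tables into a `marker_trial` object after
#' validating column schemas, per-table invariants (non-negative masses,
#' orts not exceeding hay offered, ADF <= NDF <= 1000 g/kg) and
#' cross-references (every animal/period/diet referenced by the intake,
#' fecal and design tables must resolve). A fecal output at or above the
#' corresponding dry-matter intake is implausible and triggers a warning,
#' not an error.
#'
#' @param design Data frame with columns `animal_id`, `block`, `period_id`,
#'   `diet_id`.
#' @param diets Data frame with columns `diet_id`, `cp`, `ndf`, `adf`,
#'   `total_ash`, `dm`, optionally `true_dmd`, plus one numeric column per
#'   marker.
#' @param intake Data frame with columns `animal_id`, `period_id`, `day`,
#'   `offered_mass_g_dm`, `ort_mass_g_dm` (`NA` ort is read as zero).
#' @param fecal Data frame with columns `animal_id`, `period_id`, `day`,
#'   `fecal_dm_g`.
#' @param assays Data frame with columns `material_id`, `marker_name`,
#'   `rep_index`, `value_g_per_kg_dm`.
#' @param truth Optional ground-truth table (from the simulator).
#' @return An object of class `marker_trial`: a named list of validated
#'   tibbles.
#' @seealso [read_trial()], [write_trial()], [simulate_trial()]
#' @export
marker_trial <- function(design, diets, intake, fecal, assays, truth = NULL) {
  design <- tibble::as_tibble(design)
  diets <- tibble::as_tibble(diets)
  intake <- tibble::as_tibble(intake)
  fecal <- tibble::as_tibble(fecal)
  assays <- tibble::as_tibble(assays)

  require_cols(design, c("animal_id", "block", "period_id", "diet_id"), "design")
  require_cols(diets, c("diet_id", "cp", "ndf", "adf", "total_ash", "dm"), "diets")
  require_cols(intake, c("animal_id", "period_id", "day", "offered_mass_g_dm", "ort_mass_g_dm"), "intake")
  require_cols(fecal, c("animal_id", "period_id", "day", "fecal_dm_g"), "fecal")
  require_cols(assays, c("material_id", "marker_name", "rep_index", "value_g_per_kg_dm"), "assays")

  check_youden_design(design)

  if (any(diets$adf > diets$ndf) || any(diets$ndf > 1000)) {
    abort_validation("diets: ADF <= NDF <= 1000 g/kg violated")
  }
  if (any(diets$total_ash >= 1000)) {
    abort_validation("diets: total ash must be < 1000 g/kg")
  }
  if ("true_dmd" %in% names(diets)) {
    td <- diets$true_dmd[!is.na(diets$true_dmd)]
    if (any(td <= 0 | td >= 1000)) {
      abort_validation("diets: true_dmd must lie in (0, 1000) g/kg")
    }
  }

  intake$ort_mass_g_dm[is.na(intake$ort_mass_g_dm)] <- 0
  if (any(intake$offered_mass_g_dm < 0) || any(intake$ort_mass_g_dm < 0) ||
      any(fecal$fecal_dm_g < 0)) {
    abort_validation("masses must be non-negative")
  }
  if (any(intake$ort_mass_g_dm > intake$offered_mass_g_dm)) {
    bad <- intake[intake$ort_mass_g_dm > intake$offered_mass_g_dm, ]
    abort_validation(sprintf(
      "intake: orts exceed hay offered for animal %s, period %s, day %s",
      bad$animal_id[1], bad$period_id[1], bad$day[1]
    ))
  }
  if (any(assays$value_g_per_kg_dm < 0) || any(assays$value_g_per_kg_dm >= 1000)) {
    abort_validation("assays: concentrations must lie in [0, 1000) g/kg DM")
  }

  # cross-references
  dangling_diet <- setdiff(design$diet_id, diets$diet_id)
  if (length(dangling_diet) > 0) {
    abort_reference(sprintf(
      "design references unknown diet id(s): %s", paste(dangling_diet, collapse = ", ")
    ))
  }
  cell_key <- paste(design$animal_id, design$period_id)
  for (nm in c("intake", "fecal")) {
    df <- if (nm == "intake") intake else fecal
    dangling <- setdiff(paste(df$animal_id, df$period_id), cell_key)
    if (length(dangling) > 0) {
      abort_reference(sprintf(
        "%s references animal-period(s) absent from the design: %s",
        nm, paste(dangling, collapse = "; ")
      ))
    }
  }

  # plausibility: fecal output below DMI (warn only)
  if (nrow(intake) > 0 && nrow(fecal) > 0) {
    dmi <- stats::aggregate(
      cbind(dmi = offered_mass_g_dm - ort_mass_g_dm) ~ animal_id + period_id,
      data = intake, FUN = sum
    )
    fo <- stats::aggregate(fecal_dm_g ~ animal_id + period_id, data = fecal, FUN = sum)
    both <- merge(dmi, fo, by = c("animal_id", "period_id"))
    if (nrow(both) > 0 && any(both$fecal_dm_g >= both$dmi & both$dmi > 0)) {
      rlang::warn("fecal output at or above DMI for at least one animal-period; check records")
    }
  }

  structure(
    list(design = design, diets = diets, intake = intake,
         fecal = fecal, assays = assays, truth = truth),
    class = "marker_trial"
  )
}

#' @export
print.marker_trial <- function(x, ...) {
  cat("<marker_trial>\n")
  cat(sprintf(
    "  %d animals x %d periods, %d diets; markers: %s\n",
    length(unique(x$design$animal_id)),
    length(unique(x$design$period_id)),
    nrow(x$diets),
    paste(sort(unique(x$assays$marker_name)), collapse = ", ")
  ))
  cat(sprintf(
    "  %d intake rows, %d fecal rows, %d assay rows%s\n",
    nrow(x$intake), nrow(x$fecal), nrow(x$assays),
    if (!is.null(x$truth)) " (+ simulation truth)" else ""
  ))
  invisible(x)
}

#' Check the Youden-square properties of a design
#'
#' A (possibly incomplete) Latin-square crossover design must satisfy two
#' properties: every diet appears the same number of times within each
#' period, and no animal receives the same diet in two periods.
#'
#' @param design Data frame with columns `animal_id`, `period_id`,
#'   `diet_id` (a `block` column is ignored here).
#' @return Invisibly `TRUE`; aborts with a validation error otherwise.
#' @export
check_youden_design <- function(design) {
  require_cols(design, c("animal_id", "period_id", "diet_id"), "design")
  if (anyDuplicated(design[, c("animal_id", "period_id")])) {
    abort_validation("design: duplicate animal-period assignment")
  }
  counts <- table(design$period_id, design$diet_id)
  if (any(apply(counts, 1, function(r) length(unique(r)) > 1))) {
    abort_validation("design: diets are not equally replicated within every period")
  }
  rep_diet <- table(design$animal_id, design$diet_id)
  if (any(rep_diet > 1)) {
    abort_validation("design: an animal receives the same diet in more than one period")
  }
  invisible(TRUE)
}

#' Summarize assay replicates into marker panels
#'
#' Collapses the replicate-level assay table to one row per material and
#' marker: the accepted concentration (the replicate mean), the number of
#' replicates, the duplicate CV and whether the pair passes the 5% QC rule
#' (single-replicate assays pass trivially with `cv = NA`).
#'
#' @param assays Assay table as in [marker_trial()].
#' @param cv_limit QC limit on the duplicate CV, default 0.05.
#' @return A tibble with columns `material_id`, `marker_name`,
#'   `concentration`, `n_rep`, `cv`, `cv_pass`.
#' @export
assay_panels <- function(assays, cv_limit = 0.05) {
  require_cols(assays, c("material_id", "marker_name", "rep_index", "value_g_per_kg_dm"), "assays")
  assays |>
    dplyr::group_by(.data$material_id, .data$marker_name) |>
    dplyr::summarise(
      concentration = mean(.data$value_g_per_kg_dm),
      n_rep = dplyr::n(),
      cv = dplyr::if_else(
        dplyr::n() >= 2 & mean(.data$value_g_per_kg_dm) > 0,
        stats::sd(.data$value_g_per_kg_dm) / mean(.data$value_g_per_kg_dm),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv_pass = is.na(.data$cv) | .data$cv <= cv_limit)
}

#' Convert an as-fed mass to a dry-matter basis
#'
#' All internal arithmetic runs on grams of DM; field records taken as-fed
#' are converted at ingest using the material's DM content.
#'
#' @param mass_as_fed Mass as fed, g.
#' @param dm Dry-matter content of the material, g/kg as-fed.
#' @return Mass of dry matter, g.
#' @examples
#' as_fed_to_dm(1000, dm = 885)  # 885 g DM
#' @export
as_fed_to_dm <- function(mass_as_fed, dm) {
  if (any(dm < 0) || any(dm > 1000)) {
    abort_validation("DM content must lie in [0, 1000] g/kg as-fed")
  }
  mass_as_fed * dm / 1000
}

# Build a material key. Vectorized.
material_id <- function(role, animal_id = NULL, period_id = NULL, diet_id = NULL) {
  if (role == "diet") paste("diet", diet_id, sep = ":")
  else paste(role, animal_id, period_id, sep = ":")
}

#' Read a trial from a directory of CSV files
#'
#' Expects `diets.csv`, `design.csv`, `intake.csv`, `assays.csv` and
#' `fecal.csv` (UTF-8, comma-separated, `.` decimal, header row) in `dir`,
#' plus an optional `truth.csv` written by the simulator. All validation in
#' [marker_trial()] is applied; a missing file or column raises a schema
#' error naming it.
#'
#' @param dir Directory containing the CSV files.
#' @return A validated `marker_trial`.
#' @export
read_trial <- function(dir) {
  paths <- file.path(dir, TRIAL_FILES)
  names(paths) <- names(TRIAL_FILES)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort_schema(sprintf(
      "missing trial file(s): %s", paste(TRIAL_FILES[missing], collapse = ", ")
    ))
  }
  read1 <- function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_guess()))
  }
  tabs <- lapply(paths, read1)
  # ids as character regardless of how they guess
  fix_ids <- function(df) {
    for (col in intersect(names(df), c("animal_id", "period_id", "diet_id", "block", "material_id", "marker_name"))) {
      df[[col]] <- as.character(df[[col]])
    }
    df
  }
  tabs <- lapply(tabs, fix_ids)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) fix_ids(read1(truth_path)) else NULL
  marker_trial(
    design = tabs$design, diets = tabs$diets, intake = tabs$intake,
    fecal = tabs$fecal, assays = tabs$assays, truth = truth
  )
}

#' Write a trial to a directory of CSV files
#'
#' Inverse of [read_trial()]: numeric fields survive a write-read
#' round-trip to better than 1e-9 (doubles are written with a shortest
#' round-trip representation). Empty record tables produce headers-only
#' files.
#'
#' @param trial A `marker_trial`.
#' @param dir Output directory; created if needed.
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "marker_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(TRIAL_FILES)) {
    p <- file.path(dir, TRIAL_FILES[[nm]])
    readr::write_csv(trial[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(trial$truth)) {
    p <- file.path(dir, "truth.csv")
    readr::write_csv(trial$truth, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
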