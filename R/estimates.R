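# Per-cell marker estimates: the trial-level pipeline over the marker
# equations. One "cell" is an animal x period; daily records are summed to
# cell totals before any ratio is taken, so the 5-d collection is analyzed
# as a single observation per cow-period.

#' Compute per-cell marker estimates for a trial
#'
#' For every animal x period and every marker assayed, aggregates the daily
#' intake and fecal records to collection totals and applies the marker
#' equations: consumed-marker concentration, fecal recovery, and the
#' marker-based fecal output and DMD estimates, alongside the
#' total-collection (observed) values.
#'
#' Offered-hay concentration is resolved, in order of preference, from a
#' per-cell `hay:<animal>:<period>` assay, a pooled `diet:<diet_id>` assay,
#' or the diet table's marker column. Ort concentration comes from the
#' `ort:<animal>:<period>` assay and is required only when orts were
#' refused; a missing ort record means nothing was refused and the ort term
#' drops out. The fecal `feces:<animal>:<period>` assay is always required.
#'
#' @param trial A `marker_trial`.
#' @param markers Character vector of markers to evaluate; defaults to all
#'   markers present in the fecal assays.
#' @return A tibble with one row per animal x period x marker:
#'   `animal_id`, `period_id`, `diet_id`, `block`, `marker_name`, `dmi`,
#'   `fo_obs`, `dmd_obs` (total collection), `m_fd`, `m_fc`, `recovery`,
#'   `fo_est`, `dmd_est` (marker-based), all masses g DM and concentrations
#'   g/kg DM.
#' @seealso [recovery_table()], [estimates_table()]
#' @export
marker_estimates <- function(trial, markers = NULL) {
  stopifnot(inherits(trial, "marker_trial"))
  panels <- assay_panels(trial$assays)

  fecal_panels <- panels[startsWith(panels$material_id, "feces:"), ]
  if (is.null(markers)) {
    markers <- sort(unique(fecal_panels$marker_name))
  }
  if (length(markers) == 0) {
    abort_reference("no fecal marker assays present in the trial")
  }

  intake_cell <- trial$intake |>
    dplyr::group_by(.data$animal_id, .data$period_id) |>
    dplyr::summarise(
      q_of = sum(.data$offered_mass_g_dm),
      q_or = sum(.data$ort_mass_g_dm),
      .groups = "drop"
    )
  fecal_cell <- trial$fecal |>
    dplyr::group_by(.data$animal_id, .data$period_id) |>
    dplyr::summarise(fo_obs = sum(.data$fecal_dm_g), .groups = "drop")

  cells <- trial$design |>
    dplyr::inner_join(intake_cell, by = c("animal_id", "period_id")) |>
    dplyr::inner_join(fecal_cell, by = c("animal_id", "period_id"))
  if (nrow(cells) == 0) {
    abort_reference("no animal-period has both intake and fecal records")
  }

  conc <- stats::setNames(
    panels$concentration,
    paste(panels$material_id, panels$marker_name, sep = "|")
  )
  lookup <- function(mat, marker) unname(conc[paste(mat, marker, sep = "|")])

  out <- lapply(markers, function(mk) {
    m_of <- lookup(material_id("hay", cells$animal_id, cells$period_id), mk)
    pooled <- lookup(material_id("diet", diet_id = cells$diet_id), mk)
    m_of <- dplyr::coalesce(m_of, pooled)
    if (mk %in% names(trial$diets)) {
      from_diets <- trial$diets[[mk]][match(cells$diet_id, trial$diets$diet_id)]
      m_of <- dplyr::coalesce(m_of, from_diets)
    }
    if (anyNA(m_of)) {
      abort_reference(sprintf(
        "no offered-hay %s assay (hay:, diet: or diets column) for animal %s, period %s",
        mk, cells$animal_id[which(is.na(m_of))[1]], cells$period_id[which(is.na(m_of))[1]]
      ))
    }
    m_or <- lookup(material_id("ort", cells$animal_id, cells$period_id), mk)
    need_ort <- cells$q_or > 0
    if (any(need_ort & is.na(m_or))) {
      i <- which(need_ort & is.na(m_or))[1]
      abort_reference(sprintf(
        "orts were refused but no ort %s assay exists for animal %s, period %s",
        mk, cells$animal_id[i], cells$period_id[i]
      ))
    }
    m_or <- dplyr::coalesce(m_or, 0)
    m_fc <- lookup(material_id("feces", cells$animal_id, cells$period_id), mk)
    if (anyNA(m_fc)) {
      i <- which(is.na(m_fc))[1]
      abort_reference(sprintf(
        "missing fecal %s assay for animal %s, period %s",
        mk, cells$animal_id[i], cells$period_id[i]
      ))
    }

    m_fd <- consumed_marker_conc(m_of, cells$q_of, m_or, cells$q_or)
    tibble::tibble(
      animal_id = cells$animal_id,
      period_id = cells$period_id,
      diet_id = cells$diet_id,
      block = cells$block,
      marker_name = mk,
      dmi = cells$q_of - cells$q_or,
      fo_obs = cells$fo_obs,
      dmd_obs = observed_dmd(dmi, cells$fo_obs),
      m_fd = m_fd,
      m_fc = m_fc,
      recovery = marker_recovery(m_fc, cells$fo_obs, m_of, cells$q_of, m_or, cells$q_or),
      fo_est = fo_estimate(dmi, m_fd, m_fc),
      dmd_est = dmd_estimate(m_fd, m_fc)
    )
  })
  dplyr::bind_rows(out)
}
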