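# Core marker-ratio arithmetic.
#
# All masses are grams of dry matter (DM); all concentrations are g/kg DM.
# The marker-ratio technique rests on a mass balance for an indigestible
# dietary constituent: the marker consumed (offered minus orts) must appear
# quantitatively in the feces.  From the concentration of the marker in the
# consumed forage and in the feces one obtains estimates of fecal output and
# apparent dry-matter digestibility without total fecal collection.

#' Marker concentration in consumed forage
#'
#' Corrects the offered-hay marker concentration for feed refusals (orts):
#' the marker mass refused is subtracted from the marker mass offered and
#' the remainder is divided by the dry matter actually consumed,
#'
#' \deqn{M_{fd} = (M_{of} Q_{of} - M_{or} Q_{or}) / (Q_{of} - Q_{or})}
#'
#' With no orts (`q_or = 0`) this reduces to `m_of`. If the animal refuses
#' feed non-selectively (`m_or == m_of`), the consumed concentration equals
#' the offered concentration regardless of ort mass.
#'
#' @param m_of Marker concentration in hay offered, g/kg DM.
#' @param q_of Mass of hay offered, g DM.
#' @param m_or Marker concentration in orts, g/kg DM. Default 0.
#' @param q_or Mass of orts refused, g DM. Default 0.
#' @return Marker concentration in the consumed forage, g/kg DM.
#'
#' Inputs are recycled to a common length. A negative result (possible only
#' when the ort assay is inconsistent with the offered-hay assay) is an
#' error, not a silent clamp.
#' @seealso [marker_recovery()], [dmd_estimate()], [fo_estimate()]
#' @examples
#' consumed_marker_conc(m_of = 45, q_of = 10000, m_or = 50, q_or = 1000)
#' @export
consumed_marker_conc <- function(m_of, q_of, m_or = 0, q_or = 0) {
  if (any(m_of < 0) || any(m_or < 0)) {
    abort_validation("marker concentrations must be non-negative")
  }
  if (any(q_or < 0)) {
    abort_validation("ort mass must be non-negative")
  }
  if (any(q_of <= q_or)) {
    abort_validation(
      "nothing consumed: hay offered must exceed orts refused (q_of > q_or)"
    )
  }
  m_fd <- (m_of * q_of - m_or * q_or) / (q_of - q_or)
  if (any(m_fd < 0)) {
    abort_validation(
      "negative consumed-marker concentration: ort assay inconsistent with offered-hay assay"
    )
  }
  m_fd
}

#' Fecal marker recovery
#'
#' The ratio of marker excreted in the feces to marker consumed,
#'
#' \deqn{R = M_{fc} \, FO / (M_{of} Q_{of} - M_{or} Q_{or})}
#'
#' An ideal internal marker has `R = 1` (fully indigestible, fully
#' recovered). `R > 1` indicates apparent over-recovery (e.g. artifact
#' formation during gastrointestinal transit, or soil contamination for
#' ash-based markers); `R < 1` indicates marker disappearance.
#'
#' @param m_fc Marker concentration in feces, g/kg DM.
#' @param fo Fecal DM excreted over the collection, g DM.
#' @param m_of,q_of,m_or,q_or As in [consumed_marker_conc()].
#' @return Recovery, g marker excreted per g marker consumed.
#' @examples
#' marker_recovery(m_fc = 93, fo = 4000, m_of = 43, q_of = 8000)
#' @export
marker_recovery <- function(m_fc, fo, m_of, q_of, m_or = 0, q_or = 0) {
  if (any(m_fc < 0) || any(fo < 0)) {
    abort_validation("fecal concentration and fecal output must be non-negative")
  }
  consumed <- m_of * q_of - m_or * q_or
  if (any(consumed <= 0)) {
    abort_validation("marker intake must be positive: marker absent from consumed diet")
  }
  m_fc * fo / consumed
}

#' Marker-based estimate of dry-matter digestibility
#'
#' \deqn{DMD = 1000 \, (1 - M_{fd} / M_{fc})}
#'
#' on a g/kg DM basis. Valid under the assumption of complete fecal
#' recovery of the marker; with true recovery \eqn{R \ne 1} the estimate is
#' biased as \eqn{1000 - (1000 - DMD_{true})/R}.
#'
#' @param m_fd Marker concentration in consumed forage, g/kg DM.
#' @param m_fc Marker concentration in feces, g/kg DM. Must be positive.
#' @return Estimated apparent DMD, g/kg DM. Negative values (fecal
#'   concentration below consumed concentration) are possible for a failing
#'   marker and are returned with a warning.
#' @examples
#' dmd_estimate(m_fd = 43, m_fc = 93)
#' @export
dmd_estimate <- function(m_fd, m_fc) {
  if (any(m_fc <= 0)) {
    abort_validation("fecal marker concentration must be positive")
  }
  dmd <- 1000 * (1 - m_fd / m_fc)
  if (any(dmd < 0)) {
    rlang::warn("negative DMD estimate: consumed-marker concentration exceeds fecal concentration")
  }
  dmd
}

#' Marker-based estimate of fecal output
#'
#' \deqn{FO = DMI \, M_{fd} / M_{fc}}
#'
#' The estimate satisfies the marker balance `fo * m_fc == dmi * m_fd`
#' exactly, and is therefore algebraically consistent with
#' [dmd_estimate()]: `dmd_estimate(m_fd, m_fc)` equals
#' `observed_dmd(dmi, fo_estimate(dmi, m_fd, m_fc))` for any inputs.
#'
#' @param dmi Dry-matter intake, g DM.
#' @param m_fd,m_fc As in [dmd_estimate()].
#' @return Estimated fecal output, g DM.
#' @examples
#' fo_estimate(dmi = 7740, m_fd = 43, m_fc = 93)
#' @export
fo_estimate <- function(dmi, m_fd, m_fc) {
  if (any(m_fc <= 0)) {
    abort_validation("fecal marker concentration must be positive")
  }
  if (any(dmi < 0)) {
    abort_validation("DMI must be non-negative")
  }
  dmi * m_fd / m_fc
}

#' Dry-matter digestibility from total collection
#'
#' The reference (direct) measurement: `1000 * (1 - fo/dmi)` where both
#' masses come from weighing, not from marker ratios.
#'
#' @param dmi Dry-matter intake, g DM. Must be positive.
#' @param fo Fecal DM excreted, g DM.
#' @return Apparent DMD, g/kg DM.
#' @examples
#' observed_dmd(dmi = 7740, fo = 3760)
#' @export
observed_dmd <- function(dmi, fo) {
  if (any(dmi <= 0)) {
    abort_validation("DMI must be positive")
  }
  1000 * (1 - fo / dmi)
}

#' Acid-detergent insoluble ash fraction
#'
#' ADIA is the ash remaining after combustion of the acid-detergent fiber
#' residue, expressed per unit of the original sample:
#' `1000 * residual_ash_mass / initial_sample_mass` g/kg DM.
#'
#' @param residual_ash_mass Ash remaining after combustion of the ADF
#'   residue, g.
#' @param initial_sample_mass Original sample mass, g. Must be positive.
#' @return ADIA concentration, g/kg DM.
#' @examples
#' adia_fraction(0.0125, 0.5)  # 25 g/kg
#' @export
adia_fraction <- function(residual_ash_mass, initial_sample_mass) {
  if (any(initial_sample_mass <= 0)) {
    abort_validation("initial sample mass must be positive")
  }
  if (any(residual_ash_mass < 0) || any(residual_ash_mass > initial_sample_mass)) {
    abort_validation("residual ash must lie between 0 and the initial sample mass")
  }
  1000 * residual_ash_mass / initial_sample_mass
}

#' Ash-free alkaline-peroxide lignin fraction
#'
#' APL is measured after an alkaline hydrogen peroxide pretreatment and
#' sequential acid-detergent analysis; the lignin residue is ash-corrected
#' and expressed per unit of the original sample:
#' `1000 * (adl_residue_mass - residue_ash_mass) / initial_sample_mass`.
#'
#' @param adl_residue_mass Mass of the lignin residue, g.
#' @param residue_ash_mass Ash content of that residue, g. Must not exceed
#'   the residue mass.
#' @param initial_sample_mass Original sample mass, g. Must be positive.
#' @return Ash-free APL concentration, g/kg DM.
#' @examples
#' apl_fraction(0.015, 0.003, 0.5)  # 24 g/kg
#' @export
apl_fraction <- function(adl_residue_mass, residue_ash_mass, initial_sample_mass) {
  if (any(initial_sample_mass <= 0)) {
    abort_validation("initial sample mass must be positive")
  }
  if (any(residue_ash_mass < 0) || any(residue_ash_mass > adl_residue_mass)) {
    abort_validation("residue ash must lie between 0 and the residue mass")
  }
  1000 * (adl_residue_mass - residue_ash_mass) / initial_sample_mass
}

#' Duplicate-assay coefficient-of-variation check
#'
#' Lab QC rule for duplicate marker assays: the accepted concentration is
#' the arithmetic mean of the replicates, and the pair passes when the
#' coefficient of variation (sample SD / mean) is at most 5%; failing pairs
#' are rerun.
#'
#' @param replicates Numeric vector of at least two replicate assay values,
#'   g/kg DM, all non-negative.
#' @param cv_limit Maximum acceptable CV as a fraction. Default 0.05.
#' @return A list with `mean`, `cv` (a fraction; `NA` when the mean is zero
#'   with nonzero spread) and `pass` (logical).
#' @examples
#' duplicate_cv_check(c(48, 52))  # cv 5.66%, fails
#' duplicate_cv_check(c(49, 51))  # cv 2.83%, passes
#' @export
duplicate_cv_check <- function(replicates, cv_limit = 0.05) {
  if (length(replicates) < 2) {
    abort_validation("at least two replicate values are required")
  }
  if (any(replicates < 0)) {
    abort_validation("replicate values must be non-negative")
  }
  m <- mean(replicates)
  s <- stats::sd(replicates)
  if (m == 0) {
    cv <- if (s > 0) NA_real_ else 0
  } else {
    cv <- s / m
  }
  list(mean = m, cv = cv, pass = !is.na(cv) && cv <= cv_limit)
}

#' Derived proximate composition
#'
#' Hemicellulose is the difference between neutral- and acid-detergent
#' fiber; organic matter is the DM remaining after combustion of the total
#' ash: `hemicellulose = ndf - adf`, `om = 1000 - total_ash`, all g/kg DM.
#'
#' @param ndf Neutral-detergent fiber, g/kg DM.
#' @param adf Acid-detergent fiber, g/kg DM. Must not exceed `ndf`.
#' @param total_ash Total ash, g/kg DM. Must not exceed 1000.
#' @return A tibble with columns `hemicellulose` and `om`.
#' @examples
#' proximate_derive(ndf = 768, adf = 428, total_ash = 61)
#' @export
proximate_derive <- function(ndf, adf, total_ash) {
  if (any(adf > ndf)) {
    abort_validation("ADF cannot exceed NDF")
  }
  if (any(total_ash > 1000) || any(total_ash < 0)) {
    abort_validation("total ash must lie in [0, 1000] g/kg")
  }
  tibble::tibble(hemicellulose = ndf - adf, om = 1000 - total_ash)
}
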