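# Shared helpers: condition classes and paper-style rounding.

abort_schema <- function(msg) {
  rlang::abort(msg, class = "markerdig_schema_error")
}

abort_reference <- function(msg) {
  rlang::abort(msg, class = "markerdig_reference_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "markerdig_validation_error")
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = "markerdig_usage_error")
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, the convention used when formatting
#' summary tables for display: 0.5 always rounds away from zero, unlike
#' [base::round()]'s round-half-to-even. A tiny epsilon guards against
#' binary representation error in values that are exact decimals
#' (e.g. `1.155` stored as `1.15499...`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(3587.5)      # 3588
#' round_half_up(1.155, 2)    # 1.16
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Round to an arbitrary unit (e.g. nearest 10 g), half-up. Fractional
# units go through decimal-digit rounding so the result is the correctly
# rounded double (114 * 0.01 is one ulp off 1.14; 114/100 is not).
round_to_unit <- function(x, unit) {
  if (unit <= 0) return(x)
  if (unit < 1) return(round_half_up(x, as.integer(round(-log10(unit)))))
  round_half_up(x / unit) * unit
}

# Abort (with the schema class) unless `df` has all of `cols`.
require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
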