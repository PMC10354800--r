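#' Percent difference between the pH method and the LLE reference
#'
#' Relative difference of the monoprotonated-nicotine quantities,
#' `100 * |mp_ph - mp_lle| / mp_lle`. Because the metric is scale-invariant,
#' rows reported as mp fractions and rows reported as mg/mL concentrations
#' are handled identically.
#'
#' @param mp_ph Monoprotonated quantity from the pH method (fraction or
#'   mg/mL).
#' @param mp_lle Reference quantity from liquid-liquid extraction, > 0, in
#'   the same units.
#' @return Percent difference(s), >= 0.
#' @examples
#' percent_difference(0.857, 0.850)     # 0.8
#' percent_difference(43.950, 56.982)   # 22.9
#' @export
percent_difference <- function(mp_ph, mp_lle) {
  if (any(!is.finite(mp_ph)) || any(!is.finite(mp_lle))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(mp_lle <= 0)) {
    stop("the LLE reference quantity must be positive", call. = FALSE)
  }
  100 * abs(mp_ph - mp_lle) / mp_lle
}

#' The bundled reference validation table
#'
#' 22 e-liquids (4 commercial pods, 18 lab-made nicotine benzoate /
#' salicylate / lactate salts) with measured apparent pH, PG/VG composition,
#' dielectric constant, and the freebase and monoprotonated results of both
#' the pH method and the LLE reference method.
#'
#' @return A data frame with columns `label`, `nicotine_conc`, `vol_pct_pg`,
#'   `vol_pct_vg`, `dielectric`, `ph_app`, `fb_ph`, `fb_lle`, `mp_ph`,
#'   `mp_lle`, `pct_difference`.
#' @export
table2_reference <- function() {
  path <- system.file("extdata", "table2_eliquids.csv", package = "nicospec",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute the validation table and flag deviations
#'
#' Re-runs the whole pH-method pipeline on the reference e-liquids:
#' dielectric constant from the volume composition, freebase fraction from
#' the apparent pH and D, monoprotonated quantity (fraction for rows whose
#' reference is a fraction, i.e. < 1; otherwise mg/mL from the unrounded
#' fb), and the percent difference against LLE. Each recomputed cell is
#' compared with the bundled reference value and flagged when it deviates
#' beyond tolerance.
#'
#' @param reference Reference rows, as from [table2_reference()].
#' @param calib A `calibration_set`.
#' @param tol Named list of tolerances for the flag comparison: `fb`
#'   (default 0.001), `D` (0.01), `mp` (0.005), `pct` (0.1).
#' @return An object of class `table2_report`: a data frame with the
#'   recomputed columns `D_calc`, `fb_calc`, `mp_calc`, `pct_diff_calc`, a
#'   logical `flagged`, and attribute `n_flags`.
#' @examples
#' rep <- reproduce_table2()
#' attr(rep, "n_flags")   # 0 with the default calibration
#' @export
reproduce_table2 <- function(reference = table2_reference(),
                             calib = default_calibration(),
                             tol = list(fb = 0.001, D = 0.01,
                                        mp = 0.005, pct = 0.1)) {
  required <- c("label", "nicotine_conc", "vol_pct_pg", "vol_pct_vg",
                "dielectric", "ph_app", "fb_ph", "mp_ph", "mp_lle",
                "pct_difference")
  missing <- setdiff(required, names(reference))
  if (length(missing) > 0) {
    stop("reference table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mix <- solvent_mixture(reference$vol_pct_pg, reference$vol_pct_vg)
  D_calc <- mix$dielectric
  spec <- fraction_fb_from_measurements(reference$ph_app, D_calc, calib,
                                        nicotine_conc = reference$nicotine_conc,
                                        extrapolation_policy = "silent")
  fb <- spec$fraction_fb
  # rows whose LLE reference mp is a fraction (< 1) report the mp fraction;
  # the others report the monoprotonated concentration in mg/mL
  as_fraction <- reference$mp_lle < 1
  mp_calc <- ifelse(as_fraction, 1 - fb, reference$nicotine_conc * (1 - fb))
  pct_calc <- percent_difference(mp_calc, reference$mp_lle)
  out <- reference
  out$D_calc <- D_calc
  out$fb_calc <- fb
  out$mp_calc <- mp_calc
  out$pct_diff_calc <- pct_calc
  out$flagged <- abs(D_calc - reference$dielectric) > tol$D |
    abs(fb - reference$fb_ph) > tol$fb |
    abs(mp_calc - reference$mp_ph) > tol$mp |
    abs(pct_calc - reference$pct_difference) > tol$pct
  attr(out, "n_flags") <- sum(out$flagged)
  class(out) <- c("table2_report", "data.frame")
  out
}

#' @export
print.table2_report <- function(x, ...) {
  n <- attr(x, "n_flags")
  cat(sprintf("Validation report: %d rows, %d flagged\n", nrow(x), n))
  show <- data.frame(
    label = x$label, conc = x$nicotine_conc,
    D = round_half_up(x$D_calc, 2),
    fb = round_half_up(x$fb_calc, 3),
    mp = round_half_up(x$mp_calc, 3),
    pct_diff = round_half_up(x$pct_diff_calc, 1),
    flag = ifelse(x$flagged, "*", "")
  )
  print(show, row.names = FALSE)
  invisible(x)
}
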