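#' Correct an apparent pH reading for the solvent offset
#'
#' An aqueous-calibrated glass electrode immersed in a non-aqueous PG/VG
#' medium reads an apparent pH that is offset from the real solution pH by a
#' solvent-specific constant delta: `ph_app = ph_s + delta`. In PG/VG
#' mixtures delta is negative, so the real pH is higher than the reading.
#'
#' @param ph_app Apparent pH (electrode reading).
#' @param delta Solvent offset in pH units (0 in water).
#' @return The real pH `ph_s = ph_app - delta`.
#' @examples
#' correct_ph(6.06, -2.12)   # 8.18
#' @export
correct_ph <- function(ph_app, delta) {
  if (any(!is.finite(ph_app)) || any(!is.finite(delta))) {
    stop("ph_app and delta must be finite", call. = FALSE)
  }
  ph_app - delta
}

#' Freebase fraction from real pH and pKa
#'
#' Henderson-Hasselbalch speciation for a single protonation equilibrium
#' B + H+ <-> BH+: the fraction of the neutral (freebase) form is
#' `fb = 1 / (1 + 10^(pKa - pH))`.
#'
#' @param ph_s Real (solvent-corrected) pH.
#' @param pka pKa of the monoprotonated form in the same solvent.
#' @return Freebase fraction in \[0, 1\]; 0.5 when `ph_s == pka`.
#' @examples
#' fraction_freebase(8.18, 8.7775)   # 0.202
#' @export
fraction_freebase <- function(ph_s, pka) {
  if (any(!is.finite(ph_s)) || any(!is.finite(pka))) {
    stop("ph_s and pka must be finite", call. = FALSE)
  }
  1 / (1 + 10^(pka - ph_s))
}

#' Nicotine speciation from an apparent pH and a dielectric constant
#'
#' The core one-step method: given the apparent pH read by a non-aqueous pH
#' meter and the dielectric constant D of the e-liquid's PG/VG matrix, the
#' nicotine pKa and the pH-scale offset delta are evaluated from their linear
#' D calibrations and combined into the freebase fraction
#' `fb = 1 / (1 + 10^[(a D + b) - (ph_app - (f D + g))])`.
#' When the total nicotine concentration is supplied, the freebase and
#' monoprotonated concentrations are computed from the unrounded fraction.
#'
#' @param ph_app Apparent pH reading(s).
#' @param D Dielectric constant(s) of the liquid, > 0.
#' @param calib A `calibration_set`; defaults to [default_calibration()].
#' @param nicotine_conc Optional total nicotine concentration(s), mg/mL.
#' @param label Optional record label(s), carried through to the output.
#' @param extrapolation_policy Passed to [pka_at()] / [delta_at()].
#' @return A data frame of class `speciation_result` with columns `label`
#'   (if given), `ph_app`, `D`, `delta`, `ph_s`, `pka`, `fraction_fb`,
#'   `fraction_mp`, and — when `nicotine_conc` is given — `nicotine_conc`,
#'   `conc_fb`, `conc_mp` (mg/mL).
#' @examples
#' fraction_fb_from_measurements(6.06, 34.67)            # fb = 0.143
#' fraction_fb_from_measurements(6.28, 27.50, nicotine_conc = 60)
#' @export
fraction_fb_from_measurements <- function(ph_app, D,
                                          calib = default_calibration(),
                                          nicotine_conc = NULL,
                                          label = NULL,
                                          extrapolation_policy = "warn") {
  stopifnot(inherits(calib, "calibration_set"))
  pka <- pka_at(calib$pka_base_model, D, extrapolation_policy)
  delta <- delta_at(calib$delta_model, D, extrapolation_policy)
  ph_s <- correct_ph(ph_app, delta)
  fb <- fraction_freebase(ph_s, pka)
  out <- data.frame(ph_app = ph_app, D = D, delta = delta, ph_s = ph_s,
                    pka = pka, fraction_fb = fb, fraction_mp = 1 - fb)
  if (!is.null(label)) out <- cbind(data.frame(label = label), out)
  if (!is.null(nicotine_conc)) {
    if (any(nicotine_conc < 0, na.rm = TRUE)) {
      stop("nicotine_conc must be non-negative", call. = FALSE)
    }
    out$nicotine_conc <- nicotine_conc
    out$conc_fb <- nicotine_conc * fb
    out$conc_mp <- nicotine_conc * (1 - fb)
  }
  class(out) <- c("speciation_result", "data.frame")
  out
}

#' Ionic strength of a set of ionic species
#'
#' `I = 1/2 * sum(c_i * z_i^2)` over all anions and cations in solution.
#'
#' @param charge Integer charges z_i (one per species).
#' @param conc Molar concentrations c_i, mol/L, >= 0.
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength(c(1, -1), c(0.001, 0.001))   # 0.001
#' @export
ionic_strength <- function(charge, conc) {
  if (length(charge) != length(conc)) {
    stop("charge and conc must have equal length", call. = FALSE)
  }
  if (length(conc) == 0) return(0)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  0.5 * sum(conc * charge^2)
}

#' Davies activity coefficient (log10 scale)
#'
#' Empirical extension of Debye-Hueckel theory:
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)` with the Debye
#' coefficient `A = 1.825e6 * (D T)^(-3/2)`, which is about 0.509 in water at
#' 25 C. Neutral species (z = 0) have log10(gamma) = 0. These activity
#' corrections do not enter the calibrated freebase pipeline — they are
#' absorbed empirically by the fitted delta and pKa(D) constants — but are
#' provided for equilibrium work at non-trivial ionic strength.
#'
#' @param z Integer ion charge.
#' @param I Ionic strength, mol/L, >= 0.
#' @param D Dielectric constant of the medium, > 0 (default water, 78.5).
#' @param temperature Temperature in K, > 0.
#' @return `log10(gamma)` (0 for neutral species or infinite dilution).
#' @examples
#' davies_log_gamma(1, 0.001)         # about -0.0155 in water at 25 C
#' @export
davies_log_gamma <- function(z, I, D = 78.5, temperature = 298.15) {
  if (any(!is.finite(I)) || any(I < 0)) {
    stop("ionic strength must be finite and >= 0", call. = FALSE)
  }
  if (any(D <= 0) || any(temperature <= 0)) {
    stop("D and temperature must be positive", call. = FALSE)
  }
  A <- 1.825e6 * (D * temperature)^(-1.5)
  -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)
}

#' Round half away from zero
#'
#' Reported fractions and concentrations are rounded half-away-from-zero
#' (the convention used in the reference tables), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(0.2945, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
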