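#' Specify a simulated titration experiment
#'
#' Declares the ground truth for a synthetic potentiometric titration:
#' species type, true pKa in the solvent, analyte concentration and volume,
#' titrant concentration, the solvent pH-scale offset injected into the
#' apparent readings, the sampling grid and the read-noise level.
#'
#' @param species One of `"strong_acid"`, `"strong_base"` (titrated by the
#'   opposite strong titrant), `"weak_base"` (e.g. nicotine titrated by a
#'   strong acid) or `"weak_acid"` (e.g. benzoic acid titrated by a strong
#'   base).
#' @param c0 Analyte concentration, mol/L.
#' @param titrant_conc Titrant concentration, mol/L.
#' @param pka_true True pKa of the weak species in the solvent (ignored for
#'   strong species).
#' @param v0 Analyte volume, mL.
#' @param delta_true Solvent offset added to the real pH to produce the
#'   apparent readings (0 in water).
#' @param volume_step Titrant increment, mL.
#' @param max_volume Final cumulative titrant volume, mL; defaults to twice
#'   the stoichiometric equivalence volume.
#' @param noise_sd Standard deviation of Gaussian read noise on the apparent
#'   pH (pH units).
#' @param seed Integer seed for the noise generator (`NULL` leaves the RNG
#'   state alone).
#' @return An object of class `simulation_spec`.
#' @examples
#' simulation_spec("weak_base", c0 = 1e-3, titrant_conc = 1e-3, pka_true = 8.79)
#' @export
simulation_spec <- function(species = c("weak_base", "weak_acid",
                                        "strong_acid", "strong_base"),
                            c0, titrant_conc, pka_true = NA_real_, v0 = 20,
                            delta_true = 0, volume_step = 0.1,
                            max_volume = NULL, noise_sd = 0, seed = NULL) {
  species <- match.arg(species)
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (!is.finite(titrant_conc) || titrant_conc <= 0) {
    stop("titrant_conc must be positive", call. = FALSE)
  }
  if (v0 <= 0 || volume_step <= 0) {
    stop("v0 and volume_step must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (species %in% c("weak_base", "weak_acid") && !is.finite(pka_true)) {
    stop("pka_true is required for weak species", call. = FALSE)
  }
  if (is.null(max_volume)) max_volume <- 2 * c0 * v0 / titrant_conc
  structure(
    list(species = species, pka_true = pka_true, c0 = c0, v0 = v0,
         titrant_conc = titrant_conc, delta_true = delta_true,
         volume_step = volume_step, max_volume = max_volume,
         noise_sd = noise_sd, seed = seed),
    class = "simulation_spec"
  )
}

# Hydrogen-ion concentration solving mass action + charge balance for one
# titration point. All concentrations are post-dilution totals; pKw 14 on
# the real pH scale. The balance function is strictly increasing in [H+],
# so bisection via uniroot is safe; the root is polished to |f| < 1e-12.
solve_hydrogen <- function(species, c_analyte, c_titrant_added, ka, kw = 1e-14) {
  f <- switch(species,
    # strong acid analyte (Cl-) + strong base titrant cation (R+)
    strong_acid = function(h) h + c_titrant_added - c_analyte - kw / h,
    # strong base analyte cation + strong acid titrant (Cl-)
    strong_base = function(h) h + c_analyte - c_titrant_added - kw / h,
    # weak base B titrated by strong acid: [BH+] = C_B h / (h + Ka)
    weak_base = function(h) h + c_analyte * h / (h + ka) - c_titrant_added - kw / h,
    # weak acid HA titrated by strong base: [A-] = C_A Ka / (h + Ka)
    weak_acid = function(h) h + c_titrant_added - c_analyte * ka / (h + ka) - kw / h,
    stop("unknown species", call. = FALSE)
  )
  lo <- 1e-16; hi <- 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no positive hydrogen-ion root: non-physical simulation spec",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-18)$root
  # polish with a few Newton-free bisections if uniroot's tol left residual
  if (abs(f(root)) > 1e-12) {
    lo2 <- root / 2; hi2 <- root * 2
    for (it in 1:200) {
      mid <- sqrt(lo2 * hi2)   # geometric bisection suits the decade scale
      if (f(mid) > 0) hi2 <- mid else lo2 <- mid
      if (abs(f(mid)) < 1e-12) break
    }
    root <- sqrt(lo2 * hi2)
  }
  root
}

#' Simulate a potentiometric titration curve
#'
#' Generates a synthetic (volume, apparent pH) series with known ground
#' truth. At each cumulative titrant volume the post-dilution analyte and
#' titrant concentrations are formed, the hydrogen-ion concentration is
#' solved from the mass-action / charge-balance system for the declared
#' species (water autoprotolysis included, pKw 14), and the apparent reading
#' is `-log10([H+]) + delta_true` plus Gaussian read noise.
#'
#' Solvent autoprotolysis in PG/VG is not modelled explicitly (its constants
#' in these media are not established); the aqueous pKw is used on the
#' corrected scale. Mid-titration chemistry at millimolar concentrations,
#' where the pKa and delta analyses operate, is insensitive to this choice.
#'
#' @param spec A [simulation_spec()].
#' @return A [titration_curve()]; the spec is attached as attribute
#'   `"truth"`.
#' @examples
#' crv <- simulate_titration(simulation_spec("weak_base", c0 = 1e-3,
#'   titrant_conc = 1e-3, pka_true = 8.79, delta_true = -2.05))
#' equivalence_volume(crv)
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  V <- seq(0, spec$max_volume, by = spec$volume_step)
  ka <- if (is.finite(spec$pka_true)) 10^(-spec$pka_true) else NA_real_
  dil <- spec$v0 + V
  c_analyte <- spec$c0 * spec$v0 / dil
  c_titrant <- spec$titrant_conc * V / dil
  h <- vapply(seq_along(V), function(i) {
    solve_hydrogen(spec$species, c_analyte[i], c_titrant[i], ka)
  }, numeric(1))
  ph_s <- -log10(h)
  ph_app <- ph_s + spec$delta_true
  if (spec$noise_sd > 0) {
    ph_app <- ph_app + local_rnorm(length(ph_app), spec$noise_sd, spec$seed)
  }
  direction <- if (spec$species %in% c("weak_base", "strong_base")) {
    "acidimetric"
  } else {
    "alkalimetric"
  }
  crv <- titration_curve(V, ph_app, analyte_volume_ml = spec$v0,
                         titrant_conc = spec$titrant_conc,
                         solvent_label = sprintf("simulated %s", spec$species),
                         direction = direction)
  attr(crv, "truth") <- spec
  crv
}

# Draw Gaussian noise under a local seed without disturbing the caller's
# RNG stream.
local_rnorm <- function(n, sd, seed) {
  if (is.null(seed)) return(stats::rnorm(n, 0, sd))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

#' Generate synthetic e-liquid records with known freebase fraction
#'
#' Samples plausible e-liquid compositions (PG fraction uniform over the
#' PG/VG range, nicotine concentrations from the common commercial strengths
#' 12/28/58/60 mg/mL, target freebase fraction uniform in \[0.01, 0.5\]) and
#' inverts the speciation model to set the apparent pH each record would
#' read, so every record carries exact ground truth.
#'
#' @param n Number of records, >= 1.
#' @param calib A `calibration_set` used for the inversion.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return A data frame with columns `label`, `nicotine_conc`, `vol_pct_pg`,
#'   `vol_pct_vg`, `dielectric`, `ph_app` and the ground truth `fb_true`.
#' @examples
#' fx <- generate_eliquid_fixtures(3, seed = 1)
#' res <- fraction_fb_from_measurements(fx$ph_app, fx$dielectric)
#' all.equal(res$fraction_fb, fx$fb_true)
#' @export
generate_eliquid_fixtures <- function(n, calib = default_calibration(),
                                      seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draw <- function() {
    data.frame(
      vol_pct_pg = stats::runif(n, 0, 100),
      fb_true = stats::runif(n, 0.01, 0.5),
      nicotine_conc = sample(c(12, 28, 58, 60), n, replace = TRUE)
    )
  }
  smp <- if (is.null(seed)) draw() else {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    out <- draw()
    if (had) assign(".Random.seed", old, envir = globalenv())
    out
  }
  mix <- solvent_mixture(smp$vol_pct_pg, 100 - smp$vol_pct_pg)
  D <- mix$dielectric
  pka <- pka_at(calib$pka_base_model, D, "silent")
  delta <- delta_at(calib$delta_model, D, "silent")
  # invert fb = 1/(1 + 10^(pka - ph_s)): ph_s = pka - log10(1/fb - 1)
  ph_s <- pka - log10(1 / smp$fb_true - 1)
  data.frame(
    label = sprintf("synthetic-%03d", seq_len(n)),
    nicotine_conc = smp$nicotine_conc,
    vol_pct_pg = smp$vol_pct_pg,
    vol_pct_vg = 100 - smp$vol_pct_pg,
    dielectric = D,
    ph_app = ph_s + delta,
    fb_true = smp$fb_true,
    stringsAsFactors = FALSE
  )
}
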