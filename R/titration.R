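#' Construct a potentiometric titration curve
#'
#' A series of apparent-pH readings taken at strictly increasing cumulative
#' titrant volumes, plus the metadata needed to analyse it: the analyte
#' volume pipetted into the vessel and (when known) the titrant
#' concentration.
#'
#' @param volume_ml Cumulative titrant volumes, mL, strictly increasing,
#'   at least 5 points.
#' @param ph Apparent pH reading at each volume.
#' @param analyte_volume_ml Volume of analyte solution titrated, mL.
#' @param titrant_conc Titrant concentration, mol/L (`NA` if not standardized).
#' @param solvent_label Free-text solvent description (e.g. `"100/0 PG/VG"`).
#' @param direction `"acidimetric"` (pH falls; base titrated by acid) or
#'   `"alkalimetric"` (pH rises; acid titrated by base).
#' @return An object of class `titration_curve`.
#' @examples
#' v <- seq(0, 40, by = 2)
#' titration_curve(v, 7 + 3 * tanh((v - 20) / 2), direction = "alkalimetric")
#' @export
titration_curve <- function(volume_ml, ph, analyte_volume_ml = 20,
                            titrant_conc = NA_real_, solvent_label = "",
                            direction = c("alkalimetric", "acidimetric")) {
  direction <- match.arg(direction)
  if (length(volume_ml) != length(ph)) {
    stop("volume_ml and ph must have equal length", call. = FALSE)
  }
  if (length(volume_ml) < 5) {
    stop("a titration curve needs at least 5 points", call. = FALSE)
  }
  if (any(!is.finite(volume_ml)) || any(!is.finite(ph))) {
    stop("volumes and pH readings must be finite", call. = FALSE)
  }
  if (any(diff(volume_ml) <= 0)) {
    stop("titrant volumes must be strictly increasing", call. = FALSE)
  }
  if (analyte_volume_ml <= 0) {
    stop("analyte_volume_ml must be positive", call. = FALSE)
  }
  structure(
    list(volume_ml = as.numeric(volume_ml), ph = as.numeric(ph),
         analyte_volume_ml = analyte_volume_ml, titrant_conc = titrant_conc,
         solvent_label = solvent_label, direction = direction),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: %d points, V = %g..%g mL, pH %0.2f..%0.2f (%s)\n",
              length(x$volume_ml), min(x$volume_ml), max(x$volume_ml),
              x$ph[1L], x$ph[length(x$ph)], x$direction))
  if (nzchar(x$solvent_label)) cat("  solvent:", x$solvent_label, "\n")
  invisible(x)
}

#' Equivalence volume by the first-derivative method
#'
#' Locates the equivalence point as the titrant volume maximizing
#' `|d(pH)/dV|`, estimated by central finite differences on the sampled
#' curve, then refined by fitting a parabola through the peak derivative
#' point and its two neighbours (vertex of the quadratic). Ties break to the
#' earliest maximal point. An optional moving-average pre-smoothing of the pH
#' series is available for noisy data.
#'
#' @param curve A [titration_curve()].
#' @param smooth_window Odd integer width of a moving-average filter applied
#'   to the pH readings before differencing; 0 (default) disables smoothing.
#' @return The equivalence volume `v_eq` in the same units as the curve's
#'   volumes.
#' @examples
#' v <- seq(0, 40, by = 0.5)
#' crv <- titration_curve(v, 7 + 3 * tanh(2 * (v - 20)))
#' equivalence_volume(crv)   # 20
#' @export
equivalence_volume <- function(curve, smooth_window = 0) {
  stopifnot(inherits(curve, "titration_curve"))
  v <- curve$volume_ml
  p <- curve$ph
  if (smooth_window > 1) {
    if (smooth_window %% 2 != 1) {
      stop("smooth_window must be odd", call. = FALSE)
    }
    sm <- stats::filter(p, rep(1 / smooth_window, smooth_window), sides = 2)
    keep <- !is.na(sm)
    p[keep] <- sm[keep]
  }
  n <- length(v)
  i <- 2:(n - 1)
  d <- abs((p[i + 1L] - p[i - 1L]) / (v[i + 1L] - v[i - 1L]))
  vd <- v[i]
  # a flat or featureless curve has no derivative peak standing clear of the
  # baseline; require the maximum to dominate the typical slope
  if (max(d) < 3 * (stats::median(d) + 1e-12)) {
    stop("no equivalence point: derivative peak indistinguishable from baseline",
         call. = FALSE)
  }
  k <- which.max(d)              # which.max takes the earliest maximum
  if (k == 1L || k == length(d)) {
    return(vd[k])                # peak at the edge: no neighbours to refine with
  }
  # quadratic through (vd[k-1], d[k-1]), (vd[k], d[k]), (vd[k+1], d[k+1])
  x1 <- vd[k - 1L]; x2 <- vd[k]; x3 <- vd[k + 1L]
  y1 <- d[k - 1L];  y2 <- d[k];  y3 <- d[k + 1L]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (a >= 0) return(x2)         # degenerate (not concave): keep the sample peak
  vertex <- -b / (2 * a)
  # the refinement must stay between the peak's neighbours
  if (vertex < x1 || vertex > x3) x2 else vertex
}

#' Analyte concentration from a standardization titration
#'
#' Stoichiometry at the equivalence point of a 1:1 titration:
#' `c0 = titrant_conc * v_eq / analyte_volume`.
#'
#' @param curve A [titration_curve()].
#' @param titrant_conc Titrant concentration, mol/L (defaults to the value
#'   stored on the curve).
#' @param v_eq Equivalence volume; computed by [equivalence_volume()] when
#'   not supplied.
#' @return The analyte concentration `c0` in mol/L.
#' @export
standardize <- function(curve, titrant_conc = curve$titrant_conc, v_eq = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(titrant_conc) || titrant_conc <= 0) {
    stop("titrant_conc must be a positive number", call. = FALSE)
  }
  if (is.null(v_eq)) v_eq <- equivalence_volume(curve)
  titrant_conc * v_eq / curve$analyte_volume_ml
}

#' pKa from the half-equivalence point of a titration curve
#'
#' For a monoprotic system the real pH at `V = v_eq / 2` equals the
#' analyte's pKa. The apparent pH is interpolated linearly between the
#' bracketing samples and corrected to the real scale with the solvent
#' offset (`pka = pka_app - delta`).
#'
#' @param curve A [titration_curve()].
#' @param v_eq Equivalence volume, mL; computed with [equivalence_volume()]
#'   when not supplied.
#' @param delta Solvent pH-scale offset (0 in water).
#' @return A list with `pka_app` (apparent scale) and `pka` (real scale).
#' @export
half_equivalence_pka <- function(curve, v_eq = NULL, delta = 0) {
  stopifnot(inherits(curve, "titration_curve"))
  if (is.null(v_eq)) v_eq <- equivalence_volume(curve)
  v_half <- v_eq / 2
  if (v_half < min(curve$volume_ml) || v_half > max(curve$volume_ml)) {
    stop("half-equivalence volume lies outside the sampled range", call. = FALSE)
  }
  pka_app <- stats::approx(curve$volume_ml, curve$ph, xout = v_half)$y
  list(pka_app = pka_app, pka = pka_app - delta)
}

#' Solvent pH-scale offset from a strong-acid/strong-base titration
#'
#' Titrating a standardized strong acid with a strong base in the same
#' solvent, the real pH before the equivalence point is fixed by
#' stoichiometry: `[H+] = (c0 V0 - c_t V) / (V0 + V)`. The offset is the
#' mean difference between the apparent readings and this calculated real
#' pH over the points with `V <= frac_pre * v_eq`; points close to
#' equivalence are excluded because the vanishing `[H+]` amplifies volume
#' errors.
#'
#' @param curve A [titration_curve()] of a strong acid titrated by a strong
#'   base.
#' @param c0 Analyte (strong acid) concentration, mol/L.
#' @param titrant_conc Strong-base titrant concentration, mol/L.
#' @param frac_pre Fraction of `v_eq` up to which points are used
#'   (default 0.8).
#' @return The offset delta (pH units), negative in PG/VG media.
#' @export
determine_delta <- function(curve, c0, titrant_conc = curve$titrant_conc,
                            frac_pre = 0.8) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (!is.finite(titrant_conc) || titrant_conc <= 0) {
    stop("titrant_conc must be a positive number", call. = FALSE)
  }
  v0 <- curve$analyte_volume_ml
  v_eq <- c0 * v0 / titrant_conc
  use <- curve$volume_ml <= frac_pre * v_eq
  if (!any(use)) {
    stop("no usable pre-equivalence points (V <= ", frac_pre, " * v_eq)",
         call. = FALSE)
  }
  V <- curve$volume_ml[use]
  h <- (c0 * v0 - titrant_conc * V) / (v0 + V)
  ph_s_calc <- -log10(h)
  mean(curve$ph[use] - ph_s_calc)
}
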