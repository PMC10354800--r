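#' Construct a fitted straight line
#'
#' Internal-facing constructor for the `linear_model` class used for the
#' pKa(D) and delta(D) calibrations.
#'
#' @param slope,intercept Line coefficients (y = slope * x + intercept).
#' @param r_squared Coefficient of determination in \[0, 1\], or `NA` when the
#'   model was not obtained by fitting (e.g. published constants).
#' @param n_points Number of calibration points behind the line.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(slope, intercept, r_squared = NA_real_, n_points = 0L) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = as.integer(n_points)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("y = %.6g * x + %.6g  (R^2 = %s, n = %d)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n_points))
  invisible(x)
}

#' Ordinary least-squares line through calibration points
#'
#' Fits `y = slope * x + intercept` by unweighted least squares via
#' [stats::lm()]; the R-squared is the squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 2 points, with at
#'   least two distinct x values).
#' @return A [linear_model()].
#' @examples
#' fit_linear(c(0, 1), c(0, 1))
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 calibration points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("calibration points must be finite", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("calibration x values are all equal; cannot fit a line", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (diff(range(y)) == 0) 1 else stats::cor(x, y)^2
  linear_model(slope = unname(co[2L]), intercept = unname(co[1L]),
               r_squared = r2, n_points = length(x))
}

#' Evaluate a pKa calibration line at a dielectric constant
#'
#' @param model A [linear_model()] relating pKa to the dielectric constant D.
#' @param D Dielectric constant(s), > 0.
#' @param extrapolation_policy `"warn"` (default) emits a warning when D lies
#'   outside the calibrated range \[27.5, 78.5\] (pure PG to water);
#'   `"error"` fails instead; `"silent"` does neither.
#' @return pKa value(s) `slope * D + intercept`.
#' @examples
#' nic <- linear_model(-0.015, 9.19)
#' pka_at(nic, 27.5)   # 8.7775
#' @export
pka_at <- function(model, D, extrapolation_policy = c("warn", "error", "silent")) {
  eval_calibration_line(model, D, match.arg(extrapolation_policy))
}

#' Evaluate a delta (pH-scale offset) calibration line
#'
#' Same affine evaluation as [pka_at()]; kept separate so delta and pKa
#' calibrations are not interchangeable by accident. Over the PG/VG range the
#' default delta is negative (apparent pH reads below the real pH).
#'
#' @inheritParams pka_at
#' @return delta value(s) in pH units.
#' @examples
#' delta_at(linear_model(0.04, -3.22), 27.5)   # -2.12
#' @export
delta_at <- function(model, D, extrapolation_policy = c("warn", "error", "silent")) {
  eval_calibration_line(model, D, match.arg(extrapolation_policy))
}

eval_calibration_line <- function(model, D, policy) {
  stopifnot(inherits(model, "linear_model"))
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("dielectric constant must be finite and > 0", call. = FALSE)
  }
  out_of_range <- D < 27.5 | D > 78.5
  if (any(out_of_range) && policy != "silent") {
    msg <- sprintf("D = %s outside the calibrated range [27.5, 78.5]",
                   paste(format(D[out_of_range]), collapse = ", "))
    if (policy == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  model$slope * D + model$intercept
}

#' Default calibration points: delta and pKa in four solvents
#'
#' The bundled calibration set measured by potentiometric titration in
#' 100/0, 50/50 and 0/100 PG/VG and in water: the pH-scale offset delta, the
#' pKa of benzoic acid (neutral-acid probe) and the pKa of nicotine's
#' monoprotonated form. The dielectric constant of the 50/50 mixture is
#' computed with [solvent_mixture()]; pure PG, pure VG and water use 27.5,
#' 42.5 and 78.5.
#'
#' @param constants A [solvent_constants()] object.
#' @return A data frame with columns `label`, `D`, `delta`, `pka_acid`
#'   (benzoic acid) and `pka_base` (nicotine).
#' @export
table1_points <- function(constants = solvent_constants()) {
  D50 <- solvent_mixture(50, 50, constants)$dielectric
  data.frame(
    label    = c("100/0 PG/VG", "50/50 PG/VG", "0/100 PG/VG", "100% water"),
    D        = c(constants$D_pg, D50, constants$D_vg, constants$D_water),
    delta    = c(-2.05, -1.78, -1.59, 0),
    pka_acid = c(8.83, 8.11, 7.01, 4.20),
    pka_base = c(8.79, 8.63, 8.50, 8.02),
    stringsAsFactors = FALSE
  )
}

#' Fit a calibration set from (D, value) points
#'
#' Least-squares refit of the three calibration lines — nicotine pKa vs D,
#' benzoic acid pKa vs D and delta vs D — from a calibration point table.
#'
#' @param points A data frame like [table1_points()]: columns `D`, `delta`,
#'   `pka_acid`, `pka_base` and optionally `label`.
#' @return An object of class `calibration_set` with elements
#'   `pka_base_model`, `pka_acid_model`, `delta_model` and `source_points`.
#' @examples
#' fit_calibration(table1_points())
#' @export
fit_calibration <- function(points) {
  required <- c("D", "delta", "pka_acid", "pka_base")
  missing <- setdiff(required, names(points))
  if (length(missing) > 0) {
    stop("calibration points lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(pka_base_model = fit_linear(points$D, points$pka_base),
         pka_acid_model = fit_linear(points$D, points$pka_acid),
         delta_model    = fit_linear(points$D, points$delta),
         source_points  = points),
    class = "calibration_set"
  )
}

#' The default calibration set (published constants)
#'
#' The evaluation constants used throughout the package: nicotine
#' pKa = -0.015 D + 9.19, benzoic acid pKa = -0.090 D + 11.14 and
#' delta = 0.04 D - 3.22, with the reported fit qualities (R-squared 0.982,
#' 0.988 and 0.995). These are the rounded constants as published; a fresh
#' least-squares refit of the same four calibration points (available via
#' `fit_calibration(table1_points())`) reproduces them at the same rounding
#' except for the nicotine intercept, which refits to about 9.16. The
#' published constants are kept as the default so that downstream freebase
#' fractions agree exactly with the reference validation table.
#'
#' @return A `calibration_set`.
#' @examples
#' calib <- default_calibration()
#' pka_at(calib$pka_base_model, 34.67)
#' @export
default_calibration <- function() {
  structure(
    list(pka_base_model = linear_model(-0.015, 9.19, r_squared = 0.982, n_points = 4L),
         pka_acid_model = linear_model(-0.090, 11.14, r_squared = 0.988, n_points = 4L),
         delta_model    = linear_model(0.04, -3.22, r_squared = 0.995, n_points = 4L),
         source_points  = table1_points()),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("Calibration set (", x$pka_base_model$n_points, " solvents)\n", sep = "")
  cat("  pKa nicotine:     "); print(x$pka_base_model)
  cat("  pKa benzoic acid: "); print(x$pka_acid_model)
  cat("  delta:            "); print(x$delta_model)
  invisible(x)
}

#' Read or write calibration points as CSV
#'
#' Plain-text interchange for calibration point sets with columns
#' `label,D,delta,pka_acid,pka_base`.
#'
#' @param path File path.
#' @param points Data frame of calibration points.
#' @return `read_calibration_csv()` returns the data frame;
#'   `write_calibration_csv()` returns `path` invisibly.
#' @export
read_calibration_csv <- function(path) {
  pts <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("label", "D", "delta", "pka_acid", "pka_base")
  missing <- setdiff(required, names(pts))
  if (length(missing) > 0) {
    stop("calibration CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pts
}

#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
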