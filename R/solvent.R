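#' Physical constants for PG/VG/water solvent systems
#'
#' Bundles the dielectric constants of the pure solvents at 25 degrees C
#' together with the densities and molar masses needed to convert a
#' volume-percent PG/VG composition into mole fractions.
#'
#' @param D_pg Dielectric constant of propylene glycol (PG) at 25 C.
#' @param D_vg Dielectric constant of vegetable glycerin (VG, glycerol) at 25 C.
#' @param D_water Dielectric constant of water at 25 C.
#' @param density_pg,density_vg Densities in g/mL at 25 C.
#' @param molar_mass_pg,molar_mass_vg Molar masses in g/mol.
#' @param temperature Temperature in K.
#'
#' @return An object of class `solvent_constants` (a named list).
#' @examples
#' solvent_constants()
#' @export
solvent_constants <- function(D_pg = 27.5, D_vg = 42.5, D_water = 78.5,
                              density_pg = 1.036, density_vg = 1.261,
                              molar_mass_pg = 76.09, molar_mass_vg = 92.09,
                              temperature = 298.15) {
  vals <- c(D_pg, D_vg, D_water, density_pg, density_vg,
            molar_mass_pg, molar_mass_vg, temperature)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all solvent constants must be finite and positive", call. = FALSE)
  }
  if (!(D_water > D_vg && D_vg > D_pg)) {
    stop("expected D_water > D_vg > D_pg", call. = FALSE)
  }
  structure(
    list(D_pg = D_pg, D_vg = D_vg, D_water = D_water,
         density_pg = density_pg, density_vg = density_vg,
         molar_mass_pg = molar_mass_pg, molar_mass_vg = molar_mass_vg,
         temperature = temperature),
    class = "solvent_constants"
  )
}

#' Mole fractions of a PG/VG mixture from volume percentages
#'
#' Converts a volume/volume composition to mole fractions assuming volume
#' additivity: each component's moles per 100 mL of mixture are
#' `vol_pct * density / molar_mass`.
#'
#' @param vol_pct_pg,vol_pct_vg Volume percentages of PG and VG; each pair
#'   must be non-negative and sum to 100 (vectorised).
#' @param constants A [solvent_constants()] object.
#'
#' @return A data frame with columns `x_pg` and `x_vg` (mole fractions
#'   summing to 1).
#' @examples
#' mole_fractions(100, 0)
#' mole_fractions(52.33, 47.67)
#' @export
mole_fractions <- function(vol_pct_pg, vol_pct_vg = 100 - vol_pct_pg,
                           constants = solvent_constants()) {
  if (length(vol_pct_pg) != length(vol_pct_vg)) {
    stop("vol_pct_pg and vol_pct_vg must have equal length", call. = FALSE)
  }
  if (any(!is.finite(vol_pct_pg)) || any(!is.finite(vol_pct_vg)) ||
      any(vol_pct_pg < 0) || any(vol_pct_vg < 0)) {
    stop("volume percentages must be finite and non-negative", call. = FALSE)
  }
  bad <- abs(vol_pct_pg + vol_pct_vg - 100) > 1e-9
  if (any(bad)) {
    stop(sprintf("volume percentages must sum to 100 (first offending entry: %d)",
                 which(bad)[1L]), call. = FALSE)
  }
  n_pg <- vol_pct_pg * constants$density_pg / constants$molar_mass_pg
  n_vg <- vol_pct_vg * constants$density_vg / constants$molar_mass_vg
  x_pg <- n_pg / (n_pg + n_vg)
  data.frame(x_pg = x_pg, x_vg = 1 - x_pg)
}

#' Dielectric constant of a PG/VG mixture
#'
#' Mole-fraction-weighted arithmetic mean of the pure-component dielectric
#' constants: `D = x_pg * D_pg + x_vg * D_vg`.
#'
#' @param x_pg,x_vg Mole fractions in \[0, 1\], summing to 1 (vectorised).
#' @param constants A [solvent_constants()] object.
#'
#' @return Dielectric constant(s), dimensionless, in \[D_pg, D_vg\].
#' @examples
#' dielectric_constant(1, 0)                     # pure PG: 27.5
#' x <- mole_fractions(70, 30)
#' dielectric_constant(x$x_pg, x$x_vg)           # 32.02
#' @export
dielectric_constant <- function(x_pg, x_vg = 1 - x_pg,
                                constants = solvent_constants()) {
  if (any(!is.finite(x_pg)) || any(!is.finite(x_vg)) ||
      any(x_pg < 0) || any(x_pg > 1) || any(x_vg < 0) || any(x_vg > 1)) {
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(x_pg + x_vg - 1) > 1e-9)) {
    stop("mole fractions must sum to 1", call. = FALSE)
  }
  x_pg * constants$D_pg + x_vg * constants$D_vg
}

#' Describe a PG/VG solvent mixture
#'
#' Convenience constructor combining [mole_fractions()] and
#' [dielectric_constant()].
#'
#' @inheritParams mole_fractions
#' @return An object of class `solvent_mixture`: a list with `vol_pct_pg`,
#'   `vol_pct_vg`, `x_pg`, `x_vg` and `dielectric`.
#' @examples
#' solvent_mixture(70, 30)
#' @export
solvent_mixture <- function(vol_pct_pg, vol_pct_vg = 100 - vol_pct_pg,
                            constants = solvent_constants()) {
  x <- mole_fractions(vol_pct_pg, vol_pct_vg, constants)
  structure(
    list(vol_pct_pg = vol_pct_pg, vol_pct_vg = vol_pct_vg,
         x_pg = x$x_pg, x_vg = x$x_vg,
         dielectric = dielectric_constant(x$x_pg, x$x_vg, constants)),
    class = "solvent_mixture"
  )
}

#' @export
print.solvent_mixture <- function(x, ...) {
  cat(sprintf("PG/VG %s/%s %%v/v  (x_PG = %.4f)  D = %.2f\n",
              format(x$vol_pct_pg), format(x$vol_pct_vg),
              x$x_pg, x$dielectric))
  invisible(x)
}
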