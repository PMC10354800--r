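#' Read e-liquid records from CSV
#'
#' Expected columns: `label,nicotine_conc,vol_pct_pg,vol_pct_vg,ph_app`,
#' optionally `dielectric` (which, when present and non-missing, overrides
#' the composition-derived value). Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @param constants A [solvent_constants()] object for the dielectric
#'   computation.
#' @return A data frame of validated records with a filled `dielectric`
#'   column.
#' @export
read_eliquid_csv <- function(path, constants = solvent_constants()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  required <- c("label", "nicotine_conc", "vol_pct_pg", "vol_pct_vg", "ph_app")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("e-liquid CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("e-liquid CSV has no data rows", call. = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate column names", call. = FALSE)
  num_cols <- c("nicotine_conc", "vol_pct_pg", "vol_pct_vg", "ph_app")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("column ", cl, " contains non-numeric values", call. = FALSE)
    }
  }
  bad <- which(!is.finite(df$nicotine_conc) | df$nicotine_conc < 0)
  if (length(bad) > 0) {
    stop("non-negative nicotine_conc required (row ", bad[1L], ")", call. = FALSE)
  }
  bad <- which(!is.finite(df$ph_app) | df$ph_app < 0 | df$ph_app > 14)
  if (length(bad) > 0) {
    stop("ph_app must lie in [0, 14] (row ", bad[1L], ")", call. = FALSE)
  }
  bad <- which(abs(df$vol_pct_pg + df$vol_pct_vg - 100) > 1e-9)
  if (length(bad) > 0) {
    stop("vol_pct_pg + vol_pct_vg must equal 100 (row ", bad[1L], ")",
         call. = FALSE)
  }
  D_comp <- solvent_mixture(df$vol_pct_pg, df$vol_pct_vg, constants)$dielectric
  if ("dielectric" %in% names(df)) {
    df$dielectric <- ifelse(is.na(df$dielectric), D_comp, df$dielectric)
  } else {
    df$dielectric <- D_comp
  }
  df
}

#' Write e-liquid records (or speciation results) to CSV
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eliquid_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration curve from CSV
#'
#' Two numeric columns `volume_ml,ph` preceded by optional metadata comment
#' lines of the form `# key=value` (recognised keys: `analyte_volume_ml`,
#' `titrant_conc`, `solvent`, `direction`). Rows are sorted by volume before
#' validation.
#'
#' @param path CSV file path.
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("volume_ml", "ph") %in% names(df))) {
    stop("titration CSV needs columns volume_ml and ph", call. = FALSE)
  }
  if (!is.numeric(df$volume_ml) || !is.numeric(df$ph)) {
    stop("titration CSV columns must be numeric", call. = FALSE)
  }
  df <- df[order(df$volume_ml), , drop = FALSE]
  if (anyDuplicated(df$volume_ml)) {
    stop("duplicated titrant volumes in ", path, call. = FALSE)
  }
  titration_curve(
    df$volume_ml, df$ph,
    analyte_volume_ml = as.numeric(meta$analyte_volume_ml %||% 20),
    titrant_conc = as.numeric(meta$titrant_conc %||% NA),
    solvent_label = meta$solvent %||% "",
    direction = meta$direction %||% "alkalimetric"
  )
}

#' Write a titration curve to CSV
#'
#' Inverse of [read_titration_csv()]: metadata as `# key=value` comment
#' lines followed by the `volume_ml,ph` table at full precision.
#'
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# analyte_volume_ml=%.15g", curve$analyte_volume_ml), con)
  if (is.finite(curve$titrant_conc)) {
    writeLines(sprintf("# titrant_conc=%.15g", curve$titrant_conc), con)
  }
  if (nzchar(curve$solvent_label)) {
    writeLines(sprintf("# solvent=%s", curve$solvent_label), con)
  }
  writeLines(sprintf("# direction=%s", curve$direction), con)
  writeLines("volume_ml,ph", con)
  writeLines(sprintf("%.15g,%.15g", curve$volume_ml, curve$ph), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
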