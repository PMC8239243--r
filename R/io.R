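# CSV readers with schema validation, and JSON report writers. CSV is the
# sole tabular interchange; parameters and ground truth travel as JSON.

read_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")),
          class = "coordkit_missing_column")
  }
  for (col in required) {
    if (!is.numeric(d[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[col]]))))
      abort(sprintf("%s: column `%s` is not numeric (e.g. row %s).",
                    what, col, paste(head(bad, 3), collapse = ", ")),
            class = "coordkit_bad_type")
    }
  }
  d
}

abort_rows <- function(what, msg, rows, class) {
  abort(sprintf("%s: %s at row(s) %s.", what, msg,
                paste(head(rows, 5), collapse = ", ")),
        class = class)
}

#' Read a metal-ligand titration CSV
#'
#' Expects columns `metal_conc_M`, `ligand_conc_M`, `absorbance`;
#' validates positivity row by row.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_titration <- function(path) {
  d <- read_checked(path, c("metal_conc_M", "ligand_conc_M", "absorbance"),
                    "titration.csv")
  bad <- which(d$metal_conc_M <= 0 | d$ligand_conc_M <= 0)
  if (length(bad) > 0) {
    abort_rows("titration.csv", "non-positive concentration", bad,
               "coordkit_bad_value")
  }
  bad <- which(d$absorbance < 0)
  if (length(bad) > 0) {
    abort_rows("titration.csv", "negative absorbance", bad,
               "coordkit_bad_value")
  }
  d
}

#' Read a DNA titration CSV
#'
#' Expects `dna_conc_M` plus `epsilon_apparent` or `absorbance`.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_dna_titration <- function(path) {
  d <- read_checked(path, "dna_conc_M", "dna_titration.csv")
  if (!any(c("epsilon_apparent", "absorbance") %in% names(d))) {
    abort("dna_titration.csv: need an `epsilon_apparent` or `absorbance` column.",
          class = "coordkit_missing_column")
  }
  bad <- which(d$dna_conc_M <= 0)
  if (length(bad) > 0) {
    abort_rows("dna_titration.csv", "non-positive DNA concentration", bad,
               "coordkit_bad_value")
  }
  d
}

#' Read a TGA trace CSV
#'
#' Expects `temp_C` (strictly increasing) and `mass_pct` in \[0, 100\]
#' (plus noise headroom).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_tga <- function(path) {
  d <- read_checked(path, c("temp_C", "mass_pct"), "tga.csv")
  bad <- which(diff(d$temp_C) <= 0) + 1L
  if (length(bad) > 0) {
    abort_rows("tga.csv", "temperature not strictly increasing", bad,
               "coordkit_nonmonotone_temperature")
  }
  bad <- which(d$mass_pct < -1 | d$mass_pct > 101)
  if (length(bad) > 0) {
    abort_rows("tga.csv", "mass percent outside [0, 100]", bad,
               "coordkit_bad_value")
  }
  d
}

#' Read an MTT plate CSV
#'
#' Expects `dose_ug_ml` and `od560`; optional `od620_bg` and `replicate`.
#' Dose-0 rows are the untreated controls.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_plate <- function(path) {
  d <- read_checked(path, c("dose_ug_ml", "od560"), "plate.csv")
  bad <- which(d$dose_ug_ml < 0)
  if (length(bad) > 0) {
    abort_rows("plate.csv", "negative dose", bad, "coordkit_bad_value")
  }
  d
}

#' Write a fit report as JSON
#'
#' Serializes a fitted object's [glance()] row (and [tidy()] table) to a
#' JSON file so any report regenerates bit-identically from the same
#' inputs.
#'
#' @param fit A fitted object with `glance()`/`tidy()` methods, or a
#'   tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (is.data.frame(fit)) {
    list(table = fit)
  } else {
    list(summary = as.list(glance(fit)), points = tidy(fit))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
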