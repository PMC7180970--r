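# CSV I/O for the pipeline's three plain-text formats:
#   spectra:  sample_id,230,231,...,700   (one row per sample, values in AU)
#   assays:   sample_id,anthocyanins,tannins,tips   (mg/L assay equivalents)
#   standard: single-row spectra file
# Output files may carry "# key: value" metadata header lines; readers skip
# any line starting with '#'.

read_csv_strict <- function(path, context) {
  if (!file.exists(path)) {
    wp_data_error(sprintf("%s: file not found: %s", context, path))
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    wp_data_error(sprintf("%s: no data rows in %s", context, path))
  }
  df
}

parse_numeric_cols <- function(df, cols, context) {
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !(is.na(df[[cn]]) | df[[cn]] == ""))
    if (length(bad) > 0) {
      wp_data_error(sprintf(
        "%s: non-numeric value '%s' at row %d, column '%s'",
        context, df[[cn]][bad[1]], bad[1], cn
      ))
    }
    if (anyNA(v)) {
      wp_data_error(sprintf(
        "%s: missing value at row %d, column '%s'",
        context, which(is.na(v))[1], cn
      ))
    }
    df[[cn]] <- v
  }
  df
}

#' Read and write wide-format spectra CSV files
#'
#' The spectra format has a header `sample_id,230,231,...,700` and one row
#' per sample; wavelengths are integer nm and are validated against the
#' expected grid. Lines beginning with `#` are treated as metadata comments.
#'
#' @param path File path.
#' @param grid Optional `wavelength_grid` the file must match; a missing or
#'   extra wavelength column is reported by name.
#' @param instrument_id,dilution_ratio Optional labels attached to the set.
#' @return `read_spectra()` returns a `spectra_set`; `read_standard()` a
#'   single-row `spectra_set` (errors if the file holds more than one row).
#' @export
read_spectra <- function(path, grid = NULL, instrument_id = NA_character_,
                         dilution_ratio = NA_real_) {
  df <- read_csv_strict(path, "spectra")
  names(df)[1] <- "sample_id"
  wl_cols <- names(df)[-1]
  if (suppressWarnings(anyNA(as.integer(wl_cols)))) {
    wp_data_error("spectra: header wavelengths must be integer nm")
  }
  if (!is.null(grid)) {
    want <- as.character(grid_wavelengths(grid))
    miss <- setdiff(want, wl_cols)
    if (length(miss) > 0) {
      wp_data_error(sprintf(
        "spectra: missing wavelength column(s): %s",
        paste(head(miss, 5), collapse = ", ")
      ))
    }
    extra <- setdiff(wl_cols, want)
    if (length(extra) > 0) {
      wp_data_error(sprintf(
        "spectra: unexpected wavelength column(s): %s",
        paste(head(extra, 5), collapse = ", ")
      ))
    }
  }
  df <- parse_numeric_cols(df, wl_cols, "spectra")
  spectra_set(df, grid = grid, instrument_id = instrument_id,
              dilution_ratio = dilution_ratio)
}

#' @rdname read_spectra
#' @param s A `spectra_set` to write.
#' @param meta Optional named character vector written as `# key: value`
#'   header lines.
#' @export
write_spectra <- function(s, path, meta = NULL) {
  s <- assert_spectra(s)
  body <- readr::format_csv(as_tibble(unclass_spectra(s)))
  writeLines(c(format_meta(meta), sub("\n$", "", body)), path)
  cli_register(path)
  invisible(path)
}

unclass_spectra <- function(s) {
  out <- as_tibble(s)
  class(out) <- class(tibble())
  out
}

format_meta <- function(meta) {
  if (is.null(meta) || length(meta) == 0) return(character())
  sprintf("# %s: %s", names(meta), as.character(meta))
}

#' @rdname read_spectra
#' @export
read_standard <- function(path, grid = NULL) {
  s <- read_spectra(path, grid = grid)
  if (nrow(s) != 1) {
    wp_data_error(sprintf(
      "standard: expected exactly one spectrum, found %d", nrow(s)
    ))
  }
  s
}

#' Read and write phenolic assay tables
#'
#' Assay tables pair sample ids with the three reference concentrations in
#' mg/L assay equivalents: `anthocyanins` (malvidin-3-glucoside equivalents),
#' `tannins` (catechin equivalents, protein precipitation), `tips` (total
#' iron reactive phenolics, catechin equivalents).
#'
#' @param path File path.
#' @return A tibble with columns `sample_id`, `anthocyanins`, `tannins`,
#'   `tips`.
#' @export
read_assays <- function(path) {
  df <- read_csv_strict(path, "assays")
  names(df)[1] <- "sample_id"
  need <- c("anthocyanins", "tannins", "tips")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    wp_data_error(sprintf(
      "assays: missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  df <- parse_numeric_cols(df[c("sample_id", need)], need, "assays")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    wp_data_error("assays: sample_ids must be unique")
  }
  if (any(as.matrix(df[need]) < 0)) {
    wp_data_error("assays: concentrations must be non-negative")
  }
  as_tibble(df)
}

#' @rdname read_assays
#' @param assays Assay tibble to write.
#' @param meta Optional named character vector of metadata header lines.
#' @export
write_assays <- function(assays, path, meta = NULL) {
  body <- readr::format_csv(assays)
  writeLines(c(format_meta(meta), sub("\n$", "", body)), path)
  cli_register(path)
  invisible(path)
}

#' Read a timepoint-series manifest
#'
#' The manifest is a small CSV with columns `week,label,spectra,assays`
#' listing, per timepoint, the week index (0 = initial), a display label and
#' the paths (relative to the manifest) of the spectra and assay CSVs.
#'
#' @param path Manifest path.
#' @return A `timepoint_series`.
#' @export
read_series_manifest <- function(path) {
  df <- read_csv_strict(path, "series manifest")
  need <- c("week", "label", "spectra", "assays")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    wp_data_error(sprintf(
      "series manifest: missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  df <- parse_numeric_cols(df, "week", "series manifest")
  timepoint_series(
    week = as.integer(df$week),
    label = df$label,
    spectra = purrr::map(resolve(df$spectra), read_spectra),
    assays = purrr::map(resolve(df$assays), read_assays)
  )
}
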