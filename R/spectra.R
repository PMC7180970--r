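#' Define a wavelength grid
#'
#' Every spectrum in the pipeline lives on a shared integer wavelength grid.
#' The default grid is 230-700 nm in 1 nm increments (471 points), the
#' acquisition range of the spectrophotometers the workflow targets.
#'
#' @param start_nm,end_nm Integer grid bounds in nm, `start_nm < end_nm`.
#' @param step_nm Integer increment in nm, at least 1.
#' @return A `wavelength_grid` list with fields `start_nm`, `end_nm`,
#'   `step_nm` and `n_points`.
#' @examples
#' wavelength_grid()          # 230-700 nm, 471 points
#' wavelength_grid(400, 700)  # visible only
#' @export
wavelength_grid <- function(start_nm = 230L, end_nm = 700L, step_nm = 1L) {
  start_nm <- as.integer(start_nm)
  end_nm <- as.integer(end_nm)
  step_nm <- as.integer(step_nm)
  if (is.na(start_nm) || is.na(end_nm) || is.na(step_nm)) {
    wp_usage_error("wavelength grid bounds must be integers")
  }
  if (start_nm >= end_nm) wp_usage_error("grid requires start_nm < end_nm")
  if (step_nm < 1L) wp_usage_error("grid step must be at least 1 nm")
  if ((end_nm - start_nm) %% step_nm != 0L) {
    wp_usage_error("grid span must be an exact multiple of the step")
  }
  structure(
    list(
      start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
      n_points = (end_nm - start_nm) %/% step_nm + 1L
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d-%d nm, step %d nm (%d points)\n",
    x$start_nm, x$end_nm, x$step_nm, x$n_points
  ))
  invisible(x)
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @return `grid_wavelengths()` returns the integer wavelengths of the grid.
#' @export
grid_wavelengths <- function(grid) {
  seq.int(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

grid_from_wavelengths <- function(wl, context = "spectra") {
  wl <- as.integer(wl)
  if (anyNA(wl)) {
    wp_data_error(sprintf("%s: wavelength columns must be integer nm", context))
  }
  if (anyDuplicated(wl)) {
    wp_data_error(sprintf(
      "%s: duplicate wavelength column(s): %s",
      context, paste(unique(wl[duplicated(wl)]), collapse = ", ")
    ))
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    wp_data_error(sprintf("%s: wavelength columns must increase", context))
  }
  step <- min(diff(wl))
  full <- seq.int(wl[1], wl[length(wl)], by = step)
  missing <- setdiff(full, wl)
  if (length(missing) > 0) {
    wp_data_error(sprintf(
      "%s: missing wavelength column(s): %s",
      context, paste(head(missing, 5), collapse = ", ")
    ))
  }
  wavelength_grid(wl[1], wl[length(wl)], step)
}

#' Construct a spectra set
#'
#' A spectra set is a tibble with a `sample_id` column followed by one column
#' per grid wavelength (named `"230"`, `"231"`, ...), one row per sample. The
#' wavelength grid is stored once per set so that cross-sample alignment is a
#' structural property, not a runtime check. Negative absorbances are allowed
#' (spectral subtraction can produce them); non-finite values are rejected.
#'
#' @param x A data frame with `sample_id` plus wavelength columns, or a
#'   numeric matrix (rows = samples, columns named by wavelength).
#' @param grid Optional `wavelength_grid` the columns must match exactly.
#' @param instrument_id Optional instrument label.
#' @param dilution_ratio Optional dilution factor (e.g. 5 for a 1:5 dilution).
#' @return A `spectra_set` tibble.
#' @export
spectra_set <- function(x, grid = NULL, instrument_id = NA_character_,
                        dilution_ratio = NA_real_) {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
    x <- dplyr::bind_cols(tibble(sample_id = ids), as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    if (names(x)[1] != "" && suppressWarnings(anyNA(as.integer(names(x)[1])))) {
      names(x)[1] <- "sample_id"
    } else {
      wp_data_error("spectra require a sample_id column")
    }
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    wp_data_error("sample_ids must be unique within a spectra set")
  }
  inferred <- grid_from_wavelengths(names(x)[-1])
  if (!is.null(grid)) {
    if (!identical(unclass(grid)[c("start_nm", "end_nm", "step_nm")],
                   unclass(inferred)[c("start_nm", "end_nm", "step_nm")])) {
      miss <- setdiff(grid_wavelengths(grid), grid_wavelengths(inferred))
      if (length(miss) > 0) {
        wp_data_error(sprintf(
          "spectra do not match the declared grid; missing wavelength(s): %s",
          paste(head(miss, 5), collapse = ", ")
        ))
      }
      wp_data_error("spectra wavelengths do not match the declared grid")
    }
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) wp_data_error("absorbance values must be numeric")
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    wp_data_error(sprintf(
      "non-finite absorbance at sample '%s', wavelength %s nm",
      x$sample_id[bad[1]], names(x)[-1][bad[2]]
    ))
  }
  structure(
    x,
    class = c("spectra_set", class(tibble())),
    wp_grid = inferred,
    wp_instrument = as.character(instrument_id),
    wp_dilution = as.numeric(dilution_ratio)
  )
}

new_spectra_like <- function(template, sample_id, values, wl) {
  colnames(values) <- as.character(wl)
  spectra_set(
    dplyr::bind_cols(tibble(sample_id = sample_id),
                     as_tibble(values, .name_repair = "minimal")),
    instrument_id = attr(template, "wp_instrument") %||% NA_character_,
    dilution_ratio = attr(template, "wp_dilution") %||% NA_real_
  )
}

#' @rdname spectra_set
#' @param s A `spectra_set`.
#' @return `spectra_grid()` returns the set's `wavelength_grid`;
#'   `wavelengths()` its integer wavelengths; `spectra_matrix()` the
#'   absorbance values as a samples-by-wavelengths matrix with sample ids as
#'   row names.
#' @export
spectra_grid <- function(s) {
  attr(s, "wp_grid") %||% grid_from_wavelengths(setdiff(names(s), "sample_id"))
}

#' @rdname spectra_set
#' @export
wavelengths <- function(s) grid_wavelengths(spectra_grid(s))

#' @rdname spectra_set
#' @export
spectra_matrix <- function(s) {
  m <- as.matrix(s[setdiff(names(s), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- s$sample_id
  m
}

assert_spectra <- function(s, arg = "spectra") {
  if (!inherits(s, "spectra_set")) {
    if (is.data.frame(s)) return(spectra_set(s))
    wp_usage_error(sprintf("%s must be a spectra_set or compatible data frame", arg))
  }
  s
}

assert_shared_grid <- function(a, b, what = "spectra") {
  if (!identical(wavelengths(a), wavelengths(b))) {
    wp_usage_error(sprintf("%s must share the same wavelength grid", what))
  }
  invisible(TRUE)
}

#' Sum-normalize spectra
#'
#' Rescales each spectrum so the absorbance at each wavelength is a fraction
#' of the sum over the full grid, making the spectrum sum to one. This is the
#' transformation applied to the malvidin chloride standard before it is used
#' as a shape template: it removes concentration and pathlength scale while
#' preserving spectral shape. The denominator is always the sum over the
#' entire grid, never a sub-range.
#'
#' @param s A `spectra_set` (any number of rows).
#' @return A `spectra_set` of the same shape; each row sums to 1.
#' @examples
#' lib <- default_component_library()
#' mc <- sum_normalize(lib$standard)
#' sum(spectra_matrix(mc))  # 1
#' @export
sum_normalize <- function(s) {
  s <- assert_spectra(s)
  m <- spectra_matrix(s)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    wp_data_error(sprintf(
      "cannot sum-normalize: non-positive spectrum sum for sample(s) %s",
      paste(head(s$sample_id[tot <= 0], 5), collapse = ", ")
    ))
  }
  new_spectra_like(s, s$sample_id, m / tot, wavelengths(s))
}

#' Absorbance at a single wavelength
#'
#' Exact lookup of the stored value at a grid wavelength; no interpolation is
#' ever performed (the pipeline assumes 1 nm native instrument increments).
#'
#' @param s A `spectra_set`.
#' @param wavelength A wavelength that must lie exactly on the grid.
#' @return A tibble with `sample_id` and `absorbance`.
#' @export
absorbance_at <- function(s, wavelength) {
  s <- assert_spectra(s)
  wl <- wavelengths(s)
  if (length(wavelength) != 1 || !is.finite(wavelength) ||
      wavelength != as.integer(wavelength) || !(as.integer(wavelength) %in% wl)) {
    wp_usage_error(sprintf(
      "wavelength %s nm is not on the %d-%d nm (step %d) grid",
      format(wavelength), min(wl), max(wl), spectra_grid(s)$step_nm
    ))
  }
  tibble(
    sample_id = s$sample_id,
    absorbance = unname(spectra_matrix(s)[, as.character(as.integer(wavelength))])
  )
}

absorbance_vec <- function(s, wavelength) {
  a <- absorbance_at(s, wavelength)
  setNames(a$absorbance, a$sample_id)
}

#' Restrict spectra to a wavelength window
#'
#' Returns the sub-spectra on `[lo, hi]` inclusive. Restriction partitions
#' exactly: `restrict_spectra(s, 230, 429)` and `restrict_spectra(s, 430, 700)`
#' together reproduce `s`. Used to take the visible range (430-700 nm,
#' anthocyanin features) and the UV range (230-429 nm, tannin/TIP features).
#'
#' @param s A `spectra_set`.
#' @param lo,hi Grid wavelengths with `lo <= hi`.
#' @return A `spectra_set` on the restricted grid.
#' @export
restrict_spectra <- function(s, lo, hi) {
  s <- assert_spectra(s)
  wl <- wavelengths(s)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (!(lo %in% wl) || !(hi %in% wl) || lo > hi) {
    wp_usage_error(sprintf(
      "restriction bounds [%s, %s] must be on-grid with lo <= hi", lo, hi
    ))
  }
  keep <- wl >= lo & wl <= hi
  new_spectra_like(s, s$sample_id, spectra_matrix(s)[, keep, drop = FALSE], wl[keep])
}

#' @export
print.spectra_set <- function(x, ...) {
  g <- spectra_grid(x)
  cat(sprintf(
    "<spectra_set> %d sample(s), %d-%d nm step %d (%d points)\n",
    nrow(x), g$start_nm, g$end_nm, g$step_nm, g$n_points
  ))
  NextMethod()
}
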