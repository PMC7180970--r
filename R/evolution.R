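#' Longitudinal timepoint series
#'
#' Post-fermentation phenolic evolution is tracked with a weekly series of
#' paired spectra and assay tables: week 0 ("Initial") immediately after
#' fermentation, then one set per week. Within each timepoint the spectra and
#' assays must cover matched sample ids; week indices must strictly increase.
#'
#' @param week Integer week indices (0 = initial).
#' @param label Display labels (default `"Initial"`, `"Week 1"`, ...).
#' @param spectra List of `spectra_set`s, one per timepoint.
#' @param assays List of assay tibbles, one per timepoint.
#' @return A `timepoint_series` tibble with list-columns `spectra`, `assays`.
#' @export
timepoint_series <- function(week, label = NULL, spectra, assays) {
  week <- as.integer(week)
  if (anyNA(week) || is.unsorted(week, strictly = TRUE)) {
    wp_usage_error("week indices must be strictly increasing integers")
  }
  if (length(spectra) != length(week) || length(assays) != length(week)) {
    wp_usage_error("one spectra set and one assay table required per week")
  }
  label <- label %||% ifelse(week == 0, "Initial", paste("Week", week))
  spectra <- purrr::map(spectra, assert_spectra)
  purrr::walk2(spectra, assays, function(s, a) {
    if (length(intersect(s$sample_id, a$sample_id)) == 0) {
      wp_data_error("timepoint has no sample ids shared between spectra and assays")
    }
  })
  structure(
    tibble(week = week, label = label, spectra = spectra, assays = assays),
    class = c("timepoint_series", class(tibble()))
  )
}

# Matched (absorbance, assay) pairs for one timepoint; complete cases only.
timepoint_pairs <- function(spectra, assays, wavelength, phenolic) {
  ids <- intersect(spectra$sample_id, assays$sample_id)
  a <- absorbance_vec(spectra[match(ids, spectra$sample_id), ], wavelength)
  y <- assays[[phenolic]][match(ids, assays$sample_id)]
  keep <- is.finite(a) & is.finite(y)
  list(absorbance = unname(a[keep]), assay = y[keep], n = sum(keep))
}

safe_pearson <- function(x, y) {
  tryCatch(pearson(x, y), wp_error = function(e) NA_real_)
}

#' Assay-versus-wavelength correlation table
#'
#' For each timepoint, correlates each phenolic's assay values with the
#' wines' absorbance at the requested wavelengths (default 520 nm, the
#' anthocyanin visible maximum, and 280 nm, the phenolic UV band). As wines
#' age and polymeric pigments form, these correlations drift — the table
#' makes the drift visible week by week. Row labels follow the convention
#' `"Anthos @520"`, `"TIPs@520"`, `"Tannin@520"`, `"Anthos@280"`, ....
#'
#' @param series A `timepoint_series`.
#' @param wavelengths_nm Wavelengths to correlate at (default `c(520, 280)`).
#' @return A wide `evolution_table` tibble: `phenolic_id` rows by timepoint
#'   label columns, entries in \[-1, 1\]. Attribute `wp_cells` holds the long
#'   form with per-cell sample counts; timepoints with fewer than 2 usable
#'   samples yield `NA` with a warning recorded there.
#' @export
assay_wavelength_table <- function(series, wavelengths_nm = c(520, 280)) {
  if (!inherits(series, "timepoint_series")) {
    wp_usage_error("series must be a timepoint_series")
  }
  phen <- c(Anthos = "anthocyanins", TIPs = "tips", Tannin = "tannins")
  cells <- tidyr::expand_grid(
    wavelength = as.integer(wavelengths_nm),
    display = names(phen),
    t = seq_len(nrow(series))
  )
  cells <- dplyr::mutate(
    cells,
    phenolic = unname(phen[.data$display]),
    label = series$label[.data$t],
    week = series$week[.data$t]
  )
  res <- purrr::pmap(cells, function(wavelength, display, t, phenolic, ...) {
    pr <- timepoint_pairs(series$spectra[[t]], series$assays[[t]],
                          wavelength, phenolic)
    if (pr$n < 2) {
      warn(sprintf("timepoint '%s': fewer than 2 usable samples; cell skipped",
                   series$label[t]))
      return(list(r = NA_real_, n = pr$n))
    }
    list(r = safe_pearson(pr$absorbance, pr$assay), n = pr$n)
  })
  cells$r <- purrr::map_dbl(res, "r")
  cells$n <- purrr::map_int(res, ~ as.integer(.x$n))
  # row labels follow the reporting convention, including the historical
  # space in "Anthos @520"
  cells$phenolic_id <- paste0(
    cells$display,
    ifelse(cells$display == "Anthos" & cells$wavelength == 520, " @", "@"),
    cells$wavelength
  )
  wide <- cells |>
    dplyr::select("phenolic_id", "label", "r") |>
    tidyr::pivot_wider(names_from = "label", values_from = "r")
  wide <- wide[match(unique(cells$phenolic_id), wide$phenolic_id), ]
  structure(wide,
            class = c("evolution_table", class(tibble())),
            wp_cells = cells,
            wp_kind = "assay_wavelength")
}

#' Assay cross-correlation table
#'
#' Per-timepoint Pearson correlations between the anthocyanin assay and the
#' TIP and tannin assays. Early after fermentation these are non-negative;
#' as anthocyanins condense into polymeric pigments (consuming anthocyanin
#' preferentially in tannin-rich wines) the week-4 correlations turn
#' negative.
#'
#' @param series A `timepoint_series`.
#' @return A wide `evolution_table`: rows `"TIPs"` (anthocyanins vs TIPs) and
#'   `"Tannins"` (anthocyanins vs tannins), timepoint label columns.
#' @export
assay_cross_table <- function(series) {
  if (!inherits(series, "timepoint_series")) {
    wp_usage_error("series must be a timepoint_series")
  }
  pairs <- tibble(
    phenolic_id = c("TIPs", "Tannins"),
    other = c("tips", "tannins")
  )
  cells <- tidyr::expand_grid(pairs, t = seq_len(nrow(series))) |>
    dplyr::mutate(label = series$label[.data$t], week = series$week[.data$t])
  res <- purrr::pmap(cells, function(phenolic_id, other, t, ...) {
    a <- series$assays[[t]]
    keep <- is.finite(a$anthocyanins) & is.finite(a[[other]])
    if (sum(keep) < 2) {
      warn(sprintf("timepoint '%s': fewer than 2 usable samples; cell skipped",
                   series$label[t]))
      return(list(r = NA_real_, n = sum(keep)))
    }
    list(r = safe_pearson(a$anthocyanins[keep], a[[other]][keep]),
         n = sum(keep))
  })
  cells$r <- purrr::map_dbl(res, "r")
  cells$n <- purrr::map_int(res, ~ as.integer(.x$n))
  wide <- cells |>
    dplyr::select("phenolic_id", "label", "r") |>
    tidyr::pivot_wider(names_from = "label", values_from = "r")
  structure(wide,
            class = c("evolution_table", class(tibble())),
            wp_cells = cells,
            wp_kind = "assay_cross")
}

#' Peak-correlation wavelength
#'
#' Scans every grid wavelength and returns the one whose absorbance
#' correlates most strongly (by absolute value) with the assay values,
#' together with the signed correlation. The absolute value drives the
#' search because aging can flip associations negative while Table-style
#' reports keep the sign; ties go to the lowest wavelength. For fermenting
#' wines the anthocyanin peak sits in the visible (~520 nm); weeks after
#' fermentation, pigment formation drags it into the UV.
#'
#' @param spectra A `spectra_set` for one timepoint.
#' @param assay_values Numeric assay vector aligned with `spectra` rows (or a
#'   named vector matched by sample id).
#' @return A one-row tibble: `wavelength`, `correlation`, `n`.
#' @export
peak_correlation_wavelength <- function(spectra, assay_values) {
  spectra <- assert_spectra(spectra)
  y <- if (!is.null(names(assay_values))) {
    as.numeric(assay_values[spectra$sample_id])
  } else {
    as.numeric(assay_values)
  }
  if (length(y) != nrow(spectra)) {
    wp_usage_error("assay_values must align with the spectra rows")
  }
  keep <- is.finite(y)
  if (sum(keep) < 2) wp_usage_error("at least 2 samples required")
  y <- y[keep]
  if (sd(y) == 0) {
    wp_data_error("degenerate assay column: constant values")
  }
  m <- spectra_matrix(spectra)[keep, , drop = FALSE]
  r <- suppressWarnings(drop(cor(m, y)))
  r[!is.finite(r)] <- 0  # constant wavelength columns carry no signal
  best <- which.max(abs(r))  # which.max takes the first (lowest wavelength) tie
  tibble(
    wavelength = wavelengths(spectra)[best],
    correlation = r[best],
    n = sum(keep)
  )
}

#' @describeIn assay_wavelength_table Line plot of each row's correlation
#'   across timepoints.
#' @param object An `evolution_table`.
#' @param ... Unused.
#' @export
autoplot.evolution_table <- function(object, ...) {
  cells <- attr(object, "wp_cells")
  ggplot2::ggplot(cells, ggplot2::aes(.data$week, .data$r,
                                      colour = .data$phenolic_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "weeks after fermentation", y = "Pearson correlation",
                  colour = NULL)
}
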