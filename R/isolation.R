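#' Estimate the anthocyanin UV contribution of wine spectra
#'
#' Red wine phenolics overlap heavily in the UV, so the absorbance a wine
#' shows below 430 nm mixes anthocyanins with tannins and total iron reactive
#' phenolics (TIPs). Anthocyanins, however, are the only class with visible
#' absorbance, so their level can be anchored at 520 nm and their UV shape
#' supplied by an external malvidin chloride (MC) standard. For every sample
#' i and UV wavelength j the estimated anthocyanin absorbance is
#'
#'   estimate\[i, j\] = MCnorm\[j\] * A\[i, 520\] / MCnorm\[520\]
#'
#' where `MCnorm` is the sum-normalized standard spectrum. The estimate is by
#' construction proportional to the UV portion of the standard, scaled per
#' sample by its 520 nm absorbance.
#'
#' @param spectra A `spectra_set` of raw wine spectra on the full grid.
#' @param standard A single-row `spectra_set`: the sum-normalized MC standard
#'   on the same grid (each value a fraction of the spectrum total; must sum
#'   to 1 within 1e-9). Use [sum_normalize()] on a raw standard first.
#' @param anchor Visible anchor wavelength in nm (default 520, the
#'   anthocyanin absorbance maximum at wine pH).
#' @param boundary UV/visible boundary in nm (default 430); the correction
#'   applies to wavelengths strictly below it, i.e. 230-429 nm on the default
#'   grid.
#' @return A `spectra_set` on `[grid start, boundary - 1]` nm.
#' @export
estimate_anthocyanin_uv <- function(spectra, standard, anchor = 520,
                                    boundary = 430) {
  spectra <- assert_spectra(spectra)
  standard <- assert_spectra(standard, "standard")
  if (nrow(standard) != 1) {
    wp_usage_error("standard must contain exactly one spectrum")
  }
  assert_shared_grid(spectra, standard, "spectra and standard")
  std_total <- sum(spectra_matrix(standard))
  if (abs(std_total - 1) > 1e-9) {
    wp_usage_error(sprintf(
      "standard must be sum-normalized (sums to %.6g, expected 1); apply sum_normalize() first",
      std_total
    ))
  }
  mc_anchor <- absorbance_vec(standard, anchor)[[1]]
  if (mc_anchor <= 0) {
    wp_data_error(sprintf(
      "degenerate standard: normalized MC absorbance at %d nm is %.3g (must be > 0)",
      as.integer(anchor), mc_anchor
    ))
  }
  g <- spectra_grid(spectra)
  if (boundary <= g$start_nm || boundary > g$end_nm) {
    wp_usage_error("UV boundary must lie inside the grid")
  }
  scale_factor <- absorbance_vec(spectra, anchor) / mc_anchor
  mc_uv <- spectra_matrix(restrict_spectra(standard, g$start_nm, boundary - g$step_nm))
  est <- outer(unname(scale_factor), drop(mc_uv))
  new_spectra_like(spectra, spectra$sample_id, est,
                   wavelengths(spectra)[wavelengths(spectra) < boundary])
}

#' Isolate the tannin/TIP UV spectrum by anthocyanin subtraction
#'
#' Subtracts the per-sample anthocyanin UV estimate (see
#' [estimate_anthocyanin_uv()]) from the raw spectra below the UV/visible
#' boundary, leaving the corrected UV spectrum attributable to tannins and
#' TIPs. Subtraction residuals are left negative by default so that
#' downstream regression sees unbiased features; set `clip_negative = TRUE`
#' to floor them at zero for display.
#'
#' @inheritParams estimate_anthocyanin_uv
#' @param clip_negative If `TRUE`, negative corrected values are set to 0 and
#'   the result's `clipped` flag records that clipping occurred.
#' @return An `isolation_result`: a list with `raw`, `anthocyanin_estimate_uv`,
#'   `corrected_uv` (all `spectra_set`s), a per-sample `scale_factor` tibble
#'   (raw absorbance at the anchor divided by the normalized standard's anchor
#'   value), the `clipped` flag and the parameters used.
#' @examples
#' lib <- default_component_library()
#' sim <- simulate_calibration_set(mixture_design(n = 5, seed = 1), lib)
#' iso <- isolate_uv(sim$spectra, sum_normalize(lib$standard))
#' iso$corrected_uv
#' @export
isolate_uv <- function(spectra, standard, clip_negative = FALSE, anchor = 520,
                       boundary = 430) {
  spectra <- assert_spectra(spectra)
  standard <- assert_spectra(standard, "standard")
  est <- estimate_anthocyanin_uv(spectra, standard, anchor = anchor,
                                 boundary = boundary)
  g <- spectra_grid(spectra)
  raw_uv <- restrict_spectra(spectra, g$start_nm, boundary - g$step_nm)
  corrected <- spectra_matrix(raw_uv) - spectra_matrix(est)
  clipped <- FALSE
  if (isTRUE(clip_negative) && any(corrected < 0)) {
    corrected[corrected < 0] <- 0
    clipped <- TRUE
  }
  mc_anchor <- absorbance_vec(sum_normalize(standard), anchor)[[1]]
  structure(
    list(
      raw = spectra,
      anthocyanin_estimate_uv = est,
      corrected_uv = new_spectra_like(spectra, spectra$sample_id, corrected,
                                      wavelengths(est)),
      scale_factor = tibble(
        sample_id = spectra$sample_id,
        scale_factor = unname(absorbance_vec(spectra, anchor)) / mc_anchor
      ),
      clipped = clipped,
      anchor = as.integer(anchor),
      boundary = as.integer(boundary)
    ),
    class = "isolation_result"
  )
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf(
    "<isolation_result> %d sample(s); anchor %d nm, boundary %d nm; clipped: %s\n",
    nrow(x$raw), x$anchor, x$boundary, x$clipped
  ))
  invisible(x)
}

#' Per-phenolic feature spectra
#'
#' Builds the feature representation each phenolic class is predicted from:
#' anthocyanins use the visible range (430-700 nm, 271 features on the
#' default grid) of the raw spectra, untouched by the standard; tannins and
#' TIPs use the anthocyanin-corrected UV range (230-429 nm, 200 features)
#' from [isolate_uv()]. Features are ordered by ascending wavelength.
#'
#' @inheritParams isolate_uv
#' @param target One of `"anthocyanins"`, `"tannins"`, `"tips"`.
#' @return A `spectra_set` restricted to the feature wavelengths.
#' @export
features_for <- function(spectra, target, standard = NULL,
                         clip_negative = FALSE, anchor = 520, boundary = 430) {
  spectra <- assert_spectra(spectra)
  targets <- c("anthocyanins", "tannins", "tips")
  if (length(target) != 1 || !target %in% targets) {
    wp_usage_error(sprintf("target must be one of: %s",
                           paste(targets, collapse = ", ")))
  }
  g <- spectra_grid(spectra)
  if (target == "anthocyanins") {
    return(restrict_spectra(spectra, as.integer(boundary), g$end_nm))
  }
  if (is.null(standard)) {
    wp_usage_error("tannin/TIP features require the normalized MC standard")
  }
  isolate_uv(spectra, standard, clip_negative = clip_negative,
             anchor = anchor, boundary = boundary)$corrected_uv
}

#' @describeIn isolate_uv Overlay one sample's raw UV spectrum, anthocyanin
#'   estimate and corrected spectrum.
#' @param object,x An `isolation_result`.
#' @param sample_id Sample to plot (default: the first).
#' @param ... Unused.
#' @export
autoplot.isolation_result <- function(object, sample_id = NULL, ...) {
  sid <- sample_id %||% object$raw$sample_id[1]
  g <- spectra_grid(object$raw)
  pick <- function(s, what) {
    s |>
      dplyr::filter(.data$sample_id == sid) |>
      unclass_spectra() |>
      tidyr::pivot_longer(-"sample_id", names_to = "wavelength",
                          values_to = "absorbance") |>
      dplyr::mutate(wavelength = as.integer(.data$wavelength), component = what)
  }
  df <- dplyr::bind_rows(
    pick(restrict_spectra(object$raw, g$start_nm, object$boundary - g$step_nm), "raw UV"),
    pick(object$anthocyanin_estimate_uv, "anthocyanin estimate"),
    pick(object$corrected_uv, "corrected (tannin/TIP)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$absorbance,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)",
                  title = paste("Anthocyanin UV subtraction:", sid))
}
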