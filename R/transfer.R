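#' Match dilution ratios across instruments
#'
#' When a calibration built on one spectrophotometer is moved to another, the
#' working dilution must be re-established: instruments differ in sensitivity
#' and usable absorbance range, so the dilution that keeps spectra in range
#' on one (e.g. 1:5 on a Genesys 10S) can saturate or starve another (1:25
#' on a Cary 14). Each candidate set's mean spectrum and the reference mean
#' spectrum are sum-normalized — normalization absorbs the dilution scale —
#' and compared by root-mean-square difference; the candidate whose scaled
#' mean most closely resembles the reference wins.
#'
#' @param reference `spectra_set` acquired on the reference instrument at its
#'   established dilution.
#' @param candidates A list of `spectra_set`s acquired on the new instrument
#'   at different dilution ratios (list names or the sets' `dilution_ratio`
#'   attribute label the candidates).
#' @return A `dilution_match` tibble with one row per candidate (`candidate`,
#'   `dilution_ratio`, `distance`, `best`); the minimum-distance candidate is
#'   flagged `best`. Metadata attribute `wp_distance` records the distance
#'   notion (`"rms of sum-normalized mean spectra"`) so alternatives can be
#'   compared.
#' @export
match_dilution <- function(reference, candidates) {
  reference <- assert_spectra(reference, "reference")
  if (inherits(candidates, "spectra_set")) candidates <- list(candidates)
  if (!is.list(candidates) || length(candidates) == 0) {
    wp_usage_error("at least one candidate spectra set is required")
  }
  candidates <- purrr::map(candidates, assert_spectra, arg = "candidate")
  purrr::walk(candidates, assert_shared_grid, b = reference,
              what = "reference and candidates")
  norm_mean <- function(s) {
    m <- colMeans(spectra_matrix(s))
    tot <- sum(m)
    if (tot <= 0) wp_data_error("cannot normalize a non-positive mean spectrum")
    m / tot
  }
  ref <- norm_mean(reference)
  dist <- purrr::map_dbl(candidates, function(s) {
    sqrt(mean((norm_mean(s) - ref)^2))
  })
  labels <- names(candidates) %||% rep(NA_character_, length(candidates))
  if (is.null(names(candidates))) {
    labels <- paste0("candidate_", seq_along(candidates))
  }
  ratios <- purrr::map_dbl(candidates, ~ attr(.x, "wp_dilution") %||% NA_real_)
  out <- tibble(
    candidate = labels,
    dilution_ratio = unname(ratios),
    distance = unname(dist),
    best = seq_along(dist) == which.min(dist)
  )
  structure(out,
            class = c("dilution_match", class(tibble())),
            wp_distance = "rms of sum-normalized mean spectra",
            wp_reference = attr(reference, "wp_instrument") %||% NA_character_)
}

#' Augment a calibration set with new-instrument data
#'
#' Calibrating an instrument against a standard is not enough to transport a
#' multivariate model: signal-to-noise and UV/visible response ratios differ
#' between spectrophotometers. The recommended remedy is to add a subset of
#' new-instrument samples — spectra plus their assay values — to the original
#' calibration data and refit. This helper concatenates the two sets row-wise
#' (original data first, order preserved) and keeps per-row instrument
#' provenance for reporting. As guidance, a new-instrument subset of about
#' 10% of the original set is a reasonable starting point.
#'
#' @param old_x,new_x Feature matrices / `spectra_set`s with matching feature
#'   dimensionality (`new_x` may have zero rows).
#' @param old_y,new_y Concentration vectors matching the row counts.
#' @param old_label,new_label Provenance labels (defaults `"old"`, `"new"`).
#' @return A list with the combined feature matrix `x`, response `y`, and a
#'   character `provenance` vector.
#' @export
augment_calibration <- function(old_x, old_y, new_x, new_y,
                                old_label = "old", new_label = "new") {
  Xo <- as_feature_matrix(old_x)
  Xn <- if (is.null(new_x) ||
            (is.matrix(new_x) && nrow(new_x) == 0) ||
            (is.data.frame(new_x) && nrow(new_x) == 0)) {
    matrix(numeric(0), 0, ncol(Xo))
  } else {
    as_feature_matrix(new_x)
  }
  new_y <- if (is.null(new_y)) numeric(0) else as.numeric(new_y)
  if (nrow(Xn) > 0 && ncol(Xn) != ncol(Xo)) {
    wp_usage_error(sprintf(
      "feature count mismatch: original has %d, new has %d", ncol(Xo), ncol(Xn)
    ))
  }
  if (nrow(Xo) != length(old_y) || nrow(Xn) != length(new_y)) {
    wp_usage_error("feature rows and response lengths must match")
  }
  colnames(Xn) <- colnames(Xo)
  list(
    x = rbind(Xo, Xn),
    y = c(as.numeric(old_y), new_y),
    provenance = c(rep(old_label, nrow(Xo)), rep(new_label, nrow(Xn)))
  )
}
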