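#' Gaussian absorbance band
#'
#' Building block of the synthetic component library: a Gaussian band
#' `height * exp(-(lambda - center)^2 / (2 * width^2))` evaluated on the
#' grid. Real phenolic UV-Vis bands are broad and smooth; sums of a few
#' Gaussians emulate them well enough for pipeline testing.
#'
#' @param center Band center in nm.
#' @param width Gaussian width (sd) in nm, > 0.
#' @param height Peak absorbance in AU (per unit concentration when used as a
#'   component shape).
#' @param grid A `wavelength_grid` (default 230-700 nm).
#' @param sample_id Label for the returned single-row set.
#' @return A one-row `spectra_set`.
#' @export
gaussian_band <- function(center, width, height, grid = wavelength_grid(),
                          sample_id = "band") {
  if (!is.numeric(width) || width <= 0) {
    wp_usage_error("band width must be positive")
  }
  wl <- grid_wavelengths(grid)
  v <- matrix(height * exp(-(wl - center)^2 / (2 * width^2)), nrow = 1)
  colnames(v) <- as.character(wl)
  spectra_set(dplyr::bind_cols(tibble(sample_id = sample_id),
                               as_tibble(v, .name_repair = "minimal")))
}

gaussian_band_vec <- function(center, width, height, wl) {
  height * exp(-(wl - center)^2 / (2 * width^2))
}

#' Phenolic component spectra
#'
#' A component spectrum is a named sum of Gaussian bands with peak heights in
#' AU per mg/L equivalent. Tannin and TIP components carry a hard visible
#' cutoff: their absorbance is exactly zero at and above 430 nm, encoding the
#' chemistry that only anthocyanins (and polymeric pigments) absorb in the
#' visible.
#'
#' @param name Component name.
#' @param bands Tibble/data frame with columns `center`, `width`, `height`
#'   (nm, nm, AU per mg/L).
#' @param visible_cutoff Optional wavelength at and above which the component
#'   is forced to zero.
#' @return A `component_spectrum` object.
#' @export
component_spectrum <- function(name, bands, visible_cutoff = NULL) {
  bands <- as_tibble(bands)
  if (!all(c("center", "width", "height") %in% names(bands))) {
    wp_usage_error("bands require center, width and height columns")
  }
  if (any(bands$height < 0)) wp_usage_error("band heights must be >= 0")
  if (any(bands$width <= 0)) wp_usage_error("band widths must be > 0")
  structure(
    list(name = name, bands = bands, visible_cutoff = visible_cutoff),
    class = "component_spectrum"
  )
}

component_shape <- function(comp, grid = wavelength_grid()) {
  wl <- grid_wavelengths(grid)
  v <- rowSums(vapply(
    seq_len(nrow(comp$bands)),
    function(i) gaussian_band_vec(comp$bands$center[i], comp$bands$width[i],
                                  comp$bands$height[i], wl),
    numeric(length(wl))
  ))
  if (!is.null(comp$visible_cutoff)) v[wl >= comp$visible_cutoff] <- 0
  setNames(v, as.character(wl))
}

#' Default phenolic component library
#'
#' Four component shapes (AU per mg/L assay equivalent) plus the matching
#' malvidin chloride standard:
#'
#' * `anthocyanin` — UV band at 277 nm and the visible band at 520 nm (the
#'   flavylium maximum at wine pH);
#' * `tannin` — 280 nm band with a 310 nm shoulder, zero at/above 430 nm;
#' * `tip` — 280 and 320 nm bands, zero at/above 430 nm;
#' * `polymeric_pigment` — 280 nm band plus a broad visible band centered at
#'   500 nm (pigmented polymers absorb across the whole anthocyanin visible
#'   region, which is what degrades the 520 nm-anthocyanin correlation as
#'   wines age).
#'
#' The returned `standard` is exactly the anthocyanin shape by default; a
#' `standard_shift_nm` knob displaces the standard's band centers to exercise
#' the shape-mismatch error source inherent in single-standard subtraction.
#' Heights are scaled so a typical wine at a 1:5 dilution stays below 2 AU.
#'
#' @param standard_shift_nm Shift (nm) applied to the standard's band centers
#'   relative to the true anthocyanin component (default 0: exact match).
#' @param grid Wavelength grid for the standard spectrum.
#' @return A list with `components` (named list of `component_spectrum`) and
#'   `standard` (one-row `spectra_set`, unnormalized).
#' @export
default_component_library <- function(standard_shift_nm = 0,
                                      grid = wavelength_grid()) {
  anth_bands <- tibble(
    center = c(277, 520), width = c(28, 32), height = c(0.002, 0.003)
  )
  components <- list(
    anthocyanin = component_spectrum("anthocyanin", anth_bands),
    tannin = component_spectrum(
      "tannin",
      tibble(center = c(280, 310), width = c(22, 30),
             height = c(0.0022, 0.0009)),
      visible_cutoff = 430
    ),
    tip = component_spectrum(
      "tip",
      tibble(center = c(280, 320), width = c(24, 35),
             height = c(0.0012, 0.0009)),
      visible_cutoff = 430
    ),
    polymeric_pigment = component_spectrum(
      "polymeric_pigment",
      tibble(center = c(280, 500), width = c(25, 75),
             height = c(0.002, 0.0035))
    )
  )
  std_bands <- dplyr::mutate(anth_bands,
                             center = .data$center + standard_shift_nm)
  std <- component_shape(component_spectrum("malvidin_chloride", std_bands),
                         grid)
  v <- matrix(std, nrow = 1, dimnames = list(NULL, names(std)))
  list(
    components = components,
    standard = spectra_set(dplyr::bind_cols(
      tibble(sample_id = "malvidin_chloride"),
      as_tibble(v, .name_repair = "minimal")
    ))
  )
}

#' Mixture design for the synthetic calibration set
#'
#' Describes how a synthetic calibration cohort is drawn: per-component
#' concentration ranges (uniform draws, optionally correlated through a
#' Gaussian copula), the spectral noise model, the assay error model and the
#' working dilution. Defaults mirror a young-red-wine calibration set:
#' anthocyanins 50-900, tannins 100-1400, TIPs 300-2800 mg/L equivalents,
#' additive spectral noise sigma 0.005 AU, 5% multiplicative assay CV
#' (wet-assay error scales with concentration), 1:5 dilution.
#'
#' @param n Number of samples (>= 1).
#' @param ranges Named list of `c(min, max)` mg/L ranges for `anthocyanin`,
#'   `tannin`, `tip`, `polymeric_pigment`.
#' @param noise_sd Additive spectral noise sd in AU.
#' @param noise_mult Multiplicative spectral noise fraction.
#' @param assay_cv Coefficient of variation of the assay error.
#' @param correlation Named numeric vector of pairwise concentration
#'   correlations, e.g. `c(anthocyanin_tannin = 0.7)`; achieved on the
#'   uniform scale via a Gaussian copula.
#' @param dilution Dilution ratio (e.g. 5 for 1:5 in model wine).
#' @param seed Seed controlling every random draw of the design.
#' @return A `mixture_design` list.
#' @export
mixture_design <- function(n,
                           ranges = list(
                             anthocyanin = c(50, 900),
                             tannin = c(100, 1400),
                             tip = c(300, 2800),
                             polymeric_pigment = c(0, 0)
                           ),
                           noise_sd = 0.005, noise_mult = 0, assay_cv = 0.05,
                           correlation = NULL, dilution = 5, seed = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) wp_usage_error("design requires n >= 1")
  defaults <- list(anthocyanin = c(50, 900), tannin = c(100, 1400),
                   tip = c(300, 2800), polymeric_pigment = c(0, 0))
  ranges <- modifyList(defaults, as.list(ranges))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      wp_usage_error(sprintf("invalid range for %s", nm))
    }
  }
  if (noise_sd < 0 || noise_mult < 0 || assay_cv < 0) {
    wp_usage_error("noise parameters must be non-negative")
  }
  design_cor_matrix(correlation)  # validate pair names and definiteness now
  structure(
    list(n = n, ranges = ranges, noise_sd = noise_sd, noise_mult = noise_mult,
         assay_cv = assay_cv, correlation = correlation,
         dilution = dilution, seed = as.integer(seed)),
    class = "mixture_design"
  )
}

# Latent normal correlation matrix achieving the requested uniform-scale
# Pearson correlations (inverse of r_u = (6/pi) asin(rho/2)).
design_cor_matrix <- function(correlation) {
  comps <- c("anthocyanin", "tannin", "tip", "polymeric_pigment")
  R <- diag(4)
  dimnames(R) <- list(comps, comps)
  if (is.null(correlation)) return(R)
  for (nm in names(correlation)) {
    first <- comps[startsWith(nm, paste0(comps, "_"))]
    first <- first[which.max(nchar(first))]
    pair <- c(first, substring(nm, nchar(first) + 2))
    if (length(first) != 1 || !all(pair %in% comps) || pair[1] == pair[2]) {
      wp_usage_error(sprintf(
        "correlation name '%s' must join two component names with '_'", nm
      ))
    }
    r_u <- correlation[[nm]]
    if (abs(r_u) > 0.99) wp_usage_error("correlations must lie in [-0.99, 0.99]")
    rho <- 2 * sin(pi * r_u / 6)
    R[pair[1], pair[2]] <- rho
    R[pair[2], pair[1]] <- rho
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    wp_usage_error("requested correlation structure is not positive definite")
  }
  R
}

draw_concentrations <- function(design) {
  comps <- c("anthocyanin", "tannin", "tip", "polymeric_pigment")
  R <- design_cor_matrix(design$correlation)
  with_local_seed(design$seed, {
    Z <- matrix(rnorm(design$n * 4), ncol = 4) %*% chol(R)
    U <- pnorm(Z)
    conc <- matrix(NA_real_, nrow = design$n, ncol = length(comps),
                   dimnames = list(NULL, comps))
    for (k in seq_along(comps)) {
      r <- design$ranges[[comps[k]]]
      conc[, k] <- r[1] + (r[2] - r[1]) * U[, k]
    }
    conc
  })
}

#' Instrument response model
#'
#' Applies, in order: a wavelength-dependent gain (near 1), a stray-light
#' offset in AU, saturation clipping at the detector ceiling, and additive
#' detector noise. The default is a well-behaved reference instrument: unit
#' gain, no offset, no noise, 2.0 AU ceiling (clipping only engages above
#' the ceiling, so in-range spectra pass through the saturation stage
#' unchanged).
#'
#' @param instrument_id Label.
#' @param gain Scalar, vector over the grid, or function of wavelength;
#'   must be positive everywhere.
#' @param offset Stray-light offset in AU.
#' @param noise_sd Detector noise sd in AU.
#' @param ceiling Saturation ceiling in AU (> 0).
#' @return An `instrument_model`.
#' @export
instrument_model <- function(instrument_id = "A", gain = 1, offset = 0,
                             noise_sd = 0, ceiling = 2.0) {
  if (!is.function(gain) && any(gain <= 0)) {
    wp_usage_error("instrument gain must be positive everywhere")
  }
  if (ceiling <= 0) wp_usage_error("saturation ceiling must be positive")
  structure(
    list(instrument_id = instrument_id, gain = gain, offset = offset,
         noise_sd = noise_sd, ceiling = ceiling),
    class = "instrument_model"
  )
}

instrument_gain_vec <- function(instrument, wl) {
  g <- instrument$gain
  if (is.function(g)) g <- g(wl)
  if (length(g) == 1) g <- rep(g, length(wl))
  if (length(g) != length(wl)) {
    wp_usage_error("instrument gain vector must match the grid length")
  }
  g
}

# Render observed spectra + assays from true concentrations. All noise draws
# happen under `seed`, so a fixed render seed gives identical observations
# for identical truths (the aging series relies on this).
render_observation <- function(conc, library, instrument, design, grid, seed) {
  comps <- c("anthocyanin", "tannin", "tip", "polymeric_pigment")
  wl <- grid_wavelengths(grid)
  shapes <- t(vapply(comps,
                     function(k) component_shape(library$components[[k]], grid),
                     numeric(length(wl))))
  clean <- (conc[, comps, drop = FALSE] %*% shapes) / design$dilution
  gain <- instrument_gain_vec(instrument, wl)
  with_local_seed(seed, {
    obs <- clean
    if (design$noise_mult > 0) {
      obs <- obs * (1 + matrix(rnorm(length(obs), sd = design$noise_mult),
                               nrow = nrow(obs)))
    }
    if (design$noise_sd > 0) {
      obs <- obs + matrix(rnorm(length(obs), sd = design$noise_sd),
                          nrow = nrow(obs))
    }
    obs <- sweep(obs, 2, gain, "*") + instrument$offset
    obs[obs > instrument$ceiling] <- instrument$ceiling
    if (instrument$noise_sd > 0) {
      obs <- obs + matrix(rnorm(length(obs), sd = instrument$noise_sd),
                          nrow = nrow(obs))
    }
    assay_noise <- matrix(rnorm(nrow(conc) * 3, sd = design$assay_cv),
                          ncol = 3)
    list(spectra_values = obs, assay_noise = assay_noise)
  })
}

assemble_calibration <- function(ids, rendered, conc, design, instrument,
                                 grid, pigment_tip_weight = 0) {
  wl <- grid_wavelengths(grid)
  colnames(rendered$spectra_values) <- as.character(wl)
  spectra <- spectra_set(
    dplyr::bind_cols(tibble(sample_id = ids),
                     as_tibble(rendered$spectra_values,
                               .name_repair = "minimal")),
    instrument_id = instrument$instrument_id,
    dilution_ratio = design$dilution
  )
  true_assay <- cbind(
    anthocyanins = conc[, "anthocyanin"],
    tannins = conc[, "tannin"],
    tips = conc[, "tip"] + pigment_tip_weight * conc[, "polymeric_pigment"]
  )
  observed <- pmax(true_assay * (1 + rendered$assay_noise), 0)
  assays <- tibble(
    sample_id = ids,
    anthocyanins = observed[, "anthocyanins"],
    tannins = observed[, "tannins"],
    tips = observed[, "tips"]
  )
  truth <- dplyr::bind_cols(tibble(sample_id = ids),
                            as_tibble(conc, .name_repair = "minimal"))
  list(spectra = spectra, assays = assays, truth = truth)
}

#' Simulate a synthetic calibration set
#'
#' Draws per-sample component concentrations from the design, builds clean
#' Beer-Lambert mixture spectra (concentration-weighted sum of component
#' shapes divided by the dilution ratio), applies the design's spectral noise
#' and the instrument response, and perturbs the true concentrations with
#' multiplicative assay error. Everything is reproducible from the design
#' seed: identical seeds yield byte-identical CSV output.
#'
#' @param design A [mixture_design()].
#' @param library Component library from [default_component_library()].
#' @param instrument An [instrument_model()].
#' @param grid Wavelength grid.
#' @return A `calibration_sim` list: `spectra` (`spectra_set`), `assays`
#'   (observed assay tibble), `truth` (true component concentrations), plus
#'   the design, library and instrument used.
#' @examples
#' sim <- simulate_calibration_set(mixture_design(n = 10, seed = 7))
#' sim$spectra
#' @export
simulate_calibration_set <- function(design,
                                     library = default_component_library(),
                                     instrument = instrument_model(),
                                     grid = wavelength_grid()) {
  if (!inherits(design, "mixture_design")) {
    wp_usage_error("design must be a mixture_design")
  }
  conc <- draw_concentrations(design)
  render_seed <- derive_seeds(design$seed, 1)
  rendered <- render_observation(conc, library, instrument, design, grid,
                                 render_seed)
  ids <- sprintf("s%04d", seq_len(design$n))
  out <- assemble_calibration(ids, rendered, conc, design, instrument, grid)
  structure(
    c(out, list(design = design, library = library, instrument = instrument,
                grid = grid, render_seed = render_seed)),
    class = "calibration_sim"
  )
}

#' @export
print.calibration_sim <- function(x, ...) {
  cat(sprintf(
    "<calibration_sim> %d sample(s), instrument %s, 1:%g dilution, seed %d\n",
    x$design$n, x$instrument$instrument_id, x$design$dilution, x$design$seed
  ))
  invisible(x)
}

#' Aging (pigment-formation) model
#'
#' Phenomenological post-fermentation aging: each week a fraction of the
#' remaining monomeric anthocyanin condenses into polymeric pigment, and a
#' fraction of the remaining tannin is incorporated into the pigment pool.
#' Condensation requires tannin as a reaction partner, so the effective
#' weekly conversion of a wine scales with its initial tannin level:
#' `f_i = conversion * tannin_i / max(tannin)`. Pigment is tracked in mg/L
#' precursor equivalents; the anthocyanin-equivalents ledger balances exactly
#' (anthocyanin consumed equals pigment anthocyanin-equivalents created).
#'
#' @param conversion Maximum weekly anthocyanin-to-pigment conversion
#'   fraction, in \[0, 1\].
#' @param tannin_incorporation Weekly fraction of remaining tannin
#'   incorporated into pigment, in \[0, 1\].
#' @param weeks Number of weekly timepoints after the initial one.
#' @param pigment_tip_weight Weight of the pigment pool in the observed TIP
#'   assay (pigmented polymers remain iron-reactive).
#' @param tannin_rate_scaling If `TRUE` (default) the weekly conversion of
#'   each wine scales with its initial tannin level; if `FALSE` the stated
#'   fraction applies uniformly to every wine.
#' @return An `aging_model`.
#' @export
aging_model <- function(conversion = 0.3, tannin_incorporation = 0.02,
                        weeks = 4, pigment_tip_weight = 0.3,
                        tannin_rate_scaling = TRUE) {
  if (conversion < 0 || conversion > 1 ||
      tannin_incorporation < 0 || tannin_incorporation > 1) {
    wp_usage_error("aging fractions must lie in [0, 1]")
  }
  if (weeks < 1) wp_usage_error("weeks must be at least 1")
  structure(
    list(conversion = conversion,
         tannin_incorporation = tannin_incorporation,
         weeks = as.integer(weeks),
         pigment_tip_weight = pigment_tip_weight,
         tannin_rate_scaling = isTRUE(tannin_rate_scaling)),
    class = "aging_model"
  )
}

#' Default longitudinal cohort design
#'
#' The post-fermentation evolution cohort: 45 finished wines sampled weekly.
#' Finished young reds span a narrower anthocyanin range than fermenting
#' samples (300-700 mg/L) and their phenolic pools co-vary (riper, more
#' extracted fruit raises everything), so the design uses mild positive assay
#' collinearity: anthocyanin-tannin 0.2, anthocyanin-TIP 0.2, tannin-TIP 0.7.
#'
#' @param n Cohort size (default 45).
#' @param seed Design seed.
#' @param ... Overrides passed to [mixture_design()].
#' @return A `mixture_design`.
#' @export
default_aging_design <- function(n = 45, seed = 1, ...) {
  mixture_design(
    n = n,
    ranges = list(anthocyanin = c(300, 700), tannin = c(100, 1400),
                  tip = c(300, 2800), polymeric_pigment = c(0, 0)),
    correlation = c(anthocyanin_tannin = 0.2, anthocyanin_tip = 0.2,
                    tannin_tip = 0.7),
    seed = seed,
    ...
  )
}

#' Simulate a post-fermentation aging series
#'
#' Starting from a simulated calibration set (week 0, "Initial"), advances
#' the aging model week by week, regenerating spectra and assays from the
#' updated true concentrations under the same render seed as the base set —
#' so a zero conversion fraction reproduces the base observations at every
#' week. Observed assays report remaining monomeric anthocyanin, remaining
#' tannin, and TIPs including the configurable pigment contribution.
#'
#' @param base A `calibration_sim` (e.g. built from [default_aging_design()]).
#' @param aging An [aging_model()].
#' @return A `timepoint_series` with attribute `wp_truth`: a tibble of true
#'   weekly concentrations including the pigment pool and the cumulative
#'   anthocyanin-equivalents ledger (`pigment_anthocyanin_equiv`).
#' @export
simulate_aging_series <- function(base, aging = aging_model()) {
  if (!inherits(base, "calibration_sim")) {
    wp_usage_error("base must come from simulate_calibration_set()")
  }
  comps <- c("anthocyanin", "tannin", "tip", "polymeric_pigment")
  conc <- as.matrix(base$truth[comps])
  tannin0 <- conc[, "tannin"]
  rate_scale <- if (!isTRUE(aging$tannin_rate_scaling)) {
    rep(1, length(tannin0))
  } else if (max(tannin0) > 0) {
    tannin0 / max(tannin0)
  } else {
    rep(0, length(tannin0))
  }
  pig_anth_equiv <- numeric(nrow(conc))

  weeks <- c(0L, seq_len(aging$weeks))
  spectra_list <- vector("list", length(weeks))
  assay_list <- vector("list", length(weeks))
  truth_list <- vector("list", length(weeks))
  ids <- base$truth$sample_id

  snapshot <- function(week) {
    dplyr::bind_cols(
      tibble(week = week, sample_id = ids),
      as_tibble(conc, .name_repair = "minimal"),
      tibble(pigment_anthocyanin_equiv = pig_anth_equiv)
    )
  }

  for (k in seq_along(weeks)) {
    w <- weeks[k]
    if (w > 0) {
      d_anth <- aging$conversion * rate_scale * conc[, "anthocyanin"]
      d_tan <- aging$tannin_incorporation * conc[, "tannin"]
      conc[, "anthocyanin"] <- conc[, "anthocyanin"] - d_anth
      conc[, "tannin"] <- conc[, "tannin"] - d_tan
      conc[, "polymeric_pigment"] <- conc[, "polymeric_pigment"] + d_anth + d_tan
      pig_anth_equiv <- pig_anth_equiv + d_anth
    }
    rendered <- render_observation(conc, base$library, base$instrument,
                                   base$design, base$grid, base$render_seed)
    obs <- assemble_calibration(ids, rendered, conc, base$design,
                                base$instrument, base$grid,
                                pigment_tip_weight = aging$pigment_tip_weight)
    spectra_list[[k]] <- obs$spectra
    assay_list[[k]] <- obs$assays
    truth_list[[k]] <- snapshot(w)
  }
  series <- timepoint_series(week = weeks, spectra = spectra_list,
                             assays = assay_list)
  attr(series, "wp_truth") <- dplyr::bind_rows(truth_list)
  attr(series, "wp_aging") <- aging
  series
}

#' @describeIn spectra_set Spaghetti plot of all spectra in the set.
#' @param object A `spectra_set`.
#' @param ... Unused.
#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- unclass_spectra(object) |>
    tidyr::pivot_longer(-"sample_id", names_to = "wavelength",
                        values_to = "absorbance") |>
    dplyr::mutate(wavelength = as.integer(.data$wavelength))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$absorbance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = min(1, 20 / nrow(object))) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)")
}
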