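#' Random train/test split
#'
#' Partitions `1:n` into disjoint, exhaustive train and test index sets; the
#' training set holds `floor(train_fraction * n)` indices (at least 1 in each
#' set). The split is reproducible for a fixed seed and does not disturb the
#' caller's RNG state.
#'
#' @param n Number of samples (>= 2).
#' @param train_fraction Training proportion in (0, 1); default 0.9, the
#'   repeated 90/10 protocol.
#' @param seed Integer seed.
#' @return A list with integer vectors `train` and `test`.
#' @examples
#' s <- random_split(323, 0.9, seed = 1)
#' lengths(s)  # 290 train, 33 test
#' @export
random_split <- function(n, train_fraction = 0.9, seed = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) wp_usage_error("random_split requires n >= 2")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    wp_usage_error("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- max(1L, min(n - 1L, as.integer(floor(train_fraction * n))))
  train <- with_local_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

safe_r2 <- function(predicted, observed) {
  tryCatch(r_squared(predicted, observed),
           wp_data_error = function(e) 0)
}

#' Repeated 90/10 split validation
#'
#' The validation protocol behind every evaluation report: the data are
#' randomly split into ~90% training / ~10% test, the model is calibrated on
#' the training split and used to predict the held-out samples, and the whole
#' process is repeated (10 times by default). Reported quantities:
#'
#' * `r2_c`, `rmsec` — calibration (training resubstitution), averaged over
#'   repeats;
#' * `r2_p`, `rmsep` — held-out prediction, averaged over repeats;
#' * `r2_cv`, `rmsecv` — cross-validation, computed once on the held-out
#'   predictions pooled across all repeats (`rmsep_mean` keeps the average of
#'   per-repeat RMSEP for comparison; with a single repeat the cv and p
#'   columns coincide).
#'
#' All R² values are squared Pearson correlations of predicted versus
#' observed; a repeat whose predictions are degenerate (constant) records an
#' R² of 0. One master seed drives all repeats via deterministically derived
#' per-repeat seeds.
#'
#' @inheritParams fit_phenolic_model
#' @param repeats Number of random splits (default 10).
#' @param train_fraction Training proportion (default 0.9).
#' @param seed Master seed.
#' @param ... Passed on to [fit_phenolic_model()].
#' @return A `validation_result` with the summary row (`glance()`), the
#'   per-repeat metrics (`tidy()`), and the pooled held-out predictions
#'   (`$pooled`, a tibble of `repeat`, `index`, `observed`, `predicted`).
#' @export
repeated_validation <- function(x, y, algorithm, weight, repeats = 10,
                                train_fraction = 0.9, seed = 1, ...) {
  X <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) wp_usage_error("x and y must match in length")
  if (repeats < 1) wp_usage_error("repeats must be at least 1")
  seeds <- derive_seeds(seed, repeats)
  per_repeat <- vector("list", repeats)
  pooled <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    split <- random_split(nrow(X), train_fraction, seeds[r])
    if (length(split$train) < 2 || length(split$test) < 1) {
      wp_usage_error("degenerate split: too few samples per subset")
    }
    model <- fit_phenolic_model(X[split$train, , drop = FALSE], y[split$train],
                                algorithm = algorithm, weight = weight, ...)
    pred_train <- predict(model, X[split$train, , drop = FALSE])
    pred_test <- predict(model, X[split$test, , drop = FALSE])
    per_repeat[[r]] <- tibble(
      repeat_id = r, seed = seeds[r],
      r2_c = safe_r2(pred_train, y[split$train]),
      rmsec = rmse(pred_train, y[split$train]),
      r2_p = safe_r2(pred_test, y[split$test]),
      rmsep = rmse(pred_test, y[split$test]),
      n_train = length(split$train), n_test = length(split$test)
    )
    pooled[[r]] <- tibble(
      repeat_id = r, index = split$test,
      observed = y[split$test], predicted = pred_test
    )
  }
  per_repeat <- dplyr::bind_rows(per_repeat)
  pooled <- dplyr::bind_rows(pooled)
  summary <- tibble(
    algorithm = algorithm, weight = weight, repeats = repeats, seed = seed,
    r2_c = mean(per_repeat$r2_c), rmsec = mean(per_repeat$rmsec),
    r2_p = mean(per_repeat$r2_p), rmsep = mean(per_repeat$rmsep),
    r2_cv = safe_r2(pooled$predicted, pooled$observed),
    rmsecv = rmse(pooled$predicted, pooled$observed),
    rmsep_mean = mean(per_repeat$rmsep)
  )
  structure(
    list(summary = summary, per_repeat = per_repeat, pooled = pooled,
         seed = seed),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<validation_result> %s, weight %.6g, %d repeats (seed %d)\n  R2C %.3f RMSEC %.3f | R2P %.3f RMSEP %.3f | R2CV %.3f RMSECV %.3f\n",
    s$algorithm, s$weight, s$repeats, s$seed,
    s$r2_c, s$rmsec, s$r2_p, s$rmsep, s$r2_cv, s$rmsecv
  ))
  invisible(x)
}

#' @describeIn repeated_validation Per-repeat metrics as a tibble.
#' @export
tidy.validation_result <- function(x, ...) x$per_repeat

#' @describeIn repeated_validation One-row summary tibble.
#' @export
glance.validation_result <- function(x, ...) x$summary

#' Default weight grids
#'
#' Search grids ordered from least to most model flexibility: SVR cost
#' 2^(-5..15) by powers of two; kernel-ridge regularization 10^(3..-6) by
#' decades (descending, since a smaller penalty means a more flexible model);
#' PLS components 1..min(30, n_train - 1).
#'
#' @param algorithm `"svr"`, `"krr"` or `"kpls"`.
#' @param n_train Training-set size (used to cap the kpls component count).
#' @return A numeric vector of weights.
#' @export
default_weight_grid <- function(algorithm, n_train = 100) {
  switch(match.arg(algorithm, c("svr", "krr", "kpls")),
    svr = 2^seq(-5, 15),
    krr = 10^seq(3, -6),
    kpls = seq_len(max(1, min(30, n_train - 1)))
  )
}

#' Systematic weight search
#'
#' Walks the weight grid from least to most flexible, scoring each candidate
#' by the mean held-out R² from [repeated_validation()]. The search's lower
#' bound follows the minimum-weight rule: candidates are considered from the
#' last grid point of the initial run whose mean test R² is below
#' `r2_floor` (default 0.5); if the first grid point already clears the
#' floor the whole grid is eligible. The walk terminates once the running
#' maximum has been followed by two consecutive declines (a single-dip rule
#' is fragile under stochastic splits), or when the grid is exhausted. The
#' chosen weight is the candidate attaining the maximum mean test R², with
#' ties broken toward the least flexible weight.
#'
#' @inheritParams repeated_validation
#' @param grid Strictly monotone weight grid ordered by increasing model
#'   flexibility (ascending for svr cost and kpls components; descending
#'   penalties for krr). Default from [default_weight_grid()].
#' @param r2_floor Minimum-weight rule threshold (default 0.5).
#' @param patience Consecutive declines required to stop (default 2).
#' @param decline_tol Minimum drop in mean test R² that counts as a decline
#'   (default 1e-4). Without it, float-level jitter on a flat stretch of the
#'   profile registers as a decline and stops the walk prematurely.
#' @param evaluator Optional function `(weight) -> mean test R²`, replacing
#'   the repeated-validation evaluator (used for testing the search logic).
#' @return A `weight_search` object: trace tibble (`tidy()`), `chosen_weight`,
#'   `termination` (`"declined"` or `"grid exhausted"`).
#' @export
weight_search <- function(x = NULL, y = NULL, algorithm = NULL, grid = NULL,
                          repeats = 10, train_fraction = 0.9, seed = 1,
                          r2_floor = 0.5, patience = 2, decline_tol = 1e-4,
                          evaluator = NULL, ...) {
  if (is.null(grid)) {
    if (is.null(algorithm)) wp_usage_error("supply a grid or an algorithm")
    n_train <- if (!is.null(x)) {
      floor(train_fraction * nrow(as_feature_matrix(x)))
    } else {
      100
    }
    grid <- default_weight_grid(algorithm, n_train)
  }
  if (length(grid) == 0) wp_usage_error("weight grid must be non-empty")
  if (length(grid) > 1 && is.unsorted(grid, strictly = TRUE) &&
      is.unsorted(rev(grid), strictly = TRUE)) {
    wp_usage_error("weight grid must be strictly monotone")
  }
  if (is.null(evaluator)) {
    if (is.null(x) || is.null(y) || is.null(algorithm)) {
      wp_usage_error("x, y and algorithm are required without a custom evaluator")
    }
    evaluator <- function(w) {
      res <- tryCatch(
        repeated_validation(x, y, algorithm = algorithm, weight = w,
                            repeats = repeats, train_fraction = train_fraction,
                            seed = seed, ...),
        wp_error = function(e) NULL
      )
      if (is.null(res)) NA_real_ else res$summary$r2_p
    }
  }

  scores <- rep(NA_real_, length(grid))
  start_idx <- 1L
  floor_cleared <- FALSE
  declines <- 0L
  termination <- "grid exhausted"
  last_eval <- 0L
  for (i in seq_along(grid)) {
    scores[i] <- evaluator(grid[i])
    last_eval <- i
    if (!is.na(scores[i])) {
      if (!floor_cleared) {
        if (scores[i] < r2_floor) start_idx <- i else floor_cleared <- TRUE
      }
      prev <- if (i > 1) scores[i - 1] else NA_real_
      if (!is.na(prev) && scores[i] < prev - decline_tol) {
        declines <- declines + 1L
      } else {
        declines <- 0L
      }
      running_max <- max(scores[start_idx:i], na.rm = TRUE)
      if (declines >= patience && running_max > scores[i] + decline_tol) {
        termination <- "declined"
        break
      }
    }
  }
  trace <- tibble(
    weight = grid[seq_len(last_eval)],
    mean_test_r2 = scores[seq_len(last_eval)],
    candidate = seq_len(last_eval) >= start_idx
  )
  cand <- trace[trace$candidate & !is.na(trace$mean_test_r2), ]
  if (nrow(cand) == 0) {
    wp_numeric_error("weight search failed: no grid point could be evaluated")
  }
  best <- which(cand$mean_test_r2 == max(cand$mean_test_r2))[1]
  structure(
    list(trace = trace, chosen_weight = cand$weight[best],
         chosen_r2 = cand$mean_test_r2[best], termination = termination,
         r2_floor = r2_floor, seed = seed),
    class = "weight_search"
  )
}

#' @export
print.weight_search <- function(x, ...) {
  cat(sprintf(
    "<weight_search> %d weight(s) evaluated; chosen %.6g (mean test R2 %.3f); termination: %s\n",
    nrow(x$trace), x$chosen_weight, x$chosen_r2, x$termination
  ))
  invisible(x)
}

#' @describeIn weight_search Trace tibble of evaluated weights and scores.
#' @export
tidy.weight_search <- function(x, ...) x$trace

#' @describeIn weight_search Plot the search trace with the chosen weight.
#' @param object,x A `weight_search`.
#' @param ... Unused.
#' @export
autoplot.weight_search <- function(object, ...) {
  df <- object$trace[!is.na(object$trace$mean_test_r2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$weight, .data$mean_test_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$candidate)) +
    ggplot2::geom_vline(xintercept = object$chosen_weight, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "weight", y = "mean held-out R²",
                  title = sprintf("Weight search (%s)", object$termination))
}

#' Full per-phenolic, per-algorithm evaluation report
#'
#' Builds the feature representation for each phenolic class (visible range
#' for anthocyanins; anthocyanin-corrected UV for tannins and TIPs), tunes
#' each algorithm's weight by [weight_search()], and evaluates the tuned
#' model under [repeated_validation()]. Rows are ordered anthocyanins,
#' tannins, TIPs, with SVR, KRR, KPLSR within each — nine rows in total.
#'
#' @param spectra Raw wine `spectra_set` on the full grid.
#' @param assays Assay tibble (`sample_id`, `anthocyanins`, `tannins`,
#'   `tips`) covering the spectra's samples.
#' @param standard Sum-normalized malvidin chloride standard.
#' @param algorithms,targets Subsets to evaluate (defaults: all three each).
#' @param repeats,seed Validation protocol settings; per-cell seeds are
#'   derived deterministically from the master seed.
#' @param grids Optional named list of weight grids per algorithm.
#' @param anchor,boundary Isolation parameters (see [isolate_uv()]).
#' @param ... Passed on to [fit_phenolic_model()].
#' @return An `evaluation_report` tibble with columns `phenolic`,
#'   `algorithm`, `weight`, `r2_c`, `rmsec`, `r2_p`, `rmsep`, `r2_cv`,
#'   `rmsecv` (R² dimensionless, RMSE in mg/L equivalents).
#' @export
evaluate_all <- function(spectra, assays, standard,
                         algorithms = c("svr", "krr", "kpls"),
                         targets = c("anthocyanins", "tannins", "tips"),
                         repeats = 10, seed = 1, grids = NULL,
                         anchor = 520, boundary = 430, ...) {
  spectra <- assert_spectra(spectra)
  targets <- match.arg(targets, c("anthocyanins", "tannins", "tips"),
                       several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("svr", "krr", "kpls"),
                          several.ok = TRUE)
  joined_ids <- intersect(spectra$sample_id, assays$sample_id)
  if (length(joined_ids) < 4) {
    wp_data_error("too few samples shared between spectra and assays")
  }
  spectra <- spectra[match(joined_ids, spectra$sample_id), ]
  assays <- assays[match(joined_ids, assays$sample_id), ]
  cell_seeds <- matrix(
    derive_seeds(seed, length(targets) * length(algorithms) * 2L),
    ncol = 2
  )
  rows <- list()
  cell <- 0L
  for (ph in targets) {
    feats <- features_for(spectra, ph, standard = standard,
                          anchor = anchor, boundary = boundary)
    yv <- assays[[ph]]
    for (alg in algorithms) {
      cell <- cell + 1L
      grid <- grids[[alg]] %||%
        default_weight_grid(alg, floor(0.9 * length(yv)))
      ws <- weight_search(feats, yv, algorithm = alg, grid = grid,
                          repeats = repeats, seed = cell_seeds[cell, 1], ...)
      rv <- repeated_validation(feats, yv, algorithm = alg,
                                weight = ws$chosen_weight, repeats = repeats,
                                seed = cell_seeds[cell, 2], ...)
      rows[[cell]] <- dplyr::bind_cols(
        tibble(phenolic = ph, algorithm = alg, weight = ws$chosen_weight),
        rv$summary[c("r2_c", "rmsec", "r2_p", "rmsep", "r2_cv", "rmsecv")]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("evaluation_report", class(tibble())),
            wp_seed = seed, wp_repeats = repeats)
}

#' @describeIn evaluate_all Dot plot of held-out R² per phenolic and
#'   algorithm.
#' @param object An `evaluation_report`.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("r2_c", "r2_p", "r2_cv"),
                        names_to = "surface", values_to = "r2")
  ggplot2::ggplot(df, ggplot2::aes(.data$algorithm, .data$r2,
                                   colour = .data$surface)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~phenolic) +
    ggplot2::labs(y = "R²", x = NULL,
                  title = "Calibration / prediction / cross-validation R²")
}
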