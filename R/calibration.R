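# Isomer calibration model: a second-degree polynomial surface predicting
# %delta12-PGD2 from the relative abundances of the m/z 331 and 341
# channels, and a third-degree polynomial calibration curve relating the
# relative abundance of m/z 331 to %PGE2. Prediction inverts the cubic
# numerically for %PGE2, evaluates the surface for %delta12-PGD2, and
# obtains %PGD2 by closure to 100.

comp_cols <- c("pge2", "pgd2", "d12pgd2")

# Ensure r331/r333/r341 exist, deriving them from intensities if needed.
ensure_relative <- function(data) {
  if (!all(c("r331", "r341") %in% names(data))) {
    if (!all(c("i331", "i333", "i341") %in% names(data))) {
      abort("need relative-abundance columns r331/r341 or intensities i331/i333/i341")
    }
    data <- triplet_relative(data)
  }
  data
}

#' Fit the isomer prediction model
#'
#' Ordinary least squares of (1) %delta12-PGD2 on a full quadratic in
#' (r331, r341) and (2) r331 on a cubic in %PGE2. Replicates enter as
#' separate rows; no weighting is applied. Coefficients are never reused
#' across instruments or collision-energy settings: product-ion yields
#' depend on the CID settings, so the model must be retrained whenever they
#' change (record the settings in `settings` and [predict_image()] will
#' check the tag).
#'
#' @param data A data frame with true compositions in percent (`pge2`,
#'   `pgd2`, `d12pgd2`, each row summing to 100) and either relative
#'   abundances `r331`, `r333`, `r341` or raw intensities `i331`, `i333`,
#'   `i341` of the three diagnostic channels.
#' @param settings Free-text tag of the acquisition/CID settings the
#'   calibration was measured under.
#' @return An object of class `isomer_model` with elements
#'   `surface_coeffs` (p00, p10, p01, p20, p11, p02), `cubic_coeffs`
#'   (c0..c3), `r2_surface`, `r2_cubic`, `n_samples`, `training_meta`, and
#'   the training data (for diagnostics/plots).
#' @examples
#' set.seed(1)
#' cal <- make_training_set()
#' fit_isomer_model(cal)
#' @export
fit_isomer_model <- function(data, settings = "default") {
  stopifnot(is.data.frame(data))
  if (!all(comp_cols %in% names(data))) {
    abort("training data must have columns pge2, pgd2, d12pgd2 (percent)")
  }
  data <- ensure_relative(data)
  data <- data[stats::complete.cases(data[, c(comp_cols, "r331", "r341")]), ]
  if (nrow(data) < 10L) {
    abort("need at least 10 training samples with defined relative abundances")
  }
  if (sd(data$r331) == 0 || sd(data$pge2) == 0) {
    abort("degenerate training design: no spread in r331 or %PGE2")
  }
  surf <- lm(d12pgd2 ~ r331 + r341 + I(r331^2) + I(r331 * r341) + I(r341^2),
             data = data)
  cub <- lm(r331 ~ pge2 + I(pge2^2) + I(pge2^3), data = data)
  if (anyNA(coef(surf)) || anyNA(coef(cub))) {
    abort("rank-deficient design: calibration compositions are collinear")
  }
  # R^2 computed directly so that exact interpolation (zero residuals) is
  # reported as 1 without numerical noise
  r2 <- function(fit, y) {
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  }
  structure(list(
    surface_coeffs = stats::setNames(unname(coef(surf)),
                                     c("p00", "p10", "p01", "p20", "p11", "p02")),
    cubic_coeffs = stats::setNames(unname(coef(cub)), c("c0", "c1", "c2", "c3")),
    r2_surface = r2(surf, data$d12pgd2),
    r2_cubic = r2(cub, data$r331),
    n_samples = nrow(data),
    training_meta = list(settings = settings, fitted_at = format(Sys.time())),
    training_data = tibble::as_tibble(data)
  ), class = "isomer_model")
}

#' @export
print.isomer_model <- function(x, ...) {
  cat("Isomer prediction model (quadratic surface + cubic calibration curve)\n")
  cat(sprintf("  surface %%d12-PGD2 ~ (r331, r341):  R^2 = %.4f\n", x$r2_surface))
  cat(sprintf("  cubic   r331 ~ %%PGE2:              R^2 = %.4f\n", x$r2_cubic))
  cat(sprintf("  n = %d training samples; settings tag '%s'\n",
              x$n_samples, x$training_meta$settings))
  invisible(x)
}

#' @describeIn fit_isomer_model One row per coefficient, with `component`
#'   (`"surface"` or `"cubic"`), `term` and `estimate`.
#' @param x,object An `isomer_model`.
#' @param ... Unused.
#' @export
tidy.isomer_model <- function(x, ...) {
  tibble::tibble(
    component = rep(c("surface", "cubic"), c(6L, 4L)),
    term = c(names(x$surface_coeffs), names(x$cubic_coeffs)),
    estimate = c(unname(x$surface_coeffs), unname(x$cubic_coeffs))
  )
}

#' @describeIn fit_isomer_model One-row model summary (R-squared of both
#'   fits, sample count, settings tag).
#' @export
glance.isomer_model <- function(x, ...) {
  tibble::tibble(
    r2_surface = x$r2_surface,
    r2_cubic = x$r2_cubic,
    n_samples = x$n_samples,
    settings = x$training_meta$settings
  )
}

eval_surface <- function(co, x, y) {
  co[["p00"]] + co[["p10"]] * x + co[["p01"]] * y +
    co[["p20"]] * x^2 + co[["p11"]] * x * y + co[["p02"]] * y^2
}

eval_cubic <- function(co, p) {
  co[["c0"]] + co[["c1"]] * p + co[["c2"]] * p^2 + co[["c3"]] * p^3
}

#' Invert the cubic calibration curve
#'
#' Solves `g(x) = target` for the %PGE2 value `x`, where `g` is the fitted
#' cubic of r331 on %PGE2. Real roots are restricted to `[lower, upper]`
#' (the working range, default \[-10, 110\]); roots inside \[0, 100\] are
#' preferred when present. When several admissible roots remain, the one
#' nearest the grid-search minimizer of `|g(x) - target|` (step
#' `grid_step`) is chosen, with the smaller root breaking exact ties.
#'
#' @param coeffs Cubic coefficients `c(c0, c1, c2, c3)` (ascending powers).
#' @param target Target r331 value(s); vectorized.
#' @param lower,upper Admissible root range in percent.
#' @param grid_step Grid resolution (percentage points) for the tie-break
#'   search.
#' @return Numeric vector of solutions; `NA` where no admissible real root
#'   exists.
#' @export
invert_cubic <- function(coeffs, target, lower = -10, upper = 110,
                         grid_step = 0.01) {
  stopifnot(length(coeffs) == 4L)
  co <- stats::setNames(as.numeric(coeffs), c("c0", "c1", "c2", "c3"))
  vapply(target, function(tg) {
    if (!is.finite(tg)) return(NA_real_)
    rts <- polyroot(c(co[["c0"]] - tg, co[["c1"]], co[["c2"]], co[["c3"]]))
    re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    re <- re[re >= lower & re <= upper]
    if (!length(re)) return(NA_real_)
    pref <- re[re >= 0 & re <= 100]
    pool <- if (length(pref)) pref else re
    rng <- if (length(pref)) c(0, 100) else c(lower, upper)
    g <- seq(rng[1], rng[2], by = grid_step)
    gm <- g[which.min(abs(eval_cubic(co, g) - tg))]
    pool <- sort(pool)
    pool[which.min(abs(pool - gm))]
  }, numeric(1))
}

#' Predict isomer compositions from channel triplets
#'
#' For each row: %PGE2 by numeric inversion of the cubic calibration curve
#' at the measured r331; %delta12-PGD2 by evaluating the quadratic surface
#' at (r331, r341); %PGD2 by closure, 100 minus the other two, so every
#' valid composition sums to exactly 100. A prediction is flagged invalid
#' when the cubic has no admissible real root or when any component falls
#' outside the working \[-10, 110\]% range.
#'
#' @param object A fitted [fit_isomer_model()] object.
#' @param newdata Data frame with `r331`/`r341` (or intensity columns
#'   `i331`, `i333`, `i341`, from which relative abundances are derived).
#'   Rows with zero total intensity have undefined relative abundance and
#'   are rejected.
#' @param range Working range for raw predictions, default `c(-10, 110)`.
#' @param ... Unused.
#' @return A tibble with columns `pge2`, `pgd2`, `d12pgd2` (percent) and
#'   `valid`; invalid rows carry `NA` percentages.
#' @export
predict.isomer_model <- function(object, newdata, range = c(-10, 110), ...) {
  stopifnot(is.data.frame(newdata))
  newdata <- ensure_relative(newdata)
  if (anyNA(newdata$r331) || anyNA(newdata$r341)) {
    abort("undefined relative abundances (zero total intensity) in newdata")
  }
  pge2 <- invert_cubic(object$cubic_coeffs, newdata$r331,
                       lower = range[1], upper = range[2])
  d12 <- eval_surface(object$surface_coeffs, newdata$r331, newdata$r341)
  pgd2 <- 100 - pge2 - d12
  inrange <- function(v) !is.na(v) & v >= range[1] & v <= range[2]
  valid <- inrange(pge2) & inrange(d12) & inrange(pgd2)
  tibble::tibble(
    pge2 = ifelse(valid, pge2, NA_real_),
    pgd2 = ifelse(valid, pgd2, NA_real_),
    d12pgd2 = ifelse(valid, d12, NA_real_),
    valid = valid
  )
}

#' Read and write isomer models as plain text
#'
#' The model file is a small JSON record of the ten polynomial coefficients
#' (six surface, four cubic), the two R-squared values, the sample count
#' and the training metadata (settings tag, fit timestamp). Models written
#' here reload with [read_isomer_model()]; the training data itself is not
#' stored, so diagnostic plots of a reloaded model are unavailable.
#'
#' @param model A fitted `isomer_model`.
#' @param path File path.
#' @return `write_isomer_model()` returns `path` invisibly;
#'   `read_isomer_model()` returns an `isomer_model`.
#' @export
write_isomer_model <- function(model, path) {
  stopifnot(inherits(model, "isomer_model"))
  rec <- list(
    surface_coeffs = as.list(model$surface_coeffs),
    cubic_coeffs = as.list(model$cubic_coeffs),
    r2_surface = model$r2_surface,
    r2_cubic = model$r2_cubic,
    n_samples = model$n_samples,
    training_meta = model$training_meta
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_isomer_model
#' @export
read_isomer_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("surface_coeffs", "cubic_coeffs", "r2_surface", "r2_cubic")
  if (!all(need %in% names(rec))) abort("not an isomer model file")
  structure(list(
    surface_coeffs = unlist(rec$surface_coeffs),
    cubic_coeffs = unlist(rec$cubic_coeffs),
    r2_surface = rec$r2_surface,
    r2_cubic = rec$r2_cubic,
    n_samples = rec$n_samples,
    training_meta = as.list(rec$training_meta),
    training_data = NULL
  ), class = "isomer_model")
}

#' Hold-out cross-validation of the isomer model
#'
#' Repeats a random train/test split: a fraction of the calibration samples
#' is held out, the model is refitted on the remainder, the hold-out
#' samples are predicted, and a per-isomer root-mean-squared error (in
#' percentage points) is computed. Reported RMSEs are means over
#' iterations per isomer (not pooled across isomers). Splits are at the
#' sample level, so technical replicates of one composition may fall on
#' both sides.
#'
#' @param data Calibration data as for [fit_isomer_model()].
#' @param holdout_fraction Fraction of samples held out per iteration.
#' @param n_iterations Number of random splits.
#' @param seed Integer seed for the split generator (recorded in the
#'   result; the caller's RNG state is restored on exit).
#' @param settings Passed to [fit_isomer_model()].
#' @return An object of class `pg_cv`: per-iteration RMSEs plus summary.
#'   `glance()` gives the one-row summary (mean RMSE per isomer), `tidy()`
#'   the per-iteration table.
#' @export
cross_validate <- function(data, holdout_fraction = 0.1, n_iterations = 50,
                           seed = 1, settings = "default") {
  stopifnot(is.data.frame(data), holdout_fraction > 0, holdout_fraction < 1,
            n_iterations >= 1)
  data <- ensure_relative(data)
  n <- nrow(data)
  n_hold <- max(1L, round(holdout_fraction * n))
  if (n - n_hold < 10L) abort("too few samples to train after holdout")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  iters <- purrr::map_dfr(seq_len(n_iterations), function(it) {
    hold <- sample.int(n, n_hold)
    fit <- fit_isomer_model(data[-hold, ], settings = settings)
    pred <- predict(fit, data[hold, ])
    truth <- data[hold, comp_cols]
    rmse <- vapply(comp_cols, function(cc) {
      e <- pred[[cc]] - truth[[cc]]
      sqrt(mean(e^2, na.rm = TRUE))
    }, numeric(1))
    tibble::tibble(iteration = it,
                   rmse_pge2 = rmse[["pge2"]],
                   rmse_pgd2 = rmse[["pgd2"]],
                   rmse_d12pgd2 = rmse[["d12pgd2"]],
                   n_holdout = n_hold,
                   n_invalid = sum(!pred$valid))
  })
  structure(list(
    iterations = iters,
    rmse_pge2 = mean(iters$rmse_pge2, na.rm = TRUE),
    rmse_pgd2 = mean(iters$rmse_pgd2, na.rm = TRUE),
    rmse_d12pgd2 = mean(iters$rmse_d12pgd2, na.rm = TRUE),
    n_iterations = n_iterations,
    holdout_fraction = holdout_fraction,
    seed = seed
  ), class = "pg_cv")
}

#' @export
print.pg_cv <- function(x, ...) {
  cat(sprintf(
    "Hold-out cross-validation: %d iterations, %.0f%% holdout (seed %d)\n",
    x$n_iterations, 100 * x$holdout_fraction, x$seed))
  cat(sprintf("  mean RMSE (%%):  PGE2 %.2f   PGD2 %.2f   d12-PGD2 %.2f\n",
              x$rmse_pge2, x$rmse_pgd2, x$rmse_d12pgd2))
  invisible(x)
}

#' @describeIn cross_validate Per-iteration RMSE table.
#' @param x,object A `pg_cv` object.
#' @param ... Unused.
#' @export
tidy.pg_cv <- function(x, ...) x$iterations

#' @describeIn cross_validate One-row summary with mean per-isomer RMSEs.
#' @export
glance.pg_cv <- function(x, ...) {
  tibble::tibble(
    rmse_pge2 = x$rmse_pge2,
    rmse_pgd2 = x$rmse_pgd2,
    rmse_d12pgd2 = x$rmse_d12pgd2,
    n_iterations = x$n_iterations,
    holdout_fraction = x$holdout_fraction,
    seed = x$seed
  )
}

#' Diagnostic plot of a fitted isomer model
#'
#' Left: training points in the (r331, r341) plane coloured by true
#' %delta12-PGD2 (the surface's response). Right: the cubic calibration
#' curve of r331 against %PGE2 with the training points.
#'
#' @param object A fitted `isomer_model`.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @export
autoplot.isomer_model <- function(object, ...) {
  td <- object$training_data
  grid_p <- seq(0, 100, length.out = 200)
  curve <- tibble::tibble(pge2 = grid_p,
                          r331 = eval_cubic(object$cubic_coeffs, grid_p))
  pts <- dplyr::bind_rows(
    tibble::tibble(panel = "surface response", x = td$r331, y = td$r341,
                   value = td$d12pgd2),
    tibble::tibble(panel = "cubic calibration", x = td$pge2, y = td$r331,
                   value = NA_real_)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$value), na.rm = TRUE) +
    ggplot2::geom_line(
      data = tibble::tibble(panel = "cubic calibration",
                            x = curve$pge2, y = curve$r331),
      colour = "grey30"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_colour_viridis_c(name = "%d12-PGD2", na.value = NA) +
    ggplot2::labs(
      x = "%PGE2 (cubic panel) / r331 (surface panel)",
      y = "r331 (cubic panel) / r341 (surface panel)",
      title = sprintf("Isomer model: R2 surface %.3f, cubic %.3f",
                      object$r2_surface, object$r2_cubic)
    ) +
    ggplot2::theme_minimal()
}
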