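# Forward-model simulator: mixtures of the three isomers produce the three
# diagnostic MS3 channels by linear mixing of per-isomer fragment yields,
# followed by multiplicative and additive Gaussian noise. Relative
# abundances are formed afterwards, which reproduces the
# rational-in-composition behaviour the polynomial model approximates.

#' Default MS3 fragment-yield signature
#'
#' Per-isomer relative yields of the diagnostic channels, each isomer
#' normalized to its own base peak. Anchors: PGE2 yields the m/z 333.206
#' ion at 5% of its base peak (the 331 channel); PGD2 and delta12-PGD2
#' have 333.206 as base peak; 331 is below 2% in the non-PGE2 isomers; the
#' 341 channel is specific to delta12-PGD2. The delta12 yield of channel
#' 341 (0.35 here) and the sub-2% placements are free parameters of the
#' simulator, not measured values.
#'
#' @return A 3 x 3 numeric matrix, rows `c("i331","i333","i341")`, columns
#'   `c("pge2","pgd2","d12pgd2")`.
#' @export
default_signature <- function() {
  matrix(
    c(1.00, 0.05, 0.01,
      0.02, 1.00, 0.02,
      0.02, 1.00, 0.35),
    nrow = 3, byrow = FALSE,
    dimnames = list(c("i331", "i333", "i341"), c("pge2", "pgd2", "d12pgd2"))
  )
}

#' Noise model for simulated channel intensities
#'
#' Proportional Gaussian noise (coefficient of variation) applied per
#' channel, plus additive Gaussian noise; simulated intensities are clipped
#' at zero.
#'
#' @param proportional_cv Relative standard deviation of the multiplicative
#'   term (default 0.03).
#' @param additive_sd Standard deviation of the additive term, in the same
#'   arbitrary units as the simulated intensities. The default `NULL` means
#'   1% of the simulation's total intensity (roughly 1% of the base peak at
#'   tissue-level signal).
#' @return A list with class `pg_noise`.
#' @export
noise_model <- function(proportional_cv = 0.03, additive_sd = NULL) {
  stopifnot(proportional_cv >= 0, is.null(additive_sd) || additive_sd >= 0)
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd),
            class = "pg_noise")
}

resolve_additive_sd <- function(noise, total_intensity) {
  noise$additive_sd %||% (0.01 * total_intensity)
}

# Noiseless closed-form mixing: channel intensities for compositions in
# percent. comps: matrix/data frame with pge2, pgd2, d12pgd2 columns.
mix_intensities <- function(comps, total_intensity, signature) {
  f <- as.matrix(comps[, c("pge2", "pgd2", "d12pgd2"), drop = FALSE]) / 100
  t(signature %*% t(f)) * total_intensity
}

#' Simulate diagnostic-channel triplets for isomer mixtures
#'
#' Channel intensity = `total_intensity x sum_i(fraction_i x yield_i)`,
#' then proportional and additive Gaussian noise, clipped at zero; relative
#' abundances are computed from the noisy intensities.
#'
#' @param compositions Data frame with columns `pge2`, `pgd2`, `d12pgd2` in
#'   percent (each row summing to 100, all non-negative).
#' @param total_intensity Total mixed channel signal per sample (arbitrary
#'   units, > 0); recycled.
#' @param signature Yield matrix, see [default_signature()].
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for the
#'   deterministic closed-form output.
#' @return The input compositions with added columns `i331`, `i333`,
#'   `i341`, `r331`, `r333`, `r341`.
#' @export
simulate_triplets <- function(compositions, total_intensity = 1000,
                              signature = default_signature(),
                              noise = noise_model()) {
  stopifnot(is.data.frame(compositions),
            all(c("pge2", "pgd2", "d12pgd2") %in% names(compositions)))
  comp <- as.matrix(compositions[, c("pge2", "pgd2", "d12pgd2")])
  if (any(comp < 0) || any(abs(rowSums(comp) - 100) > 1e-6)) {
    abort("compositions must be non-negative percentages summing to 100")
  }
  if (any(total_intensity <= 0)) abort("total_intensity must be positive")
  n <- nrow(comp)
  total_intensity <- rep_len(total_intensity, n)
  I <- mix_intensities(compositions, total_intensity, signature)
  asd <- resolve_additive_sd(noise, total_intensity)
  if (noise$proportional_cv > 0) {
    I <- I * (1 + matrix(rnorm(3L * n, 0, noise$proportional_cv), n, 3L))
  }
  if (any(asd > 0)) {
    I <- I + matrix(rnorm(3L * n, 0, rep(asd, 3L)), n, 3L)
  }
  I[I < 0] <- 0
  out <- tibble::as_tibble(compositions)
  out$i331 <- as.numeric(I[, 1L])
  out$i333 <- as.numeric(I[, 2L])
  out$i341 <- as.numeric(I[, 3L])
  triplet_relative(out)
}

#' Simplex design of calibration compositions
#'
#' A lattice over the three-isomer simplex at multiples of `step` percent
#' (for the default 25: the three pure standards, the binary 25/50/75
#' blends and the interior points, 15 compositions) plus the equimolar
#' point.
#'
#' @param step Lattice spacing in percent (must divide 100).
#' @param include_equimolar Add the 1:1:1 mixture.
#' @return A tibble with columns `pge2`, `pgd2`, `d12pgd2`.
#' @export
simplex_design <- function(step = 25, include_equimolar = TRUE) {
  stopifnot(step > 0, 100 %% step == 0)
  g <- expand.grid(pge2 = seq(0, 100, step), pgd2 = seq(0, 100, step))
  g$d12pgd2 <- 100 - g$pge2 - g$pgd2
  g <- g[g$d12pgd2 >= 0, ]
  out <- tibble::as_tibble(g)
  if (include_equimolar) {
    out <- dplyr::bind_rows(out, tibble::tibble(pge2 = 100 / 3, pgd2 = 100 / 3,
                                                d12pgd2 = 100 / 3))
  }
  out
}

#' Simulate a calibration training set
#'
#' One sample per composition and technical replicate, mirroring a
#' flow-injection calibration series in which every solution holds the
#' total prostaglandin amount constant and varies the isomer proportions
#' over the 0-100% simplex, injected in triplicate.
#'
#' @param design Compositions (percent), default [simplex_design()].
#' @param replicates Technical replicates per composition (default 3).
#' @inheritParams simulate_triplets
#' @param seed Optional integer seed; if given, the RNG state is set for
#'   the simulation and restored afterwards.
#' @return A tibble with the design columns, `replicate`, channel
#'   intensities and relative abundances.
#' @export
make_training_set <- function(design = simplex_design(), replicates = 3,
                              total_intensity = 1000,
                              signature = default_signature(),
                              noise = noise_model(), seed = NULL) {
  stopifnot(is.data.frame(design), nrow(design) >= 1, replicates >= 1)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  full <- dplyr::bind_rows(purrr::map(seq_len(replicates), function(r) {
    d <- tibble::as_tibble(design)
    d$replicate <- r
    d
  }))
  simulate_triplets(full, total_intensity, signature, noise)
}

#' Generate a model-consistent (polynomial) calibration set
#'
#' Produces noiseless triplets that satisfy a given quadratic-surface +
#' cubic-curve model exactly: r331 is the cubic evaluated at %PGE2 and
#' r341 solves the surface equation at the row's %delta12-PGD2. Refitting
#' on this set recovers the generating coefficients to solver tolerance
#' (R-squared = 1), which makes it the exact-interpolation oracle for the
#' fitting and inversion code; unlike [make_training_set()] it does not
#' emulate the rational mixing behaviour of real channel intensities.
#'
#' @param model An `isomer_model` supplying the generating coefficients.
#' @param design Compositions in percent, default [simplex_design()].
#' @return A tibble with composition columns and `r331`, `r333`, `r341`;
#'   rows whose surface equation has no admissible solution are dropped.
#' @export
make_polynomial_set <- function(model, design = simplex_design()) {
  stopifnot(inherits(model, "isomer_model"))
  cs <- model$surface_coeffs
  r331 <- eval_cubic(model$cubic_coeffs, design$pge2)
  r341 <- vapply(seq_len(nrow(design)), function(i) {
    x <- r331[i]
    # quadratic in y: p02 y^2 + (p01 + p11 x) y + (p00 + p10 x + p20 x^2 - z)
    a <- cs[["p02"]]
    b <- cs[["p01"]] + cs[["p11"]] * x
    cc <- cs[["p00"]] + cs[["p10"]] * x + cs[["p20"]] * x^2 - design$d12pgd2[i]
    if (abs(a) < 1e-12) {
      if (abs(b) < 1e-12) return(NA_real_)
      y <- -cc / b
      return(if (y >= 0 && y + x <= 1) y else NA_real_)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    ys <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
    ys <- ys[ys >= 0 & ys + x <= 1]
    if (length(ys)) ys[1] else NA_real_
  }, numeric(1))
  out <- tibble::as_tibble(design)
  out$r331 <- r331
  out$r341 <- r341
  out$r333 <- 1 - out$r331 - out$r341
  out[stats::complete.cases(out[, c("r331", "r341")]), ]
}

#' Add channel interference emulating a complex matrix
#'
#' Injects a non-negative additive background into selected channels, as a
#' stand-in for co-isolated isobaric material in a biological extract, then
#' recomputes the relative abundances. Per sample and channel the
#' interference amplitude is uniform on `[0, max_frac]` times either the
#' channel's own intensity (`reference = "channel"`, default: contamination
#' proportional to the channel signal, consistent with the diagnostic
#' channels remaining PG-specific in a complex matrix) or the summed
#' three-channel intensity (`reference = "total"`, a much harsher regime
#' for the minor channels).
#'
#' @param data A tibble with `i331`, `i333`, `i341` columns (e.g. from
#'   [make_training_set()]).
#' @param max_frac Maximum interference fraction (default 0.05).
#' @param channels Channels receiving interference (default 331 and 333).
#' @param reference `"channel"` or `"total"`, see above.
#' @return `data` with perturbed intensities and recomputed `r331`, `r333`,
#'   `r341`.
#' @export
add_interference <- function(data, max_frac = 0.05,
                             channels = c("i331", "i333"),
                             reference = c("channel", "total")) {
  reference <- match.arg(reference)
  stopifnot(all(channels %in% c("i331", "i333", "i341")),
            all(c("i331", "i333", "i341") %in% names(data)), max_frac >= 0)
  n <- nrow(data)
  total <- data$i331 + data$i333 + data$i341
  for (ch in channels) {
    ref <- if (reference == "channel") data[[ch]] else total
    data[[ch]] <- data[[ch]] + runif(n, 0, max_frac) * ref
  }
  triplet_relative(data)
}
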