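# Shared fixtures and independent oracles used across test files.

pg_isomers <- c("pge2", "pgd2", "d12pgd2")

# Pinned constants, read back from the exported table so oracle sums are
# independent of the formula-parsing path.
mass_of <- function(el) {
  tab <- pg_atomic_masses()
  tab$mass[match(el, tab$element)]
}

# Exhaustive brute-force oracle for neutral-loss assignment: enumerate every
# subformula of the precursor ion over C/H/O (+ optional AgH-containing
# losses) and keep candidates within the ppm tolerance, ranked like the
# implementation (|ppm|, then heavy atoms in the loss, smaller first).
brute_force_assign <- function(measured, tol_ppm = 5, allow_metal = TRUE) {
  me <- mass_of("electron")
  prec <- c(C = 20, H = 32, O = 5, Ag = 1)
  prec_mass <- 20 * mass_of("C") + 32 * mass_of("H") + 5 * mass_of("O") +
    mass_of("Ag")
  rows <- list()
  for (ag in if (allow_metal) 0:1 else 0) {
    for (c_ in 0:20) for (h in (if (ag) 1 else 0):32) for (o in 0:5) {
      loss_mass <- c_ * mass_of("C") + h * mass_of("H") + o * mass_of("O") +
        ag * mass_of("Ag")
      mz <- prec_mass - loss_mass - me
      ppm <- (measured - mz) / mz * 1e6
      if (abs(ppm) <= tol_ppm) {
        rows[[length(rows) + 1]] <- data.frame(
          C = c_, H = h, O = o, Ag = ag, mz = mz, ppm = ppm,
          heavy = c_ + o + ag
        )
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(abs(out$ppm), out$heavy), ]
}

# Grid-search oracle for cubic inversion: argmin of |g(x) - target| on a
# 0.01-step grid over [-10, 110], restricted to [0, 100] whenever the grid
# shows a solution there (a sign change of g - target between neighbouring
# grid points). Same selection policy as the implementation, but pure
# brute-force search with no analytic root-finding.
grid_invert <- function(coeffs, target, step = 0.01) {
  g <- function(x) coeffs[1] + coeffs[2] * x + coeffs[3] * x^2 + coeffs[4] * x^3
  x <- seq(-10, 110, by = step)
  d <- g(x) - target
  s <- sign(d)
  cross <- which(s[-1] * s[-length(s)] <= 0)
  solvable_in01 <- any(x[cross] >= 0 & x[cross] + step <= 100)
  use <- if (solvable_in01) x >= 0 & x <= 100 else rep(TRUE, length(x))
  x[use][which.min(abs(d[use]))]
}

rmse_by_isomer <- function(pred, truth) {
  vapply(pg_isomers, function(cc) {
    sqrt(mean((pred[[cc]] - truth[[cc]])^2, na.rm = TRUE))
  }, numeric(1))
}

# A small standard calibration set and model reused by several files.
std_training_set <- function(seed = 1, ...) make_training_set(seed = seed, ...)

std_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_isomer_model(std_training_set())
    cache
  }
})

# A three-scan run (MS1 SIM, MS2, MS3) used by the spectra tests.
tiny_run <- function() {
  mass_spectra(
    ms_level = c(1L, 2L, 3L),
    scan_time = c(0.1, 0.5, 0.9),
    mz = list(c(459.1295, 468.1860), 441.119, c(331.0096, 333.2060, 341.0301)),
    intensity = list(c(1000, 500), 800, c(100, 600, 250)),
    precursor_chain = list(numeric(), 459.13, c(459.13, 441.12)),
    analyzer = c("high_res", "high_res", "low_res")
  )
}
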