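# Synthetic MSI phantom: interlaced SIM + MS3 line scans over a labelled
# tissue layout, with ground-truth maps for round-trip testing of the
# assembly -> mask -> S/N -> prediction pipeline.

#' SIM-scan channels for imaging runs
#'
#' The precursor channel (m/z 459.1295, the shared silver-adduct
#' composition) and the PGD2-d9 internal-standard channel, both read from
#' high-resolution SIM scans at 5 ppm.
#'
#' @return A channel tibble as used by [extract_channels()].
#' @export
pg_sim_channels <- function() {
  tibble::tibble(
    label = c("pre459", "std"),
    target_mz = c(pg_precursor_mz(), pg_internal_standard_mz()),
    tol_mode = "ppm",
    tol_value = 5
  )
}

#' Phantom tissue layout
#'
#' A rectangular grid partitioned into an off-tissue border and three
#' tissue regions echoing an embryo implantation site: an
#' antimesometrial-pole-like block, a luminal-epithelium-like strip and a
#' mesometrial-pole-like block, each with its own isomer composition
#' (percent) and total diagnostic-channel signal level. Off-tissue signal
#' is far below the tissue level so masking can be exercised.
#'
#' @param n_lines,n_pixels Grid shape (lines x pixels per line).
#' @param border Off-tissue border width in pixels.
#' @param regions A tibble with columns `region`, `pge2`, `pgd2`,
#'   `d12pgd2`, `total_intensity`; must contain rows named `am_pole`,
#'   `epithelium`, `m_pole` and `off_tissue`.
#' @param standard_intensity Internal-standard channel level (uniform, the
#'   standard is doped into the solvent).
#' @param precursor_factor SIM precursor intensity per unit of total
#'   MS3-channel signal.
#' @return A `phantom_layout` object with a `labels` matrix and the region
#'   table.
#' @export
phantom_layout <- function(n_lines = 20, n_pixels = 32, border = 2,
                           regions = NULL, standard_intensity = 500,
                           precursor_factor = 10) {
  stopifnot(n_lines > 2 * border + 1, n_pixels > 2 * border + 3)
  regions <- regions %||% tibble::tribble(
    ~region,       ~pge2, ~pgd2, ~d12pgd2, ~total_intensity,
    "am_pole",        35,    15,       50,             1000,
    "epithelium",     45,    10,       45,              800,
    "m_pole",         20,    40,       40,              200,
    "off_tissue",    100 / 3, 100 / 3, 100 / 3,           2
  )
  stopifnot(all(c("am_pole", "epithelium", "m_pole", "off_tissue") %in%
                  regions$region))
  labels <- matrix("off_tissue", n_lines, n_pixels)
  inner_c <- (border + 1):(n_pixels - border)
  inner_r <- (border + 1):(n_lines - border)
  w <- length(inner_c)
  am <- inner_c[seq_len(floor(0.4 * w))]
  le <- inner_c[(floor(0.4 * w) + 1):floor(0.6 * w)]
  mp <- setdiff(inner_c, c(am, le))
  labels[inner_r, am] <- "am_pole"
  labels[inner_r, le] <- "epithelium"
  labels[inner_r, mp] <- "m_pole"
  structure(list(labels = labels, regions = tibble::as_tibble(regions),
                 standard_intensity = standard_intensity,
                 precursor_factor = precursor_factor),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("Phantom layout %d x %d pixels:\n", nrow(x$labels), ncol(x$labels)))
  print(x$regions)
  invisible(x)
}

#' Logical mask of one phantom region
#'
#' @param layout A [phantom_layout()].
#' @param region Region name, e.g. `"am_pole"`.
#' @return A logical matrix.
#' @export
phantom_region <- function(layout, region) {
  stopifnot(inherits(layout, "phantom_layout"),
            region %in% layout$regions$region)
  layout$labels == region
}

#' Simulate an MSI phantom as interlaced line scans
#'
#' Emits, per pixel, one high-resolution SIM scan (precursor channel
#' proportional to the region's total signal, plus the constant
#' internal-standard channel) followed by one ion-trap MS3 scan of the
#' three diagnostic channels simulated from the region's composition
#' ([simulate_triplets()]). Scan times follow the duty-cycle period of
#' `geom`, so [assemble_grid()] on the emitted lines reconstructs the
#' layout grid.
#'
#' @param layout A [phantom_layout()].
#' @param geom A [grid_geometry()]; defaults to the 0.02 mm/s, 1.55 s,
#'   100 um line-scan geometry (31 x 100 um^2 pixels).
#' @param signature,noise Forward-model parameters, see
#'   [simulate_triplets()]. The noise default uses an absolute additive
#'   floor (`additive_sd = 5`) so off-tissue pixels carry realistic
#'   detector noise for S/N estimation.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A list with elements `lines` (list of spectrum tibbles), `geom`,
#'   `layout`, and `truth`: ground-truth maps (`pge2`, `pgd2`, `d12pgd2`,
#'   `total`, noiseless channel maps `i331`, `i333`, `i341`, `pre459`,
#'   `std`, and the `region` label matrix).
#' @export
make_msi_phantom <- function(layout = phantom_layout(),
                             geom = grid_geometry(0.02, cycle_s = 1.55,
                                                  line_step = 100),
                             signature = default_signature(),
                             noise = noise_model(additive_sd = 5),
                             seed = NULL) {
  stopifnot(inherits(layout, "phantom_layout"), inherits(geom, "grid_geometry"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  lab <- layout$labels
  nr <- nrow(lab); nc <- ncol(lab)
  reg <- layout$regions
  ridx <- match(as.vector(lab), reg$region)
  comp <- tibble::tibble(pge2 = reg$pge2[ridx], pgd2 = reg$pgd2[ridx],
                         d12pgd2 = reg$d12pgd2[ridx])
  total <- reg$total_intensity[ridx]
  sim_t <- simulate_triplets(comp, total, signature, noise)
  # noiseless ground-truth channel maps
  I0 <- mix_intensities(comp, total, signature)
  mzs <- pg_channels()$target_mz
  sim_mz <- pg_sim_channels()$target_mz
  asd <- resolve_additive_sd(noise, total)
  pre0 <- layout$precursor_factor * total
  pre <- pmax(0, pre0 * (1 + rnorm(nr * nc, 0, noise$proportional_cv)) +
                rnorm(nr * nc, 0, asd))
  std <- pmax(0, layout$standard_intensity *
                (1 + rnorm(nr * nc, 0, noise$proportional_cv)) +
                rnorm(nr * nc, 0, asd))
  per <- geom$cycle_period
  lines <- purrr::map(seq_len(nr), function(i) {
    cells <- (seq_len(nc) - 1L) * nr + i  # column-major index of (i, j)
    n <- nc
    t0 <- (seq_len(n) - 1L) * per
    ms_level <- rep(c(1L, 3L), n)
    scan_time <- as.vector(rbind(t0 + 0.3 * per, t0 + 0.7 * per))
    mz <- vector("list", 2L * n)
    inten <- vector("list", 2L * n)
    chain <- vector("list", 2L * n)
    for (j in seq_len(n)) {
      k <- cells[j]
      mz[[2L * j - 1L]] <- sim_mz
      inten[[2L * j - 1L]] <- c(pre[k], std[k])
      chain[[2L * j - 1L]] <- numeric()
      mz[[2L * j]] <- mzs
      inten[[2L * j]] <- as.numeric(sim_t[k, c("i331", "i333", "i341")])
      chain[[2L * j]] <- c(459.13, 441.12)
    }
    mass_spectra(ms_level, scan_time, mz, inten, chain,
                 analyzer = rep(c("high_res", "low_res"), n))
  })
  shape <- function(v) matrix(v, nr, nc)
  list(
    lines = lines,
    geom = geom,
    layout = layout,
    truth = list(
      pge2 = shape(comp$pge2), pgd2 = shape(comp$pgd2),
      d12pgd2 = shape(comp$d12pgd2), total = shape(total),
      i331 = shape(I0[, 1L]), i333 = shape(I0[, 2L]), i341 = shape(I0[, 3L]),
      pre459 = shape(pre0), std = shape(rep(layout$standard_intensity, nr * nc)),
      region = lab
    )
  )
}
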