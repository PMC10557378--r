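# Mass spectrometry imaging: line-scan assembly into pixel grids,
# internal-standard quantitation, tissue masking, S/N filtering, per-pixel
# isomer prediction and ROI statistics.

#' Line-scan grid geometry
#'
#' Pixel width along the scan axis is `stage_speed x 1000 x cycle_period`
#' (mm/s times s gives mm, converted to um); pixel height across lines is
#' the line step. The spectral duty cycle may be given as a period in
#' seconds (`cycle_s`) or as a rate in Hz (`duty_cycle_hz`, converted as
#' `1/Hz`); supply exactly one. With 0.02 mm/s, a 1.55 s cycle and a
#' 100 um line step the pixel is 31 x 100 um^2. (Published figures quoting
#' a "1.55 Hz" duty cycle alongside a 31 um pixel are only dimensionally
#' consistent with a 1.55 s cycle period, which is why the distinction is
#' explicit here.)
#'
#' @param stage_speed Stage speed along the scan axis, mm/s.
#' @param cycle_s Full spectral duty-cycle period, seconds per cycle.
#' @param duty_cycle_hz Alternative: cycle rate in Hz.
#' @param line_step Step between lines, um.
#' @param n_lines Optional expected number of lines.
#' @return A `grid_geometry` object.
#' @examples
#' pixel_size(grid_geometry(0.02, cycle_s = 1.55, line_step = 100))
#' @export
grid_geometry <- function(stage_speed, cycle_s = NULL, duty_cycle_hz = NULL,
                          line_step = 100, n_lines = NULL) {
  if (is.null(cycle_s) == is.null(duty_cycle_hz)) {
    abort("supply exactly one of cycle_s or duty_cycle_hz")
  }
  period <- cycle_s %||% (1 / duty_cycle_hz)
  stopifnot(stage_speed > 0, period > 0, line_step > 0)
  structure(list(stage_speed = stage_speed, cycle_period = period,
                 line_step = line_step, n_lines = n_lines),
            class = "grid_geometry")
}

#' @describeIn grid_geometry Pixel dimensions `c(width, height)` in um.
#' @param geom A `grid_geometry`.
#' @export
pixel_size <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  c(width = geom$stage_speed * 1000 * geom$cycle_period,
    height = geom$line_step)
}

#' @export
print.grid_geometry <- function(x, ...) {
  ps <- pixel_size(x)
  cat(sprintf(
    "Line-scan geometry: %.3g mm/s, %.3g s/cycle, %.3g um line step -> pixel %.3g x %.3g um^2\n",
    x$stage_speed, x$cycle_period, x$line_step, ps["width"], ps["height"]))
  invisible(x)
}

#' Construct an ion image
#'
#' A 2-D pixel grid (rows = lines, columns = position along the scan axis)
#' with physical pixel dimensions, a validity mask and units. Masked-out
#' pixels are excluded from every statistic, never treated as zeros.
#'
#' @param values Numeric matrix of intensities/concentrations/percentages.
#' @param pixel_size `c(width, height)` in um.
#' @param mask Logical matrix of valid pixels (default: non-`NA` values).
#' @param units Unit string (e.g. `"counts"`, `"uM"`, `"%"`).
#' @return An `ion_image` object.
#' @export
ion_image <- function(values, pixel_size, mask = NULL, units = "counts") {
  stopifnot(is.matrix(values), length(pixel_size) == 2L, all(pixel_size > 0))
  mask <- mask %||% !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    abort("mask must be a logical matrix of the same shape as values")
  }
  mask[is.na(mask)] <- FALSE
  mask <- mask & !is.na(values)
  structure(list(values = values, pixel_size = as.numeric(pixel_size),
                 mask = mask, units = units),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("Ion image: %d x %d pixels (%.3g x %.3g um^2 each), %d valid, units '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size[1], x$pixel_size[2],
              sum(x$mask), x$units))
  invisible(x)
}

#' Tidy an ion image into pixel rows
#'
#' @param x An `ion_image`.
#' @param ... Unused.
#' @return A tibble with `line`, `pixel` (grid indices), `x_um`, `y_um`
#'   (pixel-centre physical coordinates), `value` and `valid`.
#' @importFrom tibble as_tibble
#' @method as_tibble ion_image
#' @export
as_tibble.ion_image <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble::tibble(
    line = rep(seq_len(nr), times = nc),
    pixel = rep(seq_len(nc), each = nr),
    x_um = (rep(seq_len(nc), each = nr) - 0.5) * x$pixel_size[1],
    y_um = (rep(seq_len(nr), times = nc) - 0.5) * x$pixel_size[2],
    value = as.vector(x$values),
    valid = as.vector(x$mask)
  )
}

#' Plot an ion image
#'
#' Renders the pixel grid at its physical aspect ratio. Invalid pixels are
#' drawn black. For percent images, valid predictions outside 0-100% are
#' displayed as 0 (`clamp_percent`), matching the rendering convention for
#' isomer-fraction images, while the stored values are left untouched.
#'
#' @param object An `ion_image`.
#' @param clamp_percent Clamp displayed percent values into 0-100.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ion_image <- function(object, clamp_percent = TRUE, ...) {
  df <- as_tibble.ion_image(object)
  df$display <- ifelse(df$valid, df$value, NA_real_)
  if (clamp_percent && identical(object$units, "%")) {
    out_of_range <- df$valid & (df$display < 0 | df$display > 100)
    df$display[out_of_range] <- 0
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$display)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$units, na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Assemble line scans into per-channel ion images
#'
#' Pixels are indexed by the MS3 duty cycle: the j-th matching MS3 scan of
#' a line becomes pixel column j of that line's row. Interlaced SIM (or
#' full-scan) channels are sampled at the scan nearest in time to each
#' pixel's MS3 scan. Lines may differ in scan count; trailing pixels of
#' shorter lines are invalid.
#'
#' @param lines List of spectrum tibbles, one per line, in line order; each
#'   must be time-ordered.
#' @param geom A [grid_geometry()].
#' @param ms3_channels Channel table applied to the MS3 scans (default
#'   [pg_channels()]).
#' @param chain MS3 precursor chain used to select pixel scans (default
#'   `c(459.13, 441.12)`); `NULL` keeps every MS3 scan.
#' @param chain_tol Chain match tolerance, amu.
#' @param sim_channels Optional channel table applied to the interlaced
#'   MS1/SIM scans (e.g. precursor and internal standard).
#' @return A named list of [ion_image()] objects, one per channel label.
#' @export
assemble_grid <- function(lines, geom, ms3_channels = pg_channels(),
                          chain = c(459.13, 441.12), chain_tol = 0.5,
                          sim_channels = NULL) {
  stopifnot(is.list(lines), length(lines) >= 1, inherits(geom, "grid_geometry"))
  per_line <- purrr::map(lines, function(ln) {
    validate_spectra(ln)
    if (is.unsorted(ln$scan_time)) abort("line scans must be time-ordered")
    ms3 <- if (is.null(chain)) {
      ln[ln$ms_level == 3L, ]
    } else {
      select_scans(ln, 3L, chain, chain_tol)
    }
    if (!nrow(ms3)) abort("a line contains no matching MS3 scans")
    ext <- extract_channels(ms3, ms3_channels)
    if (!is.null(sim_channels)) {
      sim <- ln[ln$ms_level == 1L, ]
      if (!nrow(sim)) abort("sim_channels given but a line has no MS1/SIM scans")
      sext <- extract_channels(sim, sim_channels)
      idx <- vapply(ext$scan_time, function(t) which.min(abs(sext$scan_time - t)),
                    integer(1))
      for (lab in sim_channels$label) ext[[lab]] <- sext[[lab]][idx]
    }
    ext
  })
  labs <- c(ms3_channels$label, if (!is.null(sim_channels)) sim_channels$label)
  ncol_max <- max(vapply(per_line, nrow, integer(1)))
  ps <- pixel_size(geom)
  out <- lapply(labs, function(lab) {
    m <- matrix(NA_real_, nrow = length(lines), ncol = ncol_max)
    for (i in seq_along(per_line)) {
      v <- per_line[[i]][[lab]]
      m[i, seq_along(v)] <- v
    }
    ion_image(m, ps, units = "counts")
  })
  stats::setNames(out, labs)
}

#' One-point internal-standard quantitation
#'
#' Per-pixel concentration: the analyte-to-standard intensity ratio times
#' the known standard concentration. Pixels where the standard intensity is
#' zero (or either image is invalid) are invalid in the result.
#'
#' @param analyte,standard `ion_image`s of matching shape.
#' @param standard_conc Standard concentration in uM (> 0).
#' @return An `ion_image` in uM.
#' @export
quantify_channel <- function(analyte, standard, standard_conc) {
  stopifnot(inherits(analyte, "ion_image"), inherits(standard, "ion_image"),
            standard_conc > 0)
  if (!identical(dim(analyte$values), dim(standard$values))) {
    abort("analyte and standard images differ in shape")
  }
  ok <- analyte$mask & standard$mask & standard$values > 0
  v <- ifelse(ok, analyte$values / standard$values * standard_conc, NA_real_)
  ion_image(matrix(v, nrow = nrow(analyte$values)), analyte$pixel_size,
            mask = ok, units = "uM")
}

#' Tissue mask from a reference channel
#'
#' A pixel belongs to tissue iff the reference intensity is at or above the
#' threshold (inclusive boundary); invalid reference pixels are off-tissue.
#' The canonical reference is the common MS3 product ion at m/z 333.2 with
#' threshold 30.
#'
#' @param reference An `ion_image`.
#' @param threshold Intensity threshold (default 30).
#' @return A logical matrix (`TRUE` = tissue).
#' @export
tissue_mask <- function(reference, threshold = 30) {
  stopifnot(inherits(reference, "ion_image"))
  m <- reference$mask & !is.na(reference$values) & reference$values >= threshold
  m[is.na(m)] <- FALSE
  m
}

#' Per-channel signal-to-noise inclusion filter
#'
#' The per-channel noise level is a robust location-plus-scale estimate
#' (median plus MAD, by default) over off-tissue pixels; a pixel's channel
#' is included iff `intensity / noise > min_snr` (strict, "above" the
#' cutoff). At least 20 valid off-tissue pixels are required to estimate
#' the noise.
#'
#' @param images Named list of `ion_image`s (channel images).
#' @param tissue Logical tissue matrix from [tissue_mask()].
#' @param min_snr S/N cutoff (default 5).
#' @param noise_fun Function of the off-tissue intensity vector returning a
#'   positive noise level; swap for a different noise model.
#' @return A named list of logical inclusion matrices, one per channel.
#' @export
snr_filter <- function(images, tissue, min_snr = 5,
                       noise_fun = function(x) median(x) + mad(x)) {
  stopifnot(is.list(images), is.logical(tissue))
  purrr::map(images, function(img) {
    stopifnot(inherits(img, "ion_image"))
    off <- img$values[!tissue & img$mask]
    if (length(off) < 20L) {
      abort("need at least 20 valid off-tissue pixels to estimate noise")
    }
    noise <- noise_fun(off)
    if (!is.finite(noise)) {
      abort("noise estimate is not finite; supply a different noise_fun")
    }
    # a zero noise floor (e.g. an all-zero channel) must not let zero-signal
    # pixels through as 0/0; any truly positive signal then has infinite S/N
    noise <- max(noise, .Machine$double.eps)
    inc <- img$mask & !is.na(img$values) & (img$values / noise > min_snr)
    inc[is.na(inc)] <- FALSE
    inc
  })
}

#' Predict per-pixel isomer fractions
#'
#' Builds the diagnostic-channel triplet of every retained pixel and
#' predicts the isomer composition with the calibration model. A pixel is
#' retained only if it passes the tissue mask and, in every channel, the
#' S/N inclusion filter; a pixel failing any filter (or with an
#' out-of-range raw prediction) is invalid in all three output images.
#' Valid fractions sum to exactly 100 per pixel.
#'
#' The calibration is only transferable between runs acquired under the
#' same CID settings, so the model's settings tag is compared with
#' `settings`; a mismatch is an error unless `override = TRUE` (which
#' proceeds with a warning).
#'
#' @param model A fitted [fit_isomer_model()].
#' @param images Named list of channel `ion_image`s including `i331`,
#'   `i333`, `i341` (e.g. from [assemble_grid()]).
#' @param tissue Logical tissue matrix ([tissue_mask()]); `NULL` retains
#'   all pixels.
#' @param inclusion Named list of logical matrices ([snr_filter()]); `NULL`
#'   skips S/N filtering.
#' @param settings Settings tag of the imaging run.
#' @param override Proceed (with a warning) on a settings mismatch.
#' @return Named list of three percent-unit `ion_image`s: `pge2`, `pgd2`,
#'   `d12pgd2`.
#' @export
predict_image <- function(model, images, tissue = NULL, inclusion = NULL,
                          settings = "default", override = FALSE) {
  stopifnot(inherits(model, "isomer_model"),
            all(c("i331", "i333", "i341") %in% names(images)))
  if (!identical(model$training_meta$settings, settings)) {
    msg <- sprintf(
      "model trained under settings '%s' but data tagged '%s'; predictions are only valid when CID settings match",
      model$training_meta$settings, settings)
    if (override) warn(msg) else abort(paste0(msg, " (use override = TRUE to proceed)"))
  }
  i331 <- images$i331; i333 <- images$i333; i341 <- images$i341
  dm <- dim(i331$values)
  ok <- i331$mask & i333$mask & i341$mask
  if (!is.null(tissue)) ok <- ok & tissue
  if (!is.null(inclusion)) {
    for (inc in inclusion[c("i331", "i333", "i341")]) ok <- ok & inc
  }
  tot <- i331$values + i333$values + i341$values
  ok <- ok & !is.na(tot) & tot > 0
  trip <- tibble::tibble(i331 = i331$values[ok], i333 = i333$values[ok],
                         i341 = i341$values[ok])
  out_v <- replicate(3, matrix(NA_real_, dm[1], dm[2]), simplify = FALSE)
  out_m <- matrix(FALSE, dm[1], dm[2])
  if (nrow(trip)) {
    pred <- predict(model, trip)
    out_v[[1]][ok] <- pred$pge2
    out_v[[2]][ok] <- pred$pgd2
    out_v[[3]][ok] <- pred$d12pgd2
    out_m[ok] <- pred$valid
  }
  ps <- i331$pixel_size
  stats::setNames(
    lapply(out_v, function(v) ion_image(v, ps, mask = out_m, units = "%")),
    c("pge2", "pgd2", "d12pgd2")
  )
}

#' Region-of-interest composition statistics
#'
#' Mean and standard deviation of each isomer fraction over the valid
#' pixels of a region; the SD is over pixels, so it reflects pixel-to-pixel
#' (largely biological) variability on top of the model's prediction error.
#'
#' @param fraction_images Named list of percent `ion_image`s
#'   (from [predict_image()]).
#' @param roi Logical matrix selecting the region; `NULL` = whole grid.
#' @return A tibble with `isomer`, `mean`, `sd`, `n_pixels`.
#' @export
roi_stats <- function(fraction_images, roi = NULL) {
  stopifnot(is.list(fraction_images), length(fraction_images) >= 1)
  first <- fraction_images[[1]]
  roi <- roi %||% matrix(TRUE, nrow(first$values), ncol(first$values))
  purrr::map_dfr(names(fraction_images), function(nm) {
    img <- fraction_images[[nm]]
    sel <- roi & img$mask
    if (!any(sel)) abort("ROI contains no valid pixels")
    v <- img$values[sel]
    tibble::tibble(isomer = nm, mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0,
                   n_pixels = length(v))
  })
}
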