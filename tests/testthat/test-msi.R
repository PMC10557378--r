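test_that("line-scan geometry reproduces the 31 x 100 um pixel", {
  geom <- grid_geometry(stage_speed = 0.02, cycle_s = 1.55, line_step = 100)
  expect_equal(unname(pixel_size(geom)), c(31, 100))
  # a rate in Hz is converted as 1/Hz and must be flagged explicitly
  expect_equal(grid_geometry(0.02, duty_cycle_hz = 2, line_step = 50)$cycle_period,
               0.5)
  expect_error(grid_geometry(0.02, cycle_s = 1.55, duty_cycle_hz = 1.55),
               "exactly one")
  expect_error(grid_geometry(0.02), "exactly one")
  expect_error(grid_geometry(-1, cycle_s = 1), "stage_speed")
})

test_that("grid assembly indexes pixels by MS3 cycle with nearest-in-time SIM", {
  geom <- grid_geometry(0.02, cycle_s = 1.55, line_step = 100)
  # single line of n MS3 scans -> 1 x n grid
  n <- 5
  line <- mass_spectra(
    ms_level = rep(3L, n), scan_time = (seq_len(n) - 1) * 1.55,
    mz = rep(list(pg_channels()$target_mz), n),
    intensity = lapply(seq_len(n), function(i) c(i, 10 * i, 100 * i)),
    precursor_chain = rep(list(c(459.13, 441.12)), n)
  )
  img <- assemble_grid(list(line), geom)
  expect_equal(dim(img$i331$values), c(1L, n))
  expect_equal(img$i331$values[1, ], as.numeric(1:5))
  expect_equal(img$i333$pixel_size, c(31, 100))
  # unequal line lengths: shorter lines padded with invalid pixels
  img2 <- assemble_grid(list(line, line[1:3, ]), geom)
  expect_equal(dim(img2$i341$values), c(2L, n))
  expect_false(any(img2$i341$mask[2, 4:5]))
  expect_error(assemble_grid(list(line[0, ]), geom), "no matching MS3")
})

test_that("internal-standard quantitation is linear and scale-invariant", {
  ps <- c(31, 100)
  an <- ion_image(matrix(c(0, 50, 100, 200), 2), ps)
  st <- ion_image(matrix(100, 2, 2), ps)
  q <- quantify_channel(an, st, standard_conc = 0.5)
  expect_equal(q$units, "uM")
  # ratio 1 gives the standard concentration; 0 gives 0; doubling doubles
  expect_equal(quantify_channel(st, st, 0.5)$values, matrix(0.5, 2, 2))
  expect_equal(q$values[1, 1], 0)
  an2 <- ion_image(2 * an$values, ps)
  expect_equal(quantify_channel(an2, st, 0.5)$values, 2 * q$values)
  # joint rescaling of analyte and standard leaves concentrations unchanged
  sc <- 7.3
  expect_equal(quantify_channel(ion_image(sc * an$values, ps),
                                ion_image(sc * st$values, ps), 0.5)$values,
               q$values)
  # zero standard intensity invalidates the pixel
  st0 <- ion_image(matrix(c(100, 0, 100, 100), 2), ps)
  q0 <- quantify_channel(an, st0, 0.5)
  expect_false(q0$mask[2, 1])
  expect_true(is.na(q0$values[2, 1]))
  expect_error(quantify_channel(an, ion_image(matrix(1, 3, 3), ps), 0.5),
               "shape")
})

test_that("tissue mask uses an inclusive intensity threshold", {
  ps <- c(31, 100)
  expect_false(any(tissue_mask(ion_image(matrix(29, 4, 4), ps), 30)))
  expect_true(all(tissue_mask(ion_image(matrix(30, 4, 4), ps), 30)))
  v <- matrix(c(29, 30, NA, 45), 2)
  m <- tissue_mask(ion_image(v, ps), 30)
  expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))
  # phantom round trip: mask recovers the tissue region
  ph <- make_msi_phantom(phantom_layout(n_lines = 8, n_pixels = 12),
                         noise = noise_model(0, 0))
  img <- assemble_grid(ph$lines, ph$geom)
  expect_equal(tissue_mask(img$i333, 30), ph$truth$region != "off_tissue")
})

test_that("S/N filter includes only channels strictly above the cutoff", {
  ps <- c(31, 100)
  # off-tissue pixels at a constant 10 pin the noise level (median + MAD) at 10
  v <- matrix(10, 5, 10)
  tissue <- matrix(FALSE, 5, 10)
  tissue[2:4, 6:9] <- TRUE
  v[2, 6] <- 60   # S/N 6 -> included
  v[3, 6] <- 40   # S/N 4 -> excluded
  v[4, 6] <- 50   # S/N 5, cutoff is strict -> excluded
  inc <- snr_filter(list(x = ion_image(v, ps)), tissue)$x
  expect_true(inc[2, 6])
  expect_false(inc[3, 6])
  expect_false(inc[4, 6])
  # all-zero channel: everything excluded
  inc0 <- snr_filter(list(x = ion_image(matrix(0, 5, 10), ps)), tissue)$x
  expect_false(any(inc0))
  # too few off-tissue pixels to estimate noise
  expect_error(snr_filter(list(x = ion_image(matrix(1, 3, 3), ps)),
                          matrix(TRUE, 3, 3)), "off-tissue")
})

test_that("mask and S/N filters are idempotent and order-commutative", {
  ph <- make_msi_phantom(seed = 17)
  img <- assemble_grid(ph$lines, ph$geom)
  tm1 <- tissue_mask(img$i333)
  expect_identical(tm1, tissue_mask(img$i333)) # idempotent on the same image
  inc <- snr_filter(img, tm1)
  inc2 <- snr_filter(img, tm1)
  expect_identical(inc, inc2)
  # combined retention is an intersection, hence order does not matter
  both_a <- tm1 & inc$i331 & inc$i333 & inc$i341
  both_b <- inc$i341 & inc$i333 & inc$i331 & tm1
  expect_identical(both_a, both_b)
})

test_that("per-pixel prediction propagates filters and closes to 100", {
  fit <- std_model()
  ph <- make_msi_phantom(noise = noise_model(0.01, 1), seed = 19)
  img <- assemble_grid(ph$lines, ph$geom)
  tm <- tissue_mask(img$i333)
  inc <- snr_filter(img[c("i331", "i333", "i341")], tm)
  fr <- predict_image(fit, img, tm, inc)
  expect_named(fr, c("pge2", "pgd2", "d12pgd2"))
  # identical validity in all three images; off-tissue always invalid
  expect_identical(fr$pge2$mask, fr$pgd2$mask)
  expect_identical(fr$pge2$mask, fr$d12pgd2$mask)
  expect_false(any(fr$pge2$mask & !tm))
  # a pixel failing S/N in any channel is invalid in all three outputs
  failing <- tm & !(inc$i331 & inc$i333 & inc$i341)
  if (any(failing)) expect_false(any(fr$pge2$mask[failing]))
  ok <- fr$pge2$mask
  expect_gt(sum(ok), 0)
  expect_equal(fr$pge2$values[ok] + fr$pgd2$values[ok] + fr$d12pgd2$values[ok],
               rep(100, sum(ok)), tolerance = 1e-12)
  expect_true(all(is.na(fr$pge2$values[!ok])))
})

test_that("prediction refuses mismatched CID settings unless overridden", {
  fit <- fit_isomer_model(std_training_set(), settings = "cid30")
  ph <- make_msi_phantom(phantom_layout(n_lines = 8, n_pixels = 12), seed = 3)
  img <- assemble_grid(ph$lines, ph$geom)
  expect_error(predict_image(fit, img, settings = "cid35"), "settings")
  expect_warning(
    fr <- predict_image(fit, img, settings = "cid35", override = TRUE),
    "settings"
  )
  expect_named(fr, c("pge2", "pgd2", "d12pgd2"))
})

test_that("ROI statistics are consistent with whole-grid statistics", {
  ps <- c(31, 100)
  u <- ion_image(matrix(42, 6, 6), ps, units = "%")
  st <- roi_stats(list(pge2 = u))
  expect_equal(st$mean, 42)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pixels, 36)
  # whole-grid ROI equals direct grid statistics
  set.seed(4)
  v <- matrix(rnorm(36, 50, 5), 6)
  img <- ion_image(v, ps, units = "%")
  st2 <- roi_stats(list(x = img), matrix(TRUE, 6, 6))
  expect_equal(st2$mean, mean(v))
  expect_equal(st2$sd, sd(as.vector(v)))
  # ROI with no valid pixels errors
  m <- matrix(FALSE, 6, 6); m[1, 1] <- TRUE
  masked <- ion_image(v, ps, mask = !m & !is.na(v), units = "%")
  expect_error(roi_stats(list(x = masked), m), "no valid pixels")
})

test_that("ion images tidy and plot with physical coordinates", {
  img <- ion_image(matrix(1:6, 2), c(31, 100), units = "counts")
  tb <- tibble::as_tibble(img)
  expect_equal(nrow(tb), 6)
  expect_equal(sort(unique(tb$x_um)), c(0.5, 1.5, 2.5) * 31)
  expect_equal(sort(unique(tb$y_um)), c(0.5, 1.5) * 100)
  expect_s3_class(autoplot(img), "ggplot")
  pct <- ion_image(matrix(c(-5, 20, 120, NA), 2), c(31, 100), units = "%")
  expect_s3_class(autoplot(pct), "ggplot")
})
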