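test_that("bandpass filter equals the explicit double-sum DFT oracle", {
  set.seed(9)
  px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  out <- bandpass_filter(micrograph(px, 0.2, 8L))$pixels
  oracle <- dft_bandpass_oracle(px, 0.2, 1.2, 2.0)
  expect_lt(max(abs(out - oracle)), 1e-6)
})

test_that("constant images produce all-zero output (DC removed)", {
  out <- bandpass_filter(micrograph(matrix(180, 64, 64), 0.2, 8L))
  expect_true(all(out$pixels == 0))
})

test_that("in-band gratings pass and out-of-band gratings are suppressed", {
  g_in <- make_grating(1.6)                    # 8 px period, in band
  f_in <- bandpass_filter(g_in)
  expect_gte(max(f_in$pixels), 0.9 * 100)

  g_lo <- make_grating(4.0)                    # 20 px period, below band
  f_lo <- bandpass_filter(g_lo)
  expect_lt(max(f_lo$pixels), 1)

  g_hi <- make_grating(0.8)                    # 4 px period, above band
  f_hi <- bandpass_filter(g_hi)
  expect_lt(max(f_hi$pixels), 1)

  e <- function(f) mean(f$pixels^2)
  expect_gt(e(f_in) / max(e(f_lo), 1e-12), 100)
  expect_gt(e(f_in) / max(e(f_hi), 1e-12), 100)
})

test_that("Nyquist violations are rejected with the required pixel size", {
  img <- micrograph(matrix(0, 32, 32), pixel_size_um = 0.8, bit_depth = 8L)
  expect_error(bandpass_filter(img), "Nyquist")
})

test_that("mask thresholding is strict and matches the sinusoid fraction", {
  flat21 <- micrograph(matrix(21, 16, 16), 0.2, 8L)
  expect_equal(sum(make_mask(flat21, 21)$mask), 0)

  # grating with 9 px period (1.8 um): filtered signal is the pure
  # sinusoid, so the mask fraction approximates the closed-form arc
  # fraction where A sin > threshold
  g <- make_grating(1.8, n = 162)
  f <- bandpass_filter(g)
  frac <- mean(make_mask(f, 21)$mask)
  closed <- (pi - 2 * asin(21 / 100)) / (2 * pi)
  expect_lt(abs(frac - closed), 0.05)
})

test_that("z-line extraction recovers orientation, length and count", {
  m <- matrix(FALSE, 20, 20)
  m[10, 5:14] <- TRUE  # 1x10 horizontal run
  mask <- structure(list(mask = m, pixel_size_um = 0.2),
                    class = "sarcomere_mask")
  zl <- extract_zlines(mask, min_area_px = 3)
  expect_equal(nrow(zl), 1)
  expect_equal(zl$orientation_deg, 0)
  expect_equal(zl$length_um, 2.0)

  m2 <- m; m2[3, 2:6] <- TRUE  # second disjoint run
  mask2 <- structure(list(mask = m2, pixel_size_um = 0.2),
                     class = "sarcomere_mask")
  expect_equal(nrow(extract_zlines(mask2, 3)), 2)

  # area filter discards a 2 px component when min_area_px = 3
  m3 <- matrix(FALSE, 10, 10); m3[5, 5:6] <- TRUE
  mask3 <- structure(list(mask = m3, pixel_size_um = 0.2),
                     class = "sarcomere_mask")
  expect_equal(nrow(extract_zlines(mask3, 3)), 0)
  expect_equal(nrow(extract_zlines(mask3, 2)), 1)
})

test_that("components touching only diagonally are one 8-connected z-line", {
  m <- matrix(FALSE, 10, 10)
  m[cbind(3:6, 3:6)] <- TRUE  # pure diagonal
  mask <- structure(list(mask = m, pixel_size_um = 0.2),
                    class = "sarcomere_mask")
  zl <- extract_zlines(mask, min_area_px = 2)
  expect_equal(nrow(zl), 1)
  expect_equal(zl$orientation_deg, 45, tolerance = 1e-8)
})

fake_zlines <- function(rows, cols, ori) {
  data.frame(id = seq_along(rows), centroid_row = rows, centroid_col = cols,
             orientation_deg = ori, length_um = 1.5)
}

test_that("fibril assembly chains regularly spaced parallel z-lines", {
  # 5 vertical z-lines spaced 1.8 um along x (pixel size 0.2)
  zl <- fake_zlines(rows = rep(50, 5), cols = 10 + 9 * (0:4), ori = rep(90, 5))
  fb <- assemble_fibrils(zl, 0.2)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$n_zlines, 5)
  expect_equal(fb$length_um, 7.2, tolerance = 1e-8)
  expect_equal(fb$mean_spacing_um, 1.8, tolerance = 1e-8)
  expect_equal(fb$axis_orientation_deg, 0, tolerance = 1e-8)
})

test_that("widely spaced pairs form no fibril", {
  zl <- fake_zlines(rows = c(50, 50), cols = c(10, 35), ori = c(90, 90))
  expect_equal(nrow(assemble_fibrils(zl, 0.2)), 0)
})

test_that("two orthogonal chains give two fibrils 90 degrees apart", {
  zl <- rbind(
    fake_zlines(rows = rep(20, 4), cols = 10 + 9 * (0:3), ori = rep(90, 4)),
    fake_zlines(rows = 40 + 9 * (0:3), cols = rep(60, 4), ori = rep(0, 4))
  )
  zl$id <- seq_len(nrow(zl))
  fb <- assemble_fibrils(zl, 0.2)
  expect_equal(nrow(fb), 2)
  expect_equal(ang_err(fb$axis_orientation_deg[1], fb$axis_orientation_deg[2]),
               90, tolerance = 1e-8)
})

test_that("perpendicularity gate rejects laterally offset parallel z-lines", {
  # parallel vertical z-lines displaced along their own axis, not the normal
  zl <- fake_zlines(rows = c(20, 29), cols = c(10, 10), ori = c(90, 90))
  zl <- rbind(zl, fake_zlines(38, 10, 90))
  zl$id <- 1:3
  expect_equal(nrow(assemble_fibrils(zl, 0.2)), 0)
})

test_that("structure metrics follow their definitions", {
  m <- matrix(FALSE, 4, 4); m[1:2, 1] <- TRUE
  mask <- structure(list(mask = m, pixel_size_um = 0.2),
                    class = "sarcomere_mask")
  zl <- fake_zlines(rows = seq(10, 100, 10), cols = rep(10, 10),
                    ori = rep(0, 10))
  fb <- data.frame(id = 1:2, n_zlines = 3,
                   axis_orientation_deg = c(30, 30),
                   length_um = c(3.6, 3.6), mean_spacing_um = 1.8)
  fb$zline_ids <- list(1:3, 4:6)
  sm <- structure_metrics(mask, zl, fb)
  expect_equal(sm$sarcomere_presence_px, 2)
  expect_equal(sm$fibril_number, 2)
  expect_equal(sm$assigned_zline_fraction, 0.6)
  expect_equal(sm$orientation_index, 1.0)  # parallel fibrils
  expect_equal(sm$sarcomere_width_um, 1.5)

  # no z-lines: undefined metrics are NA, assigned fraction 0
  zl0 <- zl[0, ]; fb0 <- fb[0, ]; fb0$zline_ids <- list()
  sm0 <- structure_metrics(mask, zl0, fb0)
  expect_true(is.na(sm0$sarcomere_width_um))
  expect_equal(sm0$assigned_zline_fraction, 0)
})

test_that("baseline normalization is the identity at t0 and linear", {
  ser <- data.frame(timepoint = c(0, 5),
                    sarcomere_presence_px = c(600, 300),
                    fibril_number = c(4, 4))
  out <- normalize_to_baseline(ser, 0)
  expect_equal(out$sarcomere_presence_px, c(100, 50))
  expect_equal(out$fibril_number, c(100, 100))

  ser$fibril_number[1] <- 0
  expect_warning(out2 <- normalize_to_baseline(ser, 0), "zero or missing")
  expect_true(all(is.na(out2$fibril_number)))
})

test_that("metrics are invariant under 90-degree image rotation", {
  sc <- make_sarcomere_image(n_fibrils = 3, spacing_um = 1.8,
                             noise_sigma = 0, seed = 12)
  a <- analyze_sarcomere_image(sc$image)
  rot <- micrograph(t(sc$image$pixels)[, nrow(sc$image$pixels):1],
                    sc$image$pixel_size_um, 8L)
  b <- analyze_sarcomere_image(rot)
  expect_equal(b$metrics$fibril_number, a$metrics$fibril_number)
  expect_equal(b$metrics$sarcomere_presence_px,
               a$metrics$sarcomere_presence_px, tolerance = 0.02)
  expect_equal(b$metrics$sarcomere_width_um, a$metrics$sarcomere_width_um,
               tolerance = 0.05)
  expect_equal(sort(b$fibrils$mean_spacing_um),
               sort(a$fibrils$mean_spacing_um), tolerance = 0.03)
  expect_equal(b$metrics$orientation_index, a$metrics$orientation_index,
               tolerance = 0.02)
})

test_that("noise-free synthetic scenes are recovered within tolerance", {
  sc <- make_sarcomere_image(n_fibrils = 3, spacing_um = c(1.4, 1.6, 1.8),
                             orientation_deg = c(10, 70, 130),
                             noise_sigma = 0, seed = 4)
  an <- analyze_sarcomere_image(sc$image)
  expect_equal(an$metrics$fibril_number, 3)
  idx <- match_fibrils(an$fibrils, an$zlines, sc$truth$fibrils,
                       sc$truth$zlines)
  expect_lt(max(abs(an$fibrils$mean_spacing_um[idx] -
                    sc$truth$fibrils$mean_spacing_um)), 0.05)
  expect_lt(max(ang_err(an$fibrils$axis_orientation_deg[idx],
                        sc$truth$fibrils$axis_orientation_deg)), 2)
  expect_lt(abs(an$metrics$sarcomere_width_um - 1.5), 0.2)
  expect_equal(an$metrics$assigned_zline_fraction,
               sc$truth$metrics$assigned_zline_fraction, tolerance = 0.05)
})
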