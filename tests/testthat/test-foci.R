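draw_disk <- function(px, r0, c0, rad, value) {
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    if ((r - r0)^2 + (c - c0)^2 <= rad^2) px[r, c] <- value
  }
  px
}

test_that("disjoint bright disks segment into that many nuclei", {
  px <- matrix(5, 128, 128)
  px <- draw_disk(px, 30, 30, 12, 200)
  px <- draw_disk(px, 30, 90, 12, 200)
  px <- draw_disk(px, 95, 60, 12, 200)
  seg <- segment_nuclei(micrograph(px, 1), min_area_px = 80)
  expect_equal(nrow(seg$nuclei), 3)
})

test_that("touching disks are split by the watershed", {
  px <- matrix(5, 128, 128)
  px <- draw_disk(px, 60, 50, 14, 200)
  px <- draw_disk(px, 60, 70, 14, 200)  # centers 20 px apart, radius 14
  seg <- segment_nuclei(micrograph(px, 1), min_area_px = 80)
  expect_equal(nrow(seg$nuclei), 2)
})

test_that("area bounds exclude small objects; empty images warn", {
  px <- matrix(5, 64, 64)
  px <- draw_disk(px, 32, 32, 3, 200)  # ~28 px, below min area
  expect_warning(seg <- segment_nuclei(micrograph(px, 1), min_area_px = 80),
                 "area bounds")
  expect_equal(nrow(seg$nuclei), 0)
  expect_warning(segment_nuclei(micrograph(matrix(5, 64, 64), 1)),
                 "no foreground|constant")
})

test_that("foci are counted per nucleus and outside spots are ignored", {
  dapi <- matrix(5, 128, 128)
  dapi <- draw_disk(dapi, 64, 64, 20, 200)
  seg <- segment_nuclei(micrograph(dapi, 1), min_area_px = 80)
  expect_equal(nrow(seg$nuclei), 1)

  gh <- matrix(3, 128, 128)
  spots <- rbind(c(56, 56), c(56, 72), c(72, 56), c(72, 72))  # inside
  spots_out <- rbind(c(20, 20))                               # outside
  gauss <- function(px, r0, c0) {
    for (r in (r0 - 8):(r0 + 8)) for (c in (c0 - 8):(c0 + 8)) {
      px[r, c] <- px[r, c] + 150 * exp(-((r - r0)^2 + (c - c0)^2) / (2 * 4))
    }
    px
  }
  for (i in seq_len(nrow(spots))) gh <- gauss(gh, spots[i, 1], spots[i, 2])
  for (i in seq_len(nrow(spots_out))) {
    gh <- gauss(gh, spots_out[i, 1], spots_out[i, 2])
  }
  rec <- count_foci(micrograph(pmin(gh, 255), 1), seg,
                    spot_sigma_px = 2, min_spot_intensity = 50)
  expect_equal(rec$focus_count, 4)

  # uniform nucleus: no foci
  rec0 <- count_foci(micrograph(matrix(3, 128, 128), 1), seg)
  expect_equal(rec0$focus_count, 0)
})

test_that("summaries follow the percent-positive definition", {
  rec <- data.frame(nucleus_id = 1:4, focus_count = c(0, 0, 2, 3))
  s <- summarize_foci(rec)
  expect_equal(s$n_nuclei, 4)
  expect_equal(s$percent_positive, 50)
  expect_equal(s$mean_dots_per_positive, 2.5)

  s0 <- summarize_foci(data.frame(focus_count = c(0, 0, 0)))
  expect_equal(s0$percent_positive, 0)
  expect_true(is.na(s0$mean_dots_per_positive))

  expect_error(summarize_foci(data.frame(focus_count = integer())),
               "no nuclei")

  # positivity threshold is configurable
  s2 <- summarize_foci(rec, positivity_min = 3)
  expect_equal(s2$percent_positive, 25)
})

test_that("counting is additive across disjoint fields", {
  a <- make_foci_scene(n_nuclei = 6, seed = 21)
  b <- make_foci_scene(n_nuclei = 8, seed = 22)
  score <- function(scene) {
    seg <- segment_nuclei(scene$dapi)
    count_foci(scene$foci_img, seg)
  }
  ra <- score(a); rb <- score(b)
  pooled <- summarize_foci(rbind(ra, rb))
  expect_equal(pooled$n_nuclei, nrow(ra) + nrow(rb))
  expect_equal(pooled$n_nuclei * pooled$percent_positive / 100,
               sum(ra$focus_count >= 1) + sum(rb$focus_count >= 1))
})

test_that("noise-free synthetic scenes are counted exactly", {
  for (s in c(5, 17)) {
    scene <- make_foci_scene(n_nuclei = 10, seed = s)
    seg <- segment_nuclei(scene$dapi)
    expect_equal(nrow(seg$nuclei), 10)
    rec <- count_foci(scene$foci_img, seg)
    ids <- mapply(function(r, c) seg$labels[round(r), round(c)],
                  scene$truth$centroid_row, scene$truth$centroid_col)
    expect_true(all(ids > 0))
    expect_equal(rec$focus_count[match(ids, rec$nucleus_id)],
                 scene$truth$focus_count)
  }
})
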