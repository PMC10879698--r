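# Seeded generators producing ground-truthed inputs for every pipeline
# stage. Each call uses one local RNG stream (with_seed) and returns the
# exact truth of the noise-free render alongside the noisy image/trace.

# distance from pixel centers to a segment, anti-aliased splat:
# contribution A * max(0, 1 - d_px), combined by max with existing values
splat_segment <- function(img, p1, p2, amplitude) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(min(p1[1], p2[1]) - 2))
  r1 <- min(nr, ceiling(max(p1[1], p2[1]) + 2))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - 2))
  c1 <- min(nc, ceiling(max(p1[2], p2[2]) + 2))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  d <- p2 - p1
  len2 <- sum(d^2)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  if (len2 == 0) {
    dist <- sqrt((R - p1[1])^2 + (C - p1[2])^2)
    patch <- amplitude * pmax(0, 1 - dist)
  } else {
    # flat end caps: lateral tent falloff, sharp cut at the segment tips,
    # so the above-background footprint spans exactly the segment length
    tt <- ((R - p1[1]) * d[1] + (C - p1[2]) * d[2]) / len2
    lat <- sqrt(pmax((R - p1[1])^2 + (C - p1[2])^2 - tt^2 * len2, 0))
    patch <- amplitude * pmax(0, 1 - lat)
    patch[tt < 0 | tt > 1] <- 0
  }
  img[rr, cc] <- pmax(img[rr, cc], patch)
  img
}

#' Render a synthetic striated-cardiomyocyte image with known truth
#'
#' Each myofibril is a chain of anti-aliased bright segments (z-lines)
#' perpendicular to the fibril axis, spaced `spacing_um` apart, emulating
#' an alpha-actinin fluorescence image. Degradation deletes individual
#' z-lines with the given probability; positional jitter and additive
#' Gaussian noise emulate imaging imperfections. The exact ground truth
#' (surviving z-lines, surviving fibril chains of at least
#' `min_zlines_per_fibril` consecutive z-lines, and the derived structure
#' metrics) is computed from the noise-free geometry.
#'
#' @param n_fibrils number of fibrils (default 4).
#' @param spacing_um sarcomere spacing, recycled per fibril (default 1.8).
#' @param zline_length_um z-line length (default 1.5).
#' @param zlines_per_fibril z-lines per chain (default 8).
#' @param orientation_deg fibril axis orientations, recycled; `NULL` =
#'   random per fibril.
#' @param degradation per-z-line deletion probability in `[0, 1]`.
#' @param jitter_sigma_um isotropic positional jitter SD (default 0).
#' @param noise_sigma additive Gaussian noise SD, 8-bit units (default 0).
#' @param background_level flat background intensity (default 10).
#' @param amplitude z-line peak intensity (default 200).
#' @param image_size_px square image side (default 320).
#' @param pixel_size_um pixel size (default 0.2).
#' @param min_gap_um minimum gap between fibril bounding circles
#'   (default 4).
#' @param min_zlines_per_fibril chain-survival threshold used for the
#'   truth fibrils (default 3, matching the analysis default).
#' @param threshold_8bit threshold used for the truth presence count
#'   (default 21).
#' @param seed RNG seed.
#' @return A list: `image` (8-bit `micrograph`), `truth` (lists `zlines`,
#'   `fibrils`, `metrics`), and the generating parameters.
#' @export
make_sarcomere_image <- function(n_fibrils = 4, spacing_um = 1.8,
                                 zline_length_um = 1.5,
                                 zlines_per_fibril = 8,
                                 orientation_deg = NULL,
                                 degradation = 0, jitter_sigma_um = 0,
                                 noise_sigma = 0, background_level = 10,
                                 amplitude = 200, image_size_px = 320,
                                 pixel_size_um = 0.2, min_gap_um = 4,
                                 min_zlines_per_fibril = 3,
                                 threshold_8bit = 21, seed = 1) {
  stopifnot(degradation >= 0, degradation <= 1, jitter_sigma_um >= 0,
            noise_sigma >= 0, n_fibrils >= 1, zlines_per_fibril >= 2)
  spacing_um <- rep_len(spacing_um, n_fibrils)
  d <- pixel_size_um
  size_um <- image_size_px * d
  with_seed(seed, {
    ori <- if (is.null(orientation_deg)) {
      stats::runif(n_fibrils, 0, 180)
    } else rep_len(orientation_deg, n_fibrils) %% 180
    # place fibril bounding circles with pairwise gaps
    chain_len <- (zlines_per_fibril - 1) * spacing_um
    rad <- sqrt((chain_len / 2)^2 + (zline_length_um / 2)^2) + 1
    centers <- matrix(NA_real_, n_fibrils, 2)  # (x, y) in um
    margin <- rad + 1
    for (f in seq_len(n_fibrils)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        cand <- stats::runif(2, margin[min(f, length(margin))],
                             size_um - rad[f] - 1)
        ok <- TRUE
        if (f > 1) {
          dd <- sqrt((centers[seq_len(f - 1), 1] - cand[1])^2 +
                     (centers[seq_len(f - 1), 2] - cand[2])^2)
          ok <- all(dd >= rad[f] + rad[seq_len(f - 1)] + min_gap_um)
        }
        if (ok) { centers[f, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place ", n_fibrils, " fibrils with ", min_gap_um,
             " um gaps in a ", round(size_um, 1), " um field after 100 tries")
      }
    }

    img <- matrix(0, image_size_px, image_size_px)
    zl_rows <- list()
    fib_rows <- list()
    zl_id <- 0L
    for (f in seq_len(n_fibrils)) {
      th <- ori[f] * pi / 180
      u <- c(cos(th), sin(th))              # chain direction (x, y)
      w <- c(-sin(th), cos(th))             # z-line direction
      offs <- (seq_len(zlines_per_fibril) - (zlines_per_fibril + 1) / 2)
      keep <- stats::runif(zlines_per_fibril) >= degradation
      jit <- matrix(stats::rnorm(2 * zlines_per_fibril, 0, jitter_sigma_um),
                    ncol = 2)
      pos_x <- centers[f, 1] + offs * spacing_um[f] * u[1] + jit[, 1]
      pos_y <- centers[f, 2] + offs * spacing_um[f] * u[2] + jit[, 2]
      ids <- integer(zlines_per_fibril)
      for (k in seq_len(zlines_per_fibril)) {
        if (!keep[k]) next
        zl_id <- zl_id + 1L
        ids[k] <- zl_id
        hx <- (zline_length_um / 2) * w[1]
        hy <- (zline_length_um / 2) * w[2]
        # px coords: row = y/d, col = x/d (+0.5 so um-origin = pixel corner)
        p1 <- c((pos_y[k] - hy) / d + 0.5, (pos_x[k] - hx) / d + 0.5)
        p2 <- c((pos_y[k] + hy) / d + 0.5, (pos_x[k] + hx) / d + 0.5)
        img <- splat_segment(img, p1, p2, amplitude)
        zl_rows[[zl_id]] <- data.frame(
          id = zl_id, fibril = f,
          centroid_row = pos_y[k] / d + 0.5, centroid_col = pos_x[k] / d + 0.5,
          orientation_deg = (ori[f] + 90) %% 180,
          length_um = zline_length_um
        )
      }
      # surviving consecutive runs of length >= min_zlines_per_fibril
      r <- rle(keep)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$lengths)) {
        if (!r$values[j] || r$lengths[j] < min_zlines_per_fibril) next
        nz <- r$lengths[j]
        fib_rows[[length(fib_rows) + 1]] <- data.frame(
          source_fibril = f, n_zlines = nz,
          axis_orientation_deg = ori[f],
          length_um = (nz - 1) * spacing_um[f],
          mean_spacing_um = spacing_um[f],
          first_zline = ids[starts[j]], last_zline = ids[ends[j]]
        )
      }
    }
    zlines <- if (length(zl_rows)) do.call(rbind, zl_rows) else
      data.frame(id = integer(), fibril = integer(), centroid_row = numeric(),
                 centroid_col = numeric(), orientation_deg = numeric(),
                 length_um = numeric())
    fibrils <- if (length(fib_rows)) do.call(rbind, fib_rows) else
      data.frame(source_fibril = integer(), n_zlines = integer(),
                 axis_orientation_deg = numeric(), length_um = numeric(),
                 mean_spacing_um = numeric(), first_zline = integer(),
                 last_zline = integer())

    clean <- clip01_8bit(background_level + img)
    noisy <- clean
    if (noise_sigma > 0) {
      noisy <- clip01_8bit(noisy + stats::rnorm(length(noisy), 0, noise_sigma))
    }
    noisy <- floor(noisy + 0.5)

    n_assigned <- sum(fibrils$n_zlines)
    truth_metrics <- data.frame(
      sarcomere_presence_px = sum(clean > threshold_8bit),
      fibril_number = nrow(fibrils),
      orientation_index = if (nrow(fibrils)) {
        circular_order_parameter(fibrils$axis_orientation_deg,
                                 fibrils$length_um)
      } else NA_real_,
      sarcomere_width_um = if (nrow(zlines)) zline_length_um else NA_real_,
      fibril_length_um = if (nrow(fibrils)) mean(fibrils$length_um)
        else NA_real_,
      assigned_zline_fraction = if (nrow(zlines)) n_assigned / nrow(zlines)
        else 0
    )
    list(
      image = micrograph(noisy, pixel_size_um, 8L, channel = "actinin"),
      truth = list(zlines = zlines, fibrils = fibrils,
                   metrics = truth_metrics),
      params = list(n_fibrils = n_fibrils, spacing_um = spacing_um,
                    zline_length_um = zline_length_um,
                    zlines_per_fibril = zlines_per_fibril,
                    orientation_deg = ori, degradation = degradation,
                    seed = seed)
    )
  })
}

#' Render a synthetic viability coverage field with known truth
#'
#' Places random bright disks on a dark background until the covered
#' fraction is within 0.005 of the requested truth, then records the
#' exactly realized pixel fraction.
#'
#' @param coverage_truth target coverage in `[0, 0.9]`.
#' @param image_size_px square image side (default 256).
#' @param noise_sigma additive Gaussian noise SD (default 0).
#' @param background,foreground intensities (defaults 10, 200).
#' @param radius_range_px disk radius range (default 5-15).
#' @param seed RNG seed.
#' @return A list: `image` (8-bit `micrograph`), `truth` (realized
#'   fraction), `mask` (the exact boolean coverage).
#' @export
make_coverage_field <- function(coverage_truth, image_size_px = 256,
                                noise_sigma = 0, background = 10,
                                foreground = 200,
                                radius_range_px = c(5, 15), seed = 1) {
  if (coverage_truth < 0 || coverage_truth > 0.9) {
    stop("coverage_truth must lie in [0, 0.9]")
  }
  n <- image_size_px
  with_seed(seed, {
    mask <- matrix(FALSE, n, n)
    xg <- matrix(seq_len(n), n, n, byrow = TRUE)
    yg <- matrix(seq_len(n), n, n)
    it <- 0
    while (mean(mask) < coverage_truth - 0.005) {
      it <- it + 1
      if (it > 20000) stop("coverage ", coverage_truth, " unreachable")
      ctr <- stats::runif(2, 1, n)
      r <- stats::runif(1, radius_range_px[1], radius_range_px[2])
      repeat {
        disk <- (yg - ctr[1])^2 + (xg - ctr[2])^2 <= r^2
        newmask <- mask | disk
        if (mean(newmask) <= coverage_truth + 0.005 || r <= 1) break
        r <- r - 1
      }
      if (mean(newmask) <= coverage_truth + 0.005) mask <- newmask
    }
    img <- background + (foreground - background) * mask
    if (noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sigma)
    }
    img <- floor(clip01_8bit(img) + 0.5)
    list(image = micrograph(img, 1, 8L, channel = "calcein"),
         truth = mean(mask), mask = mask)
  })
}

#' Generate a synthetic calcium/force transient trace with known truth
#'
#' Sums stereotyped beats (linear rise over `time_to_peak_s`, exponential
#' decay with time constant `decay_tau_s`) at regular intervals
#' `1/frequency_hz` on a linearly drifting baseline, plus Gaussian noise.
#' Beats must not overlap: `frequency_hz * (time_to_peak_s +
#' 3 * decay_tau_s) < 1`. The truth metrics come from the noise-free
#' closed form; the time-to-decay truth is the 90%-decay point,
#' `decay_tau_s * ln(10)` after the peak.
#'
#' @param fps frames per second (default 70).
#' @param duration_s trace duration (default 10).
#' @param frequency_hz beat rate (default 1).
#' @param time_to_peak_s rise time (default 0.15).
#' @param decay_tau_s decay time constant (default 0.2).
#' @param amplitude beat amplitude, AU (default 100).
#' @param baseline diastolic baseline, AU (default 20).
#' @param baseline_drift_per_s linear drift, AU/s (default 0).
#' @param noise_sigma additive Gaussian noise SD, AU (default 0).
#' @param seed RNG seed.
#' @return A list: `trace` ([cm_trace()]) and `truth` (a one-row
#'   data.frame of the noise-free kinetics).
#' @export
make_trace <- function(fps = 70, duration_s = 10, frequency_hz = 1,
                       time_to_peak_s = 0.15, decay_tau_s = 0.2,
                       amplitude = 100, baseline = 20,
                       baseline_drift_per_s = 0, noise_sigma = 0, seed = 1) {
  if (frequency_hz * (time_to_peak_s + 3 * decay_tau_s) >= 1) {
    stop("beats overlap: need frequency_hz * (time_to_peak_s + ",
         "3 * decay_tau_s) < 1")
  }
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  sig <- baseline + baseline_drift_per_s * t
  onsets <- seq(0, duration_s - 1e-9, by = 1 / frequency_hz)
  kernel <- function(dt) {
    ifelse(dt < 0, 0,
           ifelse(dt <= time_to_peak_s, amplitude * dt / time_to_peak_s,
                  amplitude * exp(-(dt - time_to_peak_s) / decay_tau_s)))
  }
  clean <- sig
  for (o in onsets) clean <- clean + kernel(t - o)
  values <- clean
  if (noise_sigma > 0) {
    values <- with_seed(seed, values + stats::rnorm(n, 0, noise_sigma))
  }
  n_complete <- sum(onsets + time_to_peak_s < duration_s)
  truth <- data.frame(
    frequency_hz = if (amplitude > 0) frequency_hz else NA_real_,
    time_to_peak_s = time_to_peak_s,
    time_to_decay_s = decay_tau_s * log(10),
    amplitude_au = amplitude,
    baseline_load_au = min(clean),
    contraction_velocity = amplitude / time_to_peak_s,
    relaxation_velocity = amplitude / decay_tau_s,
    n_events = if (amplitude > 0) n_complete else 0L
  )
  list(trace = cm_trace(values, fps), truth = truth, clean = clean)
}

#' Generate a synthetic DAPI + gamma-H2AX image pair with known truth
#'
#' Non-overlapping elliptical nuclei (rejection-sampled) in the DAPI
#' channel; per-nucleus focus counts drawn from a Poisson distribution;
#' foci rendered as Gaussian spots at uniform positions inside the
#' nucleus with pairwise separation at least `4 * spot_sigma_px`.
#'
#' @param n_nuclei number of nuclei (default 20).
#' @param nucleus_radius_px semi-axis range (default 16-22 px).
#' @param foci_lambda Poisson mean focus count per nucleus (default 3).
#' @param spot_sigma_px Gaussian spot scale (default 2).
#' @param spot_amplitude spot peak intensity (default 150).
#' @param noise_sigma additive Gaussian noise SD on both channels
#'   (default 0).
#' @param dapi_level nucleus fill intensity (default 180).
#' @param background background intensity, both channels (default 10).
#' @param image_size_px square side; `NULL` = sized automatically from
#'   the nucleus count.
#' @param seed RNG seed.
#' @return A list: `dapi` and `foci_img` (8-bit `micrograph`s) and
#'   `truth`, a data.frame with per-nucleus `centroid_row`,
#'   `centroid_col`, radii and `focus_count`.
#' @export
make_foci_scene <- function(n_nuclei = 20, nucleus_radius_px = c(16, 22),
                            foci_lambda = 3, spot_sigma_px = 2,
                            spot_amplitude = 150, noise_sigma = 0,
                            dapi_level = 180, background = 10,
                            image_size_px = NULL, seed = 1) {
  rmax <- max(nucleus_radius_px)
  if (is.null(image_size_px)) {
    # ~20% packing density keeps rejection sampling fast and reliable
    image_size_px <- max(192, ceiling(sqrt(n_nuclei * pi * (rmax + 4)^2 / 0.2)))
  }
  n <- image_size_px
  with_seed(seed, {
    centers <- matrix(NA_real_, n_nuclei, 2)
    radii <- matrix(NA_real_, n_nuclei, 2)  # semi-axes a, b
    angs <- stats::runif(n_nuclei, 0, pi)
    for (i in seq_len(n_nuclei)) {
      ab <- sort(stats::runif(2, nucleus_radius_px[1], nucleus_radius_px[2]),
                 decreasing = TRUE)
      placed <- FALSE
      for (try in seq_len(1000)) {
        ctr <- stats::runif(2, rmax + 3, n - rmax - 3)
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt((centers[seq_len(i - 1), 1] - ctr[1])^2 +
                     (centers[seq_len(i - 1), 2] - ctr[2])^2)
          ok <- all(dd >= ab[1] + radii[seq_len(i - 1), 1] + 4)
        }
        if (ok) { centers[i, ] <- ctr; radii[i, ] <- ab; placed <- TRUE; break }
      }
      if (!placed) stop("could not place ", n_nuclei,
                        " non-overlapping nuclei; enlarge image_size_px")
    }

    dapi <- matrix(background, n, n)
    fim <- matrix(background, n, n)
    counts <- integer(n_nuclei)
    for (i in seq_len(n_nuclei)) {
      a <- radii[i, 1]; b <- radii[i, 2]; phi <- angs[i]
      r0 <- max(1, floor(centers[i, 1] - a - 1))
      r1 <- min(n, ceiling(centers[i, 1] + a + 1))
      c0 <- max(1, floor(centers[i, 2] - a - 1))
      c1 <- min(n, ceiling(centers[i, 2] + a + 1))
      rr <- r0:r1; cc <- c0:c1
      R <- matrix(rr, length(rr), length(cc)) - centers[i, 1]
      C <- matrix(cc, length(rr), length(cc), byrow = TRUE) - centers[i, 2]
      X <- R * cos(phi) + C * sin(phi)
      Y <- -R * sin(phi) + C * cos(phi)
      inside <- (X / a)^2 + (Y / b)^2 <= 1
      blk <- dapi[rr, cc]
      blk[inside] <- dapi_level
      dapi[rr, cc] <- blk

      cnt <- stats::rpois(1, foci_lambda)
      if (cnt > 0) {
        # uniform in the ellipse shrunk by a 2*sigma margin, pairwise
        # separation >= 4*sigma; restart the whole draw when a sequential
        # placement dead-ends
        pts <- matrix(NA_real_, cnt, 2)
        got <- 0
        for (restart in seq_len(50)) {
          got <- 0
          for (try in seq_len(200 * cnt)) {
            if (got == cnt) break
            u <- sqrt(stats::runif(1)); v <- stats::runif(1, 0, 2 * pi)
            ex <- u * max(a - 2 * spot_sigma_px, 1) * cos(v)
            ey <- u * max(b - 2 * spot_sigma_px, 1) * sin(v)
            pr <- centers[i, 1] + ex * cos(phi) - ey * sin(phi)
            pc <- centers[i, 2] + ex * sin(phi) + ey * cos(phi)
            if (got > 0) {
              dd <- sqrt((pts[seq_len(got), 1] - pr)^2 +
                         (pts[seq_len(got), 2] - pc)^2)
              if (any(dd < 4 * spot_sigma_px)) next
            }
            got <- got + 1
            pts[got, ] <- c(pr, pc)
          }
          if (got == cnt) break
        }
        if (got < cnt) stop("could not place ", cnt, " foci with 4-sigma ",
                            "separation in nucleus ", i)
        counts[i] <- cnt
        hw <- ceiling(4 * spot_sigma_px)
        for (s in seq_len(cnt)) {
          sr0 <- max(1, floor(pts[s, 1] - hw))
          sr1 <- min(n, ceiling(pts[s, 1] + hw))
          sc0 <- max(1, floor(pts[s, 2] - hw))
          sc1 <- min(n, ceiling(pts[s, 2] + hw))
          srr <- sr0:sr1; scc <- sc0:sc1
          SR <- matrix(srr, length(srr), length(scc)) - pts[s, 1]
          SC <- matrix(scc, length(srr), length(scc), byrow = TRUE) - pts[s, 2]
          fim[srr, scc] <- fim[srr, scc] +
            spot_amplitude * exp(-(SR^2 + SC^2) / (2 * spot_sigma_px^2))
        }
      }
    }
    if (noise_sigma > 0) {
      dapi <- dapi + stats::rnorm(length(dapi), 0, noise_sigma)
      fim <- fim + stats::rnorm(length(fim), 0, noise_sigma)
    }
    dapi <- floor(clip01_8bit(dapi) + 0.5)
    fim <- floor(clip01_8bit(fim) + 0.5)
    list(
      dapi = micrograph(dapi, 1, 8L, channel = "dapi"),
      foci_img = micrograph(fim, 1, 8L, channel = "gh2ax"),
      truth = data.frame(nucleus_id = seq_len(n_nuclei),
                         centroid_row = centers[, 1],
                         centroid_col = centers[, 2],
                         semi_major_px = radii[, 1],
                         semi_minor_px = radii[, 2],
                         focus_count = counts)
    )
  })
}

#' Sample a noisy saturating uptake series with known truth
#'
#' Model values `P (1 - exp(-k t))` (offset `v0 = 0`) plus Gaussian noise,
#' clipped to `[0, 1]` for fraction-type data. The default time ladder
#' mirrors a 13-point flow-cytometry design from 0 to 300 minutes.
#'
#' @param P plateau (default 0.9).
#' @param k uptake rate per minute (default 0.02).
#' @param times measurement times in minutes, strictly increasing.
#' @param noise_sigma Gaussian noise SD (default 0).
#' @param value_kind `"fraction"` (clipped to `[0,1]`) or `"mfi"`.
#' @param seed RNG seed.
#' @return A list: `series` ([uptake_series()]) and `truth`
#'   (`list(P =, k =)`).
#' @export
make_uptake_samples <- function(P = 0.9, k = 0.02,
                                times = c(0, 10, 20, 30, 60, 90, 120, 150,
                                          180, 210, 240, 270, 300),
                                noise_sigma = 0,
                                value_kind = c("fraction", "mfi"), seed = 1) {
  value_kind <- match.arg(value_kind)
  v <- uptake_curve(times, P, k)
  if (noise_sigma > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sigma))
  }
  if (value_kind == "fraction") v <- pmin(pmax(v, 0), 1) else v <- pmax(v, 0)
  list(series = uptake_series(times, v, value_kind),
       truth = list(P = P, k = k))
}
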