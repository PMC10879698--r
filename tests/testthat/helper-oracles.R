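# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths they check.

# O(N^4) double-sum DFT bandpass: forward sum, annulus mask, inverse sum
dft_bandpass_oracle <- function(px, pixel_size_um, period_min_um,
                                period_max_um) {
  n <- nrow(px); m <- ncol(px)
  W <- function(size) exp(-2i * pi * outer(0:(size - 1), 0:(size - 1)) / size)
  Fm <- matrix(0i, n, m)
  for (u in 0:(n - 1)) {
    for (v in 0:(m - 1)) {
      ph <- outer(exp(-2i * pi * u * (0:(n - 1)) / n),
                  exp(-2i * pi * v * (0:(m - 1)) / m))
      Fm[u + 1, v + 1] <- sum(px * ph)
    }
  }
  f1 <- 0:(n - 1); f1[f1 > n / 2] <- f1[f1 > n / 2] - n
  f2 <- 0:(m - 1); f2[f2 > m / 2] <- f2[f2 > m / 2] - m
  fu <- f1 / (n * pixel_size_um)
  fv <- f2 / (m * pixel_size_um)
  rho2 <- outer(fu^2, fv^2, "+")
  keep <- rho2 >= (1 / period_max_um)^2 & rho2 <= (1 / period_min_um)^2
  Fm[!keep] <- 0i
  out <- matrix(0, n, m)
  for (x in 0:(n - 1)) {
    for (y in 0:(m - 1)) {
      ph <- outer(exp(2i * pi * x * (0:(n - 1)) / n),
                  exp(2i * pi * y * (0:(m - 1)) / m))
      out[x + 1, y + 1] <- Re(sum(Fm * ph)) / (n * m)
    }
  }
  pmin(pmax(out, 0), 255)
}

# brute-force grayscale opening (erosion then dilation) with a disc
opening_oracle <- function(px, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(px); nc <- ncol(px)
  er <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    er[r, c] <- min(px[cbind(rr[ok], cc[ok])])
  }
  di <- matrix(-Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    di[r, c] <- max(er[cbind(rr[ok], cc[ok])])
  }
  di
}

# brute-force transient segmentation on a noise-free single-pulse trace
single_pulse_oracle <- function(v, onset_frac = 0.1, decay_frac = 0.9) {
  p <- which.max(v)
  base <- min(v)
  amp <- v[p] - base
  on_level <- base + onset_frac * amp
  end_level <- base + (1 - decay_frac) * amp
  onset <- max(which(v[seq_len(p - 1)] <= on_level))
  after <- (p + 1):length(v)
  endi <- min(after[v[after] <= end_level])
  c(onset = onset, peak = p, end = endi)
}

# horizontal sinusoidal grating micrograph; periods that divide the window
# avoid spectral leakage
make_grating <- function(period_um, pixel_size_um = 0.2, n = 160,
                         amplitude = 100, offset = 128, phase = 0) {
  x <- outer(rep(1, n), ((0:(n - 1)) + phase) * pixel_size_um)
  px <- pmin(pmax(offset + amplitude * sin(2 * pi * x / period_um), 0), 255)
  micrograph(px, pixel_size_um, 8L)
}

# match measured fibrils to truth fibrils by mean member-centroid position
match_fibrils <- function(measured, zlines, truth_fibrils, truth_zlines) {
  mc <- t(vapply(measured$zline_ids, function(ids) {
    zz <- zlines[match(ids, zlines$id), ]
    c(mean(zz$centroid_row), mean(zz$centroid_col))
  }, numeric(2)))
  tc <- t(vapply(seq_len(nrow(truth_fibrils)), function(i) {
    sel <- truth_zlines$fibril == truth_fibrils$source_fibril[i] &
      truth_zlines$id >= truth_fibrils$first_zline[i] &
      truth_zlines$id <= truth_fibrils$last_zline[i]
    c(mean(truth_zlines$centroid_row[sel]),
      mean(truth_zlines$centroid_col[sel]))
  }, numeric(2)))
  vapply(seq_len(nrow(tc)), function(i) {
    which.min((mc[, 1] - tc[i, 1])^2 + (mc[, 2] - tc[i, 2])^2)
  }, integer(1))
}

ang_err <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
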