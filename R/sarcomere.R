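#' Bandpass parameters for sarcomere striation detection
#'
#' The striation period of an organized sarcomere lattice equals the
#' sarcomere length, 1.2-2 um in these cardiomyocytes; the bandpass keeps
#' only spatial frequencies in `[1/period_max, 1/period_min]` cycles/um.
#' After filtering, a fixed hard threshold of 21 intensity units (8-bit
#' scale) defines the organized-sarcomere mask.
#'
#' @param period_min_um minimum sarcomere length, um (default 1.2).
#' @param period_max_um maximum sarcomere length, um (default 2.0).
#' @param threshold_8bit mask threshold on the filtered 8-bit image
#'   (default 21; strict `>`).
#' @return An object of class `bandpass_params`.
#' @export
bandpass_params <- function(period_min_um = 1.2, period_max_um = 2.0,
                            threshold_8bit = 21) {
  if (!(period_min_um > 0 && period_min_um < period_max_um)) {
    stop("need 0 < period_min_um < period_max_um")
  }
  if (threshold_8bit < 0 || threshold_8bit > 255) {
    stop("threshold_8bit must be in [0, 255]")
  }
  structure(list(period_min_um = period_min_um,
                 period_max_um = period_max_um,
                 threshold_8bit = threshold_8bit),
            class = "bandpass_params")
}

fft_freqs <- function(n, step_um) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * step_um)
}

#' Isotropic FFT bandpass restricted to the sarcomere period band
#'
#' Forward 2D FFT, zeroing of every coefficient whose radial spatial
#' frequency (cycles/um, from the integer frequency indices and the pixel
#' size) lies outside `[1/period_max_um, 1/period_min_um]` - including the
#' DC term - then inverse FFT, real part, clipped to `[0, 255]`. The
#' annulus is orientation-agnostic, so striations at any angle are kept.
#' The output is deliberately not re-stretched: the downstream threshold
#' of 21 is a fixed absolute intensity.
#'
#' @param img an 8-bit, preprocessed `micrograph`.
#' @param params a [bandpass_params()] object.
#' @return The filtered `micrograph` (8-bit scale, values in `[0, 255]`).
#' @export
bandpass_filter <- function(img, params = bandpass_params()) {
  stopifnot(inherits(img, "micrograph"), inherits(params, "bandpass_params"))
  if (img$bit_depth != 8L) stop("bandpass_filter expects an 8-bit micrograph")
  d <- img$pixel_size_um
  if (params$period_min_um < 2 * d) {
    stop(sprintf(paste0("Nyquist violation: period_min_um = %.3g um needs ",
                        "pixel size <= %.3g um (have %.3g um)"),
                 params$period_min_um, params$period_min_um / 2, d))
  }
  px <- img$pixels
  fr <- fft_freqs(nrow(px), d)
  fc <- fft_freqs(ncol(px), d)
  rho2 <- outer(fr^2, fc^2, "+")
  lo <- 1 / params$period_max_um
  hi <- 1 / params$period_min_um
  keep <- rho2 >= lo^2 & rho2 <= hi^2  # DC (rho = 0) always excluded
  fk <- stats::fft(px)
  fk[!keep] <- 0i
  out <- Re(stats::fft(fk, inverse = TRUE)) / length(px)
  out <- pmin(pmax(out, 0), 255)
  micrograph(out, d, 8L, img$channel, img$timepoint)
}

#' Threshold a filtered image into the organized-sarcomere mask
#'
#' @param filtered output of [bandpass_filter()].
#' @param threshold_8bit intensity threshold; pixels strictly above it are
#'   mask members (default 21).
#' @return An object of class `sarcomere_mask`: logical matrix `mask` plus
#'   the pixel size.
#' @export
make_mask <- function(filtered, threshold_8bit = 21) {
  stopifnot(inherits(filtered, "micrograph"))
  structure(list(mask = filtered$pixels > threshold_8bit,
                 threshold_8bit = threshold_8bit,
                 pixel_size_um = filtered$pixel_size_um),
            class = "sarcomere_mask")
}

#' @export
print.sarcomere_mask <- function(x, ...) {
  cat(sprintf("sarcomere_mask: %d x %d px, %d positive (%.2f%%), threshold %g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_8bit))
  invisible(x)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# touching diagonally with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dr <- shift[1]; dc <- shift[2]
    rs <- seq_len(nr - 1)
    cs <- if (dc == 1) seq_len(nc - 1) else 2:nc
    a <- lab[rs, cs, drop = FALSE]
    b <- lab[rs + dr, cs + dc, drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

principal_axis <- function(rows, cols) {
  # orientation (deg, [0,180), measured from the +column axis toward the
  # +row axis) and extent (px) of a pixel cloud along its principal axis
  x <- cols - mean(cols)
  y <- rows - mean(rows)
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)  # radians, major axis
  u <- c(cos(theta), sin(theta))
  proj <- x * u[1] + y * u[2]
  list(orientation_deg = (theta * 180 / pi) %% 180,
       extent_px = diff(range(proj)) + 1)
}

#' Extract z-line primitives from a sarcomere mask
#'
#' 8-connected components of the mask with area at least `min_area_px`
#' become z-lines: short bright alpha-actinin bands. Orientation is the
#' principal axis of the component's pixel coordinates (degrees in
#' `[0, 180)` from the image x-axis); length is the extent along that axis
#' times the pixel size.
#'
#' @param mask a `sarcomere_mask`.
#' @param min_area_px minimum component area in pixels (default 4).
#' @return A data.frame with one row per z-line: `id`, `area_px`,
#'   `centroid_row`, `centroid_col` (pixel units), `orientation_deg`,
#'   `length_um`, plus a `coords` list-column of pixel index matrices.
#' @export
extract_zlines <- function(mask, min_area_px = 4) {
  stopifnot(inherits(mask, "sarcomere_mask"))
  empty <- data.frame(id = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      orientation_deg = numeric(), length_um = numeric())
  empty$coords <- list()
  if (!any(mask$mask)) return(empty)
  lab <- label_components_8(mask$mask)
  idx <- which(lab > 0)
  comp <- split(idx, lab[idx])
  nr <- nrow(lab)
  keep <- vapply(comp, length, integer(1)) >= min_area_px
  comp <- comp[keep]
  if (!length(comp)) return(empty)
  rows <- lapply(comp, function(ii) ((ii - 1) %% nr) + 1)
  cols <- lapply(comp, function(ii) ((ii - 1) %/% nr) + 1)
  pa <- Map(principal_axis, rows, cols)
  out <- data.frame(
    id = seq_along(comp),
    area_px = vapply(comp, length, integer(1)),
    centroid_row = vapply(rows, mean, numeric(1)),
    centroid_col = vapply(cols, mean, numeric(1)),
    orientation_deg = vapply(pa, `[[`, numeric(1), "orientation_deg"),
    length_um = vapply(pa, `[[`, numeric(1), "extent_px") * mask$pixel_size_um
  )
  out$coords <- Map(function(r, c) cbind(row = r, col = c), rows, cols)
  rownames(out) <- NULL
  out
}

angdiff180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Assemble z-lines into myofibrils
#'
#' Two z-lines are linkable when their centroid distance falls inside the
#' sarcomere period band (widened by `spacing_tol`), their orientations
#' differ by at most `angle_tol_deg`, and the centroid-link direction is
#' within `angle_tol_deg` of the perpendicular to both z-lines. Myofibrils
#' are maximal simple chains of linkable z-lines, found by a greedy
#' longest-chain decomposition with deterministic lowest-id tie-breaking;
#' each z-line joins at most one fibril, and chains shorter than
#' `min_zlines_per_fibril` are dropped.
#'
#' @param zlines data.frame from [extract_zlines()].
#' @param pixel_size_um pixel size in micrometres.
#' @param params a [bandpass_params()] (supplies the period band).
#' @param angle_tol_deg orientation/perpendicularity tolerance (default 20).
#' @param spacing_tol relative widening of the period band (default 0.15).
#' @param min_zlines_per_fibril minimum chain length (default 3, i.e. at
#'   least two sarcomeres in series).
#' @return A data.frame with one row per fibril: `id`, `n_zlines`,
#'   `axis_orientation_deg`, `length_um`, `mean_spacing_um`, and a
#'   `zline_ids` list-column (ordered along the chain).
#' @export
assemble_fibrils <- function(zlines, pixel_size_um,
                             params = bandpass_params(),
                             angle_tol_deg = 20, spacing_tol = 0.15,
                             min_zlines_per_fibril = 3) {
  empty <- data.frame(id = integer(), n_zlines = integer(),
                      axis_orientation_deg = numeric(),
                      length_um = numeric(), mean_spacing_um = numeric())
  empty$zline_ids <- list()
  n <- nrow(zlines)
  if (n < min_zlines_per_fibril) return(empty)

  cy <- zlines$centroid_row * pixel_size_um
  cx <- zlines$centroid_col * pixel_size_um
  ori <- zlines$orientation_deg
  dmin <- params$period_min_um * (1 - spacing_tol)
  dmax <- params$period_max_um * (1 + spacing_tol)

  # adjacency lists
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    dx <- cx[(i + 1):n] - cx[i]
    dy <- cy[(i + 1):n] - cy[i]
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d >= dmin & d <= dmax)
    for (jj in cand) {
      j <- i + jj
      if (angdiff180(ori[i], ori[j]) > angle_tol_deg) next
      link <- (atan2(dy[jj], dx[jj]) * 180 / pi) %% 180
      if (angdiff180(link, ori[i] + 90) > angle_tol_deg) next
      if (angdiff180(link, ori[j] + 90) > angle_tol_deg) next
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }

  assigned <- rep(FALSE, n)
  # grow a chain greedily from s over unassigned z-lines; at each step take
  # the neighbor best aligned with the current chain direction, lowest id
  # on ties
  grow <- function(s) {
    chain <- s
    in_chain <- rep(FALSE, n); in_chain[s] <- TRUE
    extend_end <- function(chain, at_front) {
      repeat {
        e <- if (at_front) chain[1] else chain[length(chain)]
        prev <- if (length(chain) >= 2) {
          if (at_front) chain[2] else chain[length(chain) - 1]
        } else NA_integer_
        nb <- adj[[e]]
        nb <- nb[!assigned[nb] & !in_chain[nb]]
        if (!length(nb)) return(chain)
        if (is.na(prev)) {
          pick <- min(nb)
        } else {
          dir0 <- (atan2(cy[e] - cy[prev], cx[e] - cx[prev]) * 180 / pi) %% 180
          dirs <- (atan2(cy[nb] - cy[e], cx[nb] - cx[e]) * 180 / pi) %% 180
          dev <- angdiff180(dirs, dir0)
          ok <- dev <= angle_tol_deg
          if (!any(ok)) return(chain)
          nb <- nb[ok]; dev <- dev[ok]
          pick <- nb[order(dev, nb)][1]
        }
        in_chain[pick] <<- TRUE
        chain <- if (at_front) c(pick, chain) else c(chain, pick)
      }
    }
    chain <- extend_end(chain, at_front = FALSE)
    chain <- extend_end(chain, at_front = TRUE)
    chain
  }

  fibrils <- list()
  repeat {
    todo <- which(!assigned)
    if (!length(todo)) break
    best <- NULL
    for (s in todo) {
      ch <- grow(s)
      if (is.null(best) || length(ch) > length(best) ||
          (length(ch) == length(best) && min(ch) < min(best))) best <- ch
    }
    if (length(best) < min_zlines_per_fibril) break
    assigned[best] <- TRUE
    fibrils[[length(fibrils) + 1]] <- best
  }

  if (!length(fibrils)) return(empty)
  rows <- lapply(seq_along(fibrils), function(k) {
    ch <- fibrils[[k]]
    dx <- diff(cx[ch]); dy <- diff(cy[ch])
    steps <- sqrt(dx^2 + dy^2)
    data.frame(
      id = k, n_zlines = length(ch),
      axis_orientation_deg =
        (atan2(cy[ch[length(ch)]] - cy[ch[1]],
               cx[ch[length(ch)]] - cx[ch[1]]) * 180 / pi) %% 180,
      length_um = sum(steps),
      mean_spacing_um = mean(steps)
    )
  })
  out <- do.call(rbind, rows)
  out$zline_ids <- lapply(fibrils, function(ch) zlines$id[ch])
  out
}

circular_order_parameter <- function(theta_deg, w) {
  # length-weighted resultant on the doubled angle (180-degree period)
  if (!length(theta_deg)) return(NA_real_)
  th <- theta_deg * pi / 90  # 2 * theta in radians
  Mod(sum(w * exp(1i * th))) / sum(w)
}

#' The six per-image myofibril structure metrics
#'
#' Computes, from one image's mask, z-lines and fibrils:
#' `sarcomere_presence_px` (mask pixel count), `fibril_number`,
#' `orientation_index` (1 minus the length-weighted circular variance of
#' fibril axis orientations on a 180-degree period; 1 = all fibrils
#' parallel), `sarcomere_width_um` (mean z-line length),
#' `fibril_length_um` (mean fibril length) and `assigned_zline_fraction`
#' (z-lines belonging to any fibril over all z-lines). With no z-lines the
#' width/length/orientation are `NA` and the assigned fraction 0.
#'
#' @param mask a `sarcomere_mask`.
#' @param zlines data.frame from [extract_zlines()].
#' @param fibrils data.frame from [assemble_fibrils()].
#' @return A one-row data.frame of class `structure_metrics`.
#' @export
structure_metrics <- function(mask, zlines, fibrils) {
  n_z <- nrow(zlines)
  n_f <- nrow(fibrils)
  assigned <- if (n_f) length(unique(unlist(fibrils$zline_ids))) else 0L
  out <- data.frame(
    sarcomere_presence_px = sum(mask$mask),
    fibril_number = n_f,
    orientation_index = if (n_f) {
      circular_order_parameter(fibrils$axis_orientation_deg,
                               fibrils$length_um)
    } else NA_real_,
    sarcomere_width_um = if (n_z) mean(zlines$length_um) else NA_real_,
    fibril_length_um = if (n_f) mean(fibrils$length_um) else NA_real_,
    assigned_zline_fraction = if (n_z) assigned / n_z else 0
  )
  class(out) <- c("structure_metrics", "data.frame")
  out
}

#' Run the full myofibril-integrity pipeline on one image
#'
#' Bandpass filter, fixed-threshold mask, z-line extraction, fibril
#' assembly, structure metrics. Preprocessing ([subtract_background()],
#' [enhance_contrast()], [to_8bit()]) is applied first when
#' `preprocess = TRUE`.
#'
#' @param img a `micrograph` (alpha-actinin channel).
#' @param params a [bandpass_params()].
#' @param min_area_px minimum z-line area (default 4).
#' @param angle_tol_deg,spacing_tol,min_zlines_per_fibril see
#'   [assemble_fibrils()].
#' @param preprocess apply background subtraction + contrast enhancement
#'   (default FALSE: synthetic and pre-cleaned images skip it).
#' @param background_radius_px,saturated_fraction preprocessing parameters.
#' @return A list with `mask`, `zlines`, `fibrils`, `metrics`, `filtered`.
#' @export
analyze_sarcomere_image <- function(img, params = bandpass_params(),
                                    min_area_px = 4, angle_tol_deg = 20,
                                    spacing_tol = 0.15,
                                    min_zlines_per_fibril = 3,
                                    preprocess = FALSE,
                                    background_radius_px = 50,
                                    saturated_fraction = 0.003) {
  if (preprocess) {
    img <- subtract_background(img, background_radius_px)
    img <- enhance_contrast(img, saturated_fraction)
  }
  img <- to_8bit(img)
  filtered <- bandpass_filter(img, params)
  mask <- make_mask(filtered, params$threshold_8bit)
  zl <- extract_zlines(mask, min_area_px)
  fb <- assemble_fibrils(zl, mask$pixel_size_um, params,
                         angle_tol_deg, spacing_tol, min_zlines_per_fibril)
  list(mask = mask, zlines = zl, fibrils = fb,
       metrics = structure_metrics(mask, zl, fb), filtered = filtered)
}

#' Normalize a metric series to its baseline timepoint
#'
#' Expresses every numeric metric column at every timepoint as a
#' percentage of its value at the baseline timepoint (normalization to
#' timepoint 0 of the experiment). Metrics with a zero or missing baseline
#' are reported `NA` with a warning.
#'
#' @param series data.frame with a `timepoint` column and numeric metric
#'   columns (e.g. rbind-ed [structure_metrics()] rows).
#' @param baseline_timepoint the timepoint to normalize to (default the
#'   smallest present).
#' @return A data.frame of the same shape with metrics as percentages.
#' @export
normalize_to_baseline <- function(series,
                                  baseline_timepoint = min(series$timepoint)) {
  stopifnot("timepoint" %in% names(series))
  b <- series[series$timepoint == baseline_timepoint, , drop = FALSE]
  if (nrow(b) != 1) stop("need exactly one baseline row at timepoint ",
                         baseline_timepoint)
  out <- series
  for (col in setdiff(names(series), "timepoint")) {
    if (!is.numeric(series[[col]])) next
    denom <- b[[col]]
    if (is.na(denom) || denom == 0) {
      warning("zero or missing baseline for '", col, "': reported as NA")
      out[[col]] <- NA_real_
    } else {
      out[[col]] <- 100 * series[[col]] / denom
    }
  }
  out
}
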