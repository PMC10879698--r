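#' Construct a uniformly sampled transient trace
#'
#' Holds a calcium-fluorescence or force time series sampled at a fixed
#' frame rate (70 fps for the calcium videos; force traces from paced
#' engineered heart tissues use the same container).
#'
#' @param values numeric vector of intensities (AU) or forces (uN).
#' @param fps frames per second (> 0; default 70).
#' @param t0_offset_s acquisition start time in seconds (default 0).
#' @return An object of class `cm_trace`.
#' @export
cm_trace <- function(values, fps = 70, t0_offset_s = 0) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  structure(list(values = values, fps = fps, t0_offset_s = t0_offset_s),
            class = "cm_trace")
}

#' @export
print.cm_trace <- function(x, ...) {
  cat(sprintf("cm_trace: %d frames at %g fps (%.2f s), range [%.3g, %.3g]\n",
              length(x$values), x$fps, length(x$values) / x$fps,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.cm_trace <- function(x) length(x$values)

#' Collapse a video stack to a whole-frame mean-intensity trace
#'
#' @param frames list of `micrograph` frames with identical dimensions
#'   (or a 3D array, rows x cols x frames).
#' @param fps frames per second of the acquisition.
#' @return A [cm_trace()] whose i-th value is the mean pixel intensity of
#'   frame i.
#' @export
extract_trace <- function(frames, fps = 70) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    vals <- apply(frames, 3, mean)
  } else {
    if (length(frames) < 2) stop("need at least 2 frames")
    d <- dim(frames[[1]]$pixels)
    vals <- vapply(frames, function(f) {
      if (!identical(dim(f$pixels), d)) stop("frame dimensions differ")
      mean(f$pixels)
    }, numeric(1))
  }
  cm_trace(vals, fps)
}

#' Diastolic baseline load of a trace
#'
#' The frame at the lowest intensity corresponds to complete relaxation;
#' its (already frame-averaged) value is the baseline calcium load.
#'
#' @param trace a [cm_trace()].
#' @return `min(trace$values)`.
#' @export
baseline_load <- function(trace) {
  stopifnot(inherits(trace, "cm_trace"))
  min(trace$values)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  # first index of any plateau that is a strict local maximum
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  idx
}

peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    lm <- v[p]
    i <- p; left <- v[p]
    while (i > 1 && v[i - 1] <= lm) { i <- i - 1; left <- min(left, v[i]) }
    if (i > 1) {  # ran into higher ground; descend to the col
      left <- min(v[i:p])
    } else left <- min(v[1:p])
    i <- p; right <- v[p]
    n <- length(v)
    while (i < n && v[i + 1] <= lm) { i <- i + 1; right <- min(right, v[i]) }
    if (i < n) right <- min(v[p:i]) else right <- min(v[p:n])
    lm - max(left, right)
  }, numeric(1))
}

#' Segment a trace into transient events
#'
#' Peaks with prominence at least `min_prominence_frac` of the trace's
#' global range are taken as beats. For each beat the local baseline is
#' the trace minimum over the inter-peak segments on either side; the
#' onset is the last frame before the peak at or below
#' `baseline + onset_frac * amplitude`, and the end is the first frame
#' after the peak at or below `baseline + (1 - decay_frac) * amplitude`
#' (i.e. after `decay_frac` of the amplitude has decayed). Events that
#' would overlap are separated at the inter-peak minimum.
#'
#' @param trace a [cm_trace()].
#' @param onset_frac fractional rise defining the onset (default 0.1).
#' @param decay_frac fractional decay defining the end (default 0.9).
#' @param min_prominence_frac peak prominence floor as a fraction of the
#'   global range (default 0.2).
#' @return A data.frame with columns `onset_idx`, `peak_idx`, `end_idx`
#'   (1-based frame indices), `amplitude`, `baseline`; zero rows when the
#'   trace has no qualifying peaks.
#' @export
detect_transients <- function(trace, onset_frac = 0.1, decay_frac = 0.9,
                              min_prominence_frac = 0.2) {
  stopifnot(inherits(trace, "cm_trace"))
  v <- trace$values
  n <- length(v)
  empty <- data.frame(onset_idx = integer(), peak_idx = integer(),
                      end_idx = integer(), amplitude = numeric(),
                      baseline = numeric())
  rng <- max(v) - min(v)
  if (rng <= 0) return(empty)
  peaks <- local_maxima(v)
  if (!length(peaks)) return(empty)
  prom <- peak_prominence(v, peaks)
  peaks <- peaks[prom >= min_prominence_frac * rng]
  if (!length(peaks)) return(empty)

  k <- length(peaks)
  seg_left <- c(1, vapply(seq_len(k - 1), function(i) {
    peaks[i] + which.min(v[peaks[i]:peaks[i + 1]]) - 1L
  }, numeric(1)))
  seg_right <- c(seg_left[-1], n)

  rows <- lapply(seq_len(k), function(i) {
    p <- peaks[i]
    base <- min(v[seg_left[i]:seg_right[i]])
    amp <- v[p] - base
    if (amp <= 0) return(NULL)
    on_level <- base + onset_frac * amp
    end_level <- base + (1 - decay_frac) * amp
    pre <- seg_left[i]:(p - 1)
    below <- pre[v[pre] <= on_level]
    onset <- if (length(below)) max(below) else seg_left[i]
    post <- if (p < seg_right[i]) (p + 1):seg_right[i] else integer()
    hit <- post[v[post] <= end_level]
    endi <- if (length(hit)) min(hit) else seg_right[i]
    data.frame(onset_idx = onset, peak_idx = p, end_idx = endi,
               amplitude = amp, baseline = base)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Beat kinetics of a transient trace
#'
#' Frequency is `(n_peaks - 1)` over the time between the first and last
#' peak (peak-interval based, robust for short recordings); time-to-peak
#' (onset to peak) and time-to-decay (peak to 90%-decay) are averaged
#' across events; contraction/relaxation velocities are the per-event
#' maximum positive / negative first difference times fps, averaged across
#' events; the amplitude is the mean per-event amplitude (for force traces
#' this is the force of contraction); the baseline load is the global
#' trace minimum.
#'
#' @param trace a [cm_trace()].
#' @param ... passed on to [detect_transients()].
#' @return A one-row data.frame of class `kinetics_metrics` with columns
#'   `frequency_hz`, `time_to_peak_s`, `time_to_decay_s`, `amplitude_au`,
#'   `baseline_load_au`, `contraction_velocity`, `relaxation_velocity`,
#'   `n_events`. Frequency is `NA` with fewer than 2 events; all beat
#'   metrics are `NA` with 0 events.
#' @export
kinetics <- function(trace, ...) {
  stopifnot(inherits(trace, "cm_trace"))
  ev <- detect_transients(trace, ...)
  fps <- trace$fps
  v <- trace$values
  ne <- nrow(ev)
  if (ne == 0) {
    out <- data.frame(frequency_hz = NA_real_, time_to_peak_s = NA_real_,
                      time_to_decay_s = NA_real_, amplitude_au = NA_real_,
                      baseline_load_au = baseline_load(trace),
                      contraction_velocity = NA_real_,
                      relaxation_velocity = NA_real_, n_events = 0L)
    class(out) <- c("kinetics_metrics", "data.frame")
    return(out)
  }
  freq <- if (ne >= 2) {
    (ne - 1) / ((ev$peak_idx[ne] - ev$peak_idx[1]) / fps)
  } else NA_real_
  vel <- vapply(seq_len(ne), function(i) {
    up <- diff(v[ev$onset_idx[i]:ev$peak_idx[i]])
    dn <- diff(v[ev$peak_idx[i]:ev$end_idx[i]])
    c(max(up) * fps, if (length(dn)) -min(dn) * fps else NA_real_)
  }, numeric(2))
  out <- data.frame(
    frequency_hz = freq,
    time_to_peak_s = mean(ev$peak_idx - ev$onset_idx) / fps,
    time_to_decay_s = mean(ev$end_idx - ev$peak_idx) / fps,
    amplitude_au = mean(ev$amplitude),
    baseline_load_au = baseline_load(trace),
    contraction_velocity = mean(vel[1, ]),
    relaxation_velocity = mean(vel[2, ], na.rm = TRUE),
    n_events = ne
  )
  class(out) <- c("kinetics_metrics", "data.frame")
  out
}

#' Normalize kinetics to timepoint 0 (and optionally to vehicle control)
#'
#' Each metric is expressed as a percentage of its value at timepoint 0;
#' when control metrics are supplied the percentage is further divided by
#' the control's percent-of-t0 (times 100), i.e. a drug and control that
#' drift identically read 100%.
#'
#' @param metrics_t,metrics_t0 one-row [kinetics()] data.frames for the
#'   treated sample at time t and at timepoint 0.
#' @param control_t,control_t0 optional matching rows for the vehicle
#'   control.
#' @return A one-row data.frame of percentages (metric columns only).
#' @export
normalize_kinetics <- function(metrics_t, metrics_t0,
                               control_t = NULL, control_t0 = NULL) {
  cols <- c("frequency_hz", "time_to_peak_s", "time_to_decay_s",
            "amplitude_au", "baseline_load_au", "contraction_velocity",
            "relaxation_velocity")
  pct <- function(num, den) {
    vapply(cols, function(cl) {
      d <- den[[cl]]
      if (is.null(d) || is.na(d) || d == 0) {
        warning("zero or missing baseline for '", cl, "'")
        NA_real_
      } else 100 * num[[cl]] / d
    }, numeric(1))
  }
  p <- pct(metrics_t, metrics_t0)
  if (!is.null(control_t)) {
    pc <- pct(control_t, control_t0)
    p <- 100 * p / pc
  }
  as.data.frame(as.list(p))
}
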