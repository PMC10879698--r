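#' Segment nuclei from a DAPI image
#'
#' Global Otsu threshold, distance-transform watershed to split touching
#' nuclei, then an area filter. DAPI fields are globally bimodal, so a
#' single global threshold is appropriate; nuclei merged in the binary
#' image are separated at the watershed of the distance map.
#'
#' @param dapi a `micrograph` (nuclear channel).
#' @param min_area_px,max_area_px area bounds for accepted nuclei
#'   (defaults 80 and `Inf`).
#' @return A list with `labels` (integer label matrix, 0 = background) and
#'   `nuclei`, a data.frame of `nucleus_id`, `area_px`, `centroid_row`,
#'   `centroid_col`. Empty (with a warning) when no foreground is found.
#' @export
segment_nuclei <- function(dapi, min_area_px = 80, max_area_px = Inf) {
  stopifnot(inherits(dapi, "micrograph"))
  x <- dapi$pixels / max_intensity(dapi)
  th <- EBImage::otsu(EBImage::Image(x))
  bin <- x > th
  empty <- list(labels = matrix(0L, nrow(x), ncol(x)),
                nuclei = data.frame(nucleus_id = integer(),
                                    area_px = integer(),
                                    centroid_row = numeric(),
                                    centroid_col = numeric()))
  if (!any(bin)) {
    warning("no foreground above the Otsu threshold")
    return(empty)
  }
  dm <- EBImage::distmap(bin)
  lab <- EBImage::imageData(EBImage::watershed(dm))
  sz <- tabulate(lab[lab > 0])
  good <- which(sz >= min_area_px & sz <= max_area_px)
  if (!length(good)) {
    warning("no nuclei within the area bounds")
    return(empty)
  }
  remap <- integer(length(sz))
  remap[good] <- seq_along(good)
  out <- array(0L, dim = dim(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  nr <- nrow(out)
  idx <- which(out > 0)
  comp <- split(idx, out[idx])
  nuclei <- data.frame(
    nucleus_id = as.integer(names(comp)),
    area_px = vapply(comp, length, integer(1)),
    centroid_row = vapply(comp, function(ii) mean(((ii - 1) %% nr) + 1),
                          numeric(1)),
    centroid_col = vapply(comp, function(ii) mean(((ii - 1) %/% nr) + 1),
                          numeric(1))
  )
  rownames(nuclei) <- NULL
  list(labels = out, nuclei = nuclei)
}

#' Count gamma-H2AX foci per nucleus
#'
#' White top-hat (disc radius `3 * spot_sigma_px`) isolates puncta from
#' diffuse nuclear background; local maxima of the top-hat image with
#' value at least `min_spot_intensity`, separated pairwise by at least
#' `2 * spot_sigma_px`, are counted as foci. Each focus is assigned to the
#' nucleus label under it; maxima outside any nucleus are discarded.
#'
#' @param foci_img a `micrograph` (gamma-H2AX channel) registered to the
#'   DAPI image.
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param spot_sigma_px Gaussian scale of a focus in pixels (default 2).
#' @param min_spot_intensity intensity floor on the top-hat image, native
#'   scale (default 50).
#' @return The `nuclei` data.frame augmented with `focus_count`.
#' @export
count_foci <- function(foci_img, labels, spot_sigma_px = 2,
                       min_spot_intensity = 50) {
  stopifnot(inherits(foci_img, "micrograph"))
  seg <- if (is.list(labels)) labels else list(labels = labels, nuclei = NULL)
  lab <- seg$labels
  if (!identical(dim(lab), dim(foci_img$pixels))) {
    stop("label map and focus image dimensions differ")
  }
  mx <- max_intensity(foci_img)
  r <- max(1L, as.integer(ceiling(3 * spot_sigma_px)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(foci_img$pixels / mx, brush) * mx
  # candidate maxima: equal to the local dilation over the separation window
  sep <- max(1L, as.integer(ceiling(2 * spot_sigma_px)))
  dil <- EBImage::dilate(th / mx, EBImage::makeBrush(2L * sep + 1L,
                                                     shape = "disc")) * mx
  cand <- which(th >= min_spot_intensity & th >= dil - 1e-9)
  n_nuc <- max(lab, 0)
  counts <- integer(n_nuc)
  if (length(cand)) {
    # greedy non-maximum suppression: brightest first, keep maxima at
    # least 2*sigma apart (deterministic index tie-break)
    ord <- cand[order(-th[cand], cand)]
    nr <- nrow(th)
    rr <- ((ord - 1) %% nr) + 1
    cc <- ((ord - 1) %/% nr) + 1
    kept <- logical(length(ord))
    for (i in seq_along(ord)) {
      if (i > 1 && any(kept[seq_len(i - 1)] &
                       (rr[seq_len(i - 1)] - rr[i])^2 +
                       (cc[seq_len(i - 1)] - cc[i])^2 < (2 * spot_sigma_px)^2)) {
        next
      }
      kept[i] <- TRUE
    }
    for (i in which(kept)) {
      l <- lab[rr[i], cc[i]]
      if (l > 0) counts[l] <- counts[l] + 1L
    }
  }
  nuclei <- seg$nuclei
  if (is.null(nuclei)) {
    nuclei <- data.frame(nucleus_id = seq_len(n_nuc))
  }
  nuclei$focus_count <- counts[nuclei$nucleus_id]
  nuclei
}

#' Summarize per-nucleus focus counts
#'
#' @param records data.frame from [count_foci()] (needs `focus_count`).
#' @param positivity_min minimum focus count for a nucleus to be scored
#'   gamma-H2AX positive (default 1).
#' @return A one-row data.frame of class `foci_summary`: `n_nuclei`,
#'   `percent_positive` and `mean_dots_per_positive` (`NA` when no nucleus
#'   is positive).
#' @export
summarize_foci <- function(records, positivity_min = 1) {
  if (!nrow(records)) stop("no nuclei to summarize")
  pos <- records$focus_count >= positivity_min
  out <- data.frame(
    n_nuclei = nrow(records),
    percent_positive = 100 * mean(pos),
    mean_dots_per_positive = if (any(pos)) {
      mean(records$focus_count[pos])
    } else NA_real_
  )
  class(out) <- c("foci_summary", "data.frame")
  out
}
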