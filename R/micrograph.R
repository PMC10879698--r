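#' Construct a micrograph
#'
#' A `micrograph` is the substrate of every imaging readout in the package:
#' a single-channel 2D intensity matrix together with its physical pixel
#' size. Intensities are stored as plain numerics on the native integer
#' scale of the acquisition (0..255 for 8-bit, 0..65535 for 16-bit);
#' nothing is rescaled on construction.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (rows = image rows, origin top-left).
#' @param pixel_size_um physical size of one pixel in micrometres
#'   (isotropic, > 0).
#' @param bit_depth 8 or 16. Defaults to 8 when all values fit in 0..255,
#'   16 otherwise.
#' @param channel free-text channel tag, e.g. `"actinin"`, `"calcein"`,
#'   `"dapi"`, `"gh2ax"`.
#' @param timepoint hours since treatment start (optional metadata).
#'
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_um, bit_depth = NULL,
                       channel = NA_character_, timepoint = NA_real_) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  if (any(pixels < 0)) stop("pixel intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  if (is.null(bit_depth)) bit_depth <- if (max(pixels) <= 255) 8L else 16L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (max(pixels) > 2^bit_depth - 1) {
    stop("pixel intensities exceed the stated bit depth")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         bit_depth = bit_depth, channel = channel, timepoint = timepoint),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px, %d-bit, %.4g um/px",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um))
  if (!is.na(x$channel)) cat(sprintf(", channel '%s'", x$channel))
  if (!is.na(x$timepoint)) cat(sprintf(", t = %g h", x$timepoint))
  cat(sprintf("\n  intensity range [%g, %g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

max_intensity <- function(img) 2^img$bit_depth - 1

#' Read a single-channel TIFF as micrograph(s)
#'
#' Reads a single- or multi-plane grayscale TIFF/OME-TIFF with intensities
#' preserved bit-exactly (no rescaling). RGB images are rejected; extract a
#' single channel upstream.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um pixel size in micrometres; always required and takes
#'   precedence over any file metadata.
#' @param channel,timepoint optional metadata forwarded to [micrograph()].
#'
#' @return A `micrograph` for a single-plane file, or a list of `micrograph`
#'   objects in plane order for a stack.
#' @export
read_micrograph <- function(path, pixel_size_um, channel = NA_character_,
                            timepoint = NA_real_) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  one <- function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1] else
        stop("RGB/multi-sample TIFF: extract a single channel first")
    }
    bd <- if (max(p) > 255) 16L else 8L
    micrograph(p, pixel_size_um, bit_depth = bd,
               channel = channel, timepoint = timepoint)
  }
  out <- lapply(planes, one)
  if (length(out) == 1) out[[1]] else out
}

#' Write a micrograph to TIFF
#'
#' Round-trips bit-exactly with [read_micrograph()] for integer-valued
#' images; non-integer intensities are rounded to the nearest integer on
#' the native scale before writing.
#'
#' @param img a `micrograph` or list of micrographs (written as a stack).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  imgs <- if (inherits(img, "micrograph")) list(img) else img
  bd <- imgs[[1]]$bit_depth
  planes <- lapply(imgs, function(m) {
    if (m$bit_depth != bd) stop("all planes must share one bit depth")
    round(m$pixels) / (2^bd - 1)
  })
  tiff::writeTIFF(planes, path, bits.per.sample = bd)
  invisible(path)
}

#' Rolling-ball style background subtraction
#'
#' Estimates the low-frequency background as a grayscale morphological
#' opening with a disc structuring element of the given radius and
#' subtracts it, clipping at zero. Any feature narrower than the disc is
#' retained; smooth background shading wider than the disc is removed.
#' This is the deterministic counterpart of ImageJ's "Subtract Background"
#' used on the alpha-actinin channel (radius 50).
#'
#' @param img a `micrograph`.
#' @param radius_px structuring-element radius in pixels (default 50).
#' @return A background-subtracted `micrograph` with the same bit depth.
#' @export
subtract_background <- function(img, radius_px = 50) {
  stopifnot(inherits(img, "micrograph"))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (2 * radius_px + 1 > min(dim(img$pixels))) {
    stop("radius_px (", radius_px, ") too large for a ",
         nrow(img$pixels), "x", ncol(img$pixels), " image")
  }
  mx <- max_intensity(img)
  # disc SE defined by dr^2 + dc^2 <= r^2 (matches the documented oracle)
  off <- -radius_px:radius_px
  brush <- (outer(off^2, off^2, "+") <= radius_px^2) * 1
  # EBImage grayscale morphology clamps to [0,1]; opening commutes with
  # the linear rescale, so work on the normalized image
  bg <- EBImage::opening(img$pixels / mx, brush) * mx
  out <- pmax(img$pixels - bg, 0)
  micrograph(out, img$pixel_size_um, img$bit_depth, img$channel, img$timepoint)
}

#' Linear contrast stretch with saturated tails
#'
#' Maps the `saturated_fraction/2` and `1 - saturated_fraction/2` intensity
#' quantiles linearly onto the full dtype range, clipping outside; intensity
#' ordering is preserved (non-strictly). Mirrors ImageJ's "Enhance Contrast"
#' with 0.3% saturated pixels used on the alpha-actinin channel.
#'
#' @param img a `micrograph`.
#' @param saturated_fraction total fraction of pixels clipped, split evenly
#'   between the two tails; in `[0, 0.5)`. Default 0.003.
#' @return A contrast-stretched `micrograph`. A constant image is returned
#'   unchanged with a warning.
#' @export
enhance_contrast <- function(img, saturated_fraction = 0.003) {
  stopifnot(inherits(img, "micrograph"))
  if (saturated_fraction < 0 || saturated_fraction >= 0.5) {
    stop("saturated_fraction must be in [0, 0.5)")
  }
  q <- stats::quantile(img$pixels,
                       c(saturated_fraction / 2, 1 - saturated_fraction / 2),
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant (or near-constant) image: contrast not stretched")
    return(img)
  }
  mx <- max_intensity(img)
  out <- (img$pixels - q[1]) / (q[2] - q[1]) * mx
  out <- floor(pmin(pmax(out, 0), mx) + 0.5)
  micrograph(out, img$pixel_size_um, img$bit_depth, img$channel, img$timepoint)
}

#' Convert a micrograph to 8-bit
#'
#' Linear min-max scale of a 16-bit image onto `[0, 255]` with round
#' half-up; 8-bit input is returned unchanged. A constant image maps to
#' all zeros with a warning.
#'
#' @param img a `micrograph`.
#' @return An 8-bit `micrograph`.
#' @export
to_8bit <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  if (img$bit_depth == 8L) return(img)
  rng <- range(img$pixels)
  if (rng[2] <= rng[1]) {
    warning("constant image: 8-bit conversion yields all zeros")
    out <- matrix(0, nrow(img$pixels), ncol(img$pixels))
  } else {
    out <- floor((img$pixels - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  }
  micrograph(out, img$pixel_size_um, 8L, img$channel, img$timepoint)
}
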