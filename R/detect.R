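## Band-pass PSF detection on raw frames. The classic particle-locating
## recipe: subtract a coarse Gaussian blur (background) from a fine one
## (noise suppression), then keep local maxima above a threshold.

#' Detect candidate PSFs with a band-pass filter
#'
#' Smooths the image with Gaussian kernels at the low-pass and high-pass
#' scales (SDs in pixels), takes their difference, clips negatives, and
#' returns the local maxima (3x3 neighborhood) whose filtered amplitude
#' exceeds `threshold`. Deterministic for a fixed input.
#'
#' @param image 2D numeric matrix (raw frame).
#' @param low_pass SD (pixels) of the fine, noise-suppressing blur.
#' @param high_pass SD (pixels) of the coarse, background-estimating blur.
#' @param threshold Minimum band-passed amplitude for a detection.
#' @return A data.frame with columns `row`, `col` (pixel coordinates) and
#'   `amplitude` (band-passed value), ordered by decreasing amplitude.
#' @export
#' @examples
#' img <- render_frame(rbind(c(20, 20), c(40, 44)), amplitudes = 50)
#' detect_spots(img)
detect_spots <- function(image, low_pass = 0.3, high_pass = 3, threshold = 10) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2D numeric matrix")
  if (any(!is.finite(image))) stop("image must be finite-valued")
  fine <- .gauss_smooth(image, low_pass)
  coarse <- .gauss_smooth(image, high_pass)
  bp <- pmax(fine - coarse, 0)
  ## strict local maxima over the 8-neighborhood, excluding the border
  nr <- nrow(bp); nc <- ncol(bp)
  if (nr < 3 || nc < 3) return(data.frame(row = integer(), col = integer(),
                                          amplitude = numeric()))
  core <- bp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= bp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                    amplitude = core[is_max])
  out[order(-out$amplitude), , drop = FALSE]
}

## Gaussian smoothing; EBImage::gblur needs sigma large enough for a kernel,
## so tiny sigmas fall back to identity (a sub-pixel blur changes nothing
## at our scales).
.gauss_smooth <- function(image, sigma) {
  if (sigma < 0.35) return(image)
  as.matrix(EBImage::gblur(image, sigma = sigma))
}
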