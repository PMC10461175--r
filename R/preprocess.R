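## Time-series preprocessing: band-stop filtering of the half-rotation
## quadrant artifact, ROI/Rician SNR, and series assembly.

#' Band-stop filter an image time series
#'
#' Removes the alternating-quadrant instrument artifact: per voxel, the
#' series mean is subtracted, a zero-phase frequency-domain notch (unit gain
#' outside each `center +- bandwidth/2` band, zero inside) is applied on the
#' gap-aware sample index axis, and the mean is restored. The default
#' centers 0.2 and 0.4 cycles per sample are the spectral lines of the
#' [10101 10101 ...] quadrant pattern. The hard mask makes the filter
#' exactly idempotent and leaves the hypercapnia band (~0.0083
#' cycles/sample) untouched.
#'
#' @param series an [ImageSeries-class] with at least 20 frames
#' @param centerFreqs notch centers (cycles per sample), all in (0, 0.5]
#' @param bandwidth full notch width (cycles per sample)
#' @return the filtered series
#' @export
bandstopFilter <- function(series, centerFreqs = c(0.2, 0.4),
                           bandwidth = 0.075) {
  if (any(centerFreqs > 0.5))
    stop("center frequencies must be <= 0.5 cycles per sample")
  if (any(centerFreqs <= 0)) stop("center frequencies must be positive")
  v <- frameMatrix(series)
  n <- ncol(v)
  if (n < 20) stop("band-stop filtering needs at least 20 frames")
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)                     # folded (two-sided) frequencies
  stopBin <- rep(FALSE, n)
  for (fc in centerFreqs)
    stopBin <- stopBin | abs(f - fc) <= bandwidth / 2
  stopBin[1] <- FALSE                     # DC handled via the mean
  x <- t(v)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  X <- stats::mvfft(xc)
  X[stopBin, ] <- 0
  xf <- Re(stats::mvfft(X, inverse = TRUE)) / n
  xf <- sweep(xf, 2L, mu, `+`)
  SummarizedExperiment::assay(series, "frames") <- t(xf)
  series
}

#' Static image SNR with Rician noise correction
#'
#' SNR of a single reconstructed image: the maximum value in the central
#' `roiSize x roiSize` voxel region, divided by the standard deviation of
#' the same region in an empty-bore image scaled by the Rician correction
#' factor (default `sqrt(2 pi^2 / 3)`), which accounts for the non-zero
#' mean of magnitude-image noise.
#'
#' @param image reconstructed image (matrix)
#' @param emptyBore empty-bore (noise-only) image of the same shape
#' @param roiSize central ROI edge length in voxels (default 10)
#' @param rician correction factor applied to the noise SD
#' @return the SNR (dimensionless)
#' @export
staticSnr <- function(image, emptyBore, roiSize = 10,
                      rician = ricianFactor()) {
  stopifnot(identical(dim(image), dim(emptyBore)))
  nx <- nrow(image); ny <- ncol(image)
  rx <- min(roiSize, nx); ry <- min(roiSize, ny)
  ix <- floor((nx - rx) / 2) + seq_len(rx)
  iy <- floor((ny - ry) / 2) + seq_len(ry)
  noiseSd <- stats::sd(emptyBore[ix, iy])
  if (noiseSd == 0) stop("empty-bore ROI has zero variance")
  max(image[ix, iy]) / (rician * noiseSd)
}

#' Assemble an image time series from frames, timestamps and a state trace
#'
#' Aligns the recorded capnia switch trace to the frames (each frame takes
#' the state of the nearest preceding switch event), builds the gap-aware
#' sample index and the set structure from the timestamp spacing.
#'
#' @param frames 3D array (nx x ny x nFrames) or voxel-by-frame matrix
#' @param timestamps frame times (s), strictly increasing
#' @param stateTrace a data frame with columns `timestamp` and `state`
#'   (0/1), a path to such a CSV file, or NULL/empty (all-hypocapnia
#'   default, with a warning)
#' @param dim image dimensions (required for matrix `frames`)
#' @param voxelSize in-plane voxel size (mm)
#' @param mask optional logical ROI mask
#' @return an [ImageSeries-class]
#' @export
assembleSeries <- function(frames, timestamps, stateTrace = NULL,
                           dim = NULL, voxelSize = 0.9, mask = NULL) {
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (is.character(stateTrace)) stateTrace <- readStateTrace(stateTrace)
  if (is.null(stateTrace) || nrow(stateTrace) == 0L) {
    warning("empty state trace; defaulting every frame to hypocapnia (0)")
    state <- rep(0, length(timestamps))
  } else {
    stopifnot(all(c("timestamp", "state") %in% colnames(stateTrace)))
    st <- stateTrace[order(stateTrace$timestamp), , drop = FALSE]
    idx <- findInterval(timestamps, st$timestamp)
    state <- ifelse(idx >= 1, st$state[pmax(idx, 1L)], st$state[1L])
  }
  ImageSeries(frames, timestamps = timestamps, dim = dim,
              voxelSize = voxelSize, state = state, mask = mask)
}
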