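# Spatio-spectral preprocessing: channel trimming, binning, mean-kernel
# denoising, display normalisation, HAADF median equalisation, and
# metadata-driven grid stitching.

#' Preprocessing configuration
#'
#' Defaults mirror the acquisition geometry this workflow targets:
#' 2048 x 2048 px tiles with 4096 channels of 5 eV reduce to
#' 1024 x 1024 x 250 by dropping the first 96 calibration-artefact
#' channels, binning 2 x 2 spatially and 16-fold spectrally, then
#' denoising each band with a small spatial mean kernel.
#'
#' @param drop_first_channels Leading channels to discard (default 96).
#' @param spatial_bin Spatial binning factor per axis (default 2).
#' @param spectral_bin Spectral binning factor (default 16).
#' @param mean_kernel_px Odd mean-kernel window (default 3).
#' @param bin_reducer `"sum"` (count-conserving, default) or `"mean"`.
#' @return A `preprocess_config` list.
#' @export
preprocessConfig <- function(drop_first_channels = 96, spatial_bin = 2,
                             spectral_bin = 16, mean_kernel_px = 3,
                             bin_reducer = c("sum", "mean")) {
  bin_reducer <- match.arg(bin_reducer)
  stopifnot(drop_first_channels >= 0, spatial_bin >= 1, spectral_bin >= 1,
            mean_kernel_px >= 1, mean_kernel_px %% 2 == 1)
  structure(list(drop_first_channels = as.integer(drop_first_channels),
                 spatial_bin = as.integer(spatial_bin),
                 spectral_bin = as.integer(spectral_bin),
                 mean_kernel_px = as.integer(mean_kernel_px),
                 bin_reducer = bin_reducer),
            class = "preprocess_config")
}

#' Output shape of trim-and-bin for given input dimensions
#'
#' Pure shape logic: lets callers reason about acquisition-scale cubes
#' (e.g. 2048 x 2048 x 4096) without materialising them.
#'
#' @param dim Integer `(rows, cols, channels)` of the input cube.
#' @param cfg A [preprocessConfig()].
#' @return Integer `(rows, cols, channels)` after trimming and binning.
#' @export
preprocessedDim <- function(dim, cfg = preprocessConfig()) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3)
  if (cfg$drop_first_channels >= dim[3])
    stop("drop_first_channels (", cfg$drop_first_channels,
         ") must be smaller than n_channels (", dim[3], ")")
  kept <- dim[3] - cfg$drop_first_channels
  if (dim[1] %% cfg$spatial_bin || dim[2] %% cfg$spatial_bin)
    stop("spatial dimensions ", dim[1], " x ", dim[2],
         " are not divisible by spatial_bin = ", cfg$spatial_bin,
         "; crop or pad the cube first")
  if (kept %% cfg$spectral_bin)
    stop("post-trim channel count ", kept,
         " is not divisible by spectral_bin = ", cfg$spectral_bin,
         "; adjust drop_first_channels or crop the channel axis")
  as.integer(c(dim[1] %/% cfg$spatial_bin, dim[2] %/% cfg$spatial_bin,
               kept %/% cfg$spectral_bin))
}

# bin one array axis by an integer factor with sum or mean reduction
.binAxis <- function(a, axis, f, reducer) {
  if (f == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(a, perm)
  dp <- dim(a)
  dim(a) <- c(f, dp[1] %/% f, prod(dp[-1]))
  a <- colSums(a, dims = 1)
  if (reducer == "mean") a <- a / f
  dim(a) <- c(dp[1] %/% f, dp[-1])
  aperm(a, order(perm))
}

#' Trim calibration channels and bin a cube spatially and spectrally
#'
#' Drops the first `drop_first_channels` channels, then bins by
#' `spatial_bin` per spatial axis and `spectral_bin` along the channel
#' axis. With the default `"sum"` reducer, total counts after trimming
#' are conserved exactly. The energy axis is updated: the new offset is
#' the mean energy of the first merged channel group and the bin width
#' is multiplied by the spectral factor.
#'
#' @param cube A [HyperspectralCube-class].
#' @param cfg A [preprocessConfig()].
#' @return The trimmed-and-binned [HyperspectralCube-class].
#' @export
trimAndBin <- function(cube, cfg = preprocessConfig()) {
  stopifnot(is(cube, "HyperspectralCube"))
  d <- dim(cube@counts)
  preprocessedDim(d, cfg)  # shape/divisibility errors surface here
  counts <- cube@counts[, , (cfg$drop_first_channels + 1L):d[3],
                        drop = FALSE]
  counts <- .binAxis(counts, 1L, cfg$spatial_bin, cfg$bin_reducer)
  counts <- .binAxis(counts, 2L, cfg$spatial_bin, cfg$bin_reducer)
  counts <- .binAxis(counts, 3L, cfg$spectral_bin, cfg$bin_reducer)
  ax <- cube@energy
  new_axis <- EnergyAxis(
    offset_ev = ax@offset_ev + cfg$drop_first_channels * ax@bin_width_ev +
      (cfg$spectral_bin - 1) / 2 * ax@bin_width_ev,
    bin_width_ev = ax@bin_width_ev * cfg$spectral_bin,
    n_channels = dim(counts)[3])
  HyperspectralCube(counts, new_axis,
                    pixel_size_nm = cube@pixel_size_nm * cfg$spatial_bin,
                    n_frames = cube@n_frames, dwell_us = cube@dwell_us,
                    tile_id = cube@tile_id)
}

#' Apply a spatial mean kernel to every spectral band
#'
#' Each band image is convolved with a normalised `k x k` box kernel;
#' borders are mirrored. A kernel of 1 is the identity.
#'
#' @param cube A [HyperspectralCube-class].
#' @param kernel_px Odd window size (default 3).
#' @return The denoised [HyperspectralCube-class].
#' @export
meanFilterBands <- function(cube, kernel_px = 3) {
  stopifnot(is(cube, "HyperspectralCube"))
  kernel_px <- as.integer(kernel_px)
  if (kernel_px %% 2 == 0) stop("mean kernel size must be odd")
  if (kernel_px == 1L) return(cube)
  k <- boxKernel1d(kernel_px)
  counts <- cube@counts
  for (ch in seq_len(dim(counts)[3]))
    counts[, , ch] <- convSeparable(counts[, , ch], k)
  initialize(cube, counts = counts)
}

#' Full cube preprocessing: trim, bin, mean-filter
#'
#' @param cube A [HyperspectralCube-class].
#' @param cfg A [preprocessConfig()].
#' @return The preprocessed [HyperspectralCube-class].
#' @export
preprocessCube <- function(cube, cfg = preprocessConfig()) {
  meanFilterBands(trimAndBin(cube, cfg), cfg$mean_kernel_px)
}

#' Display normalisation configuration
#'
#' @param saturate_frac Fraction clipped at each tail (default 0.01;
#'   0.005 for low-noise displays).
#' @param gaussian_sigma_px Gaussian pre-blur sigma for elemental maps
#'   (default 1; 0 disables).
#' @return A `normalize_config` list.
#' @export
normalizeConfig <- function(saturate_frac = 0.01, gaussian_sigma_px = 1) {
  stopifnot(saturate_frac >= 0, saturate_frac < 0.5, gaussian_sigma_px >= 0)
  structure(list(saturate_frac = saturate_frac,
                 gaussian_sigma_px = gaussian_sigma_px),
            class = "normalize_config")
}

#' Percentile min/max normalisation of a display image
#'
#' Optionally Gaussian pre-blurs, then linearly maps the
#' `saturate_frac` quantile to 0 and the `1 - saturate_frac` quantile
#' to 1 (linear-interpolation quantiles), clipping to `[0, 1]` so each
#' tail saturates. A constant image maps to 0.5 by convention.
#'
#' @param img Finite numeric matrix.
#' @param cfg A [normalizeConfig()]; for plain min/max use
#'   `normalizeConfig(0, 0)`.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalizeImage <- function(img, cfg = normalizeConfig()) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (cfg$gaussian_sigma_px > 0)
    img <- gaussianBlur(img, cfg$gaussian_sigma_px)
  q <- quantile(img, c(cfg$saturate_frac, 1 - cfg$saturate_frac),
                names = FALSE, type = 7)
  if (q[2] <= q[1]) return(matrix(0.5, nrow(img), ncol(img)))
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Equalise HAADF tile medians
#'
#' Shifts every tile additively so its median equals the minimum median
#' across tiles; shifts are only ever downward, making grayscale levels
#' comparable across a mosaic.
#'
#' @param tiles List of numeric matrices.
#' @return List of shifted matrices (same order).
#' @export
equalizeHaadfMedians <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  meds <- vapply(tiles, median, numeric(1))
  target <- min(meds)
  Map(function(t, m) t - (m - target), tiles, meds)
}

#' Stitch a tile grid into one image or cube
#'
#' Places tiles on the analytic grid (step `tile_px - overlap_px`),
#' row-major. Overlapping pixels are resolved by the chosen reducer:
#' `"first"` (first-written tile wins, default) or `"mean"`.
#'
#' @param tiles List of matrices (or `[row, col, channel]` arrays), one
#'   per grid cell, row-major order.
#' @param layout A [MosaicLayout-class].
#' @param reducer Overlap reducer.
#' @return Stitched matrix (or array) of the analytic extent.
#' @export
stitchGrid <- function(tiles, layout, reducer = c("first", "mean")) {
  reducer <- match.arg(reducer)
  stopifnot(is(layout, "MosaicLayout"))
  ntiles <- layout@grid_rows * layout@grid_cols
  if (length(tiles) != ntiles)
    stop("expected ", ntiles, " tiles, got ", length(tiles))
  is3d <- length(dim(tiles[[1]])) == 3
  tdim <- dim(tiles[[1]])
  for (t in tiles) if (!identical(dim(t)[1:2], tdim[1:2]) ||
                       !identical(length(dim(t)), length(tdim)))
    stop("tile shape mismatch")
  if (any(tdim[1:2] != layout@tile_px))
    stop("tiles must be ", layout@tile_px, " px square")
  ext <- stitchedExtentPx(layout)
  nch <- if (is3d) tdim[3] else 1L
  acc <- array(0, dim = c(ext[1], ext[2], nch))
  wsum <- matrix(0, ext[1], ext[2])
  step <- layout@tile_px - layout@overlap_px
  idx <- 1L
  for (gr in seq_len(layout@grid_rows)) for (gc in seq_len(layout@grid_cols)) {
    r0 <- (gr - 1L) * step
    c0 <- (gc - 1L) * step
    rows <- r0 + seq_len(layout@tile_px)
    cols <- c0 + seq_len(layout@tile_px)
    tile <- tiles[[idx]]
    if (!is3d) dim(tile) <- c(tdim[1], tdim[2], 1L)
    if (reducer == "first") {
      fresh <- wsum[rows, cols] == 0
      for (ch in seq_len(nch)) {
        plane <- acc[rows, cols, ch]
        plane[fresh] <- tile[, , ch][fresh]
        acc[rows, cols, ch] <- plane
      }
      wsum[rows, cols] <- wsum[rows, cols] + 1
    } else {
      acc[rows, cols, ] <- acc[rows, cols, , drop = FALSE] + tile
      wsum[rows, cols] <- wsum[rows, cols] + 1
    }
    idx <- idx + 1L
  }
  if (reducer == "mean")
    for (ch in seq_len(nch)) acc[, , ch] <- acc[, , ch] / pmax(wsum, 1)
  if (is3d) acc else acc[, , 1]
}

#' Mask of multiply-exposed (overlap) pixels in a stitched mosaic
#'
#' @param layout A [MosaicLayout-class].
#' @return Logical matrix over the stitched extent: TRUE where two or
#'   more tiles cover the pixel.
#' @export
overlapMask <- function(layout) {
  stopifnot(is(layout, "MosaicLayout"))
  ext <- stitchedExtentPx(layout)
  cover <- matrix(0L, ext[1], ext[2])
  step <- layout@tile_px - layout@overlap_px
  for (gr in seq_len(layout@grid_rows)) for (gc in seq_len(layout@grid_cols)) {
    rows <- (gr - 1L) * step + seq_len(layout@tile_px)
    cols <- (gc - 1L) * step + seq_len(layout@tile_px)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  cover >= 2L
}
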