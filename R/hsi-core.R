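# Container I/O and flattening for hyperspectral cubes.
#
# Cube container layout (defined by this package, documented in the
# vignette): a raw little-endian binary file holding the counts array in
# R's native column-major order (row fastest, then col, then channel),
# plus a JSON sidecar "<path>.json" carrying shape, dtype, the energy
# axis, acquisition metadata and an md5 checksum of the binary payload.
# Mosaics are described by a plain-text JSON manifest listing the grid
# layout and per-tile container paths.

.cubeRequiredFields <- c("shape", "dtype", "offset_ev", "bin_width_ev",
                         "n_channels", "pixel_size_nm", "n_frames",
                         "dwell_us", "tile_id")

#' Write a hyperspectral cube to the package's container format
#'
#' Writes `<path>` (raw little-endian binary counts, column-major) and
#' `<path>.json` (metadata sidecar). Integer-valued cubes are stored as
#' 32-bit unsigned-range integers, others as 64-bit doubles; the dtype
#' is recorded in the sidecar so [readCube()] round-trips bit-exactly.
#'
#' @param cube A [HyperspectralCube-class].
#' @param path Output file path (sidecar written as `paste0(path, ".json")`).
#' @return Invisibly, the sidecar path.
#' @seealso [readCube()]
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "HyperspectralCube"))
  validObject(cube)
  counts <- cube@counts
  integral <- is.integer(counts)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (integral) {
    writeBin(as.integer(counts), con, size = 4L, endian = "little")
    dtype <- "int32"
  } else {
    writeBin(as.double(counts), con, size = 8L, endian = "little")
    dtype <- "float64"
  }
  close(con)
  on.exit()
  meta <- list(
    format = "edxunmix-cube-v1",
    shape = dim(counts),
    dtype = dtype,
    byte_order = "little",
    order = "column-major",
    offset_ev = cube@energy@offset_ev,
    bin_width_ev = cube@energy@bin_width_ev,
    n_channels = cube@energy@n_channels,
    pixel_size_nm = cube@pixel_size_nm,
    n_frames = cube@n_frames,
    dwell_us = cube@dwell_us,
    tile_id = cube@tile_id,
    md5 = unname(tools::md5sum(path)))
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a hyperspectral cube from the package's container format
#'
#' @param path Path previously written by [writeCube()].
#' @param check_md5 Verify the binary payload checksum (default TRUE).
#' @return A validated [HyperspectralCube-class].
#' @export
readCube <- function(path, check_md5 = TRUE) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("cube file not found: ", path)
  if (!file.exists(sidecar)) stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(.cubeRequiredFields, names(meta))
  if (length(missing))
    stop("cube metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  shape <- as.integer(meta$shape)
  if (length(shape) != 3)
    stop("cube metadata 'shape' must have 3 entries")
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  counts <- switch(meta$dtype,
    int32 = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unknown dtype in cube metadata: ", meta$dtype))
  if (length(counts) != n)
    stop("cube file size does not match metadata shape")
  if (isTRUE(check_md5) && !is.null(meta$md5)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, meta$md5))
      stop("cube payload checksum mismatch for ", path)
  }
  dim(counts) <- shape
  if (shape[3] != as.integer(meta$n_channels))
    stop("metadata n_channels (", meta$n_channels,
         ") does not match counts shape (", shape[3], ")")
  HyperspectralCube(
    counts = counts,
    energy = EnergyAxis(meta$offset_ev, meta$bin_width_ev, meta$n_channels),
    pixel_size_nm = meta$pixel_size_nm,
    n_frames = meta$n_frames,
    dwell_us = meta$dwell_us,
    tile_id = meta$tile_id)
}

#' Write / read a mosaic manifest
#'
#' The manifest is a plain-text JSON file recording the grid layout and
#' the per-tile cube container paths (relative to the manifest).
#'
#' @param layout A [MosaicLayout-class].
#' @param tile_paths Character vector of cube paths, row-major tile order
#'   (length `grid_rows * grid_cols`).
#' @param path Manifest output path.
#' @return Invisibly, `path`.
#' @export
writeMosaicManifest <- function(layout, tile_paths, path) {
  stopifnot(is(layout, "MosaicLayout"))
  if (length(tile_paths) != layout@grid_rows * layout@grid_cols)
    stop("expected ", layout@grid_rows * layout@grid_cols, " tile paths")
  jsonlite::write_json(list(
    format = "edxunmix-mosaic-v1",
    grid_rows = layout@grid_rows, grid_cols = layout@grid_cols,
    tile_px = layout@tile_px, overlap_px = layout@overlap_px,
    pixel_size_nm = layout@pixel_size_nm,
    tiles = as.character(tile_paths)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMosaicManifest
#' @export
readMosaicManifest <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("grid_rows", "grid_cols", "tile_px", "overlap_px",
            "pixel_size_nm", "tiles")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("mosaic manifest is missing required field(s): ",
         paste(missing, collapse = ", "))
  list(layout = MosaicLayout(meta$grid_rows, meta$grid_cols, meta$tile_px,
                             meta$overlap_px, meta$pixel_size_nm),
       tiles = meta$tiles)
}

#' Flatten a cube to a pixel-by-channel table
#'
#' Rearranges `[row, col, channel]` counts into a `[pixel, channel]`
#' matrix with an origin mapping recording each row's source pixel.
#' Pixels are enumerated column-major (row index fastest), matching R's
#' array layout. An optional selection restricts the rows.
#'
#' @param cube A [HyperspectralCube-class].
#' @param select Optional selection: a logical matrix of the cube's
#'   spatial shape (TRUE = keep), or a data.frame/matrix with columns
#'   `row`, `col`.
#' @return A [FlatPixelTable-class] with `nrow = #selected pixels`,
#'   `ncol = n_channels`.
#' @seealso [unflatten()]
#' @export
flattenCube <- function(cube, select = NULL) {
  stopifnot(is(cube, "HyperspectralCube"))
  d <- dim(cube@counts)
  values <- matrix(cube@counts, d[1] * d[2], d[3])
  origin <- data.frame(
    tile_id = cube@tile_id,
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    stringsAsFactors = FALSE)
  if (!is.null(select)) {
    if (is.logical(select) && is.matrix(select)) {
      if (!all(dim(select) == d[1:2]))
        stop("selection mask shape does not match cube")
      keep <- which(as.vector(select))
    } else {
      sel <- as.data.frame(select)
      if (!all(c("row", "col") %in% names(sel)))
        stop("selection must have columns 'row' and 'col'")
      if (any(sel$row < 1 | sel$row > d[1] | sel$col < 1 | sel$col > d[2]))
        stop("selection indices out of cube bounds")
      keep <- sel$row + (sel$col - 1L) * d[1]
    }
    if (!length(keep)) stop("empty pixel selection")
    values <- values[keep, , drop = FALSE]
    origin <- origin[keep, , drop = FALSE]
    rownames(origin) <- NULL
  }
  FlatPixelTable(values, origin)
}

#' Reconstruct an array from a flat pixel table
#'
#' Inverse of [flattenCube()] for full selections: places each table row
#' back at its origin pixel. Pixels absent from the table are filled
#' with `fill`.
#'
#' @param table A [FlatPixelTable-class].
#' @param nrow,ncol Spatial shape of the target array.
#' @param fill Value for pixels not present in the table (default 0).
#' @return Numeric array `[nrow, ncol, n_features]`.
#' @export
unflatten <- function(table, nrow, ncol, fill = 0) {
  stopifnot(is(table, "FlatPixelTable"))
  org <- table@origin
  if (any(org$row < 1 | org$row > nrow | org$col < 1 | org$col > ncol))
    stop("origin indices out of bounds for the requested shape")
  nf <- ncol(table@values)
  out <- array(fill, dim = c(nrow, ncol, nf))
  idx <- org$row + (org$col - 1L) * nrow
  for (f in seq_len(nf)) {
    plane <- matrix(fill, nrow, ncol)
    plane[idx] <- table@values[, f]
    out[, , f] <- plane
  }
  # keep integer cubes integer when the fill allows it
  if (is.integer(table@values) &&
      (all(is.na(fill)) || isTRUE(all(fill == as.integer(fill)))))
    storage.mode(out) <- "integer"
  out
}
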