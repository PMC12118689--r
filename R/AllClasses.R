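NULL

# ---------------------------------------------------------------------------
# EnergyAxis
# ---------------------------------------------------------------------------

#' Energy axis of a hyperspectral EDX cube
#'
#' Describes the mapping from spectral channel index to X-ray energy.
#' Channel centers are `offset_ev + (i - 1) * bin_width_ev` for channel
#' `i = 1..n_channels` (1-based in R; the mapping is strictly increasing).
#'
#' @slot offset_ev Energy of the first channel center, in eV.
#' @slot bin_width_ev Channel width in eV; must be positive.
#' @slot n_channels Number of spectral channels (>= 1).
#'
#' @examples
#' ax <- EnergyAxis(offset_ev = 0, bin_width_ev = 5, n_channels = 4096)
#' head(channelEnergies(ax))
#' @export
setClass("EnergyAxis",
  representation(offset_ev = "numeric", bin_width_ev = "numeric",
                 n_channels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@bin_width_ev) != 1 || !is.finite(object@bin_width_ev) ||
        object@bin_width_ev <= 0)
      msg <- c(msg, "bin_width_ev must be a single positive number")
    if (length(object@offset_ev) != 1 || !is.finite(object@offset_ev))
      msg <- c(msg, "offset_ev must be a single finite number")
    if (length(object@n_channels) != 1 || is.na(object@n_channels) ||
        object@n_channels < 1L)
      msg <- c(msg, "n_channels must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param offset_ev Energy of the first channel center (eV).
#' @param bin_width_ev Channel width (eV), positive.
#' @param n_channels Number of channels.
#' @rdname EnergyAxis-class
#' @export
EnergyAxis <- function(offset_ev, bin_width_ev, n_channels) {
  new("EnergyAxis", offset_ev = as.numeric(offset_ev),
      bin_width_ev = as.numeric(bin_width_ev),
      n_channels = as.integer(n_channels))
}

#' Channel center energies (eV) of an energy axis
#' @param axis An [EnergyAxis-class] object.
#' @return Numeric vector of channel center energies, strictly increasing.
#' @export
channelEnergies <- function(axis) {
  stopifnot(is(axis, "EnergyAxis"))
  axis@offset_ev + (seq_len(axis@n_channels) - 1) * axis@bin_width_ev
}

setMethod("show", "EnergyAxis", function(object) {
  cat(sprintf("EnergyAxis: %d channels, %.6g eV bins, first center %.6g eV\n",
              object@n_channels, object@bin_width_ev, object@offset_ev))
})

# ---------------------------------------------------------------------------
# HyperspectralCube
# ---------------------------------------------------------------------------

#' Hyperspectral EDX spectrum image
#'
#' The central container: a 3-D array of X-ray counts indexed
#' `[row, col, channel]` plus acquisition metadata. Raw (pre-denoising)
#' cubes hold nonnegative integer counts; derived cubes (after mean
#' filtering) may hold nonnegative reals.
#'
#' @slot counts 3-D numeric array `[row, col, channel]`, nonnegative.
#' @slot energy [EnergyAxis-class] describing the channel axis.
#' @slot pixel_size_nm Spatial sampling in nm per pixel.
#' @slot n_frames Number of accumulated scan frames.
#' @slot dwell_us Pixel dwell time in microseconds (metadata only).
#' @slot tile_id Optional mosaic tile identifier ("" when unset).
#'
#' @export
setClass("HyperspectralCube",
  representation(counts = "array", energy = "EnergyAxis",
                 pixel_size_nm = "numeric", n_frames = "numeric",
                 dwell_us = "numeric", tile_id = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@counts)
    if (length(d) != 3)
      msg <- c(msg, "counts must be a 3-D array [row, col, channel]")
    else if (d[3] != object@energy@n_channels)
      msg <- c(msg, sprintf(
        "channel dimension (%d) does not match energy axis n_channels (%d)",
        d[3], object@energy@n_channels))
    if (anyNA(object@counts) || any(!is.finite(object@counts)))
      msg <- c(msg, "counts must be finite")
    else if (any(object@counts < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (object@pixel_size_nm <= 0)
      msg <- c(msg, "pixel_size_nm must be positive")
    if (object@n_frames < 0)
      msg <- c(msg, "n_frames must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' @param counts 3-D array `[row, col, channel]` of nonnegative counts.
#' @param energy An [EnergyAxis-class].
#' @param pixel_size_nm Pixel size (nm).
#' @param n_frames Accumulated frame count.
#' @param dwell_us Pixel dwell time (microseconds).
#' @param tile_id Optional tile identifier for mosaics.
#' @rdname HyperspectralCube-class
#' @export
HyperspectralCube <- function(counts, energy, pixel_size_nm = 1,
                              n_frames = 1, dwell_us = 0, tile_id = "") {
  new("HyperspectralCube", counts = counts, energy = energy,
      pixel_size_nm = as.numeric(pixel_size_nm),
      n_frames = as.numeric(n_frames), dwell_us = as.numeric(dwell_us),
      tile_id = as.character(tile_id))
}

#' @param cube A [HyperspectralCube-class].
#' @return `cubeCounts` returns the 3-D counts array; `energyAxis` the
#'   [EnergyAxis-class]; `cubeDim` the `(rows, cols, channels)` integer
#'   vector.
#' @rdname HyperspectralCube-class
#' @export
cubeCounts <- function(cube) cube@counts

#' @rdname HyperspectralCube-class
#' @export
energyAxis <- function(cube) cube@energy

#' @rdname HyperspectralCube-class
#' @export
cubeDim <- function(cube) dim(cube@counts)

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "HyperspectralCube: %d x %d px, %d channels | %.3g nm/px, %g frame(s)%s\n",
    d[1], d[2], d[3], object@pixel_size_nm, object@n_frames,
    if (nzchar(object@tile_id)) paste0(", tile ", object@tile_id) else ""))
  cat("  total counts:", format(sum(object@counts)), "\n")
})

# ---------------------------------------------------------------------------
# MosaicLayout
# ---------------------------------------------------------------------------

#' Regular tile-grid geometry of a mosaic acquisition
#'
#' Tiles are square (`tile_px` pixels per side) and laid out on a
#' `grid_rows x grid_cols` grid; adjacent tiles share `overlap_px`
#' pixels per touching edge. The stitched extent along an axis with
#' `n` tiles is `tile_px * n - overlap_px * (n - 1)` pixels.
#'
#' @slot grid_rows,grid_cols Tile grid shape.
#' @slot tile_px Tile side length in pixels.
#' @slot overlap_px Overlap between adjacent tiles (pixels per edge).
#' @slot pixel_size_nm Pixel size (nm).
#' @export
setClass("MosaicLayout",
  representation(grid_rows = "integer", grid_cols = "integer",
                 tile_px = "integer", overlap_px = "integer",
                 pixel_size_nm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@grid_rows < 1L || object@grid_cols < 1L)
      msg <- c(msg, "grid must have at least one tile per axis")
    if (object@overlap_px < 0L || object@overlap_px >= object@tile_px)
      msg <- c(msg, "overlap_px must satisfy 0 <= overlap_px < tile_px")
    if (object@pixel_size_nm <= 0)
      msg <- c(msg, "pixel_size_nm must be positive")
    if (length(msg)) msg else TRUE
  })

#' @param grid_rows,grid_cols Number of tile rows / columns.
#' @param tile_px Tile side length (pixels).
#' @param overlap_px Overlap per touching edge (pixels).
#' @param pixel_size_nm Pixel size (nm).
#' @rdname MosaicLayout-class
#' @export
MosaicLayout <- function(grid_rows, grid_cols, tile_px, overlap_px = 0L,
                         pixel_size_nm = 1) {
  new("MosaicLayout", grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols), tile_px = as.integer(tile_px),
      overlap_px = as.integer(overlap_px),
      pixel_size_nm = as.numeric(pixel_size_nm))
}

#' Stitched mosaic extent
#'
#' @param layout A [MosaicLayout-class].
#' @return `stitchedExtentPx`: integer `(rows, cols)` of the stitched
#'   image in pixels; `stitchedExtentNm`: the same in nm.
#' @export
stitchedExtentPx <- function(layout) {
  n <- c(layout@grid_rows, layout@grid_cols)
  as.integer(layout@tile_px * n - layout@overlap_px * (n - 1L))
}

#' @rdname stitchedExtentPx
#' @export
stitchedExtentNm <- function(layout) {
  stitchedExtentPx(layout) * layout@pixel_size_nm
}

#' Number of non-overlapping tiles needed to cover a physical area
#'
#' Computes how many square tiles of `tile_px` pixels at `pixel_size_nm`
#' nm/px are required to cover a `height_um x width_um` field, per axis
#' and in total (ceiling per axis, no overlap).
#'
#' @param height_um,width_um Field extent in micrometres.
#' @param tile_px Tile side length in pixels.
#' @param pixel_size_nm Pixel size in nm.
#' @return List with `grid` (rows, cols) and `n_tiles`.
#' @examples
#' tilesToCover(40, 48, tile_px = 2048, pixel_size_nm = 4)$n_tiles  # 30
#' @export
tilesToCover <- function(height_um, width_um, tile_px, pixel_size_nm) {
  tile_um <- tile_px * pixel_size_nm / 1000
  grid <- c(ceiling(height_um / tile_um), ceiling(width_um / tile_um))
  list(grid = as.integer(grid), n_tiles = as.integer(prod(grid)))
}

setMethod("show", "MosaicLayout", function(object) {
  ext <- stitchedExtentPx(object)
  cat(sprintf(
    "MosaicLayout: %d x %d tiles of %d px (overlap %d px) -> %d x %d px @ %.3g nm/px\n",
    object@grid_rows, object@grid_cols, object@tile_px, object@overlap_px,
    ext[1], ext[2], object@pixel_size_nm))
})

# ---------------------------------------------------------------------------
# AnnotationSet
# ---------------------------------------------------------------------------

#' Sparse manual pixel annotations
#'
#' A set of labelled pixel coordinates (e.g. representative pixels of
#' insulin granules, heterochromatin, membranes) used to derive
#' endmembers by class-mean spectra. A pixel may belong to at most one
#' class.
#'
#' @slot pixels data.frame with columns `label`, `row`, `col` (1-based).
#' @slot colors Named character vector of display colours per label.
#' @export
setClass("AnnotationSet",
  representation(pixels = "data.frame", colors = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("label", "row", "col")
    if (!all(need %in% names(object@pixels)))
      msg <- c(msg, "pixels must have columns label, row, col")
    else {
      if (anyDuplicated(object@pixels[, c("row", "col")]))
        msg <- c(msg, "a pixel may belong to at most one class")
      if (any(object@pixels$row < 1) || any(object@pixels$col < 1))
        msg <- c(msg, "pixel indices must be >= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' @param pixels data.frame with columns `label`, `row`, `col`.
#' @param colors Optional named character vector of display colours.
#' @rdname AnnotationSet-class
#' @export
AnnotationSet <- function(pixels, colors = character()) {
  pixels$label <- as.character(pixels$label)
  new("AnnotationSet", pixels = pixels, colors = colors)
}

setMethod("show", "AnnotationSet", function(object) {
  tab <- table(object@pixels$label)
  cat("AnnotationSet:", length(tab), "classes,", nrow(object@pixels),
      "pixels\n")
  for (l in names(tab)) cat(sprintf("  %s: %d px\n", l, tab[[l]]))
})

# ---------------------------------------------------------------------------
# FlatPixelTable
# ---------------------------------------------------------------------------

#' Flattened pixel-by-feature table
#'
#' A 2-D view of (a selection of) cube pixels: one row per pixel, one
#' column per feature (spectral channel, or augmented channel set). The
#' `origin` data.frame maps each row back to its source pixel and is a
#' bijection onto the selection.
#'
#' @slot values Numeric matrix `[pixel, feature]`.
#' @slot origin data.frame with columns `tile_id`, `row`, `col`, one row
#'   per table row, no duplicates.
#' @export
setClass("FlatPixelTable",
  representation(values = "matrix", origin = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != nrow(object@origin))
      msg <- c(msg, "origin must have one row per pixel row")
    need <- c("tile_id", "row", "col")
    if (!all(need %in% names(object@origin)))
      msg <- c(msg, "origin must have columns tile_id, row, col")
    else if (anyDuplicated(object@origin[, need]))
      msg <- c(msg, "origin must be a bijection (duplicate pixels found)")
    if (length(msg)) msg else TRUE
  })

#' @param values Numeric `[pixel, feature]` matrix.
#' @param origin data.frame with columns `tile_id`, `row`, `col`.
#' @rdname FlatPixelTable-class
#' @export
FlatPixelTable <- function(values, origin) {
  new("FlatPixelTable", values = values, origin = origin)
}

#' @param table A [FlatPixelTable-class].
#' @rdname FlatPixelTable-class
#' @export
tableValues <- function(table) table@values

#' @rdname FlatPixelTable-class
#' @export
tableOrigin <- function(table) table@origin

setMethod("show", "FlatPixelTable", function(object) {
  cat(sprintf("FlatPixelTable: %d pixels x %d features\n",
              nrow(object@values), ncol(object@values)))
})

# ---------------------------------------------------------------------------
# Embedding2D / Histogram2D
# ---------------------------------------------------------------------------

#' Two-dimensional embedding of pixel spectra
#'
#' Result of reducing a pixel-by-feature table to 2-D with a manifold /
#' projection backend. Row `i` of `coords` corresponds to row
#' `sample_index[i]` of the source table.
#'
#' @slot coords N x 2 numeric matrix of embedding coordinates.
#' @slot sample_index Integer vector mapping embedding rows to source
#'   table rows.
#' @slot origin data.frame (tile_id, row, col) per embedded pixel.
#' @slot backend Backend tag (e.g. "sammon", "pca").
#' @slot params List of backend parameters.
#' @slot seed Integer seed recorded for reproducibility.
#' @export
setClass("Embedding2D",
  representation(coords = "matrix", sample_index = "integer",
                 origin = "data.frame", backend = "character",
                 params = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 2)
      msg <- c(msg, "coords must have exactly 2 columns")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
    if (nrow(object@coords) != length(object@sample_index))
      msg <- c(msg, "sample_index length must match coords rows")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Embedding2D", function(object) {
  cat(sprintf("Embedding2D: %d points, backend '%s'\n",
              nrow(object@coords), object@backend))
})

#' 2-D histogram of an embedding
#'
#' Binned density of embedding coordinates on a regular grid; bins are
#' half-open except the last, which is closed, so counts always sum to
#' the number of embedded points.
#'
#' @slot counts B x B numeric matrix of bin counts (x along rows).
#' @slot x_edges,y_edges Strictly increasing bin edges (length B + 1).
#' @export
setClass("Histogram2D",
  representation(counts = "matrix", x_edges = "numeric",
                 y_edges = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@x_edges) != nrow(object@counts) + 1 ||
        length(object@y_edges) != ncol(object@counts) + 1)
      msg <- c(msg, "edges must have length nbins + 1")
    if (any(diff(object@x_edges) <= 0) || any(diff(object@y_edges) <= 0))
      msg <- c(msg, "edges must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Histogram2D", function(object) {
  cat(sprintf("Histogram2D: %d x %d bins, %d points\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

# ---------------------------------------------------------------------------
# EndmemberSet
# ---------------------------------------------------------------------------

#' A set of endmember (characteristic) spectra
#'
#' K nonnegative spectra, one per material / biostructure class, with
#' provenance: either the mean spectrum of an annotated class or the
#' mean spectrum of pixels inside a bounding box around a local maximum
#' of the embedding histogram.
#'
#' @slot spectra K x n_channels nonnegative matrix, one endmember per row.
#' @slot labels Character vector of length K.
#' @slot provenance Character vector of length K ("annotation" or
#'   "embedding").
#' @slot boxes List of selection boxes in embedding space (possibly
#'   empty), each `c(x0, x1, y0, y1)`.
#' @export
setClass("EndmemberSet",
  representation(spectra = "matrix", labels = "character",
                 provenance = "character", boxes = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@spectra) < 1)
      msg <- c(msg, "at least one endmember is required")
    if (any(!is.finite(object@spectra)))
      msg <- c(msg, "endmember spectra must be finite")
    else if (any(object@spectra < 0))
      msg <- c(msg, "endmember spectra must be nonnegative")
    if (length(object@labels) != nrow(object@spectra))
      msg <- c(msg, "labels must have one entry per endmember")
    if (length(msg)) msg else TRUE
  })

#' @param spectra K x n_channels matrix (rows = endmembers).
#' @param labels Character labels (default "em1".."emK").
#' @param provenance Per-endmember provenance tag.
#' @param boxes Optional embedding-space selection boxes.
#' @rdname EndmemberSet-class
#' @export
EndmemberSet <- function(spectra, labels = NULL, provenance = "unspecified",
                         boxes = list()) {
  spectra <- as.matrix(spectra)
  if (is.null(labels)) labels <- paste0("em", seq_len(nrow(spectra)))
  if (length(provenance) == 1) provenance <- rep(provenance, nrow(spectra))
  new("EndmemberSet", spectra = spectra, labels = as.character(labels),
      provenance = provenance, boxes = boxes)
}

#' @param x An [EndmemberSet-class].
#' @return `emSpectra`: the K x n_channels matrix; `emLabels`: labels.
#' @rdname EndmemberSet-class
#' @export
emSpectra <- function(x) x@spectra

#' @rdname EndmemberSet-class
#' @export
emLabels <- function(x) x@labels

#' Number of endmembers
#' @param x An [EndmemberSet-class].
#' @export
nEndmembers <- function(x) nrow(x@spectra)

setMethod("show", "EndmemberSet", function(object) {
  cat(sprintf("EndmemberSet: %d endmembers x %d channels\n",
              nrow(object@spectra), ncol(object@spectra)))
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# AbundanceStack / DominantMap
# ---------------------------------------------------------------------------

#' Per-pixel endmember abundances
#'
#' Nonnegative least-squares coefficients for K endmembers at every
#' pixel, plus a global display scale: once finalised, `global_scale`
#' is the maximum coefficient across all tiles of the mosaic, so
#' `coeffs / global_scale` lies in [0, 1] everywhere and colours are
#' comparable between tiles.
#'
#' @slot coeffs 3-D array `[row, col, K]`, nonnegative.
#' @slot endmembers The [EndmemberSet-class] used for unmixing.
#' @slot global_scale Positive scalar, or `NA` before finalisation.
#' @slot tile_id Source tile identifier.
#' @export
setClass("AbundanceStack",
  representation(coeffs = "array", endmembers = "EndmemberSet",
                 global_scale = "numeric", tile_id = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coeffs)
    if (length(d) != 3)
      msg <- c(msg, "coeffs must be [row, col, K]")
    else if (d[3] != nrow(object@endmembers@spectra))
      msg <- c(msg, "third dimension must equal number of endmembers")
    if (any(object@coeffs < 0))
      msg <- c(msg, "abundances must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' @param stack An [AbundanceStack-class].
#' @return `abundances`: the `[row, col, K]` array; `globalScale`: the
#'   scale (NA before [finalizeScale()]).
#' @rdname AbundanceStack-class
#' @export
abundances <- function(stack) stack@coeffs

#' @rdname AbundanceStack-class
#' @export
globalScale <- function(stack) stack@global_scale

setMethod("show", "AbundanceStack", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("AbundanceStack: %d x %d px, %d endmembers, global scale %s\n",
              d[1], d[2], d[3],
              if (is.na(object@global_scale)) "unset"
              else format(object@global_scale)))
})

#' Dominant-endmember map
#'
#' Per-pixel argmax label over scaled abundances plus the winning
#' scaled abundance as intensity. Ties break to the lowest endmember
#' index; all-zero pixels get the reserved background label 0 and
#' intensity 0.
#'
#' @slot labels Integer matrix; 0 = background, k = endmember k.
#' @slot intensity Numeric matrix in [0, 1].
#' @slot tie_rule Documentation tag for the tie-break convention.
#' @export
setClass("DominantMap",
  representation(labels = "matrix", intensity = "matrix",
                 tie_rule = "character"))

setMethod("show", "DominantMap", function(object) {
  cat(sprintf("DominantMap: %d x %d px, %d classes present\n",
              nrow(object@labels), ncol(object@labels),
              length(setdiff(unique(as.vector(object@labels)), 0L))))
})

# ---------------------------------------------------------------------------
# DistanceCurves
# ---------------------------------------------------------------------------

#' Spectral distance versus frame accumulation
#'
#' Intra-class relative Euclidean distances and intra/inter distance
#' ratios as a function of accumulated frame count, used to find the
#' minimum number of frames after which class spectra stabilise.
#'
#' @slot frame_counts Strictly increasing frame counts.
#' @slot intra Matrix `[class, frame_count]` of relative intra-class
#'   distances.
#' @slot ratio Matrix `[class_pair, frame_count]` of intra/inter ratios.
#' @slot mean_ratio Numeric vector: arithmetic mean over class pairs.
#' @slot normalization Tag documenting the "relative" convention.
#' @export
setClass("DistanceCurves",
  representation(frame_counts = "numeric", intra = "matrix",
                 ratio = "matrix", mean_ratio = "numeric",
                 normalization = "character"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@frame_counts) <= 0))
      msg <- c(msg, "frame_counts must be strictly increasing")
    if (any(object@intra < 0, na.rm = TRUE))
      msg <- c(msg, "distances must be nonnegative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DistanceCurves", function(object) {
  cat(sprintf(
    "DistanceCurves: %d classes, %d frame counts (%g..%g), normalization '%s'\n",
    nrow(object@intra), length(object@frame_counts),
    min(object@frame_counts), max(object@frame_counts),
    object@normalization))
})

# ---------------------------------------------------------------------------
# PromptSet / SegmentationMasks
# ---------------------------------------------------------------------------

#' Point prompts for promptable segmentation
#'
#' Structure-labelled pixel coordinates derived from abundance maps
#' (blur, threshold, local maxima), to be fed to a promptable segmenter
#' as seed points.
#'
#' @slot points data.frame with columns `row`, `col`, `label`, `tile_id`;
#'   deduplicated, within image bounds.
#' @export
setClass("PromptSet",
  representation(points = "data.frame"),
  validity = function(object) {
    need <- c("row", "col", "label", "tile_id")
    if (!all(need %in% names(object@points)))
      return("points must have columns row, col, label, tile_id")
    if (anyDuplicated(object@points[, need]))
      return("prompt points must be deduplicated")
    TRUE
  })

#' @param points data.frame with columns `row`, `col`, and optionally
#'   `label`, `tile_id`.
#' @rdname PromptSet-class
#' @export
PromptSet <- function(points) {
  if (is.null(points$label)) points$label <- rep("structure", nrow(points))
  if (is.null(points$tile_id)) points$tile_id <- rep("", nrow(points))
  points <- unique(points[, c("row", "col", "label", "tile_id")])
  rownames(points) <- NULL
  new("PromptSet", points = points)
}

#' @param x A [PromptSet-class].
#' @rdname PromptSet-class
#' @export
promptPoints <- function(x) x@points

setMethod("show", "PromptSet", function(object) {
  cat(sprintf("PromptSet: %d prompts, %d structure label(s)\n",
              nrow(object@points), length(unique(object@points$label))))
})

#' Per-structure binary segmentation masks
#'
#' One logical mask per structure over a common extent, plus helpers to
#' composite them into a single label image using a precedence order.
#'
#' @slot masks Named list of logical matrices (same dim).
#' @slot labels Character vector of structure labels (names of masks).
#' @export
setClass("SegmentationMasks",
  representation(masks = "list", labels = "character"),
  validity = function(object) {
    if (!length(object@masks)) return("at least one mask required")
    dims <- lapply(object@masks, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      return("all masks must share the same shape")
    if (!all(vapply(object@masks, is.logical, TRUE)))
      return("masks must be logical")
    TRUE
  })

#' @param masks Named list of logical matrices.
#' @rdname SegmentationMasks-class
#' @export
SegmentationMasks <- function(masks) {
  labels <- names(masks)
  if (is.null(labels)) labels <- paste0("structure", seq_along(masks))
  names(masks) <- labels
  new("SegmentationMasks", masks = masks, labels = labels)
}

#' @param x A [SegmentationMasks-class].
#' @rdname SegmentationMasks-class
#' @export
maskList <- function(x) x@masks

setMethod("show", "SegmentationMasks", function(object) {
  d <- dim(object@masks[[1]])
  cat(sprintf("SegmentationMasks: %d structures on %d x %d px\n",
              length(object@masks), d[1], d[2]))
  for (l in object@labels)
    cat(sprintf("  %s: %d px\n", l, sum(object@masks[[l]])))
})
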