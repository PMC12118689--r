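# Endmember extraction via 2-D manifold embedding: multi-scale Gaussian
# feature augmentation, subsampling with overlap exclusion, embedding,
# 2-D histogramming, local-maxima selection, bounding-box averaging,
# and annotation-derived endmembers.

#' Feature-augmentation configuration
#'
#' Gaussian-blurred copies of the cube are concatenated to the base
#' spectra to inject spatial correlation into the embedding. The
#' default reading of "radii 1, 3, 5 with sigma = 2" is three Gaussian
#' filters truncated at radii 1, 3 and 5 bins, each with sigma = 2 px;
#' set `sigma_per_radius = TRUE` for the alternate reading (per-copy
#' sigma equal to the radius, conventional truncation).
#'
#' @param blur_radii Positive, distinct radii (default `c(1, 3, 5)`).
#' @param blur_sigma Gaussian sigma in px (default 2).
#' @param include_base Keep the unblurred spectra as features.
#' @param sigma_per_radius Alternate interpretation (see above).
#' @return A `feature_augment_config` list.
#' @export
featureAugmentConfig <- function(blur_radii = c(1, 3, 5), blur_sigma = 2,
                                 include_base = TRUE,
                                 sigma_per_radius = FALSE) {
  stopifnot(all(blur_radii > 0), !anyDuplicated(blur_radii), blur_sigma > 0)
  structure(list(blur_radii = blur_radii, blur_sigma = blur_sigma,
                 include_base = include_base,
                 sigma_per_radius = sigma_per_radius),
            class = "feature_augment_config")
}

#' Concatenate multi-scale Gaussian features to a cube's spectra
#'
#' Blurs every spectral band spatially at each configured radius, then
#' flattens base and blurred cubes side by side: the output has
#' `n_channels * (include_base + length(blur_radii))` features per
#' pixel, with row order identical to [flattenCube()].
#'
#' @param cube A preprocessed [HyperspectralCube-class].
#' @param cfg A [featureAugmentConfig()].
#' @return A [FlatPixelTable-class].
#' @export
augmentFeatures <- function(cube, cfg = featureAugmentConfig()) {
  stopifnot(is(cube, "HyperspectralCube"))
  base <- flattenCube(cube)
  blocks <- if (cfg$include_base) list(base@values) else list()
  d <- dim(cube@counts)
  for (rad in cfg$blur_radii) {
    if (cfg$sigma_per_radius) {
      sigma <- rad; radius <- ceiling(3 * rad)
    } else {
      sigma <- cfg$blur_sigma; radius <- rad
    }
    radius <- min(radius, min(d[1:2]) - 1L)
    k <- gaussianKernel1d(radius, sigma)
    blurred <- matrix(0, d[1] * d[2], d[3])
    for (ch in seq_len(d[3]))
      blurred[, ch] <- as.vector(convSeparable(cube@counts[, , ch], k))
    blocks <- c(blocks, list(blurred))
  }
  if (!length(blocks)) stop("no features selected")
  FlatPixelTable(do.call(cbind, blocks), base@origin)
}

#' Subsample pixels from a flat table
#'
#' Uniform random sample without replacement of a fraction of rows,
#' optionally excluding pixels under a mask (e.g. mosaic overlap
#' regions). Reproducible from the seed; origin mapping retained.
#'
#' @param table A [FlatPixelTable-class].
#' @param fraction Sampling fraction in (0, 1].
#' @param exclude_mask Optional logical matrix indexed by `(row, col)`
#'   of the source tile; TRUE pixels are never sampled.
#' @param seed Integer RNG seed.
#' @return A [FlatPixelTable-class] with `round(fraction * pool)` rows.
#' @export
subsamplePixels <- function(table, fraction, exclude_mask = NULL, seed = 1) {
  stopifnot(is(table, "FlatPixelTable"), fraction > 0, fraction <= 1)
  pool <- seq_len(nrow(table@values))
  if (!is.null(exclude_mask)) {
    org <- table@origin
    masked <- exclude_mask[cbind(org$row, org$col)]
    pool <- pool[!masked]
  }
  if (!length(pool)) stop("empty sampling pool after exclusion")
  n <- max(1L, round(fraction * length(pool)))
  keep <- sort(withSeed(seed, sample(pool, n)))
  FlatPixelTable(table@values[keep, , drop = FALSE],
                 {
                   o <- table@origin[keep, , drop = FALSE]
                   rownames(o) <- NULL
                   o
                 })
}

#' Embed pixel features in two dimensions
#'
#' Reduces an N x F table to N x 2 behind a pluggable backend contract
#' (any deterministic map N x F -> N x 2). Backends:
#' \describe{
#'   \item{`"umap"`}{(default) Uniform Manifold Approximation and
#'     Projection via the Python \code{umap-learn} package through a
#'     subprocess bridge, after a PCA pre-reduction to `pca_dims`
#'     dimensions. A neighbour-graph method of this family is what the
#'     workflow relies on: it keeps well-separated spectral classes
#'     separated in 2-D where purely distance-preserving projections
#'     crowd them together. Deterministic for a fixed seed.}
#'   \item{`"sammon"`}{Sammon's nonlinear mapping
#'     (\code{MASS::sammon}) on Euclidean distances after the PCA
#'     pre-reduction, initialised from classical MDS; a pure-R
#'     alternate that preserves global distance structure. Exact
#'     duplicate rows are collapsed before the mapping and
#'     re-expanded, so duplicates always receive identical
#'     coordinates.}
#'   \item{`"pca"`}{The first two principal components; cheapest fully
#'     deterministic projection.}
#' }
#'
#' @param table A [FlatPixelTable-class] with at least 3 rows.
#' @param backend `"umap"`, `"sammon"` or `"pca"`.
#' @param pca_dims Pre-reduction dimensionality for `"umap"` and
#'   `"sammon"` (default 50).
#' @param niter Maximum Sammon iterations (default 100).
#' @param n_neighbors,min_dist UMAP graph size and layout compactness
#'   (defaults 15 and 0.1, the upstream defaults).
#' @param seed Integer seed, recorded in the result (all backends are
#'   deterministic given the input and seed).
#' @return An [Embedding2D-class].
#' @export
embedPixels <- function(table, backend = c("umap", "sammon", "pca"),
                        pca_dims = 50, niter = 100, n_neighbors = 15,
                        min_dist = 0.1, seed = 1) {
  backend <- match.arg(backend)
  stopifnot(is(table, "FlatPixelTable"))
  X <- table@values
  if (nrow(X) < 3) stop("embedding needs at least 3 pixels")
  coords <- switch(backend,
    umap = {
      ndim <- min(pca_dims, ncol(X), nrow(X) - 1L)
      Xr <- if (ncol(X) > ndim)
        unname(prcomp(X, center = TRUE, rank. = ndim)$x)
      else unname(scale(X, center = TRUE, scale = FALSE))
      .umapBridge(Xr, n_neighbors = n_neighbors, min_dist = min_dist,
                  seed = seed)
    },
    pca = {
      pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
      sc <- pc$x
      if (ncol(sc) < 2) sc <- cbind(sc, 0)[, 1:2, drop = FALSE]
      unname(sc)
    },
    sammon = {
      ndim <- min(pca_dims, ncol(X), nrow(X) - 1L)
      Xr <- if (ncol(X) > ndim)
        unname(prcomp(X, center = TRUE, rank. = ndim)$x)
      else scale(X, center = TRUE, scale = FALSE)
      key <- apply(Xr, 1, paste, collapse = "\r")
      uniq <- !duplicated(key)
      Xu <- Xr[uniq, , drop = FALSE]
      map <- match(key, key[uniq])
      if (nrow(Xu) < 3) {
        cu <- cbind(seq_len(nrow(Xu)) - 1, 0)
      } else {
        d <- dist(Xu)
        init <- cmdscale(d, k = 2)
        if (ncol(init) < 2) init <- cbind(init, 0)[, 1:2, drop = FALSE]
        # cmdscale can return exactly collinear points; nudge deterministically
        if (any(apply(init, 2, function(v) diff(range(v))) == 0))
          init <- init + withSeed(seed, matrix(rnorm(length(init), sd = 1e-8),
                                               nrow(init)))
        cu <- withSeed(seed,
          MASS::sammon(d, y = init, niter = niter, trace = FALSE)$points)
      }
      unname(cu[map, , drop = FALSE])
    })
  new("Embedding2D", coords = coords,
      sample_index = seq_len(nrow(X)), origin = table@origin,
      backend = backend,
      params = list(pca_dims = pca_dims, niter = niter,
                    n_neighbors = n_neighbors, min_dist = min_dist),
      seed = as.integer(seed))
}

# run the packaged umap-learn bridge script on a numeric matrix
.umapBridge <- function(X, n_neighbors, min_dist, seed) {
  python <- Sys.which("python")
  if (python == "")
    stop("the 'umap' backend needs a 'python' executable with umap-learn ",
         "on the PATH; use backend = \"sammon\" otherwise")
  script <- system.file("python", "umap_embed.py", package = "EDXUnmix")
  if (script == "") stop("bundled umap_embed.py not found")
  infile <- tempfile(fileext = ".f64")
  outfile <- tempfile(fileext = ".f64")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  con <- file(infile, "wb")
  writeBin(as.double(t(X)), con, size = 8L, endian = "little")  # row-major
  close(con)
  status <- system2(python, c(shQuote(script), shQuote(infile), nrow(X),
                              ncol(X), shQuote(outfile), as.integer(seed),
                              n_neighbors, min_dist),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile))
    stop("umap bridge failed (exit status ", status,
         "); is umap-learn importable from 'python'?")
  con <- file(outfile, "rb")
  co <- readBin(con, "double", n = 2L * nrow(X), size = 8L,
                endian = "little")
  close(con)
  matrix(co, ncol = 2, byrow = TRUE)
}

#' 2-D histogram of embedding coordinates
#'
#' Regular `bins x bins` grid over the coordinate range; bins are
#' half-open `[lo, hi)` except the last, which is closed, so the counts
#' always sum to the number of points.
#'
#' @param embedding An [Embedding2D-class].
#' @param bins Number of bins per axis (default 256, >= 2).
#' @return A [Histogram2D-class].
#' @export
histogram2d <- function(embedding, bins = 256) {
  stopifnot(is(embedding, "Embedding2D"), bins >= 2)
  xy <- embedding@coords
  mk_edges <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  xe <- mk_edges(xy[, 1]); ye <- mk_edges(xy[, 2])
  ix <- findInterval(xy[, 1], xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2], ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(tabulate(ix + (iy - 1L) * bins, nbins = bins * bins),
                   bins, bins)
  new("Histogram2D", counts = counts, x_edges = xe, y_edges = ye)
}

#' Local maxima of an embedding histogram
#'
#' Finds local maxima of the (optionally smoothed) bin counts with
#' [findLocalMaxima()] semantics; with `exclude_central_bulk` the maxima
#' lying inside the global-mode plateau (the connected region of bins
#' with at least `bulk_frac` of the peak count containing the global
#' mode) are suppressed — an automated stand-in for interactively
#' picking maxima at the extremities of protrusions from the primary
#' cluster.
#'
#' @param hist A [Histogram2D-class].
#' @param min_distance_bins Minimum separation between maxima (bins).
#' @param min_count Minimum (smoothed) count for a maximum.
#' @param exclude_central_bulk Suppress maxima in the global-mode
#'   plateau.
#' @param smooth_sigma Gaussian smoothing of the counts before peak
#'   picking (bins; 0 = none).
#' @param bulk_frac Plateau level as a fraction of the global peak
#'   (default 0.5).
#' @return data.frame with bin indices (`bin_row`, `bin_col`), the bin
#'   count, and embedding-space bin centers (`x`, `y`).
#' @export
findHistogramMaxima <- function(hist, min_distance_bins = 5, min_count = 1,
                                exclude_central_bulk = FALSE,
                                smooth_sigma = 0, bulk_frac = 0.5) {
  stopifnot(is(hist, "Histogram2D"))
  counts <- hist@counts
  if (smooth_sigma > 0) counts <- gaussianBlur(counts, smooth_sigma)
  pk <- findLocalMaxima(counts, min_distance = min_distance_bins,
                        min_value = min_count)
  if (exclude_central_bulk && nrow(pk)) {
    mode_idx <- which(counts == max(counts), arr.ind = TRUE)[1, ]
    bulk <- counts >= bulk_frac * max(counts)
    lab <- labelConnected(bulk)
    bulk_lab <- lab[mode_idx[1], mode_idx[2]]
    inside <- lab[cbind(pk$row, pk$col)] == bulk_lab
    pk <- pk[!inside, , drop = FALSE]
  }
  xc <- (hist@x_edges[-1] + head(hist@x_edges, -1)) / 2
  yc <- (hist@y_edges[-1] + head(hist@y_edges, -1)) / 2
  data.frame(bin_row = pk$row, bin_col = pk$col, count = pk$value,
             x = xc[pk$row], y = yc[pk$col], row.names = NULL)
}

#' Embedding-space bounding boxes around histogram maxima
#'
#' @param hist A [Histogram2D-class].
#' @param maxima data.frame from [findHistogramMaxima()].
#' @param halfwidth_bins Box half-width in bins (default 2).
#' @return List of boxes `c(x0, x1, y0, y1)` (closed intervals).
#' @export
boxesAroundMaxima <- function(hist, maxima, halfwidth_bins = 2) {
  B <- nrow(hist@counts)
  lapply(seq_len(nrow(maxima)), function(i) {
    r0 <- max(1L, maxima$bin_row[i] - halfwidth_bins)
    r1 <- min(B, maxima$bin_row[i] + halfwidth_bins)
    c0 <- max(1L, maxima$bin_col[i] - halfwidth_bins)
    c1 <- min(ncol(hist@counts), maxima$bin_col[i] + halfwidth_bins)
    c(x0 = hist@x_edges[r0], x1 = hist@x_edges[r1 + 1L],
      y0 = hist@y_edges[c0], y1 = hist@y_edges[c1 + 1L])
  })
}

#' Average the raw spectra of pixels falling in embedding-space boxes
#'
#' Endmember k is the arithmetic mean of the raw (un-augmented)
#' spectra of the pixels whose embedding coordinates fall in box k.
#' The raw spectra are looked up in `table` by pixel origin, so `table`
#' must cover every pixel that was embedded.
#'
#' @param table [FlatPixelTable-class] of raw preprocessed spectra
#'   (not augmented).
#' @param boxes List of boxes `c(x0, x1, y0, y1)`.
#' @param embedding The [Embedding2D-class] the boxes refer to.
#' @param labels Optional endmember labels.
#' @return An [EndmemberSet-class] with provenance `"embedding"`.
#' @export
endmembersFromBoxes <- function(table, boxes, embedding, labels = NULL) {
  stopifnot(is(table, "FlatPixelTable"), is(embedding, "Embedding2D"))
  if (!length(boxes)) stop("no boxes supplied")
  tkey <- paste(table@origin$tile_id, table@origin$row, table@origin$col)
  ekey <- paste(embedding@origin$tile_id, embedding@origin$row,
                embedding@origin$col)
  rows_in_table <- match(ekey, tkey)
  if (anyNA(rows_in_table))
    stop("embedding contains pixels absent from the raw spectra table")
  xy <- embedding@coords
  spectra <- matrix(0, length(boxes), ncol(table@values))
  for (k in seq_along(boxes)) {
    b <- boxes[[k]]
    sel <- xy[, 1] >= b[1] & xy[, 1] <= b[2] &
           xy[, 2] >= b[3] & xy[, 2] <= b[4]
    if (!any(sel))
      stop("box ", k, " (x [", format(b[1]), ", ", format(b[2]),
           "], y [", format(b[3]), ", ", format(b[4]),
           "]) contains no sampled pixels")
    spectra[k, ] <- colMeans(table@values[rows_in_table[sel], ,
                                          drop = FALSE])
  }
  if (is.null(labels)) labels <- paste0("em", seq_along(boxes))
  EndmemberSet(spectra, labels = labels, provenance = "embedding",
               boxes = boxes)
}

#' Endmembers from sparse manual annotations
#'
#' One endmember per annotated class: the mean spectrum over that
#' class's pixels.
#'
#' @param cube A [HyperspectralCube-class].
#' @param annotations An [AnnotationSet-class].
#' @return An [EndmemberSet-class] with provenance `"annotation"`.
#' @export
endmembersFromAnnotations <- function(cube, annotations) {
  stopifnot(is(cube, "HyperspectralCube"), is(annotations, "AnnotationSet"))
  px <- annotations@pixels
  if (!nrow(px)) stop("annotation set is empty")
  d <- dim(cube@counts)
  if (any(px$row > d[1]) || any(px$col > d[2]))
    stop("annotated pixels outside cube bounds")
  labs <- unique(px$label)
  flat <- matrix(cube@counts, d[1] * d[2], d[3])
  spectra <- t(vapply(labs, function(l) {
    sel <- px[px$label == l, ]
    colMeans(flat[sel$row + (sel$col - 1L) * d[1], , drop = FALSE])
  }, numeric(d[3])))
  EndmemberSet(spectra, labels = labs, provenance = "annotation")
}

#' Full embedding-driven endmember discovery
#'
#' Convenience composition of the extraction stages: feature
#' augmentation, subsampling (with optional overlap exclusion), 2-D
#' embedding, histogramming, automated local-maxima selection, and
#' bounding-box averaging of raw spectra.
#'
#' @param cube Preprocessed [HyperspectralCube-class].
#' @param fraction Subsample fraction (default 0.2).
#' @param exclude_mask Optional overlap mask (TRUE = excluded).
#' @param seed RNG seed for the subsample.
#' @param backend Embedding backend (see [embedPixels()]).
#' @param bins Histogram bins per axis; `NULL` (default) adapts to the
#'   sample size as `ceiling(sqrt(N))`, at least 16, so bin occupancy
#'   stays informative from desk scale up to full mosaics.
#' @param min_distance_bins Minimum maxima separation; `NULL` adapts to
#'   `bins %/% 8` (at least 2).
#' @param min_count Minimum smoothed count; `NULL` adapts to
#'   `0.001 * N` (at least 2).
#' @param smooth_sigma,exclude_central_bulk Passed to
#'   [findHistogramMaxima()].
#' @param box_halfwidth_bins Endmember box half-width (default 2).
#' @param dedup_cosine Merge endmembers whose spectra exceed this
#'   cosine similarity, keeping the one under the denser maximum
#'   (default 0.999; `NULL` disables). The permissive `min_count`
#'   default admits shoulder maxima of dense clusters; deduplication
#'   removes the resulting near-identical spectra.
#' @param augment_cfg A [featureAugmentConfig()].
#' @return List with `endmembers`, `embedding`, `hist`, `maxima`.
#' @export
discoverEndmembers <- function(cube, fraction = 0.2, exclude_mask = NULL,
                               seed = 1, backend = "umap", bins = NULL,
                               min_distance_bins = NULL, min_count = NULL,
                               smooth_sigma = 1,
                               exclude_central_bulk = FALSE,
                               box_halfwidth_bins = 2,
                               dedup_cosine = 0.999,
                               augment_cfg = featureAugmentConfig()) {
  aug <- augmentFeatures(cube, augment_cfg)
  sub <- subsamplePixels(aug, fraction, exclude_mask, seed = seed)
  emb <- embedPixels(sub, backend = backend, seed = seed)
  N <- nrow(emb@coords)
  if (is.null(bins)) bins <- max(16L, ceiling(sqrt(N)))
  if (is.null(min_distance_bins)) min_distance_bins <- max(2L, bins %/% 8L)
  if (is.null(min_count)) min_count <- max(2, 0.001 * N)
  hist <- histogram2d(emb, bins = bins)
  maxima <- findHistogramMaxima(hist, min_distance_bins = min_distance_bins,
                                min_count = min_count,
                                smooth_sigma = smooth_sigma,
                                exclude_central_bulk = exclude_central_bulk)
  if (!nrow(maxima)) stop("no histogram maxima found; lower min_count")
  boxes <- boxesAroundMaxima(hist, maxima, box_halfwidth_bins)
  raw <- flattenCube(cube)
  em <- endmembersFromBoxes(raw, boxes, emb)
  if (!is.null(dedup_cosine) && nEndmembers(em) > 1) {
    # maxima (and hence spectra) are ordered by decreasing bin count
    E <- emSpectra(em)
    keep <- 1L
    for (k in 2:nrow(E)) {
      sims <- vapply(keep, function(j) cosineSimilarity(E[k, ], E[j, ]),
                     numeric(1))
      if (all(sims < dedup_cosine)) keep <- c(keep, k)
    }
    em <- EndmemberSet(E[keep, , drop = FALSE],
                       labels = paste0("em", seq_along(keep)),
                       provenance = "embedding", boxes = boxes[keep])
    maxima <- maxima[keep, , drop = FALSE]
  }
  list(endmembers = em, embedding = emb, hist = hist, maxima = maxima)
}
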