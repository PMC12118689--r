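# Linear spectral unmixing: per-pixel non-negative least squares
# against an endmember set, global abundance scaling, dominant-
# endmember maps, per-channel endmember Z-scores, image export.

#' Non-negative least-squares unmixing
#'
#' For every pixel spectrum s solves `min || E a - s ||_2` subject to
#' `a >= 0`, where the columns of E are the endmember spectra
#' (Lawson-Hanson active set via \code{pracma::lsqnonneg}). No
#' sum-to-one constraint is imposed; display scaling is handled by
#' [finalizeScale()]. Deterministic.
#'
#' @param x A [HyperspectralCube-class] or a `[pixel, channel]` matrix.
#' @param endmembers An [EndmemberSet-class] whose channel count
#'   matches `x`.
#' @param ... Unused.
#' @return For a cube: an [AbundanceStack-class] (global scale unset).
#'   For a matrix: a `[pixel, K]` coefficient matrix.
#' @export
setGeneric("nnlsUnmix", function(x, endmembers, ...)
  standardGeneric("nnlsUnmix"))

.nnlsMatrix <- function(S, E) {
  # S: [pixel, channel]; E: [channel, K]
  if (ncol(S) != nrow(E))
    stop("channel count mismatch: spectra have ", ncol(S),
         " channels, endmembers ", nrow(E))
  if (qr(E)$rank < ncol(E))
    warning("endmember matrix is rank deficient; abundances may be unstable")
  K <- ncol(E)
  out <- matrix(0, nrow(S), K)
  for (i in seq_len(nrow(S))) {
    a <- tryCatch(pracma::lsqnonneg(E, S[i, ])$x,
                  error = function(e) NULL)
    # the active-set solver can cycle on exact-fit (noiseless) pixels;
    # fall back to exact support enumeration, valid for small K
    if (is.null(a)) a <- .nnlsEnumerate(E, S[i, ])
    out[i, ] <- a
  }
  out
}

# Exact NNLS by enumerating candidate supports: the optimum of a
# nonnegative least-squares problem is the unconstrained LS solution on
# some subset of columns with nonnegative coefficients. Exponential in
# K, used only as a robustness fallback for small endmember counts.
.nnlsEnumerate <- function(E, s) {
  K <- ncol(E)
  if (K > 12) stop("NNLS fallback supports at most 12 endmembers")
  best <- rep(0, K)
  best_res <- sum(s^2)
  for (bits in seq_len(2^K - 1)) {
    sel <- which(bitwAnd(bits, 2^(seq_len(K) - 1)) > 0)
    a_sel <- tryCatch(qr.solve(E[, sel, drop = FALSE], s),
                      error = function(e) NULL)
    if (is.null(a_sel) || any(a_sel < 0)) next
    res <- sum((E[, sel, drop = FALSE] %*% a_sel - s)^2)
    if (res < best_res - 1e-12) {
      best_res <- res
      best <- rep(0, K)
      best[sel] <- a_sel
    }
  }
  best
}

#' @rdname nnlsUnmix
#' @export
setMethod("nnlsUnmix", "matrix", function(x, endmembers, ...) {
  stopifnot(is(endmembers, "EndmemberSet"))
  .nnlsMatrix(x, t(endmembers@spectra))
})

#' @rdname nnlsUnmix
#' @export
setMethod("nnlsUnmix", "HyperspectralCube", function(x, endmembers, ...) {
  stopifnot(is(endmembers, "EndmemberSet"))
  d <- dim(x@counts)
  coeffs <- .nnlsMatrix(matrix(x@counts, d[1] * d[2], d[3]),
                        t(endmembers@spectra))
  new("AbundanceStack",
      coeffs = array(coeffs, dim = c(d[1], d[2], ncol(coeffs))),
      endmembers = endmembers, global_scale = NA_real_,
      tile_id = x@tile_id)
})

#' Finalise the global abundance scale across tiles
#'
#' Sets one shared `global_scale` — the maximum coefficient anywhere in
#' the mosaic — on every stack, so scaled abundances are in [0, 1] and
#' colours are comparable between tiles.
#'
#' @param stacks A single [AbundanceStack-class] or a list of them.
#' @return The input with `global_scale` set (list in, list out).
#' @export
finalizeScale <- function(stacks) {
  single <- is(stacks, "AbundanceStack")
  if (single) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1,
            all(vapply(stacks, is, TRUE, "AbundanceStack")))
  gmax <- max(vapply(stacks, function(s) max(s@coeffs), numeric(1)))
  if (gmax <= 0) gmax <- 1  # all-zero mosaic: scale is moot
  out <- lapply(stacks, function(s) initialize(s, global_scale = gmax))
  if (single) out[[1]] else out
}

#' Scaled abundances of a finalised stack
#' @param stack A finalised [AbundanceStack-class].
#' @return Array `[row, col, K]` in [0, 1].
#' @export
scaledAbundances <- function(stack) {
  if (is.na(stack@global_scale))
    stop("abundance stack is not finalised; call finalizeScale() first")
  stack@coeffs / stack@global_scale
}

#' Dominant-endmember map
#'
#' Per pixel, the endmember with the highest abundance (ties break to
#' the lowest index) and the winning scaled abundance as intensity;
#' all-zero pixels receive the reserved background label 0 and
#' intensity 0.
#'
#' @param stack A finalised [AbundanceStack-class].
#' @return A [DominantMap-class].
#' @export
dominantMap <- function(stack) {
  sc <- scaledAbundances(stack)
  d <- dim(sc)
  flat <- matrix(sc, d[1] * d[2], d[3])
  lab <- max.col(flat, ties.method = "first")
  top <- flat[cbind(seq_len(nrow(flat)), lab)]
  lab[top == 0] <- 0L
  new("DominantMap",
      labels = matrix(as.integer(lab), d[1], d[2]),
      intensity = matrix(top, d[1], d[2]),
      tie_rule = "lowest-index; all-zero -> background 0")
}

#' Per-channel Z-scores of an endmember set
#'
#' For each channel c, `z_k(c) = (e_k(c) - mean_k e_k(c)) / sd_k e_k(c)`
#' using the population standard deviation over the K endmembers;
#' channels with zero spread map to 0 by convention. This is the
#' fingerprint heatmap showing which channels distinguish each
#' endmember.
#'
#' @param endmembers An [EndmemberSet-class] with K >= 2.
#' @return K x n_channels matrix; each column has mean 0 (and unit
#'   population sd where the input spread is nonzero).
#' @export
endmemberZscores <- function(endmembers) {
  stopifnot(is(endmembers, "EndmemberSet"))
  E <- endmembers@spectra
  K <- nrow(E)
  if (K < 2) stop("Z-scores need at least 2 endmembers")
  mu <- colMeans(E)
  sdp <- sqrt(colMeans(sweep(E, 2, mu)^2))  # population sd
  Z <- sweep(E, 2, mu)
  nz <- sdp > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sdp[nz], "/")
  Z[, !nz] <- 0
  dimnames(Z) <- list(endmembers@labels, NULL)
  Z
}

#' Export abundance maps as images
#'
#' Produces one grayscale map per endmember (scaled abundance;
#' optionally inverted so low abundance is white and high is black)
#' and a composite colour image from the dominant map (pixel colour =
#' colour of the most abundant endmember, intensity = its scaled
#' abundance). If `dir` is given, grayscale maps are written as 32-bit
#' float TIFF and the composite as 8-bit PNG.
#'
#' @param stack A finalised [AbundanceStack-class].
#' @param colors Colour per endmember (any R colour spec); defaults to
#'   a qualitative palette.
#' @param invert Map low->white, high->black in the grayscale exports.
#' @param dir Optional output directory.
#' @return List with `grayscale` (list of matrices in [0,1]),
#'   `composite` (H x W x 3 array in [0,1]), and `files` (paths, if
#'   written).
#' @export
abundanceToImages <- function(stack, colors = NULL, invert = FALSE,
                              dir = NULL) {
  sc <- scaledAbundances(stack)
  K <- dim(sc)[3]
  labels <- stack@endmembers@labels
  if (is.null(colors))
    colors <- grDevices::hcl.colors(max(K, 3), "Dark 3")[seq_len(K)]
  gray <- lapply(seq_len(K), function(k) {
    g <- sc[, , k]
    if (invert) 1 - g else g
  })
  names(gray) <- labels
  dm <- dominantMap(stack)
  rgbmat <- grDevices::col2rgb(colors) / 255
  comp <- array(0, dim = c(dim(sc)[1], dim(sc)[2], 3))
  for (k in seq_len(K)) {
    sel <- dm@labels == k
    for (ch in 1:3) {
      plane <- comp[, , ch]
      plane[sel] <- rgbmat[ch, k] * dm@intensity[sel]
      comp[, , ch] <- plane
    }
  }
  files <- character()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(K)) {
      f <- file.path(dir, paste0("abundance_", labels[k], ".tif"))
      tiff::writeTIFF(gray[[k]], f, bits.per.sample = 32L)
      files <- c(files, f)
    }
    f <- file.path(dir, "composite.png")
    png::writePNG(comp, f)
    files <- c(files, f)
  }
  list(grayscale = gray, composite = comp, files = files)
}
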