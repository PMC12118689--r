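# Internal numeric helpers: seeded evaluation, separable filtering with
# mirrored borders, local-maximum detection, flood fill.

# Evaluate expr with a temporary RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Indices implementing mirrored ("symmetric", edge included) padding of
# 1..n by p samples on each side: (p..1, 1..n, n..n-p+1).
reflectIndex <- function(n, p) {
  if (p == 0) return(seq_len(n))
  if (p > n) stop("padding exceeds image size")
  c(rev(seq_len(p)), seq_len(n), seq.int(n, n - p + 1L))
}

# Separable 2-D convolution of matrix `img` with a 1-D kernel applied
# along rows then columns; mirrored borders.
convSeparable <- function(img, kernel) {
  p <- (length(kernel) - 1L) %/% 2L
  if (p == 0) return(img * kernel)
  n <- nrow(img); m <- ncol(img)
  # rows
  pad <- img[reflectIndex(n, p), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[seq_len(n) + (j - 1L), , drop = FALSE]
  # cols
  pad <- out[, reflectIndex(m, p), drop = FALSE]
  out2 <- matrix(0, n, m)
  for (j in seq_along(kernel))
    out2 <- out2 + kernel[j] * pad[, seq_len(m) + (j - 1L), drop = FALSE]
  out2
}

# Normalized Gaussian kernel truncated at `radius` bins with the given sigma.
gaussianKernel1d <- function(radius, sigma) {
  stopifnot(radius >= 0, sigma > 0)
  k <- dnorm(seq.int(-radius, radius), sd = sigma)
  k / sum(k)
}

# Gaussian blur of a matrix (separable, mirrored borders). Truncation
# radius defaults to ceiling(3 * sigma) as is conventional.
gaussianBlur <- function(img, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(img)
  radius <- min(radius, min(dim(img)) - 1L)
  convSeparable(img, gaussianKernel1d(radius, sigma))
}

# Normalized box (mean) kernel of odd width k.
boxKernel1d <- function(k) {
  stopifnot(k >= 1, k %% 2 == 1)
  rep(1 / k, k)
}

#' Find local maxima of a 2-D map
#'
#' A pixel is a candidate when its value is at least `min_value` and
#' equals the maximum over the Chebyshev window of radius `min_distance`
#' centred on it. Plateaus (connected candidates sharing the window
#' maximum) are collapsed to their rounded centroid. Candidates closer
#' than `min_distance` are then greedily suppressed in order of
#' decreasing value (ties: smaller row, then smaller column first).
#'
#' @param img Numeric matrix.
#' @param min_distance Chebyshev window radius in pixels (>= 1).
#' @param min_value Minimum value for a maximum to be reported.
#' @return data.frame with columns `row`, `col`, `value`, ordered by
#'   decreasing value.
#' @export
findLocalMaxima <- function(img, min_distance = 1L, min_value = -Inf) {
  stopifnot(is.matrix(img), min_distance >= 1)
  n <- nrow(img); m <- ncol(img)
  d <- as.integer(min_distance)
  # window maximum by dilation with shifted copies over an edge-padded image
  pad <- matrix(-Inf, n + 2L * d, m + 2L * d)
  pad[seq_len(n) + d, seq_len(m) + d] <- img
  wmax <- matrix(-Inf, n, m)
  for (dr in seq.int(-d, d)) for (dc in seq.int(-d, d))
    wmax <- pmax(wmax, pad[seq_len(n) + d + dr, seq_len(m) + d + dc])
  cand <- which(img == wmax & img >= min_value, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  # collapse connected plateau candidates (8-connectivity) to centroids
  candmask <- matrix(FALSE, n, m)
  candmask[cand] <- TRUE
  lab <- labelConnected(candmask)
  ids <- lab[cand]
  cr <- tapply(cand[, 1], ids, function(v) as.integer(round(mean(v))))
  cc <- tapply(cand[, 2], ids, function(v) as.integer(round(mean(v))))
  vv <- tapply(img[cand], ids, max)
  pk <- data.frame(row = as.integer(cr), col = as.integer(cc),
                   value = as.numeric(vv))
  pk <- pk[order(-pk$value, pk$row, pk$col), , drop = FALSE]
  # greedy non-maximum suppression at Chebyshev distance < min_distance
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    ok <- TRUE
    if (any(keep)) {
      kr <- pk$row[keep]; kc <- pk$col[keep]
      if (any(pmax(abs(kr - pk$row[i]), abs(kc - pk$col[i])) < d)) ok <- FALSE
    }
    keep[i] <- ok
  }
  out <- pk[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Label connected components (8-connectivity) of a logical matrix with a
# stack-based flood fill. Returns an integer matrix, 0 = background.
labelConnected <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nextlab <- 0L
  stack <- integer(max(1L, sum(mask)))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nextlab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% n + 1L
      c <- (cur - 1L) %/% n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= m) {
          j <- rr + (cc - 1L) * n
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nextlab
            top <- top + 1L
            stack[top] <- j
          }
        }
      }
    }
  }
  lab
}

# Cosine similarity between two nonzero vectors.
cosineSimilarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
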