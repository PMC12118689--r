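# Shared fixture builders: tiny cubes and phantoms generated in code.

tinyAxis <- function(n = 32, offset = 40, width = 80) {
  EnergyAxis(offset_ev = offset, bin_width_ev = width, n_channels = n)
}

# deterministic random integer cube
randomCube <- function(rows = 8, cols = 8, channels = 32, seed = 7,
                       lambda = 5) {
  counts <- withr::with_seed(seed,
    array(rpois(rows * cols * channels, lambda),
          dim = c(rows, cols, channels)))
  HyperspectralCube(counts, tinyAxis(channels), pixel_size_nm = 4,
                    n_frames = 10, dwell_us = 100)
}

# two-structure phantom with pure pixels: a disk and background
twoClassSpec <- function(rows = 32, cols = 32, channels = 24,
                         counts = 300, n_frames = 4, seed = 11) {
  m <- cannedSpectralModels()
  phantomSpec(
    c(rows, cols),
    list(
      phantomStructure("granule", m$insulin,
        list(list(type = "disk", center = c(rows / 2, cols / 2),
                  radius = rows / 4))),
      phantomStructure("background", m$background,
        list(list(type = "background")))),
    counts_per_pixel_per_frame = counts, n_frames = n_frames, seed = seed,
    energy = tinyAxis(channels))
}

# three well-separated spectral classes as disks on background
threeClassSpec <- function(rows = 48, cols = 48, channels = 32,
                           counts = 400, n_frames = 8, seed = 5) {
  m <- cannedSpectralModels()
  phantomSpec(
    c(rows, cols),
    list(
      phantomStructure("granule", m$insulin,
        list(list(type = "disk", center = c(13, 13), radius = 8))),
      phantomStructure("nucleus", m$nucleic_acids,
        list(list(type = "ellipse", center = c(33, 30), semi_axes = c(9, 7)))),
      phantomStructure("membrane", m$membranes,
        list(list(type = "disk", center = c(13, 36), radius = 7))),
      phantomStructure("background", m$background,
        list(list(type = "background")))),
    counts_per_pixel_per_frame = counts, n_frames = n_frames, seed = seed,
    energy = tinyAxis(channels))
}

# brute-force local-maxima oracle: exhaustive window scan, then the same
# greedy suppression rule, implemented independently with plain loops
oracleLocalMaxima <- function(img, d, min_value = -Inf) {
  n <- nrow(img); m <- ncol(img)
  cand <- list()
  for (r in seq_len(n)) for (c_ in seq_len(m)) {
    v <- img[r, c_]
    if (v < min_value) next
    rr <- max(1, r - d):min(n, r + d)
    cc <- max(1, c_ - d):min(m, c_ + d)
    if (v >= max(img[rr, cc]))
      cand[[length(cand) + 1]] <- c(r, c_, v)
  }
  if (!length(cand))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  pk <- do.call(rbind, cand)
  pk <- data.frame(row = pk[, 1], col = pk[, 2], value = pk[, 3])
  pk <- pk[order(-pk$value, pk$row, pk$col), ]
  keep <- rep(FALSE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    ok <- TRUE
    for (j in which(keep))
      if (max(abs(pk$row[j] - pk$row[i]), abs(pk$col[j] - pk$col[i])) < d)
        ok <- FALSE
    keep[i] <- ok
  }
  out <- pk[keep, ]
  rownames(out) <- NULL
  out
}
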