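test_that("feature augmentation multiplies the channel count", {
  cube <- randomCube(8, 8, 25)
  aug <- augmentFeatures(cube)  # radii 1, 3, 5 -> 4x features
  expect_equal(ncol(tableValues(aug)), 25 * 4)
  expect_equal(tableOrigin(aug), tableOrigin(flattenCube(cube)))

  # no radii with base kept: identity
  none <- augmentFeatures(cube, featureAugmentConfig(blur_radii = numeric(),
                                                     include_base = TRUE))
  expect_equal(tableValues(none), tableValues(flattenCube(cube)))

  # constant cube: blurred copies equal the base everywhere
  const <- HyperspectralCube(array(2, dim = c(8, 8, 3)), tinyAxis(3))
  aug2 <- tableValues(augmentFeatures(const))
  expect_true(all(abs(aug2 - 2) < 1e-12))

  # the acquisition-scale contract: 250 channels -> 1000 features
  cfg <- featureAugmentConfig()
  expect_equal(250 * (1 + length(cfg$blur_radii)), 1000)
})

test_that("subsampling is seed-deterministic and honours exclusion masks", {
  cube <- randomCube(10, 10, 4)
  tab <- flattenCube(cube)

  # fraction 1, no mask: identity up to order
  all_rows <- subsamplePixels(tab, 1, seed = 3)
  expect_equal(sort(tableValues(all_rows)[, 1]), sort(tableValues(tab)[, 1]))
  expect_equal(nrow(tableValues(all_rows)), 100)

  # exact fraction count
  expect_equal(nrow(tableValues(subsamplePixels(tab, 0.2, seed = 1))), 20)

  # determinism
  s1 <- subsamplePixels(tab, 0.3, seed = 42)
  s2 <- subsamplePixels(tab, 0.3, seed = 42)
  expect_identical(tableValues(s1), tableValues(s2))

  # masked pixels never sampled
  mask <- matrix(FALSE, 10, 10); mask[, 1:5] <- TRUE
  for (seed in 1:5) {
    sub <- subsamplePixels(tab, 0.5, exclude_mask = mask, seed = seed)
    expect_true(all(tableOrigin(sub)$col > 5))
  }
  expect_error(subsamplePixels(tab, 0.5, matrix(TRUE, 10, 10)), "empty")
})

test_that("embedding separates distinct spectral clusters", {
  r <- renderPhantom(threeClassSpec())
  cube <- meanFilterBands(r$cube, 3)
  sub <- subsamplePixels(augmentFeatures(cube), 0.5, seed = 2)
  cls <- r$truth@class_map[cbind(tableOrigin(sub)$row, tableOrigin(sub)$col)]
  for (backend in c("sammon", "umap")) {
    emb <- embedPixels(sub, backend = backend, seed = 2)
    expect_equal(dim(emb@coords), c(nrow(tableValues(sub)), 2))
    expect_true(all(is.finite(emb@coords)))
    sil <- cluster::silhouette(cls, dist(emb@coords))
    expect_gt(mean(sil[, 3]), 0.5)
  }
})

test_that("minimum-size inputs embed and duplicates map together", {
  vals <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  tab <- FlatPixelTable(vals, data.frame(tile_id = "", row = 1:3, col = 1L))
  for (backend in c("sammon", "pca"))
    expect_equal(nrow(embedPixels(tab, backend = backend)@coords), 3)

  # exact duplicate rows receive near-identical coordinates
  base <- withr::with_seed(6, matrix(rnorm(40), 10, 4))
  dup <- rbind(base, base[c(1, 5), ])
  tab2 <- FlatPixelTable(dup, data.frame(tile_id = "", row = 1:12, col = 1L))
  for (backend in c("sammon", "pca")) {
    co <- embedPixels(tab2, backend = backend)@coords
    span <- max(dist(co))
    expect_lt(sqrt(sum((co[11, ] - co[1, ])^2)), 1e-6 * span)
    expect_lt(sqrt(sum((co[12, ] - co[5, ])^2)), 1e-6 * span)
  }
  expect_error(embedPixels(FlatPixelTable(vals[1:2, ],
    data.frame(tile_id = "", row = 1:2, col = 1L))), "at least 3")
})

test_that("2-D histograms conserve points with half-open bins", {
  mk_emb <- function(xy) new("Embedding2D", coords = xy,
    sample_index = seq_len(nrow(xy)),
    origin = data.frame(tile_id = "", row = seq_len(nrow(xy)), col = 1L),
    backend = "test", params = list(), seed = 1L)

  # all points at one location: a single nonzero bin
  h1 <- histogram2d(mk_emb(matrix(1, 7, 2)), bins = 8)
  expect_equal(sum(h1@counts), 7)
  expect_equal(sum(h1@counts > 0), 1)

  # four corner points at bins = 2: one per quadrant
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  h2 <- histogram2d(mk_emb(corners), bins = 2)
  expect_equal(h2@counts, matrix(1, 2, 2))

  # conservation on random coordinates
  xy <- withr::with_seed(9, matrix(rnorm(600), 300, 2))
  h3 <- histogram2d(mk_emb(xy), bins = 16)
  expect_equal(sum(h3@counts), 300)
})

test_that("histogram maxima equal the exhaustive-scan oracle", {
  # single blob: one maximum at the mode
  g <- outer(dnorm(1:21, 11, 3), dnorm(1:21, 11, 3))
  pk <- findLocalMaxima(g, min_distance = 3)
  expect_equal(pk[, c("row", "col")], data.frame(row = 11L, col = 11L))

  # two separated blobs: two maxima
  g2 <- outer(dnorm(1:32, 8, 2), dnorm(1:32, 8, 2)) +
        outer(dnorm(1:32, 24, 2), dnorm(1:32, 24, 2))
  expect_equal(nrow(findLocalMaxima(g2, min_distance = 5)), 2)

  # random histograms vs independent brute-force oracle
  for (seed in c(1, 7, 23)) {
    img <- withr::with_seed(seed, matrix(runif(32 * 32), 32, 32))
    for (d in c(2, 4)) {
      got <- findLocalMaxima(img, min_distance = d)
      want <- oracleLocalMaxima(img, d)
      expect_equal(got, want)
    }
  }
})

test_that("central-bulk exclusion suppresses the primary-cluster mode", {
  xy <- withr::with_seed(4, rbind(
    matrix(rnorm(2000, 0, 0.6), ncol = 2),      # primary cluster
    matrix(rnorm(60, 8, 0.3), ncol = 2)))        # small protrusion
  emb <- new("Embedding2D", coords = xy,
             sample_index = seq_len(nrow(xy)),
             origin = data.frame(tile_id = "", row = seq_len(nrow(xy)),
                                 col = 1L),
             backend = "test", params = list(), seed = 1L)
  h <- histogram2d(emb, bins = 32)
  with_bulk <- findHistogramMaxima(h, min_distance_bins = 3, min_count = 2,
                                   smooth_sigma = 1)
  expect_gte(nrow(with_bulk), 2)
  no_bulk <- findHistogramMaxima(h, min_distance_bins = 3, min_count = 2,
                                 smooth_sigma = 1,
                                 exclude_central_bulk = TRUE)
  expect_lt(nrow(no_bulk), nrow(with_bulk))
  # the surviving maxima sit away from the global mode
  mode_xy <- with_bulk[1, c("x", "y")]
  expect_true(all(sqrt((no_bulk$x - mode_xy$x)^2 +
                       (no_bulk$y - mode_xy$y)^2) > 4))
})

test_that("box averaging reproduces class spectra from embeddings", {
  # noiseless two-class phantom: box over the full class recovers the
  # exact class spectrum
  r <- renderPhantom(twoClassSpec(24, 24, 16), noiseless = TRUE)
  tab <- flattenCube(r$cube)
  cls <- as.vector(r$truth@class_map)
  coords <- cbind(ifelse(cls == 1, 1, 5),
                  ifelse(cls == 1, 1, 5)) +
    withr::with_seed(2, matrix(runif(2 * length(cls), -0.3, 0.3),
                               ncol = 2))
  emb <- new("Embedding2D", coords = coords,
             sample_index = seq_along(cls), origin = tableOrigin(tab),
             backend = "test", params = list(), seed = 1L)
  em <- endmembersFromBoxes(tab, list(c(0, 2, 0, 2), c(4, 6, 4, 6)), emb)
  expect_equal(emSpectra(em)[1, ], unname(r$truth@endmembers[1, ]),
               tolerance = 1e-9)
  expect_equal(emSpectra(em)[2, ], unname(r$truth@endmembers[2, ]),
               tolerance = 1e-9)

  # a box holding a single pixel returns that pixel's spectrum
  one <- endmembersFromBoxes(tab,
    list(c(coords[5, 1] - 1e-6, coords[5, 1] + 1e-6,
           coords[5, 2] - 1e-6, coords[5, 2] + 1e-6)), emb)
  expect_equal(emSpectra(one)[1, ], tableValues(tab)[5, ])

  # empty boxes error naming the box
  expect_error(endmembersFromBoxes(tab, list(c(90, 91, 90, 91)), emb),
               "box 1")
})

test_that("embedding-discovered endmembers match phantom ground truth", {
  # the stated operating point: 5000 expected counts per pixel over the
  # full 0-20 keV axis (the Os L / Fe K lines above 5 keV are what
  # separate the membranes class, so the axis must cover them)
  spec <- fourClassPhantom(seed = 2)
  r <- renderPhantom(spec)
  cube <- preprocessCube(r$cube, preprocessConfig(0, 1, 1, 3))
  disc <- discoverEndmembers(cube, fraction = 0.2, seed = 2)
  expect_gte(nEndmembers(disc$endmembers), 4)
  expect_true(all(emSpectra(disc$endmembers) >= 0))
  expect_equal(ncol(emSpectra(disc$endmembers)), 250)
  mt <- matchEndmembers(disc$endmembers, r$truth@endmembers)
  expect_equal(nrow(mt), 4)
  expect_true(all(mt$cosine > 0.98))
})

test_that("annotation endmembers are class means within CLT bounds", {
  # one-pixel class returns that pixel's spectrum exactly
  cube <- randomCube(6, 6, 10)
  ann1 <- AnnotationSet(data.frame(label = "x", row = 3, col = 4))
  expect_equal(emSpectra(endmembersFromAnnotations(cube, ann1))[1, ],
               cubeCounts(cube)[3, 4, ])

  # noiseless two-class phantom: exact class spectra
  r0 <- renderPhantom(twoClassSpec(24, 24, 16), noiseless = TRUE)
  idx_in <- which(r0$truth@abundances[, , 1] == 1, arr.ind = TRUE)
  idx_bg <- which(r0$truth@abundances[, , 2] == 1, arr.ind = TRUE)
  ann <- AnnotationSet(data.frame(
    label = rep(c("granule", "background"), c(5, 5)),
    row = c(idx_in[1:5, 1], idx_bg[1:5, 1]),
    col = c(idx_in[1:5, 2], idx_bg[1:5, 2])))
  em0 <- endmembersFromAnnotations(r0$cube, ann)
  expect_equal(emSpectra(em0)[match("granule", emLabels(em0)), ],
               unname(r0$truth@endmembers[1, ]), tolerance = 1e-9)

  # Poisson phantom, 100 px per class: within 3 standard errors per channel
  r <- renderPhantom(twoClassSpec(48, 48, 16, counts = 300, n_frames = 4))
  for (k in 1:2) {
    idx <- which(r$truth@abundances[, , k] == 1, arr.ind = TRUE)[1:100, ]
    ann <- AnnotationSet(data.frame(label = "c", row = idx[, 1],
                                    col = idx[, 2]))
    got <- emSpectra(endmembersFromAnnotations(r$cube, ann))[1, ]
    lam <- r$truth@endmembers[k, ]
    se <- sqrt(lam / 100)
    expect_true(all(abs(got - lam) <= 3 * se + 1e-9))
  }
})
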