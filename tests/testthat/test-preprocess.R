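test_that("trim-and-bin reaches the target reduced dimensions", {
  # acquisition-scale shape logic without materialising the cube
  expect_equal(preprocessedDim(c(2048, 2048, 4096), preprocessConfig()),
               c(1024L, 1024L, 250L))

  # 4x4x32 ones, bins (2,16), sum: every output value is 2*2*16
  cube <- HyperspectralCube(array(1, dim = c(4, 4, 32)), tinyAxis(32))
  out <- trimAndBin(cube, preprocessConfig(0, 2, 16, 1))
  expect_equal(dim(cubeCounts(out)), c(2, 2, 2))
  expect_true(all(cubeCounts(out) == 64))

  # energy axis bookkeeping: drop shifts offset, binning widens channels
  cube2 <- randomCube(4, 4, 32)
  out2 <- trimAndBin(cube2, preprocessConfig(8, 2, 4, 1))
  ax <- energyAxis(cube2)
  expect_equal(energyAxis(out2)@bin_width_ev, ax@bin_width_ev * 4)
  expect_equal(energyAxis(out2)@offset_ev,
               ax@offset_ev + 8 * ax@bin_width_ev + 1.5 * ax@bin_width_ev)
  expect_equal(energyAxis(out2)@n_channels, 6L)
})

test_that("sum-reduced binning conserves post-trim counts on random cubes", {
  for (seed in c(2, 9)) {
    cube <- randomCube(8, 8, 64, seed = seed)
    out <- trimAndBin(cube, preprocessConfig(16, 2, 8, 1))
    expect_equal(sum(cubeCounts(out)), sum(cubeCounts(cube)[, , 17:64]))
  }
})

test_that("non-divisible shapes fail loudly instead of truncating", {
  cube <- randomCube(6, 6, 32)
  expect_error(trimAndBin(cube, preprocessConfig(0, 4, 1, 1)),
               "not divisible")
  expect_error(trimAndBin(cube, preprocessConfig(2, 1, 16, 1)),
               "not divisible")
  expect_error(preprocessedDim(c(8, 8, 16), preprocessConfig(16, 1, 1)),
               "smaller than n_channels")
})

test_that("mean filtering matches a direct convolution oracle", {
  # constant band unchanged; kernel 1 is the identity
  const <- HyperspectralCube(array(3, dim = c(5, 5, 2)), tinyAxis(2))
  expect_equal(cubeCounts(meanFilterBands(const, 3)), cubeCounts(const))
  cube <- randomCube(5, 5, 3)
  expect_identical(meanFilterBands(cube, 1), cube)

  # single impulse at the centre spreads into a 3x3 block of 1/9
  imp <- array(0, dim = c(5, 5, 1)); imp[3, 3, 1] <- 1
  out <- cubeCounts(meanFilterBands(
    HyperspectralCube(imp, tinyAxis(1)), 3))[, , 1]
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1 / 9
  expect_equal(out, expected, tolerance = 1e-12)

  # mirrored borders: direct oracle on a random band
  band <- withr::with_seed(4, matrix(runif(25), 5, 5))
  out <- cubeCounts(meanFilterBands(
    HyperspectralCube(array(band, c(5, 5, 1)), tinyAxis(1)), 3))[, , 1]
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  oracle <- matrix(0, 5, 5)
  for (r in 1:5) for (c_ in 1:5) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + band[refl(r + dr, 5), refl(c_ + dc, 5)]
    oracle[r, c_] <- acc / 9
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(meanFilterBands(cube, 4), "odd")
})

test_that("percentile normalisation follows the quantile oracle", {
  img <- matrix(0:99, 10, 10)
  out <- normalizeImage(img, normalizeConfig(0.01, 0))
  q <- quantile(img, c(0.01, 0.99), names = FALSE)
  oracle <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out, oracle)
  expect_equal(out[img == 0], 0)   # clipped at the bottom tail
  expect_equal(out[img == 99], 1)  # clipped at the top tail

  # frac = 0 is plain min/max normalisation and idempotent on [0,1]
  r <- withr::with_seed(8, matrix(runif(64), 8, 8))
  r[1] <- 0; r[64] <- 1
  plain <- normalizeImage(r, normalizeConfig(0, 0))
  expect_equal(plain, (r - min(r)) / (max(r) - min(r)))
  expect_equal(normalizeImage(plain, normalizeConfig(0, 0)), plain)

  # constant image maps to 0.5 by convention
  expect_true(all(normalizeImage(matrix(7, 4, 4),
                                 normalizeConfig(0.01, 0)) == 0.5))
})

test_that("HAADF median equalisation lowers all tiles to the min median", {
  expect_equal(equalizeHaadfMedians(list(matrix(5, 3, 3)))[[1]],
               matrix(5, 3, 3))
  out <- equalizeHaadfMedians(list(matrix(10, 2, 2), matrix(30, 2, 2)))
  expect_equal(out[[1]], matrix(10, 2, 2))
  expect_equal(out[[2]], matrix(10, 2, 2))

  tiles <- withr::with_seed(3, lapply(1:4, function(i)
    matrix(runif(36, i, i + 4), 6, 6)))
  out <- equalizeHaadfMedians(tiles)
  meds <- vapply(out, median, numeric(1))
  expect_equal(meds, rep(min(vapply(tiles, median, numeric(1))), 4))
  # only downward shifts
  expect_true(all(mapply(function(a, b) all(b <= a + 1e-12), tiles, out)))
})

test_that("grid stitching realises the analytic extent and inverts", {
  # 1x1 grid is the identity
  t1 <- matrix(1:16, 4, 4)
  lay1 <- MosaicLayout(1, 1, 4, 0)
  expect_equal(stitchGrid(list(t1), lay1), t1)

  # 2x2 non-overlapping constant tiles form a block image
  lay <- MosaicLayout(2, 2, 2, 0)
  tiles <- lapply(1:4, function(i) matrix(i, 2, 2))
  out <- stitchGrid(tiles, lay)
  expect_equal(out, rbind(cbind(matrix(1, 2, 2), matrix(2, 2, 2)),
                          cbind(matrix(3, 2, 2), matrix(4, 2, 2))))

  # 2x1 grid with overlap: extent formula and first-tile-wins
  lay2 <- MosaicLayout(2, 1, 8, 3)
  ta <- matrix(1, 8, 8); tb <- matrix(2, 8, 8)
  out2 <- stitchGrid(list(ta, tb), lay2)
  expect_equal(dim(out2), c(8 * 2 - 3, 8))
  expect_true(all(out2[1:8, ] == 1))   # overlap rows keep the first tile
  expect_true(all(out2[9:13, ] == 2))

  # stitch + tile extraction at zero overlap is the identity
  rt <- withr::with_seed(5, lapply(1:4, function(i) matrix(runif(9), 3, 3)))
  st <- stitchGrid(rt, MosaicLayout(2, 2, 3, 0))
  expect_equal(st[1:3, 4:6], rt[[2]])
  expect_equal(st[4:6, 1:3], rt[[3]])
  expect_error(stitchGrid(list(t1, t1), lay2), "mismatch|square")
})

test_that("overlap masks match a brute-force coverage count", {
  expect_false(any(overlapMask(MosaicLayout(2, 2, 8, 0))))

  m <- overlapMask(MosaicLayout(2, 1, 8, 3))
  expect_equal(which(apply(m, 1, any)), 6:8)  # one 3-wide band
  expect_equal(sum(m), 3 * 8)

  # r x c grids vs explicit coverage accumulation
  for (g in list(c(2, 3, 10, 2), c(3, 2, 6, 1))) {
    lay <- MosaicLayout(g[1], g[2], g[3], g[4])
    ext <- stitchedExtentPx(lay)
    cover <- matrix(0, ext[1], ext[2])
    step <- g[3] - g[4]
    for (gr in seq_len(g[1])) for (gc in seq_len(g[2]))
      cover[(gr - 1) * step + 1:g[3], (gc - 1) * step + 1:g[3]] <-
        cover[(gr - 1) * step + 1:g[3], (gc - 1) * step + 1:g[3]] + 1
    expect_equal(overlapMask(lay), cover >= 2)
  }
})
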