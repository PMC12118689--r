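test_that("NNLS recovers exact and mixed spectra", {
  e1 <- c(1, 0, 2, 0, 1); e2 <- c(0, 2, 1, 1, 0)
  em <- EndmemberSet(rbind(e1, e2), labels = c("a", "b"))

  # pure pixel: coefficient 1 on its endmember, 0 elsewhere
  a <- nnlsUnmix(matrix(e1, 1), em)
  expect_equal(as.vector(a), c(1, 0), tolerance = 1e-10)

  # noiseless mixture recovered to numerical precision
  mix <- 0.3 * e1 + 0.7 * e2
  a2 <- nnlsUnmix(matrix(mix, 1), em)
  expect_equal(as.vector(a2), c(0.3, 0.7), tolerance = 1e-10)

  # channel mismatch is a hard error
  expect_error(nnlsUnmix(matrix(1, 1, 4), em), "channel count mismatch")
})

test_that("NNLS matches a dense grid-search oracle on random pixels", {
  for (seed in c(3, 14)) {
    E <- withr::with_seed(seed, matrix(runif(10), 5, 2))
    s <- withr::with_seed(seed + 100, runif(5, 0, 2))
    em <- EndmemberSet(t(E))
    got <- as.vector(nnlsUnmix(matrix(s, 1), em))

    # independent oracle: residual norm evaluated on a dense grid
    grid <- seq(0, 2, by = 1e-3)
    G <- crossprod(E); h <- crossprod(E, s)
    # ||E a - s||^2 = a' G a - 2 h' a + const, evaluated via outer sums
    q11 <- G[1, 1] * grid^2 - 2 * h[1] * grid
    q22 <- G[2, 2] * grid^2 - 2 * h[2] * grid
    cross <- 2 * G[1, 2] * outer(grid, grid)
    obj <- outer(q11, q22, `+`) + cross
    best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    oracle <- c(grid[best[1]], grid[best[2]])
    expect_equal(got, oracle, tolerance = 2e-3)

    # no tested nonnegative candidate beats the NNLS residual
    resid <- function(a) sum((E %*% a - s)^2)
    probes <- withr::with_seed(seed, matrix(runif(40, 0, 2), 20, 2))
    expect_true(all(apply(probes, 1, resid) >= resid(got) - 1e-9))
  }
})

test_that("abundances are nonnegative and scale-invariant", {
  r <- renderPhantom(twoClassSpec(16, 16, 12))
  em <- EndmemberSet(r$truth@endmembers, labels = r$truth@labels)
  st <- finalizeScale(nnlsUnmix(r$cube, em))
  expect_true(all(abundances(st) >= 0))

  # multiplying spectra and endmembers by gamma leaves scaled
  # abundances and the dominant map unchanged
  gamma <- 3.7
  cube_g <- HyperspectralCube(cubeCounts(r$cube) * gamma,
                              energyAxis(r$cube))
  em_g <- EndmemberSet(emSpectra(em) * gamma, labels = emLabels(em))
  st_g <- finalizeScale(nnlsUnmix(cube_g, em_g))
  expect_equal(scaledAbundances(st_g), scaledAbundances(st),
               tolerance = 1e-8)
  expect_equal(dominantMap(st_g)@labels, dominantMap(st)@labels)
})

test_that("abundance recovery on a Poisson phantom is accurate", {
  # >= 1e4 expected counts per pixel over the accumulation
  spec <- fourClassPhantom(rows = 48, cols = 48, n_frames = 40,
                           counts_per_pixel_per_frame = 250, seed = 5,
                           energy = tinyAxis(32))
  r <- renderPhantom(spec)
  em <- EndmemberSet(r$truth@endmembers, labels = r$truth@labels)
  st <- finalizeScale(nnlsUnmix(r$cube, em))
  mae <- mean(abs(abundances(st) - r$truth@abundances))
  expect_lt(mae, 0.05)
})

test_that("global scaling is shared across tiles and reaches 1", {
  em <- EndmemberSet(rbind(c(1, 0), c(0, 1)))
  mk <- function(maxc) {
    co <- array(0, dim = c(2, 2, 2)); co[1, 1, 1] <- maxc
    new("AbundanceStack", coeffs = co, endmembers = em,
        global_scale = NA_real_, tile_id = "t")
  }
  one <- finalizeScale(mk(4))
  expect_equal(globalScale(one), 4)
  expect_equal(max(scaledAbundances(one)), 1)

  two <- finalizeScale(list(mk(2), mk(8)))
  expect_equal(vapply(two, globalScale, numeric(1)), c(8, 8))
  expect_equal(max(sapply(two, function(s) max(scaledAbundances(s)))), 1)
})

test_that("dominant maps use lowest-index ties and background zeros", {
  em <- EndmemberSet(rbind(c(1, 0), c(0, 1), c(1, 1)))
  co <- array(0, dim = c(2, 2, 3))
  co[1, 1, ] <- c(0, 0.5, 0.2)   # clear winner: endmember 2
  co[1, 2, ] <- c(0.4, 0.4, 0)   # tie: lowest index wins
  co[2, 1, ] <- 0                # all-zero: background
  co[2, 2, ] <- c(0, 0, 1)
  st <- finalizeScale(new("AbundanceStack", coeffs = co, endmembers = em,
                          global_scale = NA_real_, tile_id = ""))
  dm <- dominantMap(st)
  expect_equal(dm@labels[1, 1], 2L)
  expect_equal(dm@intensity[1, 1], 0.5 / globalScale(st))
  expect_equal(dm@labels[1, 2], 1L)
  expect_equal(dm@labels[2, 1], 0L)
  expect_equal(dm@intensity[2, 1], 0)

  # noiseless phantom: dominant labels match the ground-truth class map
  r <- renderPhantom(threeClassSpec(32, 32, 16), noiseless = TRUE)
  emt <- EndmemberSet(r$truth@endmembers, labels = r$truth@labels)
  dm2 <- dominantMap(finalizeScale(nnlsUnmix(r$cube, emt)))
  expect_equal(dm2@labels, unname(r$truth@class_map))
})

test_that("endmember Z-scores follow the population-sd convention", {
  # identical spectra: all zeros by the zero-spread convention
  same <- EndmemberSet(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(endmemberZscores(same) == 0))

  # two endmembers with channel values (0, 2): z = (-1, 1)
  em <- EndmemberSet(rbind(c(0, 1), c(2, 1)))
  z <- endmemberZscores(em)
  expect_equal(unname(z[, 1]), c(-1, 1))
  expect_equal(unname(z[, 2]), c(0, 0))

  # columns have mean 0 and unit population sd where spread > 0
  E <- withr::with_seed(11, matrix(runif(24), 4, 6))
  z2 <- endmemberZscores(EndmemberSet(E))
  expect_equal(colMeans(z2), rep(0, 6), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(z2^2)), rep(1, 6), tolerance = 1e-12)
  expect_error(endmemberZscores(EndmemberSet(matrix(1, 1, 3))), "at least 2")
})

test_that("abundance images invert correctly and composite by argmax", {
  em <- EndmemberSet(rbind(c(1, 0), c(0, 1)), labels = c("a", "b"))
  co <- array(0, dim = c(2, 2, 2))
  co[, , 1] <- rbind(c(1, 0), c(0, 0))
  co[, , 2] <- rbind(c(0, 0.5), c(0, 0))
  st <- finalizeScale(new("AbundanceStack", coeffs = co, endmembers = em,
                          global_scale = NA_real_, tile_id = ""))
  out <- abundanceToImages(st, colors = c("red", "blue"))
  expect_equal(out$grayscale$a, rbind(c(1, 0), c(0, 0)))

  inv <- abundanceToImages(st, colors = c("red", "blue"), invert = TRUE)
  expect_equal(inv$grayscale$a[1, 1], 0)  # max abundance -> black
  expect_equal(inv$grayscale$a[2, 1], 1)  # zero abundance -> white

  # composite colour equals the argmax endmember's colour
  expect_equal(out$composite[1, 1, ], c(1, 0, 0))          # red, full
  expect_equal(out$composite[1, 2, ], c(0, 0, 0.5))        # blue, half
  expect_equal(out$composite[2, 1, ], c(0, 0, 0))          # background

  # uniform single-endmember abundance gives a solid colour
  co1 <- array(0, dim = c(2, 2, 2)); co1[, , 1] <- 1
  st1 <- finalizeScale(new("AbundanceStack", coeffs = co1,
                           endmembers = em, global_scale = NA_real_,
                           tile_id = ""))
  comp <- abundanceToImages(st1, colors = c("red", "blue"))$composite
  expect_true(all(comp[, , 1] == 1) && all(comp[, , 2:3] == 0))
})
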