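test_that("prompt generation blurs, thresholds, and finds peaks", {
  cfg <- promptConfig(blur_sigma_px = 2, threshold = 0.3,
                      min_peak_distance_px = 5)

  # all-zero map: empty prompt set
  empty <- promptsFromAbundance(matrix(0, 32, 32), cfg)
  expect_equal(nrow(promptPoints(empty)), 0)

  # a single blob gives exactly one prompt at its centre (+- 1 px)
  blob <- outer(dnorm(1:41, 21, 4), dnorm(1:41, 21, 4))
  blob <- 0.9 * blob / max(blob)
  pr <- promptsFromAbundance(blob, cfg, label = "granule")
  pts <- promptPoints(pr)
  expect_equal(nrow(pts), 1)
  expect_lte(max(abs(unlist(pts[1, c("row", "col")]) - c(21, 21))), 1)
  expect_equal(pts$label, "granule")

  # prompts always lie where the blurred abundance clears the threshold
  amap <- withr::with_seed(13, matrix(runif(64 * 64), 64, 64))
  pts2 <- promptPoints(promptsFromAbundance(amap, cfg))
  blurred <- EDXUnmix:::gaussianBlur(amap, 2)
  expect_true(all(blurred[cbind(pts2$row, pts2$col)] >= 0.3))

  # determinism
  expect_identical(promptsFromAbundance(amap, cfg),
                   promptsFromAbundance(amap, cfg))
})

test_that("prompt maxima equal the exhaustive-scan oracle", {
  cfg <- promptConfig(blur_sigma_px = 1.5, threshold = 0.4,
                      min_peak_distance_px = 4)
  for (seed in c(5, 21)) {
    amap <- withr::with_seed(seed, matrix(runif(64 * 64), 64, 64))
    got <- promptPoints(promptsFromAbundance(amap, cfg))
    img <- EDXUnmix:::gaussianBlur(amap, 1.5)
    img[img < 0.4] <- 0
    want <- oracleLocalMaxima(img, 4, min_value = 0.4)
    expect_equal(got[, c("row", "col")],
                 want[, c("row", "col")])
  }
})

test_that("mask closing merges nearby blobs and is idempotent", {
  # radius 0 is the identity
  m <- matrix(FALSE, 16, 16); m[4:6, 4:6] <- TRUE
  expect_identical(refineMask(m, 0), m)

  # two blobs 50 px apart close into one component with radius 70
  big <- matrix(FALSE, 256, 256)
  big[100:110, 80:90] <- TRUE
  big[100:110, 141:151] <- TRUE   # 50 px gap
  closed <- refineMask(big, 70)
  lab <- EDXUnmix:::labelConnected(closed)
  expect_equal(max(lab), 1L)
  expect_true(all(big[closed == FALSE] == FALSE))  # closing only adds

  # idempotency
  expect_identical(refineMask(closed, 70), closed)
  once <- refineMask(big, 12)
  expect_identical(refineMask(once, 12), once)
})

test_that("the fallback segmenter recovers convex structures", {
  # disk phantom: one interior prompt segments the disk at IoU > 0.9
  img <- matrix(0.05, 64, 64)
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  disk <- (rr - 32)^2 + (cc - 30)^2 <= 12^2
  img[disk] <- 0.9
  img <- img + withr::with_seed(3, matrix(rnorm(64 * 64, 0, 0.01), 64))
  prompts <- PromptSet(data.frame(row = 32, col = 30, label = "d"))
  seg <- segmentWithPrompts(img, prompts)
  expect_gt(iou(maskList(seg)$d, disk), 0.9)

  # two prompts inside one convex object give the same mask as either
  p2 <- PromptSet(data.frame(row = c(32, 28), col = c(30, 33),
                             label = "d"))
  seg2 <- segmentWithPrompts(img, p2)
  expect_equal(maskList(seg2)$d, maskList(seg)$d)

  # zero prompts: empty mask
  seg0 <- segmentWithPrompts(img, PromptSet(
    data.frame(row = integer(), col = integer())))
  expect_false(any(maskList(seg0)[[1]]))

  # segmenter failures surface with prompt context
  boom <- function(image, points) stop("backend down")
  expect_error(segmentWithPrompts(img, prompts, segmenter = boom),
               "segmenter failed.*backend down")
})

test_that("IoU follows set geometry including the empty convention", {
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(iou(m, m), 1)
  expect_equal(iou(m, !m), 0)
  e <- matrix(FALSE, 2, 2)
  expect_equal(iou(e, e), 1)  # both empty

  # half-overlapping equal squares: IoU = 1/3
  a <- matrix(FALSE, 8, 8); b <- matrix(FALSE, 8, 8)
  a[1:4, 1:4] <- TRUE
  b[1:4, 3:6] <- TRUE
  expect_equal(iou(a, b), 1 / 3)
  expect_error(iou(a, matrix(FALSE, 4, 4)))
})

test_that("composites obey precedence and never exceed the union", {
  m1 <- matrix(FALSE, 4, 4); m1[1:2, 1:2] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[2:3, 2:3] <- TRUE
  masks <- SegmentationMasks(list(a = m1, b = m2))

  comp <- compositeMasks(masks)
  expect_equal(comp[1, 1], 1L)      # only a
  expect_equal(comp[2, 2], 1L)      # overlap: a has precedence
  expect_equal(comp[3, 3], 2L)      # only b
  expect_equal(comp[4, 4], 0L)      # neither

  comp2 <- compositeMasks(masks, precedence = c("b", "a"))
  expect_equal(comp2[2, 2], 1L)     # now b wins the overlap

  expect_lte(sum(comp > 0), sum(m1 | m2))
  expect_error(compositeMasks(masks, precedence = c("a", "zz")), "unknown")
})

test_that("threshold-then-blur variant is available and differs", {
  amap <- matrix(0, 32, 32); amap[16, 16] <- 1
  c1 <- promptConfig(blur_sigma_px = 3, threshold = 0.05,
                     min_peak_distance_px = 3, blur_first = TRUE)
  c2 <- promptConfig(blur_sigma_px = 3, threshold = 0.05,
                     min_peak_distance_px = 3, blur_first = FALSE)
  p1 <- promptPoints(promptsFromAbundance(amap, c1))
  p2 <- promptPoints(promptsFromAbundance(amap, c2))
  # blur-first suppresses the sub-threshold blurred impulse; the
  # threshold-first order keeps it
  expect_equal(nrow(p1), 0)
  expect_equal(nrow(p2), 1)
})
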