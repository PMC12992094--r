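test_that("software binning follows the block-mean definition", {
  m <- matrix(c(1, 5, 3, 7), 2, 2)      # [[1,3],[5,7]] in row terms
  expect_identical(applyPostbin(m, 0), m)
  expect_equal(applyPostbin(m, 0.5), matrix(4, 1, 1))
  ones <- matrix(1, 4, 4)
  out <- applyPostbin(ones, 0.5)
  expect_equal(dim(out), c(2, 2))
  expect_true(all(out == 1))
  expect_error(applyPostbin(ones, -1), "postbin")
  expect_error(applyPostbin(ones, 2), "postbin")
})

test_that("'none' background subtraction is the identity", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(subtractBackground(img, "none"), img)
  expect_error(subtractBackground(img, "fancy"), "unknown background")
})

test_that("'global nuclear' subtracts the background percentile exactly", {
  mask <- discLabelMask(60, 60, rbind(c(30, 30)), 10)
  img <- matrix(100, 60, 60)
  img[labels(mask) > 0] <- 250
  out <- subtractBackground(img, "global nuclear", mask, bgperctile = 25,
                            compression = 4)
  expect_equal(unique(out[labels(mask) > 0]), 150)
  expect_equal(unique(out[labels(mask) == 0]), 0)
  ## output background percentile is zero
  expect_equal(quant4i:::percentileValue(out[labels(mask) == 0], 25), 0)
  expect_error(subtractBackground(img, "global nuclear",
                                  discLabelMask(10, 10, rbind(c(5, 5)), 2)),
               "shapes disagree")
})

test_that("global modes are invariant to a constant intensity shift", {
  mask <- discLabelMask(48, 48, rbind(c(14, 14), c(34, 32)), 7)
  set.seed(8)
  img <- matrix(100 + runif(48 * 48, 0, 5), 48, 48)
  img[labels(mask) > 0] <- 300
  for (method in c("global nuclear", "global cyto")) {
    a <- subtractBackground(img, method, mask, compression = 2, nucr = 7)
    b <- subtractBackground(img + 57, method, mask, compression = 2, nucr = 7)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("top-hat removes a ramp and preserves small bright discs", {
  H <- 200; W <- 200
  ramp <- matrix(rep(seq(0, 199) * 0.5, each = H), H, W)  # range 0..99.5
  disc <- discMask(H, W, 100, 100, 5) * 50
  img <- ramp + disc
  out <- subtractBackground(img, "tophat", nucr = 8)
  ## dynamic range of the ramp region collapses by > 90%
  bg <- out[!discMask(H, W, 100, 100, 12)]
  expect_lt(diff(range(bg)), 0.1 * diff(range(ramp)))
  ## disc height preserved within 10%
  height <- max(out[discMask(H, W, 100, 100, 3)]) -
    stats::median(out[!discMask(H, W, 100, 100, 12)])
  expect_lt(abs(height - 50) / 50, 0.1)
})

test_that("semi-local subtraction tracks a smooth background", {
  p <- sceneParams(width = 200, height = 200, nNuclei = 10,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 200, rampPerPx = 1, minSeparation = 26)
  g <- generateScene(p, seed = 5)
  img <- getChannel(g$rounds[[1]], "DNA")
  m <- filterObjects(segmentNuclei(img, method = "thresh"), 60, 1500, 0.3)
  out <- subtractBackground(img, "semi-local nuclear", m, bgperctile = 25,
                            compression = 4)
  far <- quant4i:::nearestNucleus(m)$dist > 20
  ## the 200-unit ramp leaves only a small residual
  expect_lt(max(abs(out[far])), 0.15 * 200)
})

test_that("bleed-through correction is exact linear unmixing", {
  a <- matrix(100, 8, 8); b <- matrix(50, 8, 8)
  expect_identical(correctBleedthrough(a, b, 0, 0), a)
  expect_equal(unique(as.vector(correctBleedthrough(a, b, 0.2, 5))), 85)
  set.seed(9)
  target <- matrix(runif(400, 0, 1000), 20, 20)
  source <- matrix(runif(400, 0, 2000), 20, 20)
  mixed <- target + 0.3 * source + 10
  expect_equal(correctBleedthrough(mixed, source, 0.3, 10), target,
               tolerance = 1e-12)
  expect_error(correctBleedthrough(a, matrix(1, 3, 3), 1), "same shape")
  expect_error(correctBleedthrough(a, b, -1), "nonnegative")
})
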