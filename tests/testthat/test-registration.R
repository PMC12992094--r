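test_that("identical images give a zero shift", {
  g <- generateScene(sceneParams(width = 120, height = 120, nNuclei = 8,
                                 ecadChannel = FALSE, signalChannel = FALSE,
                                 minSeparation = 24), seed = 1)
  img <- getChannel(g$rounds[[1]], "DNA")
  expect_equal(estimateJitter(img, img, 20), c(dy = 0L, dx = 0L))
})

test_that("constructed integer shifts are recovered exactly", {
  g <- generateScene(sceneParams(width = 150, height = 150, nNuclei = 10,
                                 ecadChannel = FALSE, signalChannel = FALSE,
                                 backgroundOffset = 100, minSeparation = 24),
                     seed = 2)
  img <- getChannel(g$rounds[[1]], "DNA")
  expect_equal(estimateJitter(img, quant4i:::shiftMatrix(img, 3, -2, 100), 20),
               c(dy = 3L, dx = -2L))
  ## a shift at the window boundary is still valid
  expect_equal(estimateJitter(img, quant4i:::shiftMatrix(img, 20, 0, 100), 20),
               c(dy = 20L, dx = 0L))
})

test_that("translation equivariance holds within the window", {
  g <- generateScene(sceneParams(width = 130, height = 130, nNuclei = 9,
                                 ecadChannel = FALSE, signalChannel = FALSE,
                                 backgroundOffset = 100, minSeparation = 24),
                     seed = 4)
  img <- getChannel(g$rounds[[1]], "DNA")
  set.seed(11)
  for (k in 1:5) {
    a <- sample(-6:6, 2, replace = TRUE)
    b <- sample(-6:6, 2, replace = TRUE)
    est <- estimateJitter(quant4i:::shiftMatrix(img, a[1], a[2], 100),
                          quant4i:::shiftMatrix(img, b[1], b[2], 100), 20)
    expect_equal(unname(est), b - a)
  }
})

test_that("a shift beyond maxjit raises the documented error", {
  g <- generateScene(sceneParams(width = 140, height = 140, nNuclei = 9,
                                 ecadChannel = FALSE, signalChannel = FALSE,
                                 backgroundOffset = 100, minSeparation = 24),
                     seed = 5)
  img <- getChannel(g$rounds[[1]], "DNA")
  expect_error(
    estimateJitter(img, quant4i:::shiftMatrix(img, 25, 0, 100), 20),
    "Max jitter too high")
  expect_error(estimateJitter(img, img, 100), "half the image size")
  expect_error(estimateJitter(img, img[1:100, ], 20), "same shape")
})

test_that("align-and-crop window follows the intersection arithmetic", {
  px <- array(seq_len(100 * 100 * 1), dim = c(100, 100, 1))
  mk <- function(shifted, r) new("RoundImage", pixels = shifted,
                                 channelNames = "c", roundIndex = r,
                                 siteIndex = 1L)
  r1 <- mk(px, 1L)
  shifted <- array(quant4i:::shiftMatrix(px[, , 1], 3, -2), dim = c(100, 100, 1))
  r2 <- mk(shifted, 2L)
  off <- rbind(c(0, 0), c(3, -2))
  out <- alignAndCrop(list(r1, r2), off)
  d <- dim(pixelData(out$rounds[[1]]))
  expect_equal(d[1:2], c(97, 98))
  ## both cropped rounds carry the same physical pixels
  expect_equal(pixelData(out$rounds[[1]]), pixelData(out$rounds[[2]]),
               ignore_attr = TRUE)
  ## zero offsets are the identity
  id <- alignAndCrop(list(r1, r1), rbind(c(0, 0), c(0, 0)))
  expect_equal(pixelData(id$rounds[[1]]), px, ignore_attr = TRUE)
  expect_error(alignAndCrop(list(r1, r2), rbind(c(0, 0), c(200, 0))),
               "empty crop")
  expect_error(alignAndCrop(list(r1, r2), matrix(0, 1, 2)), "every round")
})

test_that("a jittered scene is registered back onto the reference", {
  p <- sceneParams(width = 160, height = 160, nNuclei = 10, nRounds = 2,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   jitter = rbind(c(0, 0), c(6, -4)),
                   backgroundOffset = 100, noiseSD = 30, minSeparation = 26)
  g <- generateScene(p, seed = 6)
  cfg <- sceneSettings(p, tempdir())
  off <- estimateJitterAll(g$rounds, cfg)
  expect_equal(unname(off[2, ]), c(6, -4))
  out <- alignAndCrop(g$rounds, off)
  a <- getChannel(out$rounds[[1]], "DNA")
  b <- getChannel(out$rounds[[2]], "DNA")
  ## identical up to the rendered noise
  expect_lt(mean(abs(a - b)), 5 * 30)
  expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.99)
})
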