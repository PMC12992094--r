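test_that("flat images produce no edges", {
  for (meth in c("Canny", "log"))
    expect_equal(sum(detectEcadEdges(matrix(5, 40, 40), meth, 2)), 0)
  expect_error(detectEcadEdges(matrix(1, 5, 5), "sobel"), "unknown edge")
})

test_that("a vertical step is localised to within one pixel", {
  img <- matrix(0, 60, 60)
  img[, 31:60] <- 1000
  e <- detectEcadEdges(img, "log", Gaus_filter_sigma = 2)
  cols <- which(e, arr.ind = TRUE)[, 2]
  expect_true(length(cols) > 0)
  expect_true(all(abs(cols - 30.5) <= 1.5))
  e2 <- detectEcadEdges(img, "Canny", Gaus_filter_sigma = 2)
  cols2 <- which(e2, arr.ind = TRUE)[, 2]
  expect_true(all(abs(cols2 - 30.5) <= 1.5))
})

test_that("Canny recovers the honeycomb boundaries", {
  p <- sceneParams(width = 121, height = 121, nucleiLayout = "cells",
                   cellPitch = 40, signalChannel = FALSE,
                   backgroundOffset = 50, nRounds = 1)
  g <- generateScene(p, seed = 1)
  ec <- getChannel(g$rounds[[1]], "Ecad")
  ## smoothing matched to the 2-px membrane lines keeps the gradient
  ## crests on the line flanks
  e <- detectEcadEdges(ec, "Canny", Gaus_filter_sigma = 1)
  truth <- g$premix$Ecad > 0
  near <- binaryDilateTest(e, 1)
  expect_gte(mean(near[truth]), 0.9)   # >= 90% of boundary px within 1 px
})

test_that("the E-cad positive area fills closed cells and is monotone", {
  p <- sceneParams(width = 121, height = 121, nucleiLayout = "cells",
                   cellPitch = 40, signalChannel = FALSE,
                   backgroundOffset = 50, nRounds = 1)
  g <- generateScene(p, seed = 1)
  e <- detectEcadEdges(getChannel(g$rounds[[1]], "Ecad"), "Canny", 2)
  expect_equal(sum(buildEcadPositiveArea(matrix(FALSE, 20, 20), 2, 4, 2)), 0)
  a <- buildEcadPositiveArea(e, 3, 4, 4)
  interior <- g$premix$Ecad == 0
  ## inner-cell interiors are fully covered
  inner <- matrix(FALSE, 121, 121); inner[45:75, 45:75] <- TRUE
  expect_equal(mean(a[interior & inner]), 1)
  ## monotonicity in both radii
  for (conn in c(4, 8)) {
    a1 <- buildEcadPositiveArea(e, 1, conn, 2)
    a2 <- buildEcadPositiveArea(e, 3, conn, 2)
    a3 <- buildEcadPositiveArea(e, 3, conn, 5)
    expect_true(all(a2[a1]))
    expect_true(all(a3[a2]))
  }
  expect_error(buildEcadPositiveArea(e, -1, 4, 2), "nonnegative")
})

test_that("gaps within the closing radius are bridged", {
  p <- sceneParams(width = 121, height = 121, nucleiLayout = "cells",
                   cellPitch = 40, signalChannel = FALSE, ecadGaps = 3,
                   ecadGapWidth = 4, backgroundOffset = 50, nRounds = 1)
  g <- generateScene(p, seed = 2)
  e <- detectEcadEdges(getChannel(g$rounds[[1]], "Ecad"), "Canny", 2)
  ## closing radius 3 bridges 4-px gaps: all inner interiors filled
  a <- buildEcadPositiveArea(e, 3, 4, 4)
  inner <- matrix(FALSE, 121, 121); inner[45:75, 45:75] <- TRUE
  expect_equal(mean(a[inner]), 1)
})

test_that("cells are segmented from E-cadherin edges alone", {
  p <- sceneParams(width = 121, height = 121, nucleiLayout = "cells",
                   cellPitch = 40, signalChannel = FALSE,
                   backgroundOffset = 50, nRounds = 1)
  g <- generateScene(p, seed = 1)
  e <- detectEcadEdges(getChannel(g$rounds[[1]], "Ecad"), "Canny", 2)
  cells <- segmentCellsEcadOnly(e, R_strel_edge = 3, Pixel_connectivity = 4,
                                Max_pixels = 100)
  expect_equal(nObjects(cells), 9)
  cen <- quant4i:::objectCentroids(labels(cells))
  pc <- t(vapply(g$scene@cellPolygons,
                 function(P) c(mean(P[, "y"]), mean(P[, "x"])), numeric(2)))
  for (i in seq_len(nrow(cen)))
    expect_lt(min(sqrt((pc[, 1] - cen[i, 1])^2 + (pc[, 2] - cen[i, 2])^2)), 2)
  ## labels partition the filled interior
  lbl <- labels(cells)
  filled <- buildEcadPositiveArea(e, 3, 4, 0)
  expect_true(all(filled[lbl > 0]))
  ## minimum size gate and the empty case
  few <- segmentCellsEcadOnly(e, 3, 4, Max_pixels = 2000)
  expect_equal(nObjects(few), 0)
  expect_equal(nObjects(segmentCellsEcadOnly(matrix(FALSE, 30, 30))), 0)
})

test_that("E-cadherin classification follows the overlap rule", {
  area <- matrix(FALSE, 40, 40); area[, 1:20] <- TRUE
  inside <- discLabelMask(40, 40, rbind(c(20, 10)), 4)
  expect_true(classifyEcadStatus(inside, area))
  outside <- discLabelMask(40, 40, rbind(c(20, 32)), 4)
  expect_false(classifyEcadStatus(outside, area))
  ## exactly 50% overlap is positive
  lbl <- matrix(0L, 40, 40); lbl[15:24, 19:22] <- 1L   # half in, half out
  expect_true(classifyEcadStatus(new("LabelMask", labels = lbl), area))
  expect_length(classifyEcadStatus(new("LabelMask", labels = matrix(0L, 4, 4)),
                                   matrix(TRUE, 4, 4)), 0)
  expect_error(classifyEcadStatus(inside, matrix(TRUE, 3, 3)),
               "shapes disagree")
})
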