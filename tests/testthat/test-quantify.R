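test_that("nuclear signal is the per-label mean with NA for empty labels", {
  mask <- discLabelMask(30, 30, rbind(c(10, 10), c(22, 22)), 4)
  img <- matrix(7, 30, 30)
  expect_equal(measureNuclearSignal(img, mask), c(7, 7))
  ## a label id absent from the mask yields a missing value
  lbl <- labels(mask); lbl[lbl == 1] <- 0
  gap <- new("LabelMask", labels = lbl)
  v <- measureNuclearSignal(img, gap)
  expect_true(is.na(v[1]))
  expect_equal(v[2], 7)
  expect_error(measureNuclearSignal(matrix(1, 5, 5), mask), "shapes disagree")
})

test_that("rendered nuclear intensity is recovered on a clean scene", {
  p <- sceneParams(width = 140, height = 140, nNuclei = 4, nucleusRadius = 8,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 100, minSeparation = 30)
  g <- generateScene(p, seed = 5)
  img <- getChannel(g$rounds[[1]], "DNA")
  m <- filterObjects(segmentNuclei(img, method = "thresh"), 60, 1500, 0.3)
  corrected <- subtractBackground(img, "global nuclear", m, bgperctile = 25)
  got <- measureNuclearSignal(corrected, m)
  truth <- vapply(seq_len(nObjects(m)), function(i)
    mean(g$premix$DNA[labels(m) == i]), numeric(1))
  expect_true(all(abs(got - truth) / truth < 0.05))
})

test_that("cytoring construction equals the brute-force distance oracle", {
  set.seed(12)
  for (k in 1:10) {
    n <- sample(2:4, 1)
    centers <- cbind(sample(8:32, n, replace = TRUE),
                     sample(8:32, n, replace = TRUE))
    mask <- discLabelMask(40, 40, centers, sample(3:5, 1))
    if (nObjects(mask) < 1) next
    inner <- sample(0:1, 1); outer <- inner + sample(2:4, 1)
    got <- labels(buildCytoring(mask, inner, outer))
    want <- bruteRing(mask, inner, outer)
    expect_identical(got, want)
    ## nuclear / ring disjointness
    expect_true(all(labels(mask)[got > 0] == 0))
  }
  expect_error(buildCytoring(discLabelMask(10, 10, rbind(c(5, 5)), 2), 5, 5),
               "innerrad")
})

test_that("isolated-disc ring size matches the exhaustive count", {
  mask <- discLabelMask(50, 50, rbind(c(25, 25)), 10)
  ring <- labels(buildCytoring(mask, 1, 5))
  want <- bruteRing(mask, 1, 5)
  expect_identical(ring, want)
  ## ring at a crop border is clipped to the field
  edge <- discLabelMask(30, 30, rbind(c(3, 15)), 5)
  r2 <- buildCytoring(edge, 1, 5)
  expect_true(all(dim(labels(r2)) == c(30, 30)))
  expect_gt(sum(labels(r2) > 0), 0)
})

test_that("adjacent rings stay disjoint and exclude both nuclei", {
  mask <- discLabelMask(40, 60, rbind(c(20, 20), c(20, 34)), 5)
  ring <- labels(buildCytoring(mask, 1, 5))
  lbl <- labels(mask)
  expect_true(all(lbl[ring > 0] == 0))
  ## contested pixels went to the nearer nucleus
  nn <- quant4i:::nearestNucleus(mask)
  sel <- ring > 0
  expect_true(all(ring[sel] == nn$assign[sel]))
})

test_that("ring medians honour the intensity and size gates", {
  mask <- discLabelMask(40, 40, rbind(c(20, 20)), 8)
  ring <- buildCytoring(mask, 1, 5)
  img <- matrix(20, 40, 40)
  expect_equal(measureCytoringSignal(img, ring, ringthresh = 0), 20)
  ## half 5s half 50s with threshold 10: the 5s are excluded
  rpix <- which(labels(ring) == 1)
  img2 <- matrix(0, 40, 40)
  img2[rpix[seq(1, length(rpix), by = 2)]] <- 5
  img2[rpix[seq(2, length(rpix), by = 2)]] <- 50
  expect_equal(measureCytoringSignal(img2, ring, ringthresh = 10), 50)
  ## too few qualifying pixels -> missing value
  img3 <- matrix(0, 40, 40)
  img3[rpix[1:3]] <- 100
  expect_true(is.na(measureCytoringSignal(img3, ring, ringthresh = 50,
                                          minringsize = 10)))
})

test_that("puncta are counted in the right compartment", {
  p <- sceneParams(width = 200, height = 200, nNuclei = 5, nucleusRadius = 16,
                   ecadChannel = FALSE, signalChannel = TRUE,
                   punctaPerCell = 5, backgroundOffset = 100,
                   minSeparation = 52)
  g <- generateScene(p, seed = 8)
  poi <- getChannel(g$rounds[[1]], "POI")
  dna <- getChannel(g$rounds[[1]], "DNA")
  m <- filterObjects(segmentNuclei(dna, method = "thresh"), 200, 6000, 0.3)
  pk <- detectPuncta(poi, m, punctatopsize = 3, punctaThresh = 650,
                     cytopuncta = 0)
  expect_equal(pk$count, rep(5, nObjects(m)))
  expect_true(all(pk$intensity > 0))
  ## all spots below threshold -> zero counts
  none <- detectPuncta(poi, m, punctatopsize = 3, punctaThresh = 1e6)
  expect_equal(none$count, rep(0, nObjects(m)))
  expect_error(detectPuncta(poi, m, punctatopsize = 0), "punctatopsize")
})

test_that("cytoplasmic puncta are routed away from nuclei", {
  p <- sceneParams(width = 220, height = 220, nNuclei = 4, nucleusRadius = 12,
                   ecadChannel = FALSE, signalChannel = TRUE,
                   punctaPerCell = 3, punctaCompartment = "cyto",
                   thickenradius = 30, backgroundOffset = 100,
                   minSeparation = 70)
  g <- generateScene(p, seed = 9)
  poi <- getChannel(g$rounds[[1]], "POI")
  m <- filterObjects(segmentNuclei(getChannel(g$rounds[[1]], "DNA"),
                                   method = "thresh"), 100, 3000, 0.3)
  cy <- detectPuncta(poi, m, punctatopsize = 3, punctaThresh = 650,
                     cytopuncta = 1, thickenradius = 30)
  expect_equal(cy$count, rep(3, nObjects(m)))
  nu <- detectPuncta(poi, m, punctatopsize = 3, punctaThresh = 650,
                     cytopuncta = 0)
  expect_equal(nu$count, rep(0, nObjects(m)))
})

test_that("feature table conventions: centroid, counts, locality", {
  cfg <- minimalSettings()
  lbl <- matrix(0L, 12, 12); lbl[7, 4] <- 1L
  mask <- new("LabelMask", labels = lbl)
  tab <- assembleFeatureTable(mask,
                              list(list(list(nuc = 1), list(nuc = 2))),
                              NULL, cfg, 1L)
  d <- tableData(tab)
  expect_equal(d$x, 4); expect_equal(d$y, 7); expect_equal(d$nuclear_area, 1)
  ## column count: 2 rounds x 2 channels, ring on one channel = 9
  cfg2 <- ifSettings(file_name = "x", IF_imagesessions = c("R1", "R2"),
                     signals = list(c("a", "b"), c("a", "b")),
                     maskIndex = 1, jitterIndex = 1,
                     ringcalc = list(c(0, 1), c(0, 0)))
  mask2 <- discLabelMask(40, 40, rbind(c(10, 10), c(30, 30)), 4)
  mm <- function(...) list(nuc = c(1, 2), ...)
  meas <- list(list(mm(), mm(ring = c(3, 4))), list(mm(), mm()))
  tab2 <- assembleFeatureTable(mask2, meas, c(TRUE, FALSE), cfg2, 1L)
  expect_equal(ncol(tableData(tab2)), 9)
  expect_equal(length(tableHeader(tab2)), 9)
  ## measurement vectors must cover every cell
  expect_error(assembleFeatureTable(mask2,
    list(list(mm(), mm(ring = 3)), list(mm(), mm())), NULL, cfg2, 1L),
    "ring")
  expect_error(assembleFeatureTable(mask2, meas, TRUE, cfg2, 1L),
               "flag count")
})

test_that("local background reads the box percentile outside nuclei", {
  mask <- discLabelMask(60, 60, rbind(c(30, 30)), 6)
  img <- matrix(40, 60, 60)
  img[labels(mask) > 0] <- 500
  v <- measureLocalBackground(img, mask, bgperctile = 25, nucr = 3)
  expect_equal(v, 40)
})
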