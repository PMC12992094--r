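test_that("a single rendered nucleus is segmented at its true size", {
  p <- sceneParams(width = 80, height = 80, nNuclei = 1, nucleusRadius = 10,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 0, minSeparation = 24)
  g <- generateScene(p, seed = 2)
  m <- segmentNuclei(getChannel(g$rounds[[1]], "DNA"), method = "thresh")
  expect_equal(nObjects(m), 1)
  area <- sum(labels(m) > 0)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.15)
})

test_that("well-separated nuclei give one label each at the true centroid", {
  p <- sceneParams(width = 150, height = 150, nNuclei = 2, nucleusRadius = 8,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 100, minSeparation = 48)
  g <- generateScene(p, seed = 3)
  m <- segmentNuclei(getChannel(g$rounds[[1]], "DNA"), method = "thresh")
  expect_equal(nObjects(m), 2)
  cen <- quant4i:::objectCentroids(labels(m))
  gt <- g$scene@nuclei
  for (i in 1:2)
    expect_lt(min(sqrt((cen[, 1] - gt$cy[i])^2 + (cen[, 2] - gt$cx[i])^2)), 1)
})

test_that("watershed splits overlapping pairs that plain Otsu merges", {
  p <- sceneParams(width = 140, height = 140, nNuclei = 0,
                   concatenatedPairs = 1, nucleusRadius = 10,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 50)
  for (seed in 1:5) {
    g <- generateScene(p, seed = seed)
    dna <- getChannel(g$rounds[[1]], "DNA")
    expect_equal(nObjects(segmentNuclei(dna, method = "thresh")), 1)
    expect_equal(nObjects(segmentNuclei(dna, method = "single")), 2)
  }
})

test_that("every segmentation method handles a standard field", {
  p <- sceneParams(width = 180, height = 180, nNuclei = 6, nucleusRadius = 8,
                   ecadChannel = TRUE, signalChannel = FALSE, cellPitch = 60,
                   backgroundOffset = 100, minSeparation = 30)
  g <- generateScene(p, seed = 4)
  dna <- getChannel(g$rounds[[1]], "DNA")
  ec <- getChannel(g$rounds[[1]], "Ecad")
  for (meth in c("thresh", "single", "double", "double marker",
                 "multithresh", "log", "log contour")) {
    m <- segmentNuclei(dna, method = meth, params = list(nucr = 8))
    f <- filterObjects(m, 60, 1500, 0.3)
    expect_equal(nObjects(f), 6, info = meth)
  }
  m <- segmentNuclei(dna, ec, method = "Nuc-Ecad boundary")
  expect_gte(nObjects(filterObjects(m, 60, 1500, 0.3)), 6)
  expect_error(segmentNuclei(dna, method = "Nuc-Ecad boundary"), "E-cadherin")
  expect_error(segmentNuclei(dna, method = "sorcery"), "unknown segmentation")
})

test_that("E-cadherin ridges split concatenated nuclei", {
  p <- sceneParams(width = 160, height = 160, nNuclei = 0,
                   concatenatedPairs = 2, nucleusRadius = 8,
                   ecadChannel = TRUE, signalChannel = FALSE,
                   cellPitch = 1000, backgroundOffset = 50)
  g <- generateScene(p, seed = 6)
  dna <- getChannel(g$rounds[[1]], "DNA")
  ec <- getChannel(g$rounds[[1]], "Ecad")
  merged <- segmentNuclei(dna, method = "thresh")
  expect_equal(nObjects(merged), 2)
  split <- splitByEcadBoundary(merged, ec, split_mult = 1)
  expect_equal(nObjects(split), 4)
  gt <- g$scene@nuclei
  cen <- quant4i:::objectCentroids(labels(split))
  for (i in seq_len(nrow(gt)))
    expect_lt(min(sqrt((cen[, 1] - gt$cy[i])^2 + (cen[, 2] - gt$cx[i])^2)), 4)
  ## zero E-cadherin signal leaves the mask untouched
  same <- splitByEcadBoundary(merged, matrix(0, 160, 160))
  expect_equal(labels(same), labels(merged))
  ## raising split_mult never increases the label count
  prev <- Inf
  for (sm in c(0.5, 1, 2, 4, 8, 16)) {
    n <- nObjects(splitByEcadBoundary(merged, ec, split_mult = sm))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("object filtering enforces area and solidity and is idempotent", {
  lbl <- matrix(0L, 40, 60)
  lbl[2:3, 2:4] <- 1L                       # 6 px: debris
  lbl[10:19, 10:19] <- 2L                   # filled rectangle, solidity 1
  ## plus sign: arms of length 4, width 1, area 17, hull diamond = 41 px
  lbl[25:33, 45] <- 3L
  lbl[29, 41:49] <- 3L
  mask <- new("LabelMask", labels = lbl)
  sol <- quant4i:::objectSolidity(lbl)
  expect_equal(sol[2], 1)
  expect_equal(sol[3], 17 / 41)
  out <- filterObjects(mask, debrisarea = 20, boulderarea = 5000,
                       soliditythresh = 0.8)
  expect_equal(nObjects(out), 1)            # only the rectangle survives
  expect_equal(sort(unique(labels(out)[labels(out) > 0])), 1L)
  lax <- filterObjects(mask, 10, 5000, 0.3)
  expect_equal(nObjects(lax), 2)            # rectangle + plus sign
  ## idempotence
  twice <- filterObjects(lax, 10, 5000, 0.3)
  expect_equal(labels(twice), labels(lax))
})

test_that("primary-round area histogram support lies inside the gates", {
  p <- sceneParams(width = 200, height = 200, nNuclei = 12, nucleusRadius = 8,
                   ecadChannel = FALSE, signalChannel = FALSE,
                   backgroundOffset = 100, minSeparation = 26)
  g <- generateScene(p, seed = 9)
  m <- filterObjects(segmentNuclei(getChannel(g$rounds[[1]], "DNA"),
                                   method = "thresh"), 60, 1500, 0.3)
  areas <- quant4i:::objectAreas(labels(m))
  expect_true(all(areas >= 60 & areas <= 1500))
  path <- quant4i:::writeAreaHistogram(m, tempfile(fileext = ".png"), 60, 1500)
  expect_true(file.exists(path))
})
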