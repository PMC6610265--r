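test_that("the hottest voxel is located with a lexicographic tie-break", {
  geom <- imageGeometry(c(5, 5, 5), 2)
  v <- array(0, dim = c(5, 5, 5))
  v[3, 4, 2] <- 7
  img <- staticImage(v, geom)
  expect_equal(findMaxVoxel(img), c(3L, 4L, 2L))

  v[1, 5, 4] <- 7  # tie; (1,5,4) < (3,4,2) lexicographically
  expect_equal(findMaxVoxel(staticImage(v, geom)), c(1L, 5L, 4L))

  hint <- regionMask(cbind(3L, 4L, 2L))
  expect_equal(findMaxVoxel(staticImage(v, geom), hint), c(3L, 4L, 2L))
  expect_error(findMaxVoxel(img, regionMask(matrix(integer(0), 0, 3))),
               "empty")
})

test_that("region growing matches the hand-checkable line example", {
  geom <- imageGeometry(c(5, 1, 1), 2)
  v <- array(c(1, 9, 10, 9, 1), dim = c(5, 1, 1))
  img <- staticImage(v, geom)
  m <- regionGrow(img, c(3, 1, 1), 9, mode = "3D")
  expect_equal(nrow(maskVoxels(m)), 3)
  expect_setequal(maskVoxels(m)[, 1], 2:4)
  expect_error(regionGrow(img, c(1, 1, 1), 9), "below the threshold")
})

test_that("growing a uniform volume with a low threshold floods everything", {
  geom <- imageGeometry(c(6, 5, 4), 2)
  img <- staticImage(array(2, dim = c(6, 5, 4)), geom)
  m <- regionGrow(img, c(1, 1, 1), 2, mode = "3D")
  expect_equal(nrow(maskVoxels(m)), 6 * 5 * 4)
  m2 <- regionGrow(img, c(3, 3, 2), 2, mode = "2D")
  expect_equal(nrow(maskVoxels(m2)), 6 * 5)
  expect_equal(m2@sliceIndex, 2L)
})

test_that("region growing equals the connected-component oracle on random volumes", {
  set.seed(100)
  for (rep in 1:30) {
    v <- array(sample(0:1, 9^3, replace = TRUE, prob = c(0.45, 0.55)),
               dim = c(9, 9, 9))
    img <- staticImage(v + 0, imageGeometry(c(9, 9, 9), 2))
    seeds <- which(v == 1, arr.ind = TRUE)
    s <- seeds[sample(nrow(seeds), 1), ]
    m3 <- regionGrow(img, s, 1, mode = "3D")
    expect_equal(maskLinear(m3, dim(v)),
                 ccOracleComponent(v, s, 1, "3D"))
    m2 <- regionGrow(img, s, 1, mode = "2D")
    expect_equal(maskLinear(m2, dim(v)),
                 ccOracleComponent(v, s, 1, "2D"))
  }
})

test_that("masks shrink monotonically as the threshold rises", {
  set.seed(5)
  geom <- imageGeometry(c(12, 12, 8), 2)
  v <- array(runif(12 * 12 * 8, 0, 10), dim = c(12, 12, 8))
  v[6, 6, 4] <- 10.5
  img <- staticImage(v, geom)
  seed <- c(6, 6, 4)
  prev <- NULL
  for (th in c(4, 6, 8, 10)) {
    m <- maskLinear(regionGrow(img, seed, th, mode = "3D"), geom@dim)
    if (!is.null(prev)) expect_true(all(m %in% prev))
    prev <- m
  }
})

test_that("ROI90/VOI90 use 90% of the in-tumour maximum and are scale invariant", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  summed <- windowedMeanImage(ph$image, 20, 40)
  hint <- ph$truth$lesion

  roi <- segmentROI90(summed, hint)
  voi <- segmentVOI90(summed, hint)
  expect_equal(definitionTag(roi), "ROI90")
  expect_equal(definitionTag(voi), "VOI90")
  expect_equal(roi@dimensionality, "2D")

  # homogeneous hot lesion on cold background: masks lie inside the truth
  d <- summed@geometry@dim
  lesLin <- maskLinear(hint, d)
  expect_true(all(maskLinear(voi, d) %in% lesLin))
  expect_true(all(maskLinear(roi, d) %in% lesLin))
  # the 2D region is the 3D region's intersection with the max slice
  expect_true(all(maskLinear(roi, d) %in% maskLinear(voi, d)))

  # global positive scaling leaves the masks unchanged
  scaled <- staticImage(5.3 * summed@values, summed@geometry, summed@window)
  expect_equal(maskLinear(segmentROI90(scaled, hint), d), maskLinear(roi, d))
  expect_equal(maskLinear(segmentVOI90(scaled, hint), d), maskLinear(voi, d))
})

test_that("background mean reads the contralateral sphere correctly", {
  geom <- smallGeom()
  img <- staticImage(array(2, dim = geom@dim), geom)
  ctr <- gridToWorld(geom, geom@dim / 2)
  expect_equal(backgroundMean(img, ctr, 20), 2)
  expect_error(backgroundMean(img, c(0, 0, 0), 20), "bounds")

  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  summed <- windowedMeanImage(ph$image, 20, 40)
  bgCtr <- gridToWorld(geom, (geom@dim + 1) / 2) + c(30, 0, 0)
  expect_equal(backgroundMean(summed, bgCtr, 20), 1.2, tolerance = 1e-9)
})

test_that("TBR segmentation thresholds at 1.6 x background and can include vessels", {
  vessel <- phantomStructure("vessel", "cylinder", c(62, 99, 46),
                             kineticModel("gamma_variate", A = 8, tp = 2.5,
                                          alpha = 0.12), radius = 5,
                             halfLength = 20)
  sp <- tinyPhantomSpec(noiseSigma0 = 0, confounders = list(vessel),
                        priority = c("lesion", "vessel"))
  ph <- buildPhantom(sp)
  summed <- windowedMeanImage(ph$image, 20, 40)
  d <- summed@geometry@dim
  bg <- 1.2

  m <- segmentTBR(summed, ph$truth$lesion, bg, mode = "3D")
  expect_equal(definitionTag(m), "VOI_TBR")
  # the lesion abuts the vessel: the grown region spills into vessel voxels
  expect_gt(length(intersect(maskLinear(m, d),
                             maskLinear(ph$truth$vessel, d))), 0)

  # image and background scaled together give the identical mask
  scaled <- staticImage(3 * summed@values, summed@geometry, summed@window)
  m2 <- segmentTBR(scaled, ph$truth$lesion, 3 * bg, mode = "3D")
  expect_equal(maskLinear(m2, d), maskLinear(m, d))
  expect_error(segmentTBR(summed, ph$truth$lesion, -1), "background")
})

test_that("sphere volumes converge to the analytic value as spacing shrinks", {
  analytic <- 4 / 3 * pi * (15.6 / 2)^3 / 1000  # ~1.99 mL
  expect_equal(analytic, 1.988, tolerance = 1e-3)
  rels <- vapply(c(2, 1, 0.5), function(sp) {
    n <- ceiling(24 / sp)
    geom <- imageGeometry(rep(n, 3), sp)
    ctr <- gridToWorld(geom, rep((n + 1) / 2, 3))  # half-grid worst case
    m <- sphereVOI(geom, ctr, 15.6)
    abs(maskVolume(m, geom) - analytic) / analytic
  }, numeric(1))
  # a 2 mm voxel is 0.008 mL on a ~2 mL sphere; surface effects allow ~15%
  expect_lt(rels[1], 0.15)
  expect_lt(rels[2], 0.05)
  expect_lt(rels[3], 0.02)
  expect_true(all(diff(rels) < 0))  # converges as spacing shrinks
})

test_that("a sub-voxel sphere on a voxel centre selects exactly that voxel", {
  geom <- imageGeometry(c(9, 9, 9), 2)
  ctr <- gridToWorld(geom, c(5, 5, 5))
  m <- sphereVOI(geom, ctr, 1.5)
  expect_equal(nrow(maskVoxels(m)), 1)
  expect_equal(unname(maskVoxels(m)[1, ]), c(5L, 5L, 5L))
})

test_that("implausible segmentations are excluded with a reason", {
  geom <- smallGeom()
  cfg <- segmentationConfig()
  small <- regionMask(cbind(1:5, 1:5, 1:5))
  expect_true(plausibilityCheck(small, geom, cfg)$pass)

  whole <- regionMask(which(array(TRUE, geom@dim), arr.ind = TRUE))
  res <- plausibilityCheck(whole, geom, cfg)
  expect_false(res$pass)
  expect_match(res$reason, "volume")

  # low threshold escaping the brain: brain-mask criterion
  sp <- tinyPhantomSpec(noiseSigma0 = 0,
                        confounders = list(phantomStructure(
                          "scalp", "shell",
                          gridToWorld(geom, (geom@dim + 1) / 2),
                          kineticModel("constant", A = 2),
                          semiaxes = geom@dim * geom@spacing * 0.48,
                          innerSemiaxes = geom@dim * geom@spacing * 0.44)))
  ph <- buildPhantom(sp)
  # small mask (passes the volume check) that mostly escaped the brain
  outside <- regionMask(rbind(maskVoxels(ph$truth$scalp)[1:40, ],
                              maskVoxels(ph$truth$lesion)[1:10, ]))
  expect_lt(maskVolume(outside, geom), cfg$maxPlausibleVolumeML)
  res2 <- plausibilityCheck(outside, geom, cfg,
                            brainMask = ph$truth$brain_envelope)
  expect_false(res2$pass)
  expect_match(res2$reason, "outside")
})
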