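test_that("noise-free phantom voxels follow the analytic frame averages", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  tac <- extractTAC(ph$image, ph$truth$lesion)
  expected <- frameAverageCurve(kineticModel("increasing", A = 3, tau = 12),
                                standardSchedule())
  expect_equal(meanSUV(tac), expected, tolerance = 1e-9)
  bg <- extractTAC(ph$image, ph$truth$brain)
  expect_equal(meanSUV(bg), rep(1.2, 8), tolerance = 1e-12)
})

test_that("the seed fully determines the noisy realisation", {
  a <- buildPhantom(tinyPhantomSpec(noiseSigma0 = 0.05, seed = 11L))
  b <- buildPhantom(tinyPhantomSpec(noiseSigma0 = 0.05, seed = 11L))
  c <- buildPhantom(tinyPhantomSpec(noiseSigma0 = 0.05, seed = 12L))
  expect_identical(voxelData(a$image), voxelData(b$image))
  expect_false(identical(voxelData(a$image), voxelData(c$image)))
})

test_that("noise scales inversely with the square root of frame duration", {
  sp <- tinyPhantomSpec(lesionModel = kineticModel("constant", A = 2),
                        noiseSigma0 = 0.1, seed = 4L)
  ph <- buildPhantom(sp)
  clean <- buildPhantom(tinyPhantomSpec(
    lesionModel = kineticModel("constant", A = 2), noiseSigma0 = 0))
  resid <- voxelData(ph$image) - voxelData(clean$image)
  sds <- apply(resid, 4, stats::sd)
  expected <- 0.1 / sqrt(frameDurations(standardSchedule()) / 10)
  expect_equal(sds, expected, tolerance = 0.05)
})

test_that("ground-truth labels come from the three-class rule on clean curves", {
  dec <- buildPhantom(tinyPhantomSpec(
    lesionModel = kineticModel("gamma_variate", A = 3, tp = 8, alpha = 3)))
  expect_equal(unname(dec$labels["lesion"]), "DECREASING")
  inc <- buildPhantom(tinyPhantomSpec(
    lesionModel = kineticModel("increasing", A = 3, tau = 12)))
  expect_equal(unname(inc$labels["lesion"]), "INCREASING")
  pla <- buildPhantom(tinyPhantomSpec(
    lesionModel = kineticModel("gamma_variate", A = 3, tp = 28, alpha = 2)))
  expect_equal(unname(pla$labels["lesion"]), "PLATEAU")
})

test_that("overlapping structures are an error unless a priority is given", {
  geom <- smallGeom()
  ctr <- gridToWorld(geom, (geom@dim + 1) / 2)
  brain <- phantomStructure("brain", "ellipsoid", ctr,
                            kineticModel("constant", A = 1.2),
                            semiaxes = geom@dim * geom@spacing * 0.42)
  a <- phantomStructure("a", "sphere", ctr, kineticModel("constant", A = 2),
                        radius = 10)
  b <- phantomStructure("b", "sphere", ctr + c(6, 0, 0),
                        kineticModel("constant", A = 3), radius = 10)
  expect_error(buildPhantom(phantomSpec(geom, brain, list(a, b))), "priority")
  ph <- buildPhantom(phantomSpec(geom, brain, list(a, b),
                                 priority = c("a", "b")))
  # with 'a' winning, its mask is the full sphere and 'b' loses the overlap
  lina <- maskLinear(ph$truth$a, geom@dim)
  linb <- maskLinear(ph$truth$b, geom@dim)
  expect_length(intersect(lina, linb), 0)
  expect_true(all(voxelData(ph$image)[cbind(maskVoxels(ph$truth$a), 8)] == 2))
})

test_that("lesion compartments override the parent without overlap errors", {
  geom <- smallGeom()
  ctr <- gridToWorld(geom, (geom@dim + 1) / 2)
  brain <- phantomStructure("brain", "ellipsoid", ctr,
                            kineticModel("constant", A = 1.2),
                            semiaxes = geom@dim * geom@spacing * 0.42)
  core <- phantomStructure("core", "sphere", ctr + c(4, 0, 0),
                           kineticModel("constant", A = 5), radius = 5)
  les <- phantomStructure("lesion", "sphere", ctr,
                          kineticModel("constant", A = 2), radius = 12,
                          compartments = list(core))
  ph <- buildPhantom(phantomSpec(geom, brain, list(les)))
  vals8 <- voxelData(ph$image)[, , , 8]
  inLesion <- vals8[maskVoxels(ph$truth$lesion)]
  expect_setequal(unique(inLesion), c(2, 5))
})

test_that("bias fields obey their boundary conditions and stay positive", {
  geom <- smallGeom(c(24, 24, 16))
  uni <- makeBiasField(biasFieldSpec("uniform", s = 1), geom)
  expect_true(all(uni == 1))

  rad <- makeBiasField(biasFieldSpec("radial", centerScale = 1.0,
                                     edgeScale = 0.9), geom)
  ctrIdx <- round(geom@dim / 2)
  expect_equal(rad[ctrIdx[1], ctrIdx[2], ctrIdx[3]], 1.0, tolerance = 0.01)
  expect_true(all(rad >= 0.9 - 1e-9 & rad <= 1.0 + 1e-9))

  sm <- makeBiasField(biasFieldSpec("smooth_random", correlationLength = 20,
                                    amplitude = 0.1, seed = 2L), geom)
  expect_gt(min(sm), 0.8)
  expect_true(all(sm > 0))
  # deviations are scaled so the largest is exactly the amplitude
  expect_equal(max(abs(sm - 1)), 0.1, tolerance = 1e-9)
  expect_true(all(sm >= 0.9 - 1e-9 & sm <= 1.1 + 1e-9))
  # determinism
  sm2 <- makeBiasField(biasFieldSpec("smooth_random", correlationLength = 20,
                                     amplitude = 0.1, seed = 2L), geom)
  expect_identical(sm, sm2)
})

test_that("bias application is multiplicative, time-independent and exact", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  img <- ph$image

  uni <- makeBiasField(biasFieldSpec("uniform", s = 0.9), img@geometry)
  expect_equal(voxelData(applyBias(img, uni)), 0.9 * voxelData(img),
               tolerance = 1e-12)
  expect_equal(voxelData(applyBias(img, makeBiasField(
    biasFieldSpec("uniform", s = 1), img@geometry))), voxelData(img))

  sm <- makeBiasField(biasFieldSpec("smooth_random", amplitude = 0.1,
                                    seed = 9L), img@geometry)
  biased <- applyBias(img, sm)
  # for any voxel inside the brain the biased/unbiased TAC ratio is constant
  vox <- maskVoxels(ph$truth$lesion)[1:25, , drop = FALSE]
  for (r in seq_len(nrow(vox))) {
    ratios <- voxelData(biased)[vox[r, 1], vox[r, 2], vox[r, 3], ] /
      voxelData(img)[vox[r, 1], vox[r, 2], vox[r, 3], ]
    expect_equal(ratios, rep(ratios[1], 8), tolerance = 1e-12)
  }
  expect_error(applyBias(img, sm[1:10, , ]), "dims")
  expect_error(applyBias(img, sm - 2), "positive")
})

test_that("fixed-mask labels and TTP are immune to any positive bias field", {
  sp <- tinyPhantomSpec(lesionModel = kineticModel("gamma_variate", A = 3.2,
                                                   tp = 26, alpha = 2))
  ph <- buildPhantom(sp)
  geom <- ph$image@geometry
  lesionCtr <- gridToWorld(geom, (geom@dim + 1) / 2) + c(-16, 8, 0)
  fix <- sphereVOI(geom, lesionCtr, 15.6)
  for (specb in list(biasFieldSpec("uniform", s = 0.92),
                     biasFieldSpec("radial", centerScale = 1.05, edgeScale = 0.9),
                     biasFieldSpec("smooth_random", amplitude = 0.1, seed = 3L))) {
    biased <- applyBias(ph$image, makeBiasField(specb, ph$image@geometry))
    t0 <- extractTAC(ph$image, fix); t1 <- extractTAC(biased, fix)
    expect_identical(timeToPeak(t1), timeToPeak(t0))
    expect_identical(as.character(classifyPattern3(t1)),
                     as.character(classifyPattern3(t0)))
    expect_identical(classifyPattern2(t1), classifyPattern2(t0))
  }
})

test_that("a vessel admixture flips the mixed curve to DECREASING at a stable fraction", {
  lesion <- kineticModel("increasing", A = 3, tau = 12)
  vessel <- kineticModel("gamma_variate", A = 6, tp = 2, alpha = 3)
  f <- vesselFlipFraction(lesion, vessel)
  expect_true(is.finite(f))
  expect_gt(f, 0)
  expect_lt(f, 1)
  # pure lesion stays increasing, pure vessel is decreasing
  sched <- standardSchedule()
  expect_equal(as.character(classifyPattern3(
    tacFromCurve(frameAverageCurve(lesion, sched), sched))), "INCREASING")
  expect_equal(as.character(classifyPattern3(
    tacFromCurve(frameAverageCurve(vessel, sched), sched))), "DECREASING")
  # the sweep is analytic, hence identical however often it is repeated
  expect_identical(f, vesselFlipFraction(lesion, vessel))
})
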