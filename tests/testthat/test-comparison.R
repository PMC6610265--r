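# Construct a LesionMetrics directly for harness tests.
mkMetrics <- function(def, p2 = "INCREASING", p3 = "INCREASING",
                      ttpFrame = 8L, tbrVal = 2.0, vol = 1.0,
                      excluded = FALSE, reason = NA_character_) {
  new("LesionMetrics", definition = def, pattern2 = p2, pattern3 = p3,
      ttpFrame = as.integer(ttpFrame),
      ttpMin = frameEnds(standardSchedule())[ttpFrame],
      tbr = tbrVal, volumeML = vol, lateDescent = FALSE,
      excluded = excluded, exclusionReason = reason)
}

test_that("a homogeneous increasing lesion yields INCREASING for all definitions", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  m <- suppressMessages(analyzeLesion(ph$image, tumourHint = ph$truth$lesion,
                                      brainMask = ph$truth$brain_envelope))
  expect_setequal(names(m),
                  c("ROI90", "VOI90", "ROI_TBR", "VOI_TBR", "VOI_FIX"))
  for (def in names(m)) {
    expect_false(m[[def]]@excluded)
    expect_equal(m[[def]]@pattern3, "INCREASING", label = def)
    expect_equal(m[[def]]@pattern2, "INCREASING", label = def)
    expect_equal(m[[def]]@ttpFrame, m$ROI90@ttpFrame, label = def)
    expect_gt(m[[def]]@tbr, 1)
    expect_gt(m[[def]]@volumeML, 0)
  }
  expect_error(suppressMessages(analyzeLesion(
    ph$image, tumourHint = regionMask(matrix(integer(0), 0, 3)))), "empty")
})

test_that("a flooding threshold segmentation is excluded while others are reported", {
  # heterogeneous lesion: hot core, mild rim above 1.6 x background but
  # below 90% of the core maximum, and large enough to exceed 50 mL
  geom <- smallGeom()
  ctr <- gridToWorld(geom, (geom@dim + 1) / 2)
  core <- phantomStructure("core", "sphere", ctr, kineticModel("constant", A = 4),
                           radius = 8)
  rim <- phantomStructure("lesion", "sphere", ctr,
                          kineticModel("constant", A = 2.4), radius = 26,
                          compartments = list(core))
  brain <- phantomStructure("brain", "ellipsoid", ctr,
                            kineticModel("constant", A = 1.2),
                            semiaxes = geom@dim * geom@spacing * 0.45)
  ph <- buildPhantom(phantomSpec(geom, brain, list(rim)))
  m <- suppressMessages(analyzeLesion(ph$image, tumourHint = ph$truth$lesion,
                                      backgroundCenter = ctr + c(55, 0, 0)))
  expect_true(m$VOI_TBR@excluded)
  expect_match(m$VOI_TBR@exclusionReason, "volume")
  expect_false(m$VOI90@excluded)   # 90% threshold stays in the core
  expect_false(m$ROI_TBR@excluded) # single slice stays small
  expect_false(m$VOI_FIX@excluded)
})

test_that("change records fill deltas and flag pattern changes", {
  ref <- list(ROI90 = mkMetrics("ROI90", ttpFrame = 5),
              VOI_FIX = mkMetrics("VOI_FIX", p3 = "PLATEAU"))
  idrec <- compareToReference(ref, ref)
  expect_true(all(!idrec$pattern2_changed))
  expect_true(all(!idrec$pattern3_changed))
  expect_true(all(idrec$delta_ttp_frames == 0))
  expect_true(all(idrec$tbr_rel_diff == 0))
  expect_true(all(idrec$volume_rel_diff == 0))

  test <- list(ROI90 = mkMetrics("ROI90", ttpFrame = 6, tbrVal = 1.9, vol = 1.2),
               VOI_FIX = mkMetrics("VOI_FIX", p3 = "INCREASING"))
  rec <- compareToReference(ref, test)
  r1 <- rec[rec$definition == "ROI90", ]
  expect_equal(r1$delta_ttp_frames, 1)
  expect_equal(r1$tbr_rel_diff, (1.9 - 2.0) / 2.0)
  expect_equal(r1$volume_rel_diff, 0.2)
  r2 <- rec[rec$definition == "VOI_FIX", ]
  expect_true(r2$pattern3_changed)
  expect_false(r2$pattern2_changed)

  # an exclusion on either side yields an excluded record
  test2 <- list(ROI90 = mkMetrics("ROI90", excluded = TRUE, reason = "too big"),
                VOI_FIX = mkMetrics("VOI_FIX"))
  rec2 <- compareToReference(ref, test2)
  expect_true(rec2[rec2$definition == "ROI90", "excluded"])
  expect_error(compareToReference(ref, list(ROI90 = mkMetrics("ROI90"))),
               "same definitions")
})

test_that("aggregation reports whole-percent changes and the TTP multiset format", {
  mk <- function(les, changed3, dttp) data.frame(
    lesion_id = les, ac_method = "Dixon", definition = "ROI90",
    pattern2_changed = FALSE, pattern3_changed = changed3,
    delta_ttp_frames = dttp, tbr_rel_diff = 0, volume_rel_diff = 0,
    excluded = FALSE, exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, c(lapply(1:24, function(i)
    mk(paste0("les", i), i == 1, if (i == 1) 1L else if (i == 2) -3L else 0L)),
    list(make.row.names = FALSE)))
  s <- aggregateChanges(rows)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_evaluated, 24)
  expect_equal(s$pattern3_changed_pct, 4)  # 1/24 rounds to 4%
  expect_equal(s$pattern3_changed_frac, 1 / 24)
  expect_equal(s$ttp_summary, "2/24 (1, 3)")

  none <- rows; none$pattern3_changed <- FALSE; none$delta_ttp_frames <- 0L
  s0 <- aggregateChanges(none)
  expect_equal(s0$pattern3_changed_pct, 0)
  expect_equal(s0$pattern2_changed_pct, 0)
  expect_equal(s0$ttp_summary, "0/24")
})

test_that("reference-vs-itself end to end produces zero changes everywhere", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0.05, seed = 9L)
  ph <- buildPhantom(sp)
  m <- suppressMessages(analyzeLesion(ph$image, tumourHint = ph$truth$lesion))
  rec <- compareToReference(m, m)
  ev <- rec[!rec$excluded, ]
  expect_gt(nrow(ev), 0)
  expect_true(all(!ev$pattern2_changed & !ev$pattern3_changed))
  expect_true(all(ev$delta_ttp_frames == 0))
  expect_true(all(ev$tbr_rel_diff == 0 & ev$volume_rel_diff == 0))
})

test_that("uniform bias leaves relative-threshold masks and patterns unchanged", {
  sp <- tinyPhantomSpec(noiseSigma0 = 0)
  ph <- buildPhantom(sp)
  biased <- applyBias(ph$image, makeBiasField(biasFieldSpec("uniform", s = 0.9),
                                              ph$image@geometry))
  ref <- suppressMessages(analyzeLesion(ph$image, tumourHint = ph$truth$lesion))
  tst <- suppressMessages(analyzeLesion(biased, tumourHint = ph$truth$lesion))
  rec <- compareToReference(ref, tst)
  r90 <- rec[rec$definition %in% c("ROI90", "VOI90"), ]
  expect_true(all(!r90$pattern3_changed))
  expect_true(all(r90$delta_ttp_frames == 0))
  expect_true(all(r90$volume_rel_diff == 0))
})
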