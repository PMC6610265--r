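#' Phantom scene building blocks
#'
#' `phantomStructure` describes one geometric structure of a synthetic
#' brain scene and the kinetic model its voxels follow. Shapes:
#' \describe{
#'   \item{sphere / ellipsoid}{`center` (mm) with `radius` or 3 `semiaxes`.}
#'   \item{cylinder}{z-axis-aligned tube (`center`, `radius`, `halfLength`),
#'     used for vessels such as the internal carotid artery.}
#'   \item{shell}{ellipsoidal shell between `innerSemiaxes` and `semiaxes`,
#'     used for scalp uptake.}
#' }
#' Lesions may carry `compartments` — sub-structures painted inside the
#' parent to model heterogeneous tumours; compartments override the parent
#' without counting as an overlap.
#'
#' @param name Unique structure name.
#' @param shape `"sphere"`, `"ellipsoid"`, `"cylinder"` or `"shell"`.
#' @param center World centre in mm.
#' @param model A [kineticModel()].
#' @param radius Radius in mm (sphere / cylinder).
#' @param semiaxes Semiaxes in mm (ellipsoid / shell outer).
#' @param innerSemiaxes Inner semiaxes in mm (shell).
#' @param halfLength Half-length along z in mm (cylinder).
#' @param compartments Optional list of `phantomStructure`s nested inside.
#' @return A `PhantomStructure` object.
#' @export
phantomStructure <- function(name, shape = c("sphere", "ellipsoid", "cylinder", "shell"),
                             center, model, radius = NULL, semiaxes = NULL,
                             innerSemiaxes = NULL, halfLength = NULL,
                             compartments = NULL) {
  shape <- match.arg(shape)
  stopifnot(inherits(model, "KineticModel"), length(center) == 3L)
  if (shape %in% c("sphere", "cylinder"))
    stopifnot_scalar_number(radius, "radius", positive = TRUE)
  if (shape == "cylinder")
    stopifnot_scalar_number(halfLength, "halfLength", positive = TRUE)
  if (shape %in% c("ellipsoid", "shell"))
    stopifnot(length(semiaxes) == 3L, all(semiaxes > 0))
  if (shape == "shell")
    stopifnot(length(innerSemiaxes) == 3L, all(innerSemiaxes > 0))
  structure(list(name = name, shape = shape, center = as.numeric(center),
                 model = model, radius = radius, semiaxes = semiaxes,
                 innerSemiaxes = innerSemiaxes, halfLength = halfLength,
                 compartments = compartments),
            class = "PhantomStructure")
}

.structureArray <- function(st, geometry) {
  switch(st$shape,
         sphere = ellipsoidArray(geometry, st$center, st$radius),
         ellipsoid = ellipsoidArray(geometry, st$center, st$semiaxes),
         cylinder = cylinderArray(geometry, st$center, st$radius, st$halfLength),
         shell = shellArray(geometry, st$center, st$semiaxes, st$innerSemiaxes))
}

#' Specification of a synthetic dynamic brain scene
#'
#' Declares a complete 4D phantom: geometry, frame schedule, a brain
#' background structure, lesions, physiological-uptake confounders (vessel,
#' scalp), the noise level and the seed. The seed fully determines the
#' realised image.
#'
#' Noise emulates the count statistics of frame-wise reconstruction:
#' additive zero-mean Gaussian on SUV with per-frame standard deviation
#' `noiseSigma0 / sqrt(dt_f / 10)`, i.e. `noiseSigma0` is the SUV noise of a
#' 10-min reference frame and shorter frames are noisier in proportion to
#' the square root of their duration.
#'
#' @param geometry An [ImageGeometry-class].
#' @param brain A `phantomStructure` for the brain background (painted
#'   first; lesions and intracranial confounders override it).
#' @param lesions List of `phantomStructure`s.
#' @param confounders List of `phantomStructure`s with physiological uptake.
#' @param schedule A [FrameSchedule-class] (default [standardSchedule()]).
#' @param noiseSigma0 SUV noise sigma at the 10-min reference duration;
#'   0 disables noise.
#' @param seed Integer seed for the noise realisation.
#' @param priority Optional character vector of structure names, highest
#'   priority first, resolving overlaps between lesions/confounders.
#'   Without it, any such overlap is an error.
#' @return A `PhantomSpec` object.
#' @seealso [buildPhantom()], [defaultPhantomSpec()]
#' @export
phantomSpec <- function(geometry, brain, lesions = list(), confounders = list(),
                        schedule = standardSchedule(), noiseSigma0 = 0,
                        seed = 1L, priority = NULL) {
  stopifnot(is(geometry, "ImageGeometry"), is(schedule, "FrameSchedule"),
            inherits(brain, "PhantomStructure"), noiseSigma0 >= 0)
  structs <- c(lesions, confounders)
  nm <- vapply(structs, `[[`, character(1), "name")
  if (anyDuplicated(c("brain", nm))) stop("structure names must be unique")
  structure(list(geometry = geometry, brain = brain, lesions = lesions,
                 confounders = confounders, schedule = schedule,
                 noiseSigma0 = noiseSigma0, seed = as.integer(seed),
                 priority = priority),
            class = "PhantomSpec")
}

#' Build a phantom scene
#'
#' Realises a [phantomSpec()] into a dynamic image plus ground truth. Every
#' voxel of a structure follows the frame-averaged curve of that structure's
#' kinetic model (what a frame-wise reconstruction would report), then
#' frame-duration-scaled Gaussian noise is added. Ground-truth three-class
#' pattern labels are derived from the noise-free frame-averaged curves via
#' [classifyPattern3()].
#'
#' Overlaps between two lesions/confounders are an error unless the spec
#' gives an explicit `priority` order (earlier name wins), which enables
#' deliberate partial-volume scenes.
#'
#' @param spec A [phantomSpec()].
#' @return A list with elements `image` ([DynamicImage-class]), `truth`
#'   (named list of [RegionMask-class], one per structure incl. `brain`),
#'   `labels` (named character, expected 3-class pattern per structure) and
#'   `curves` (named list of noise-free frame-averaged curves).
#' @export
buildPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  geom <- spec$geometry
  d <- geom@dim
  nf <- nFrames(spec$schedule)
  structs <- c(spec$lesions, spec$confounders)
  nm <- vapply(structs, `[[`, character(1), "name")

  owner <- array(0L, dim = d)  # 0 = outside, 1 = brain, 1+i = structs[[i]]
  brainArr <- .structureArray(spec$brain, geom)
  owner[brainArr] <- 1L
  rank <- function(name) {
    if (is.null(spec$priority)) return(NA_integer_)
    r <- match(name, spec$priority)
    if (is.na(r)) length(spec$priority) + 1L else r
  }
  for (i in seq_along(structs)) {
    arr <- .structureArray(structs[[i]], geom)
    clashIdx <- which(arr & owner > 1L)
    if (length(clashIdx) > 0 && is.null(spec$priority))
      stop(sprintf("structure '%s' overlaps '%s'; give an explicit priority order",
                   nm[i], nm[owner[clashIdx[1L]] - 1L]))
    owner[arr & owner <= 1L] <- i + 1L
    if (length(clashIdx) > 0) {
      win <- vapply(owner[clashIdx] - 1L,
                    function(j) rank(nm[i]) < rank(nm[j]), logical(1))
      owner[clashIdx[win]] <- i + 1L
    }
  }

  # frame-averaged curves, including lesion compartments
  curves <- list(brain = frameAverageCurve(spec$brain$model, spec$schedule))
  for (i in seq_along(structs))
    curves[[nm[i]]] <- frameAverageCurve(structs[[i]]$model, spec$schedule)

  vals <- array(0, dim = c(d, nf))
  nvox <- prod(d)
  flat <- matrix(vals, nrow = nvox, ncol = nf)
  ownerVec <- as.vector(owner)
  sel <- ownerVec == 1L
  if (any(sel)) flat[sel, ] <- matrix(curves$brain, sum(sel), nf, byrow = TRUE)
  for (i in seq_along(structs)) {
    sel <- ownerVec == i + 1L
    if (any(sel)) flat[sel, ] <- matrix(curves[[nm[i]]], sum(sel), nf, byrow = TRUE)
  }
  # lesion heterogeneity: compartments override the parent's voxels
  for (i in seq_along(structs)) {
    comps <- structs[[i]]$compartments
    if (is.null(comps)) next
    parent <- ownerVec == i + 1L
    for (cp in comps) {
      cpArr <- as.vector(.structureArray(cp, geom)) & parent
      if (!any(cpArr)) next
      cpCurve <- frameAverageCurve(cp$model, spec$schedule)
      curves[[paste(nm[i], cp$name, sep = ".")]] <- cpCurve
      flat[cpArr, ] <- matrix(cpCurve, sum(cpArr), nf, byrow = TRUE)
    }
  }

  if (spec$noiseSigma0 > 0) {
    sig <- spec$noiseSigma0 / sqrt(frameDurations(spec$schedule) / 10)
    noise <- withSeed(spec$seed, {
      n <- matrix(stats::rnorm(nvox * nf), nvox, nf)
      sweep(n, 2L, sig, "*")
    })
    flat <- flat + noise
  }
  img <- dynamicImage(array(flat, dim = c(d, nf)), geom, spec$schedule)

  # brain = background tissue only; brain_envelope = the full anatomical
  # brain region (embedded lesions/vessels included), the reference for
  # the outside-brain plausibility criterion
  truth <- list(brain = regionMask(which(owner == 1L, arr.ind = TRUE)),
                brain_envelope = regionMask(which(brainArr, arr.ind = TRUE)))
  labels <- c(brain = classifyPattern3(tacFromCurve(curves$brain, spec$schedule)))
  for (i in seq_along(structs)) {
    truth[[nm[i]]] <- regionMask(which(owner == i + 1L, arr.ind = TRUE))
    labels[nm[i]] <- classifyPattern3(tacFromCurve(curves[[nm[i]]], spec$schedule))
  }
  list(image = img, truth = truth, labels = labels, curves = curves)
}

#' Wrap a numeric per-frame curve as a time-activity curve
#'
#' Convenience constructor pairing a vector of per-frame mean SUVs with a
#' schedule's frame end times (nominal single-voxel source), e.g. for
#' classifying analytic curves.
#'
#' @param curve Numeric vector, one mean SUV per frame.
#' @param schedule A [FrameSchedule-class] of the same length.
#' @param definition Definition tag.
#' @return A [TimeActivityCurve-class].
#' @export
tacFromCurve <- function(curve, schedule, definition = "MANUAL") {
  new("TimeActivityCurve", frameEnd = frameEnds(schedule),
      meanSUV = as.numeric(curve), nVoxels = 1L, definition = definition)
}

#' Default phantom scene
#'
#' A brain-scale, desk-fast scene: 96 x 96 x 64 voxels at 2 mm isotropic; a
#' brain ellipsoid at constant background uptake (SUV 1.2); three spherical
#' lesions realising the three canonical patterns (increasing, plateau-like
#' late peak, early peak with descent); an internal-carotid-like vessel
#' (early blood peak near 1.5 min) and a scalp shell with physiological
#' uptake.
#'
#' @param seed Integer noise seed.
#' @param noiseSigma0 SUV noise at the 10-min reference frame duration.
#' @return A [phantomSpec()].
#' @export
defaultPhantomSpec <- function(seed = 1L, noiseSigma0 = 0.05) {
  geom <- imageGeometry(c(96, 96, 64), 2)
  ctr <- c(95, 95, 63)  # mm, volume centre
  brain <- phantomStructure("brain", "ellipsoid", ctr,
                            kineticModel("constant", A = 1.2),
                            semiaxes = c(70, 80, 50))
  lesions <- list(
    phantomStructure("lesion_inc", "sphere", ctr + c(-35, 20, 10),
                     kineticModel("increasing", A = 3, tau = 12), radius = 10),
    phantomStructure("lesion_plateau", "sphere", ctr + c(30, -25, 5),
                     kineticModel("gamma_variate", A = 3.2, tp = 28, alpha = 2),
                     radius = 9),
    # early peak with slow washout: the tail stays above background, as in
    # real early-peaking lesions (late tumour-to-brain contrast persists)
    phantomStructure("lesion_dec", "sphere", ctr + c(25, 35, -12),
                     kineticModel("gamma_variate", A = 4, tp = 8,
                                  alpha = 0.35),
                     radius = 8))
  confounders <- list(
    # blood-like curve: near-instant rise, slow washout (low-alpha gamma)
    phantomStructure("vessel", "cylinder", ctr + c(-18, -55, 0),
                     kineticModel("gamma_variate", A = 8, tp = 2.5,
                                  alpha = 0.12),
                     radius = 3, halfLength = 18),
    phantomStructure("scalp", "shell", ctr,
                     kineticModel("constant", A = 1.8),
                     semiaxes = c(82, 92, 60), innerSemiaxes = c(78, 88, 56)))
  phantomSpec(geom, brain, lesions, confounders,
              noiseSigma0 = noiseSigma0, seed = seed)
}

#' Vessel-contamination flip threshold
#'
#' When a threshold-based region spills into an adjacent vessel, the
#' extracted curve is a mixture of the lesion curve and the early-peaking
#' blood curve. This sweep locates the smallest vessel volume fraction at
#' which the mixed curve is categorised as DECREASING by the three-class
#' scheme while the pure lesion curve remains in its own class.
#'
#' @param lesionModel,vesselModel [kineticModel()]s for tumour and blood.
#' @param schedule A [FrameSchedule-class].
#' @param fractions Vessel volume fractions to sweep (default 0 to 1 by 0.01).
#' @param cfg A [classifierConfig()].
#' @return The smallest flipping fraction, or `NA` if none flips.
#' @export
vesselFlipFraction <- function(lesionModel, vesselModel,
                               schedule = standardSchedule(),
                               fractions = seq(0, 1, by = 0.01),
                               cfg = classifierConfig()) {
  lc <- frameAverageCurve(lesionModel, schedule)
  vc <- frameAverageCurve(vesselModel, schedule)
  for (f in fractions) {
    mix <- f * vc + (1 - f) * lc
    if (classifyPattern3(tacFromCurve(mix, schedule), cfg) == "DECREASING")
      return(f)
  }
  NA_real_
}
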