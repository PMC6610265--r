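#' Classifier configuration
#'
#' Quantifies the verbal rules of the established two- and three-class
#' uptake-pattern schemes.
#'
#' @param earlyPeakCutoffMin Minutes; a peak at or before this time counts
#'   as "early" (default 20, inclusive).
#' @param descentFraction Relative drop from peak to last frame,
#'   `(max - last) / max`, that counts as a true descent (default 0.10).
#' @param increaseTolerance Relative closeness of the last frame to the
#'   maximum under which a late-peaking, still-rising curve is called
#'   INCREASING rather than PLATEAU (default 0.025).
#' @return A `ClassifierConfig` list.
#' @export
classifierConfig <- function(earlyPeakCutoffMin = 20, descentFraction = 0.10,
                             increaseTolerance = 0.025) {
  stopifnot(earlyPeakCutoffMin > 0,
            descentFraction >= 0, descentFraction < 1,
            increaseTolerance >= 0, increaseTolerance < 1)
  structure(list(earlyPeakCutoffMin = earlyPeakCutoffMin,
                 descentFraction = descentFraction,
                 increaseTolerance = increaseTolerance),
            class = "ClassifierConfig")
}

#' Extract a time-activity curve
#'
#' The TAC of a region: for each reconstructed frame, the mean SUV over all
#' mask voxels, paired with the time elapsed from acquisition start to the
#' end of that frame.
#'
#' @param img A [DynamicImage-class].
#' @param mask A non-empty [RegionMask-class] inside the image grid.
#' @return A [TimeActivityCurve-class].
#' @export
extractTAC <- function(img, mask) {
  if (nrow(mask@voxels) == 0L) stop("cannot extract a TAC from an empty mask")
  d <- dim(img@values)
  lin <- maskLinearIndices(mask, d)
  nxyz <- prod(d[1:3])
  means <- vapply(seq_len(d[4L]), function(f)
    mean(img@values[lin + (f - 1L) * nxyz]), numeric(1))
  new("TimeActivityCurve", frameEnd = frameEnds(img@schedule),
      meanSUV = means, nVoxels = nrow(mask@voxels),
      definition = mask@definition)
}

#' Time to peak
#'
#' The elapsed time from tracer injection (= acquisition start) to the
#' maximum regional concentration: the end time of the earliest frame
#' attaining the maximum mean SUV (earliest-frame tie-break).
#'
#' @param tac A [TimeActivityCurve-class].
#' @return A list with `frame` (1-based index) and `min` (minutes).
#' @export
timeToPeak <- function(tac) {
  f <- which.max(tac@meanSUV)  # which.max takes the earliest maximum
  list(frame = as.integer(f), min = tac@frameEnd[f])
}

#' Tissue-to-background ratio
#'
#' Mean lesion SUV in the last 10-min frame (the frame covering 30-40 min
#' of the standard schedule) divided by the background SUV.
#'
#' @param img A [DynamicImage-class].
#' @param lesion A [RegionMask-class].
#' @param background Background SUV (> 0), typically the mean over a 2-cm
#'   contralateral sphere in the same frame or the summed image.
#' @return Dimensionless ratio.
#' @export
tbr <- function(img, lesion, background) {
  stopifnot(background > 0)
  lastFrame <- nFrames(img)
  tacv <- extractTAC(img, lesion)
  tacv@meanSUV[lastFrame] / background
}

.tacDescent <- function(tac) {
  m <- max(tac@meanSUV)
  if (m <= 0) return(0)
  (m - tac@meanSUV[length(tac@meanSUV)]) / m
}

#' Two-class uptake-pattern categorisation
#'
#' The two-pattern scheme used with the 90%-of-maximum definitions:
#' \describe{
#'   \item{DECREASING}{the curve peaks within the early cutoff (<= 20 min,
#'     inclusive) and then falls by more than `descentFraction` from peak to
#'     last frame;}
#'   \item{INCREASING}{everything else — the only non-increasing class of
#'     the scheme is the early-peak-with-descent shape.}
#' }
#'
#' @param tac A [TimeActivityCurve-class] with at least 3 frames.
#' @param cfg A [classifierConfig()].
#' @return `"INCREASING"` or `"DECREASING"`.
#' @export
classifyPattern2 <- function(tac, cfg = classifierConfig()) {
  stopifnot(length(tac@meanSUV) >= 3L)
  ttp <- timeToPeak(tac)
  if (ttp$min <= cfg$earlyPeakCutoffMin && .tacDescent(tac) > cfg$descentFraction)
    "DECREASING" else "INCREASING"
}

#' Three-class uptake-pattern categorisation
#'
#' The three-pattern scheme used with the background-relative and fixed
#' definitions:
#' \describe{
#'   \item{DECREASING}{early peak (<= `earlyPeakCutoffMin`, inclusive)
#'     followed by a descent of more than `descentFraction`;}
#'   \item{INCREASING}{uptake still rising at the end of the acquisition:
#'     the maximum lies in the final frame, or the last frame is within
#'     `increaseTolerance` of a late (> cutoff) maximum with a rising tail;}
#'   \item{PLATEAU}{a late maximum followed by a plateau or slight descent —
#'     everything else.}
#' }
#' A late peak followed by a strong descent (> `descentFraction`) has no
#' class in the published three-class scheme; it is assigned PLATEAU and the
#' returned label carries attribute `lateDescent = TRUE` so callers can flag
#' the record.
#'
#' @param tac A [TimeActivityCurve-class] with at least 3 frames.
#' @param cfg A [classifierConfig()].
#' @return `"INCREASING"`, `"PLATEAU"` or `"DECREASING"` (with attribute
#'   `lateDescent` when applicable).
#' @export
classifyPattern3 <- function(tac, cfg = classifierConfig()) {
  stopifnot(length(tac@meanSUV) >= 3L)
  v <- tac@meanSUV
  n <- length(v)
  ttp <- timeToPeak(tac)
  d <- .tacDescent(tac)
  if (ttp$min <= cfg$earlyPeakCutoffMin && d > cfg$descentFraction)
    return("DECREASING")
  if (ttp$frame == n)
    return("INCREASING")
  if (ttp$min > cfg$earlyPeakCutoffMin &&
      v[n] >= (1 - cfg$increaseTolerance) * v[ttp$frame] &&
      v[n] >= v[n - 1L])
    return("INCREASING")
  if (ttp$min > cfg$earlyPeakCutoffMin && d > cfg$descentFraction) {
    lbl <- "PLATEAU"
    attr(lbl, "lateDescent") <- TRUE
    return(lbl)
  }
  "PLATEAU"
}
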