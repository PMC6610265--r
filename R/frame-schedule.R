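#' Construct a frame schedule
#'
#' @param ends Frame end times in minutes, strictly increasing; the first
#'   frame starts at 0 and each frame starts where the previous one ends.
#' @return A [FrameSchedule-class].
#' @examples
#' frameSchedule(c(2, 4, 8, 12, 16, 20, 30, 40))
#' @export
frameSchedule <- function(ends) {
  ends <- as.numeric(ends)
  starts <- c(0, ends[-length(ends)])
  new("FrameSchedule", frames = cbind(start = starts, end = ends))
}

#' The standard 40-min dynamic protocol
#'
#' Eight frames: 2 x 2 min, 4 x 4 min, 2 x 10 min, ending at
#' 2, 4, 8, 12, 16, 20, 30, 40 minutes.
#'
#' @return A [FrameSchedule-class] with 8 frames.
#' @export
standardSchedule <- function() {
  frameSchedule(c(2, 4, 8, 12, 16, 20, 30, 40))
}

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSchedule", function(x) nrow(x@frames))

#' @rdname accessors
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) unname(x@frames[, 1L]))

#' @rdname accessors
#' @export
setMethod("frameEnds", "FrameSchedule", function(x) unname(x@frames[, 2L]))

#' @rdname accessors
#' @export
setMethod("frameDurations", "FrameSchedule",
          function(x) unname(x@frames[, 2L] - x@frames[, 1L]))

#' Read / write a frame-schedule sidecar file
#'
#' The sidecar is a small versioned whitespace-separated text file with one
#' line per frame (start and end minutes), accompanying a 4D NIfTI whose
#' header carries no frame timing.
#'
#' @param path File path.
#' @param schedule A [FrameSchedule-class].
#' @return `readFrameSchedule` returns a [FrameSchedule-class];
#'   `writeFrameSchedule` returns `path` invisibly.
#' @export
readFrameSchedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("start", "end"))
  sched <- frameSchedule(tab$end)
  if (any(abs(frameStarts(sched) - tab$start) > 1e-9))
    stop("schedule file is not contiguous: starts do not match previous ends")
  sched
}

#' @rdname readFrameSchedule
#' @export
writeFrameSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "FrameSchedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dynFET frame schedule v1",
               "# columns: start_min end_min"), con)
  utils::write.table(schedule@frames, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Indices of the frames whose union covers [startMin, endMin]; endpoints not
# on frame boundaries are snapped to the nearest boundary (frames are the
# atomic unit of reconstructed data) with a warning.
frameWindow <- function(schedule, startMin, endMin, snap = TRUE) {
  bounds <- c(frameStarts(schedule)[1L], frameEnds(schedule))
  snapTo <- function(t, what) {
    d <- abs(bounds - t)
    b <- bounds[which.min(d)]
    if (min(d) > 1e-9) {
      if (!snap)
        stop(sprintf("window %s %g min is not a frame boundary (boundaries: %s)",
                     what, t, paste(bounds, collapse = ", ")))
      logNote("window %s snapped from %g to nearest frame boundary %g min",
              what, t, b)
    }
    b
  }
  s <- snapTo(startMin, "start")
  e <- snapTo(endMin, "end")
  if (e <= s) stop("window is empty after snapping to frame boundaries")
  which(frameStarts(schedule) >= s - 1e-9 & frameEnds(schedule) <= e + 1e-9)
}
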