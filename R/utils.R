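# Internal helpers shared across modules.

# Prefixed message so pipeline decisions taken at run time (window snapping,
# tie-breaks, exclusions, unclassifiable-shape flags) are visible in logs.
logNote <- function(fmt, ...) {
  message("dynFET | ", sprintf(fmt, ...))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Neighbour offsets for the configured connectivity. 2D offsets live in the
# xy-plane (axial slice); 3D offsets span all three axes.
neighbourOffsets <- function(connectivity, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (mode == "2D") {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0L))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0), , drop = FALSE]
    if (connectivity == 4) {
      g <- g[abs(g[, 1]) + abs(g[, 2]) == 1, , drop = FALSE]
    } else if (connectivity != 8) {
      stop("2D connectivity must be 4 or 8")
    }
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    if (connectivity == 6) {
      g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
    } else if (connectivity == 18) {
      g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
    } else if (connectivity != 26) {
      stop("3D connectivity must be 6, 18 or 26")
    }
  }
  storage.mode(g) <- "integer"
  unname(g)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
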