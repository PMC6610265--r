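# Shared fixtures, built in code at test time.

# A small brain-scale geometry that keeps tests fast.
smallGeom <- function(dim = c(40, 40, 24), spacing = 4) {
  imageGeometry(dim, spacing)
}

# Dynamic image whose every voxel follows the same per-frame values.
uniformDynamic <- function(perFrame, geom = smallGeom(),
                           sched = standardSchedule()) {
  stopifnot(length(perFrame) == nFrames(sched))
  vals <- array(rep(perFrame, each = prod(geom@dim)),
                dim = c(geom@dim, length(perFrame)))
  dynamicImage(vals, geom, sched)
}

# One homogeneous spherical lesion in a constant brain, noise configurable.
tinyPhantomSpec <- function(lesionModel = kineticModel("increasing", A = 3, tau = 12),
                            noiseSigma0 = 0, seed = 1L,
                            geom = smallGeom(), confounders = list(),
                            priority = NULL) {
  ctr <- gridToWorld(geom, (geom@dim + 1) / 2)
  brain <- phantomStructure("brain", "ellipsoid", ctr,
                            kineticModel("constant", A = 1.2),
                            semiaxes = geom@dim * geom@spacing * 0.42)
  les <- phantomStructure("lesion", "sphere", ctr + c(-16, 8, 0),
                          lesionModel, radius = 10)
  phantomSpec(geom, brain, list(les), confounders,
              noiseSigma0 = noiseSigma0, seed = seed, priority = priority)
}

# Independent connected-component oracle: iterative minimum-label
# propagation over the thresholded volume (a different algorithm from the
# package's breadth-first growth). Returns the sorted linear indices of the
# component containing `seed`.
ccOracleComponent <- function(values, seed, threshold, mode = "3D") {
  d <- dim(values)
  above <- values >= threshold
  if (mode == "2D") {
    keep <- array(FALSE, dim = d); keep[, , seed[3]] <- TRUE
    above <- above & keep
    offs <- as.matrix(expand.grid(-1:1, -1:1, 0))
  } else {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  }
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0, dim = d)
  lab[above] <- seq_len(sum(above))
  repeat {
    changed <- FALSE
    idx <- which(above, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      best <- lab[p[1], p[2], p[3]]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        l <- lab[q[1], q[2], q[3]]
        if (l > 0 && l < best) best <- l
      }
      if (best < lab[p[1], p[2], p[3]]) {
        lab[p[1], p[2], p[3]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(which(lab == lab[seed[1], seed[2], seed[3]] & above))
}

maskLinear <- function(mask, d) {
  v <- maskVoxels(mask)
  sort(as.integer((v[, 3] - 1) * (d[1] * d[2]) + (v[, 2] - 1) * d[1] + v[, 1]))
}
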