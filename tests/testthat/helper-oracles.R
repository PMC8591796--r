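# Brute-force reference implementations of the texture matrices, written as
# direct loops over voxels and neighbours, independent of the package's C++
# accumulators. Intended for small volumes only.

# The canonical 13 unique offsets (one of each +/- pair, in the package's
# documented order); symmetrized GLCM and run counts are sign-invariant.
oracleDirections <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,
           1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

.inBounds <- function(v, d) all(v >= 1) && all(v <= d)

oracleGlcm <- function(levels, ng) {
  d <- dim(levels)
  dirs <- oracleDirections()
  out <- array(0L, c(ng, ng, nrow(dirs)))
  for (k in seq_len(nrow(dirs))) {
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      li <- levels[x, y, z]
      if (li == 0) next
      nb <- c(x, y, z) + dirs[k, ]
      if (!.inBounds(nb, d)) next
      lj <- levels[nb[1], nb[2], nb[3]]
      if (lj == 0) next
      out[li, lj, k] <- out[li, lj, k] + 1L
      out[lj, li, k] <- out[lj, li, k] + 1L
    }
  }
  out
}

oracleGlrlm <- function(levels, ng) {
  d <- dim(levels)
  dirs <- oracleDirections()
  lmax <- max(d)
  out <- array(0L, c(ng, lmax, nrow(dirs)))
  for (k in seq_len(nrow(dirs))) {
    dirv <- dirs[k, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      prev <- c(x, y, z) - dirv
      if (.inBounds(prev, d)) next    # not a line start
      pos <- c(x, y, z)
      runLevel <- 0L; runLen <- 0L
      while (.inBounds(pos, d)) {
        l <- levels[pos[1], pos[2], pos[3]]
        if (l == runLevel && l != 0L) runLen <- runLen + 1L
        else {
          if (runLevel != 0L) out[runLevel, runLen, k] <-
              out[runLevel, runLen, k] + 1L
          runLevel <- l
          runLen <- if (l != 0L) 1L else 0L
        }
        pos <- pos + dirv
      }
      if (runLevel != 0L) out[runLevel, runLen, k] <-
          out[runLevel, runLen, k] + 1L
    }
  }
  out
}

# Zones as a sorted data.frame (level, size, n) via queue-based flood fill.
oracleGlszm <- function(levels) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    l <- levels[x, y, z]
    if (l == 0 || seen[x, y, z]) next
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0L
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (!.inBounds(nb, d)) next
        if (!seen[nb[1], nb[2], nb[3]] && levels[nb[1], nb[2], nb[3]] == l) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(l, size)
  }
  zm <- do.call(rbind, zones)
  agg <- aggregate(list(n = rep(1L, nrow(zm))),
                   by = list(level = zm[, 1], size = zm[, 2]), FUN = sum)
  agg[order(agg$level, agg$size), ]
}

oracleNgtdm <- function(levels, ng) {
  d <- dim(levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n <- numeric(ng); s <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    l <- levels[x, y, z]
    if (l == 0) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      v <- c(x, y, z) + offs[r, ]
      if (!.inBounds(v, d)) next
      lj <- levels[v[1], v[2], v[3]]
      if (lj > 0) nb <- c(nb, lj)
    }
    if (length(nb) == 0) next
    n[l] <- n[l] + 1
    s[l] <- s[l] + abs(l - mean(nb))
  }
  cbind(n, s)
}

oracleGldm <- function(levels, ng, alpha = 0L) {
  d <- dim(levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- matrix(0L, ng, 27)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    l <- levels[x, y, z]
    if (l == 0) next
    dep <- 0L
    for (r in seq_len(nrow(offs))) {
      v <- c(x, y, z) + offs[r, ]
      if (!.inBounds(v, d)) next
      lj <- levels[v[1], v[2], v[3]]
      if (lj > 0 && abs(lj - l) <= alpha) dep <- dep + 1L
    }
    out[l, dep + 1L] <- out[l, dep + 1L] + 1L
  }
  out
}

# Package zone matrix reshaped to the oracle's (level, size, n) layout.
packageZonesAsDf <- function(q) {
  zm <- dosiomics:::.cppGlszmZones(as.integer(gridValues(q)), gridDim(q))
  agg <- aggregate(list(n = rep(1L, nrow(zm))),
                   by = list(level = zm[, 1], size = zm[, 2]), FUN = sum)
  agg[order(agg$level, agg$size), ]
}
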