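# shared fixtures and independent oracles

.acceptance_cache <- new.env(parent = emptyenv())

# a tiny constant-signal series; per-direction signal levels settable
makeSeries <- function(dims = c(6, 6, 3), s0 = 1000,
                       sr = 900, sp = 1000, ss = 800,
                       bHigh = 800, spacing = c(1.25, 1.25, 2.5)) {
  DWISeries(array(s0, dims),
            list(r = array(sr, dims), p = array(sp, dims),
                 s = array(ss, dims)),
            bHigh = bHigh, spacing = spacing)
}

auVolume <- function(values, direction = "r", spacing = c(1, 1, 1)) {
  new("AugmentedADCVolume", values = values, direction = direction,
      spacing = spacing)
}

# independent connected-component oracle: dilation to fixpoint by array
# shifts (no shared code with the package's union-find/DFS kernels)
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy; zs <- seq_len(d[3]) - dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- a[xs[okx], ys[oky], zs[okz]]
  out
}

ccOracle <- function(values, seed, threshold, connectivity = 26) {
  mask <- values > threshold
  d <- dim(values)
  comp <- array(FALSE, d)
  if (!mask[seed[1], seed[2], seed[3]]) return(comp)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  repeat {
    grown <- comp
    for (i in seq_len(nrow(offs)))
      grown <- grown | shift3d(comp, offs$dx[i], offs$dy[i], offs$dz[i])
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# number of connected components of a 3D mask under 26-connectivity,
# via repeated oracle flood fills
nComponentsOracle <- function(mask, connectivity = 26) {
  vals <- array(as.numeric(mask), dim(mask))
  n <- 0
  while (any(mask)) {
    seed <- which(mask, arr.ind = TRUE)[1, ]
    comp <- ccOracle(vals, seed, 0.5, connectivity)
    mask <- mask & !comp
    vals[comp] <- 0
    n <- n + 1
  }
  n
}

# random blob mask inside a central window
randomMask <- function(nr, nc, density = 0.4, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- runif(length(rows) * length(cols)) < density
  if (!any(m)) m[rows[1], cols[1]] <- TRUE
  m
}
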