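# Shared fixtures, all built in code.

# uniform-canopy CHM with optional carved blocks (list of list(rows, cols,
# height)); 1 m cells by default
makeCHM <- function(nr = 40, nc = 40, height = 30, cellSize = 1,
                    blocks = list()) {
  v <- matrix(height, nr, nc)
  for (b in blocks) v[b$rows, b$cols] <- b$height
  RasterGrid(v, cellSize = cellSize, origin = c(0, nr * cellSize))
}

# small all-layers stack on an n x n 10 m grid with controllable fields
makeStack <- function(n = 30, canopy = NULL, vci = NULL, swamp = NULL,
                      cellSize = 10) {
  org <- c(0, n * cellSize)
  if (is.null(canopy)) canopy <- matrix(30, n, n)
  if (is.null(vci)) vci <- matrix(0.5, n, n)
  if (is.null(swamp)) swamp <- matrix(0, n, n)
  cap <- sqrt(2) * n * cellSize
  new("LandscapeStack",
      canopyHeight = RasterGrid(canopy, cellSize, org),
      vci = RasterGrid(vci, cellSize, org),
      distGapSmall = RasterGrid(matrix(cap, n, n), cellSize, org),
      distGapLarge = RasterGrid(matrix(cap, n, n), cellSize, org),
      swamp = RasterGrid(swamp, cellSize, org),
      params = list(targetCell = cellSize, gapHeight = 5, gapSmall = 50,
                    gapLarge = 500, sourceCell = cellSize,
                    nGapsSmall = 0L, nGapsLarge = 0L))
}

defaultTentative <- function(slShape = 1.3, slRate = 0.006, taMu = 0,
                             taKappa = 0.3)
  new("TentativeKernel", slShape = slShape, slRate = slRate, taMu = taMu,
      taKappa = taKappa, degenerate = FALSE)

# standardize strata columns with a global standardization table (the scale
# synthetic truth is expressed on)
standardizeWith <- function(strata, std) {
  for (i in seq_len(nrow(std))) {
    v <- std$variable[i]
    if (v %in% names(strata))
      strata[[v]] <- (strata[[v]] - std$mean[i]) / std$sd[i]
  }
  strata
}

# brute-force conditional-logistic grid search (1-D) -- the oracle for the
# Newton fitter on tiny problems
gridSearchClogit1D <- function(strataX, usedIdx, grid = seq(-5, 5, 1e-3)) {
  ll <- vapply(grid, function(b) {
    sum(vapply(seq_along(strataX), function(s) {
      eta <- b * strataX[[s]]
      eta[usedIdx[s]] - log(sum(exp(eta)))
    }, 0))
  }, 0)
  grid[which.max(ll)]
}
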