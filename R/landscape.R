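#' Detect canopy gaps in a canopy height model
#'
#' A canopy gap is a connected region (4-connectivity) of cells with no
#' vegetation above `heightThresh`, retained when its area reaches
#' `minArea`. Nodata cells never belong to a gap.
#'
#' @param chm canopy height model, a [RasterGrid-class] in metres.
#' @param heightThresh height (m) below which a cell counts as gap;
#'   default 5 m, the standard forested/non-forested cut.
#' @param minArea minimum gap area in m^2 (50 for "small", 500 for "large"
#'   gaps).
#' @return A [GapSet-class] with labelled regions and their areas.
#' @export
detectGaps <- function(chm, heightThresh = 5, minArea = 50) {
  stopifnot(is(chm, "RasterGrid"), heightThresh > 0, minArea >= 0)
  v <- chm@values
  if (all(is.na(v))) stop("empty CHM")
  mask <- !is.na(v) & v < heightThresh
  lab <- matrix(0L, nrow(v), ncol(v))
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask + 0)          # 4-connected components
    lab <- matrix(as.integer(lab), nrow(v), ncol(v))
    counts <- tabulate(lab[lab > 0L])
    areas <- counts * chm@cellSize^2
    keep <- which(areas >= minArea)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    areas <- areas[keep]
  } else {
    areas <- numeric()
  }
  if (length(areas)) names(areas) <- as.character(seq_along(areas))
  new("GapSet", labels = lab, areas = areas, cellSize = chm@cellSize,
      origin = chm@origin, crs = chm@crs, heightThresh = heightThresh,
      minArea = minArea)
}

#' @describeIn detectGaps areas (m^2) of the retained gap regions.
#' @param gaps a [GapSet-class].
#' @export
gapAreas <- function(gaps) gaps@areas

setMethod("show", "GapSet", function(object) {
  cat("GapSet:", length(object@areas), "gap(s) | height <",
      object@heightThresh, "m, area >=", object@minArea, "m^2\n")
  if (length(object@areas))
    cat("  areas (m^2):", paste(signif(object@areas, 4), collapse = ", "),
        "\n")
})

## project gap cells onto a (possibly coarser) target grid: a target cell is
## gap if ANY overlapping source gap cell falls in it
.gapMaskOnGrid <- function(gaps, grid) {
  f <- grid@cellSize / gaps@cellSize
  if (abs(f - round(f)) > 1e-9)
    stop("target cell size must be an integer multiple of the gap raster's")
  if (any(abs(gaps@origin - grid@origin) > 1e-6) ||
      !identical(gaps@crs, grid@crs))
    stop("gap raster and target grid are not co-registered")
  f <- as.integer(round(f))
  src <- gaps@labels > 0L
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  src <- src[seq_len(min(nrow(src), nr * f)),
             seq_len(min(ncol(src), nc * f)), drop = FALSE]
  out <- matrix(FALSE, nr, nc)
  grp_r <- (seq_len(nrow(src)) - 1L) %/% f + 1L
  grp_c <- (seq_len(ncol(src)) - 1L) %/% f + 1L
  any_r <- rowsum(src + 0, grp_r) > 0
  any_rc <- t(rowsum(t(any_r + 0), grp_c)) > 0
  out[seq_len(nrow(any_rc)), seq_len(ncol(any_rc))] <- any_rc
  out
}

#' Distance to the nearest canopy gap
#'
#' Centre-to-centre Euclidean distance from every cell of `grid` to the
#' nearest gap cell, zero inside gaps. Gap regions detected on a finer
#' raster are first mapped onto `grid` by "any overlap". With no gaps at
#' all, every cell takes the `cap` value (default: the raster diagonal).
#'
#' @param gaps a [GapSet-class].
#' @param grid target [RasterGrid-class] (the covariate grid).
#' @param cap distance (m) assigned everywhere when `gaps` is empty.
#' @return a [RasterGrid-class] of distances in metres.
#' @export
gapDistance <- function(gaps, grid, cap = NULL) {
  stopifnot(is(gaps, "GapSet"), is(grid, "RasterGrid"))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  if (is.null(cap))
    cap <- sqrt((nr * grid@cellSize)^2 + (nc * grid@cellSize)^2)
  if (length(gaps@areas) == 0L)
    return(RasterGrid(matrix(cap, nr, nc), grid@cellSize, grid@origin,
                      grid@crs))
  mask <- .gapMaskOnGrid(gaps, grid)
  ## distmap: per foreground (non-zero) pixel, exact Euclidean distance to
  ## the nearest background (zero) pixel -- gaps are the background here
  d <- EBImage::distmap(matrix(as.numeric(!mask), nr, nc))
  d <- matrix(as.numeric(d), nr, nc) * grid@cellSize
  RasterGrid(d, grid@cellSize, grid@origin, grid@crs)
}

#' Vertical complexity index from return-height profiles
#'
#' Normalized Shannon entropy of the per-cell vertical distribution of
#' LiDAR returns: `VCI = -sum(p_i log p_i) / log(n_bins)` with
#' `p_i = count_i / sum(counts)`. 0 when all returns share one height bin,
#' 1 for a perfectly even vertical profile. Cells without returns become
#' nodata. Invariant under rescaling all counts by a positive constant.
#'
#' @param profileCounts 3-D array `[rows, cols, bins]` of return counts per
#'   cell and height bin.
#' @param cellSize,origin,crs grid registration of the output raster.
#' @return a [RasterGrid-class] with values in `[0, 1]`.
#' @export
verticalComplexity <- function(profileCounts, cellSize = 10,
                               origin = c(0, 0), crs = "local") {
  stopifnot(is.array(profileCounts), length(dim(profileCounts)) == 3L)
  nb <- dim(profileCounts)[3]
  if (nb < 2L) stop("need at least 2 height bins")
  if (any(profileCounts < 0, na.rm = TRUE)) stop("negative counts")
  tot <- apply(profileCounts, c(1, 2), sum)
  p <- profileCounts / rep(tot, times = nb)   # recycles over bins
  plogp <- p * log(p)
  plogp[is.na(plogp) | !is.finite(plogp)] <- 0
  vci <- -apply(plogp, c(1, 2), sum) / log(nb)
  vci[!is.finite(tot) | tot == 0] <- NA_real_
  vci <- pmin(pmax(vci, 0), 1)
  RasterGrid(vci, cellSize, origin, crs)
}

#' Build the covariate landscape stack
#'
#' Assembles the five covariate layers used by the step-selection models on
#' one grid (default 10 m): canopy height (block mean of the fine CHM),
#' vertical complexity, distance to small and large canopy gaps (detected on
#' the fine CHM, distances at the covariate resolution), and the binary
#' swamp mask. Swamp nodata is propagated, never coerced to 0.
#'
#' @param chm fine-resolution canopy height model ([RasterGrid-class], m).
#' @param profiles 3-D array of per-cell vertical return counts on the
#'   *target* grid, or `NULL` to skip (VCI layer all nodata).
#' @param swamp binary swamp raster (0/1, `NA` = nodata) at the fine or
#'   target resolution.
#' @param targetCell covariate grid resolution (m).
#' @param gapHeight canopy height threshold (m) defining gaps.
#' @param gapSmall,gapLarge minimum areas (m^2) of small and large gaps.
#' @return a [LandscapeStack-class].
#' @export
buildLandscape <- function(chm, profiles = NULL, swamp = NULL,
                           targetCell = 10, gapHeight = 5,
                           gapSmall = 50, gapLarge = 500) {
  stopifnot(is(chm, "RasterGrid"))
  canopy <- aggregateRaster(chm, targetCell)
  nr <- nrow(canopy@values); nc <- ncol(canopy@values)

  if (!is.null(swamp)) {
    if (!is(swamp, "RasterGrid")) stop("swamp must be a RasterGrid")
    if (!identical(swamp@crs, chm@crs))
      stop("CRS mismatch between swamp mask and CHM")
    if (swamp@cellSize != targetCell) {
      sw <- aggregateRaster(swamp, targetCell)
      swv <- round(sw@values)        # majority of a 0/1 block
    } else swv <- swamp@values
    swv <- swv[seq_len(nr), seq_len(nc), drop = FALSE]
    swv[!(swv %in% c(0, 1))] <- NA_real_
  } else swv <- matrix(0, nr, nc)
  swampLayer <- RasterGrid(swv, targetCell, canopy@origin, canopy@crs)

  if (!is.null(profiles)) {
    if (!identical(dim(profiles)[1:2], c(nr, nc)))
      stop("profiles must be on the target grid")
    vci <- verticalComplexity(profiles, targetCell, canopy@origin,
                              canopy@crs)
  } else {
    vci <- RasterGrid(matrix(NA_real_, nr, nc), targetCell, canopy@origin,
                      canopy@crs)
  }

  gapsS <- detectGaps(chm, gapHeight, gapSmall)
  gapsL <- detectGaps(chm, gapHeight, gapLarge)
  distS <- gapDistance(gapsS, canopy)
  distL <- gapDistance(gapsL, canopy)

  new("LandscapeStack", canopyHeight = canopy, vci = vci,
      distGapSmall = distS, distGapLarge = distL, swamp = swampLayer,
      params = list(targetCell = targetCell, gapHeight = gapHeight,
                    gapSmall = gapSmall, gapLarge = gapLarge,
                    sourceCell = chm@cellSize,
                    nGapsSmall = length(gapsS@areas),
                    nGapsLarge = length(gapsL@areas)))
}

#' Access one layer of a landscape stack
#'
#' @param stack a [LandscapeStack-class].
#' @param name one of `"canopy_height"`, `"vci"`, `"dist_gap_small"`,
#'   `"dist_gap_large"`, `"swamp"`.
#' @return the requested [RasterGrid-class] layer.
#' @export
landscapeLayer <- function(stack, name) {
  switch(name,
    canopy_height = stack@canopyHeight,
    vci = stack@vci,
    dist_gap_small = stack@distGapSmall,
    dist_gap_large = stack@distGapLarge,
    swamp = stack@swamp,
    stop("unknown layer: ", name))
}

#' @describeIn landscapeLayer the layer names in canonical order.
#' @export
landscapeLayerNames <- function(stack)
  c("canopy_height", "vci", "dist_gap_small", "dist_gap_large", "swamp")

setMethod("show", "LandscapeStack", function(object) {
  d <- dim(object@canopyHeight@values)
  cat("LandscapeStack:", d[1], "x", d[2], "cells @",
      object@canopyHeight@cellSize, "m\n")
  cat("  layers: canopy_height, vci, dist_gap_small, dist_gap_large, swamp\n")
  cat("  gaps: ", object@params$nGapsSmall, " small (>=",
      object@params$gapSmall, " m^2), ", object@params$nGapsLarge,
      " large (>=", object@params$gapLarge, " m^2)\n", sep = "")
})

#' Extract all stack covariates at point coordinates
#'
#' @param stack a [LandscapeStack-class].
#' @param xy two-column matrix of map coordinates.
#' @return data.frame with one column per layer; `NA` for points off the
#'   raster or on nodata.
#' @export
extractCovariates <- function(stack, xy) {
  nm <- landscapeLayerNames(stack)
  out <- lapply(nm, function(n) extractAt(landscapeLayer(stack, n), xy))
  names(out) <- nm
  as.data.frame(out)
}
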