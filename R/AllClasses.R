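#' @import methods
NULL

#' RasterGrid: a regular raster on a projected, metre-based grid
#'
#' Minimal single-layer raster container. Values are stored as a numeric
#' matrix with row 1 at the top (maximum y); missing cells are `NA`. Cell
#' `(row, col)` covers the half-open interval
#' `[x0 + (col-1)*s, x0 + col*s) x (y0 - row*s, y0 - (row-1)*s]` where
#' `(x0, y0)` is the outer corner of cell `(1, 1)` and `s` the cell size.
#'
#' @slot values numeric matrix of cell values (`NA` = nodata).
#' @slot cellSize cell edge length in metres.
#' @slot origin numeric length-2, map coordinates `(x0, y0)` of the top-left
#'   corner of the grid.
#' @slot crs free-text identifier of the projected CRS; layers can only be
#'   combined when it matches.
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"),
  prototype(cellSize = 1, origin = c(0, 0), crs = "local"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite coordinates")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' GapSet: labelled canopy-gap regions
#'
#' Connected regions (4-connectivity) of a canopy height model falling below
#' a height threshold, with per-region areas. Label 0 marks non-gap cells.
#'
#' @slot labels integer matrix of region ids (0 = non-gap), same grid as the
#'   source raster.
#' @slot areas named numeric vector, area of each region in m^2.
#' @slot cellSize metres.
#' @slot origin,crs grid registration, as in [RasterGrid-class].
#' @slot heightThresh canopy height (m) below which a cell counts as gap.
#' @slot minArea minimum region area (m^2) retained.
#' @exportClass GapSet
setClass("GapSet",
  representation(labels = "matrix", areas = "numeric", cellSize = "numeric",
                 origin = "numeric", crs = "character",
                 heightThresh = "numeric", minArea = "numeric"))

setValidity("GapSet", function(object) {
  msg <- character()
  lab <- object@labels
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) != length(object@areas))
    msg <- c(msg, "areas must have one entry per labelled region")
  if (length(ids)) {
    counts <- tabulate(lab[lab > 0], nbins = max(ids))[ids]
    expect <- counts * object@cellSize^2
    got <- unname(object@areas[as.character(ids)])
    if (any(abs(expect - got) > 1e-9))
      msg <- c(msg, "areas inconsistent with label counts x cellSize^2")
  }
  if (length(msg)) msg else TRUE
})

#' LandscapeStack: co-registered covariate rasters
#'
#' The 10 m covariate stack used by step-selection models: canopy height (m),
#' vertical complexity index (unitless, in \[0, 1\]), Euclidean distance to
#' small and large canopy gaps (m), and a binary swamp mask. All layers share
#' one grid.
#'
#' @slot canopyHeight,vci,distGapSmall,distGapLarge,swamp [RasterGrid-class]
#'   layers on a common grid.
#' @slot params list of provenance: thresholds and cell sizes used to build
#'   the stack.
#' @exportClass LandscapeStack
setClass("LandscapeStack",
  representation(canopyHeight = "RasterGrid", vci = "RasterGrid",
                 distGapSmall = "RasterGrid", distGapLarge = "RasterGrid",
                 swamp = "RasterGrid", params = "list"))

setValidity("LandscapeStack", function(object) {
  msg <- character()
  layers <- list(object@canopyHeight, object@vci, object@distGapSmall,
                 object@distGapLarge, object@swamp)
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (!identical(dim(l@values), dim(ref@values)) ||
        abs(l@cellSize - ref@cellSize) > 1e-9 ||
        any(abs(l@origin - ref@origin) > 1e-6) ||
        !identical(l@crs, ref@crs)) {
      msg <- c(msg, "all layers must share shape, origin, cellSize and crs")
      break
    }
  }
  v <- object@vci@values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "vci must lie in [0, 1] or be NA")
  for (d in list(object@distGapSmall@values, object@distGapLarge@values))
    if (any(d < 0, na.rm = TRUE)) {
      msg <- c(msg, "gap distances must be non-negative"); break
    }
  s <- object@swamp@values
  if (!all(s %in% c(0, 1) | is.na(s)))
    msg <- c(msg, "swamp must be binary 0/1 or NA")
  if (length(msg)) msg else TRUE
})

#' TentativeKernel: selection-free movement distributions
#'
#' Gamma distribution of step length and von Mises distribution of turn
#' angle fitted to observed steps; used to propose control and candidate
#' steps.
#'
#' @slot slShape,slRate gamma shape and rate of step length (m).
#' @slot taMu,taKappa von Mises mean direction (radians, in `(-pi, pi]`) and
#'   concentration of turn angle.
#' @slot degenerate flag set when the turn-angle concentration hit the
#'   numerical cap (all angles essentially identical).
#' @exportClass TentativeKernel
setClass("TentativeKernel",
  representation(slShape = "numeric", slRate = "numeric",
                 taMu = "numeric", taKappa = "numeric",
                 degenerate = "logical"),
  prototype(taMu = 0, degenerate = FALSE))

setValidity("TentativeKernel", function(object) {
  msg <- character()
  if (object@slShape <= 0 || object@slRate <= 0)
    msg <- c(msg, "gamma parameters must be positive")
  if (object@taKappa < 0)
    msg <- c(msg, "taKappa must be non-negative")
  if (object@taMu <= -pi || object@taMu > pi)
    msg <- c(msg, "taMu must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' SelectionModel: a fitted conditional-logistic step-selection model
#'
#' Holds the estimated selection coefficients of
#' `w(x) = exp(beta_1 x_1 + ... + beta_n x_n)`, their covariance, and the
#' standardization parameters the covariates were scaled with (needed to
#' apply the model to new landscapes).
#'
#' @slot coef named numeric vector of coefficients.
#' @slot se named numeric vector, `sqrt(diag(vcov))`.
#' @slot vcov covariance matrix of the estimates (inverse observed
#'   information).
#' @slot loglik maximized conditional log-likelihood.
#' @slot nStrata number of strata used.
#' @slot converged logical convergence flag; `FALSE` flags separation or a
#'   failed Newton run, in which case estimates are diagnostics only.
#' @slot standardization data.frame with columns `variable`, `mean`, `sd`
#'   (empty when covariates entered unscaled).
#' @slot formula character vector of term names in design order.
#' @slot animal,species optional identifiers of the fitted individual.
#' @exportClass SelectionModel
setClass("SelectionModel",
  representation(coef = "numeric", se = "numeric", vcov = "matrix",
                 loglik = "numeric", nStrata = "integer",
                 converged = "logical", standardization = "data.frame",
                 formula = "character", animal = "character",
                 species = "character"),
  prototype(standardization = data.frame(), animal = NA_character_,
            species = NA_character_))

setValidity("SelectionModel", function(object) {
  msg <- character()
  p <- length(object@coef)
  if (!identical(dim(object@vcov), c(p, p)))
    msg <- c(msg, "vcov dimension must match coef length")
  else {
    if (max(abs(object@vcov - t(object@vcov))) > 1e-6)
      msg <- c(msg, "vcov must be symmetric")
    d <- diag(object@vcov)
    if (any(d < -1e-8)) msg <- c(msg, "vcov must be positive semi-definite")
    if (length(object@se) == p &&
        any(abs(object@se - sqrt(pmax(d, 0))) > 1e-6 * (1 + object@se)))
      msg <- c(msg, "se must equal sqrt(diag(vcov))")
  }
  if (length(msg)) msg else TRUE
})

#' GutPassageModel: gamma model of seed gut-passage time
#'
#' Method-of-moments gamma fit to a reported mean and spread (minutes) of
#' gut-passage time for one frugivore x tree-species pair.
#'
#' @slot species frugivore species label.
#' @slot treeSpecies tree species label.
#' @slot mean,spread reported mean and spread (interpreted as SD), minutes.
#' @slot shape,scale gamma parameters; `shape * scale == mean`.
#' @exportClass GutPassageModel
setClass("GutPassageModel",
  representation(species = "character", treeSpecies = "character",
                 mean = "numeric", spread = "numeric",
                 shape = "numeric", scale = "numeric"),
  prototype(species = NA_character_, treeSpecies = NA_character_))

setValidity("GutPassageModel", function(object) {
  msg <- character()
  if (any(c(object@mean, object@spread, object@shape, object@scale) <= 0))
    msg <- c(msg, "all parameters must be positive")
  if (abs(object@shape * object@scale - object@mean) > 1e-9 * object@mean)
    msg <- c(msg, "shape * scale must equal mean")
  if (length(msg)) msg else TRUE
})

#' RedistributionKernel: habitat-informed movement sampler
#'
#' Combines the tentative movement kernel with the selection coefficients
#' that were statistically significant, over a landscape stack. Drives the
#' trajectory simulation: at each step candidate locations drawn from the
#' tentative kernel are kept with probability proportional to
#' `exp(beta' x)`.
#'
#' @slot tentative [TentativeKernel-class] proposal distributions.
#' @slot beta named numeric vector of retained (significant) coefficients;
#'   habitat names must match stack layers, plus the movement terms
#'   `log_sl1` and `cos_ta`.
#' @slot standardization data.frame (`variable`, `mean`, `sd`) used to scale
#'   habitat covariates before applying `beta`.
#' @slot stack [LandscapeStack-class] the kernel moves over.
#' @slot nCandidates candidate locations scored per step.
#' @exportClass RedistributionKernel
setClass("RedistributionKernel",
  representation(tentative = "TentativeKernel", beta = "numeric",
                 standardization = "data.frame", stack = "LandscapeStack",
                 nCandidates = "integer"),
  prototype(nCandidates = 100L))

setValidity("RedistributionKernel", function(object) {
  msg <- character()
  habitat <- c("canopy_height", "vci", "dist_gap_small", "dist_gap_large",
               "swamp")
  movement <- c("log_sl1", "cos_ta")
  bad <- setdiff(names(object@beta), c(habitat, movement))
  if (length(bad))
    msg <- c(msg, paste("unknown kernel terms:", paste(bad, collapse = ", ")))
  if (object@nCandidates < 1L)
    msg <- c(msg, "nCandidates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SeedShadow: a spatially explicit seed-deposition surface
#'
#' Per-pixel seed-deposition probabilities around a source tree, with the
#' Poisson intensity `lambda` (mean per-pixel probability) and dispersal
#' distance summaries.
#'
#' @slot deposition [RasterGrid-class] of deposition probability per pixel.
#' @slot lambda mean per-pixel deposition probability over the mapped extent.
#' @slot source numeric length-2, the fruiting-tree coordinate.
#' @slot nTrajectories number of simulated trajectories behind the surface.
#' @slot distanceSummary named numeric: deposition-weighted `median` and
#'   `max` dispersal distance (m) of step endpoints from the source.
#' @slot tailMass gut-passage probability mass beyond the simulated horizon
#'   (reported, not renormalized).
#' @exportClass SeedShadow
setClass("SeedShadow",
  representation(deposition = "RasterGrid", lambda = "numeric",
                 source = "numeric", nTrajectories = "integer",
                 distanceSummary = "numeric", tailMass = "numeric"))

setValidity("SeedShadow", function(object) {
  msg <- character()
  dep <- object@deposition@values
  if (any(dep < 0, na.rm = TRUE))
    msg <- c(msg, "deposition must be non-negative")
  tot <- sum(dep, na.rm = TRUE)
  lam <- tot / length(dep)
  if (abs(lam - object@lambda) > 1e-9 * (1 + lam))
    msg <- c(msg, "lambda must equal total mass / n_pixels")
  if (length(msg)) msg else TRUE
})
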