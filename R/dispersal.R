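#' Gamma model of gut-passage time from a reported mean and spread
#'
#' Method-of-moments fit: `shape = (mean/spread)^2`,
#' `scale = spread^2/mean` (minutes), so `shape * scale = mean` exactly.
#' The spread is interpreted as the standard deviation of the gut-passage
#' distribution.
#'
#' @param mean mean gut-passage time, minutes.
#' @param spread spread of gut-passage time (SD), minutes.
#' @param species,treeSpecies optional labels for the frugivore x tree pair.
#' @return a [GutPassageModel-class].
#' @examples
#' fitGutPassage(345, 39)   # Staudtia seeds in a black-casqued hornbill
#' @export
fitGutPassage <- function(mean, spread, species = NA_character_,
                          treeSpecies = NA_character_) {
  if (mean <= 0 || spread <= 0) stop("mean and spread must be positive")
  new("GutPassageModel", species = species, treeSpecies = treeSpecies,
      mean = mean, spread = spread,
      shape = (mean / spread)^2, scale = spread^2 / mean)
}

setMethod("show", "GutPassageModel", function(object) {
  cat(sprintf("GutPassageModel: %.0f +/- %.0f min -> gamma(shape %.4g, scale %.4g)\n",
              object@mean, object@spread, object@shape, object@scale))
  if (!is.na(object@species))
    cat("  ", object@species, "x", object@treeSpecies, "\n")
})

#' Per-step seed-deposition probabilities
#'
#' Probability that a seed ingested at time 0 is deposited during movement
#' step `k`: `w_k = F(k dt) - F((k-1) dt)` for the gamma CDF `F` of
#' gut-passage time. Weights plus the tail mass beyond the simulated
#' horizon sum to 1 exactly; the tail is reported, never silently
#' renormalized.
#'
#' @param gpm a [GutPassageModel-class].
#' @param stepMinutes step duration, minutes (default 20).
#' @param nSteps number of movement steps (default 50).
#' @return list with `weights` (length `nSteps`) and `tail`.
#' @export
depositionWeights <- function(gpm, stepMinutes = 20, nSteps = 50) {
  stopifnot(nSteps >= 1)
  edges <- seq(0, nSteps * stepMinutes, by = stepMinutes)
  F <- stats::pgamma(edges, shape = gpm@shape, scale = gpm@scale)
  list(weights = diff(F), tail = 1 - F[length(F)])
}

## aggregate a standardization table to one mean/sd per variable (a
## population-level kernel averages the per-animal training moments)
.stdTable <- function(standardization) {
  if (!nrow(standardization)) return(standardization)
  agg <- stats::aggregate(cbind(mean, sd) ~ variable,
                          data = standardization, FUN = mean)
  agg
}

#' Build a redistribution kernel from a fitted selection model
#'
#' Keeps only the coefficients that influenced selection significantly
#' (Wald p below `pCutoff`) and pairs them with the tentative movement
#' kernel over a landscape stack. The resulting kernel drives
#' [simulateTrajectory()].
#'
#' @param model a converged [SelectionModel-class].
#' @param stack the [LandscapeStack-class] to move over.
#' @param tentative the [TentativeKernel-class] proposal distributions.
#' @param pCutoff significance cut for retaining coefficients
#'   (default 0.05).
#' @param nCandidates candidate locations scored per simulated step
#'   (default 100).
#' @param beta optional named coefficient vector overriding the
#'   significance screen (e.g. population-level estimates).
#' @param standardization optional standardization table overriding the
#'   model's.
#' @return a [RedistributionKernel-class].
#' @export
redistributionKernel <- function(model = NULL, stack, tentative,
                                 pCutoff = 0.05, nCandidates = 100,
                                 beta = NULL, standardization = NULL) {
  if (is.null(beta)) {
    if (is.null(model)) stop("provide a model or explicit beta")
    if (!model@converged) stop("model did not converge")
    p <- modelPvalues(model)
    keep <- names(model@coef)[is.finite(p) & p < pCutoff]
    keep <- setdiff(keep, "temp_swamp")  # kernel is time-agnostic
    beta <- model@coef[keep]
  }
  if (is.null(standardization))
    standardization <- if (!is.null(model)) model@standardization
                       else data.frame()
  new("RedistributionKernel", tentative = tentative, beta = beta,
      standardization = .stdTable(standardization), stack = stack,
      nCandidates = as.integer(nCandidates))
}

setMethod("show", "RedistributionKernel", function(object) {
  cat("RedistributionKernel:", object@nCandidates, "candidates/step\n")
  cat("  beta:", paste(sprintf("%s=%.3f", names(object@beta), object@beta),
                       collapse = ", "), "\n")
})

## score candidate endpoints under exp(beta' x); NA covariates -> score 0
.kernelScores <- function(kernel, covs, sl, ta) {
  beta <- kernel@beta
  std <- kernel@standardization
  eta <- numeric(nrow(covs))
  invalid <- rep(FALSE, nrow(covs))
  for (nm in names(beta)) {
    x <- switch(nm,
                log_sl1 = log(sl + 1),
                cos_ta = cos(ta),
                covs[[nm]])
    if (nm %in% std$variable) {
      i <- match(nm, std$variable)
      x <- (x - std$mean[i]) / std$sd[i]
    }
    invalid <- invalid | is.na(x)
    x[is.na(x)] <- 0
    eta <- eta + beta[[nm]] * x
  }
  ## any candidate with a missing habitat value is unusable
  invalid <- invalid | rowSums(is.na(covs)) > 0
  s <- exp(eta - max(eta[!invalid], -Inf))
  s[invalid] <- 0
  s
}

#' Simulate one foraging trajectory from a redistribution kernel
#'
#' Starts at the source with a uniform random initial heading. At each
#' step, `nCandidates` candidate endpoints are drawn from the tentative
#' kernel (gamma length, von Mises turn applied to the current heading) and
#' one is selected with probability proportional to `exp(beta' x)`
#' including the movement terms. Candidates off the raster or on nodata
#' score zero; if every candidate is invalid the draw is retried up to
#' `retryCap` times before the trajectory is flagged stuck (it then stays
#' in place for the remaining steps).
#'
#' @param kernel a [RedistributionKernel-class].
#' @param start numeric `(x, y)` on the raster (the fruiting tree crown).
#' @param nSteps number of movement steps (default 50).
#' @param seed RNG seed; the same seed reproduces the trajectory exactly.
#' @param retryCap redraw attempts when all candidates are invalid.
#' @return `(nSteps + 1) x 2` matrix of positions, first row = `start`;
#'   attribute `stuck` is `TRUE` when the walk was flagged.
#' @export
simulateTrajectory <- function(kernel, start, nSteps = 50, seed = NULL,
                               retryCap = 10L) {
  stack <- kernel@stack
  if (is.na(extractAt(stack@canopyHeight, matrix(start, 1))))
    stop("start position off the raster")
  if (!is.null(seed)) set.seed(seed)
  tk <- kernel@tentative
  K <- kernel@nCandidates
  pos <- matrix(NA_real_, nSteps + 1L, 2L,
                dimnames = list(NULL, c("x", "y")))
  pos[1L, ] <- start
  heading <- stats::runif(1, -pi, pi)
  stuck <- FALSE
  for (k in seq_len(nSteps)) {
    if (stuck) { pos[k + 1L, ] <- pos[k, ]; next }
    chosen <- NULL
    for (try in seq_len(retryCap)) {
      sl <- stats::rgamma(K, shape = tk@slShape, rate = tk@slRate)
      ta <- rvonmises(K, tk@taMu, tk@taKappa)
      hd <- heading + ta
      ex <- pos[k, 1] + sl * cos(hd)
      ey <- pos[k, 2] + sl * sin(hd)
      covs <- extractCovariates(stack, cbind(ex, ey))
      s <- .kernelScores(kernel, covs, sl, ta)
      if (any(s > 0)) {
        i <- sample.int(K, 1L, prob = s)
        chosen <- list(x = ex[i], y = ey[i], hd = hd[i])
        break
      }
    }
    if (is.null(chosen)) {
      stuck <- TRUE
      pos[k + 1L, ] <- pos[k, ]
    } else {
      pos[k + 1L, ] <- c(chosen$x, chosen$y)
      heading <- chosen$hd
    }
  }
  attr(pos, "stuck") <- stuck
  pos
}

## weighted quantile (type-4-ish: first x whose cumulative weight reaches p)
weightedQuantile <- function(x, w, probs) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], 0)
}

#' Rasterize weighted trajectories into a seed shadow
#'
#' Every step-`k` endpoint of every trajectory deposits mass
#' `weights[k] / n_trajectories`, smoothed by an isotropic Gaussian kernel
#' (truncated at 4 sigma) and rasterized on the deposition grid. The
#' default extent is the bounding box of all endpoints padded by 4 sigma,
#' which conserves the deposited mass exactly; a user extent may crop, and
#' the truncated mass is then reported. `lambda` is the mean per-pixel
#' deposition probability over the mapped extent.
#'
#' @param trajectories list of position matrices from
#'   [simulateTrajectory()], sharing their first row (the source).
#' @param weights per-step deposition weights (see [depositionWeights()]).
#' @param bandwidth Gaussian smoothing SD in metres (default 30 m = 3
#'   pixels at 10 m).
#' @param cellSize deposition raster resolution, metres.
#' @param grid optional [RasterGrid-class] defining the output extent.
#' @param tailMass gut-passage tail mass beyond the simulated horizon,
#'   carried into the object for reporting.
#' @param crs CRS label for a newly created grid.
#' @return a [SeedShadow-class].
#' @export
seedShadow <- function(trajectories, weights, bandwidth = 30,
                       cellSize = 10, grid = NULL, tailMass = 0,
                       crs = "local") {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  nSteps <- length(weights)
  nTraj <- length(trajectories)
  stopifnot(nTraj >= 1)
  src <- trajectories[[1L]][1L, ]
  for (tr in trajectories) {
    if (nrow(tr) != nSteps + 1L)
      stop("all trajectories must have n_steps = length(weights)")
    if (max(abs(tr[1L, ] - src)) > 1e-9)
      stop("all trajectories must share the source")
  }
  ends <- do.call(rbind, lapply(trajectories, function(tr)
    tr[-1L, , drop = FALSE]))
  w <- rep(weights / nTraj, times = nTraj)

  pad <- 4 * bandwidth + cellSize
  if (is.null(grid)) {
    x0 <- floor((min(ends[, 1]) - pad) / cellSize) * cellSize
    x1 <- ceiling((max(ends[, 1]) + pad) / cellSize) * cellSize
    y0 <- floor((min(ends[, 2]) - pad) / cellSize) * cellSize
    y1 <- ceiling((max(ends[, 2]) + pad) / cellSize) * cellSize
    nr <- as.integer(round((y1 - y0) / cellSize))
    nc <- as.integer(round((x1 - x0) / cellSize))
    grid <- RasterGrid(matrix(0, nr, nc), cellSize, origin = c(x0, y1),
                       crs = crs)
  } else {
    cellSize <- grid@cellSize
  }
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  acc <- matrix(0, nr, nc)

  ## discrete Gaussian patch, truncated at 4 sigma, normalized to sum 1
  r <- ceiling(4 * bandwidth / cellSize)
  off <- (-r):r
  g1 <- exp(-0.5 * (off * cellSize / bandwidth)^2)
  patch <- outer(g1, g1)
  patch <- patch / sum(patch)

  idx <- .cellIndex(grid, ends)
  truncated <- 0
  for (i in seq_len(nrow(ends))) {
    if (w[i] == 0) next
    if (is.na(idx[i, 1])) { truncated <- truncated + w[i]; next }
    rr <- idx[i, 1] + off; cc <- idx[i, 2] + off
    rok <- rr >= 1L & rr <= nr; cok <- cc >= 1L & cc <= nc
    sub <- patch[rok, cok, drop = FALSE]
    truncated <- truncated + w[i] * (1 - sum(sub))
    acc[rr[rok], cc[cok]] <- acc[rr[rok], cc[cok]] + w[i] * sub
  }
  dist <- sqrt((ends[, 1] - src[1])^2 + (ends[, 2] - src[2])^2)
  pos <- w > 0
  dsum <- if (any(pos))
    c(median = weightedQuantile(dist[pos], w[pos], 0.5),
      max = max(dist[pos]))
  else c(median = NA_real_, max = NA_real_)
  dep <- RasterGrid(acc, cellSize, grid@origin, grid@crs)
  shadow <- new("SeedShadow", deposition = dep,
                lambda = sum(acc) / length(acc), source = as.numeric(src),
                nTrajectories = as.integer(nTraj),
                distanceSummary = dsum, tailMass = tailMass)
  attr(shadow, "truncatedMass") <- truncated
  shadow
}

setMethod("show", "SeedShadow", function(object) {
  d <- dim(object@deposition@values)
  cat("SeedShadow:", d[1], "x", d[2], "px @",
      object@deposition@cellSize, "m |", object@nTrajectories,
      "trajectories\n")
  cat(sprintf("  lambda %.4g | mass %.4g | tail %.4g\n", object@lambda,
              sum(object@deposition@values), object@tailMass))
  cat(sprintf("  dispersal distance: median %.1f m, max %.1f m\n",
              object@distanceSummary["median"],
              object@distanceSummary["max"]))
})

#' @describeIn seedShadow the Poisson intensity (mean per-pixel deposition
#'   probability).
#' @param shadow a [SeedShadow-class].
#' @export
shadowLambda <- function(shadow) shadow@lambda

#' @describeIn seedShadow deposition-weighted distance summaries (m).
#' @export
dispersalDistances <- function(shadow) shadow@distanceSummary

#' Draw seed-deposition points from a seed shadow
#'
#' Per-pixel counts are Poisson with intensity
#' `deposition * totalSeeds`; points fall uniformly within their pixel.
#'
#' @param shadow a [SeedShadow-class].
#' @param totalSeeds expected number of dispersed seeds (> 0).
#' @param seed RNG seed.
#' @return two-column matrix of point coordinates (possibly 0 rows).
#' @export
sampleSeedPoints <- function(shadow, totalSeeds, seed = NULL) {
  if (totalSeeds <= 0) stop("totalSeeds must be positive")
  if (!is.null(seed)) set.seed(seed)
  dep <- shadow@deposition
  lam <- dep@values * totalSeeds
  counts <- stats::rpois(length(lam), lam)
  dim(counts) <- dim(lam)
  hit <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(hit)) return(matrix(numeric(), 0, 2,
                                dimnames = list(NULL, c("x", "y"))))
  n <- counts[hit]
  rows <- rep(hit[, 1], n); cols <- rep(hit[, 2], n)
  s <- dep@cellSize
  x <- dep@origin[1] + (cols - 1) * s + stats::runif(length(rows)) * s
  y <- dep@origin[2] - (rows - 1) * s - stats::runif(length(rows)) * s
  cbind(x = x, y = y)
}

#' Compare covariate distributions at used, available and simulated steps
#'
#' Model check for the simulation: per covariate, quantile tables and
#' shared-bin histograms of the endpoint values of observed (used),
#' available (control) and simulated locations, plus the total-variation
#' divergence between the used and simulated histograms. Close agreement
#' indicates the redistribution kernel reproduces the selection pattern in
#' the data.
#'
#' @param used,available,simulated data.frames of endpoint covariate
#'   values (all non-empty).
#' @param covariates covariate columns to compare.
#' @param nBins histogram bins over the pooled range.
#' @param probs quantile probabilities for the tables.
#' @return named list per covariate: `quantiles` (matrix sets x probs),
#'   `density` (data.frame of bin mids and per-set histogram densities),
#'   `tvUsedSim` (total variation, used vs simulated).
#' @export
evaluateMovementModel <- function(used, available, simulated,
                                  covariates = c("canopy_height", "vci",
                                                 "dist_gap_small",
                                                 "dist_gap_large", "swamp"),
                                  nBins = 30,
                                  probs = c(.05, .25, .5, .75, .95)) {
  stopifnot(nrow(used) > 0, nrow(available) > 0, nrow(simulated) > 0)
  out <- list()
  for (v in covariates) {
    sets <- list(used = used[[v]], available = available[[v]],
                 simulated = simulated[[v]])
    sets <- lapply(sets, function(x) x[is.finite(x)])
    rng <- range(unlist(sets))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = nBins + 1L)
    hists <- lapply(sets, function(x) {
      h <- graphics::hist(x, breaks = br, plot = FALSE)
      h$counts / sum(h$counts)
    })
    qs <- t(vapply(sets, stats::quantile, numeric(length(probs)),
                   probs = probs))
    out[[v]] <- list(
      quantiles = qs,
      density = data.frame(mid = (br[-1] + br[-length(br)]) / 2,
                           used = hists$used, available = hists$available,
                           simulated = hists$simulated),
      tvUsedSim = 0.5 * sum(abs(hists$used - hists$simulated)))
  }
  out
}
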