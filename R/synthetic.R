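## Synthetic inputs with known ground truth: the test bed for parameter
## recovery. Defaults emulate the study conditions: a 3 x 3 km forest block
## at 10 m resolution, gamma/von Mises movement at a 30-min fix decision
## scale, diel temperature cycling, and selection driven by the same
## exponential habitat-selection function the models estimate.

## Gaussian random field: white noise smoothed by a separable Gaussian;
## implemented as banded-matrix products, then standardized
.smoothField <- function(nr, nc, sigmaPx) {
  W <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigmaPx > 0) {
    bandR <- outer(seq_len(nr), seq_len(nr),
                   function(i, j) exp(-0.5 * ((i - j) / sigmaPx)^2))
    bandC <- outer(seq_len(nc), seq_len(nc),
                   function(i, j) exp(-0.5 * ((i - j) / sigmaPx)^2))
    W <- bandR %*% W %*% bandC
  }
  (W - mean(W)) / stats::sd(W)
}

## near-square factor pair for a patch of `cells` cells
.patchDims <- function(cells) {
  h <- max(1L, floor(sqrt(cells)))
  w <- ceiling(cells / h)
  c(h, w)
}

#' Generate a synthetic landscape stack with known ground truth
#'
#' Canopy height is a Gaussian random field (white noise smoothed with a
#' Gaussian kernel of the configured range); gap patches are carved to
#' below the gap height threshold at requested areas; swamps are disc
#' blobs; the vertical complexity field is a second random field correlated
#' ~0.3 with canopy height (safely below the 0.6 collinearity screen). Gap
#' distance layers are computed with the package's own gap detection, and
#' the requested patch geometry is returned as truth for oracle tests.
#'
#' @param nr,nc grid dimensions (cells).
#' @param cellSize cell size, metres (default 10, the covariate
#'   resolution).
#' @param rangeM autocorrelation range of the random fields, metres.
#' @param canopyMean,canopySd canopy height moments, metres.
#' @param gapAreasSmall,gapAreasLarge requested gap areas in m^2 (small:
#'   >= 50 and < 500; large: >= 500).
#' @param nSwamp,swampRadiusM swamp blob count and radius (m).
#' @param vciCor target correlation between VCI and canopy height.
#' @param seed RNG seed; the same seed reproduces the stack exactly.
#' @return list with `stack` ([LandscapeStack-class]), `chm`, and `truth`
#'   (requested gap areas/positions, swamp fraction).
#' @export
synthLandscape <- function(nr = 300, nc = 300, cellSize = 10,
                           rangeM = 80, canopyMean = 30, canopySd = 8,
                           gapAreasSmall = c(100, 200, 300),
                           gapAreasLarge = c(600, 900),
                           nSwamp = 3, swampRadiusM = 200,
                           vciCor = 0.3, seed = 1L) {
  set.seed(seed)
  z1 <- .smoothField(nr, nc, rangeM / cellSize)
  chmv <- canopyMean + canopySd * z1
  chmv[chmv < 6] <- 6    # keep the matrix above the gap threshold;
                         # gaps are carved explicitly below

  areas <- c(gapAreasSmall, gapAreasLarge)
  centers <- matrix(NA_real_, length(areas), 2)
  occupied <- matrix(FALSE, nr, nc)
  margin <- 5L
  for (i in seq_along(areas)) {
    dims <- .patchDims(round(areas[i] / cellSize^2))
    if (dims[1] > nr - 2 * margin || dims[2] > nc - 2 * margin)
      stop("gap patch exceeds grid")
    for (try in 1:200) {
      r0 <- sample((margin + 1):(nr - margin - dims[1]), 1)
      c0 <- sample((margin + 1):(nc - margin - dims[2]), 1)
      rows <- r0:(r0 + dims[1] - 1L); cols <- c0:(c0 + dims[2] - 1L)
      ## one-cell buffer keeps separate patches from merging
      rb <- max(1, r0 - 1):min(nr, r0 + dims[1])
      cb <- max(1, c0 - 1):min(nc, c0 + dims[2])
      if (!any(occupied[rb, cb])) break
      if (try == 200) stop("could not place gap patches")
    }
    ncell <- round(areas[i] / cellSize^2)
    cells <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))[seq_len(ncell), ,
                                                   drop = FALSE]
    chmv[cells] <- stats::runif(nrow(cells), 0, 4)
    occupied[rb, cb] <- TRUE
    centers[i, ] <- c(mean(rows), mean(cols))
  }

  swamp <- matrix(0, nr, nc)
  if (nSwamp > 0) {
    rad <- swampRadiusM / cellSize
    for (i in seq_len(nSwamp)) {
      cr <- stats::runif(1, rad + 1, nr - rad)
      cc <- stats::runif(1, rad + 1, nc - rad)
      dd <- outer(seq_len(nr), seq_len(nc),
                  function(r, c) (r - cr)^2 + (c - cc)^2)
      swamp[dd <= rad^2] <- 1
    }
  }

  z2 <- vciCor * z1 + sqrt(1 - vciCor^2) * .smoothField(nr, nc,
                                                        rangeM / cellSize)
  vciv <- stats::pnorm(z2) * 0.8 + 0.1   # keep off the [0,1] boundary

  origin <- c(0, nr * cellSize)
  chm <- RasterGrid(chmv, cellSize, origin, "local")
  gapsS <- detectGaps(chm, 5, 50)
  gapsL <- detectGaps(chm, 5, 500)
  stack <- new("LandscapeStack",
               canopyHeight = chm,
               vci = RasterGrid(vciv, cellSize, origin, "local"),
               distGapSmall = gapDistance(gapsS, chm),
               distGapLarge = gapDistance(gapsL, chm),
               swamp = RasterGrid(swamp, cellSize, origin, "local"),
               params = list(targetCell = cellSize, gapHeight = 5,
                             gapSmall = 50, gapLarge = 500,
                             sourceCell = cellSize,
                             nGapsSmall = length(gapsS@areas),
                             nGapsLarge = length(gapsL@areas)))
  list(stack = stack, chm = chm,
       truth = list(gapAreasSmall = gapAreasSmall,
                    gapAreasLarge = gapAreasLarge,
                    gapCenters = centers, swampFraction = mean(swamp),
                    seed = seed))
}

#' Generate a diel temperature series
#'
#' Sinusoidal daily cycle (peak mid-afternoon) plus Gaussian noise,
#' recorded at a fixed station interval around the clock.
#'
#' @param days number of days.
#' @param intervalMin recording interval, minutes.
#' @param meanC,amplitudeC cycle mean and semi-amplitude, degrees C.
#' @param noiseSd observation noise SD, degrees C.
#' @param start first timestamp (UTC).
#' @param seed RNG seed.
#' @return data.frame with `timestamp`, `temp_c`.
#' @export
synthTemperature <- function(days = 30, intervalMin = 30, meanC = 24.5,
                             amplitudeC = 4, noiseSd = 0.4,
                             start = as.POSIXct("2023-01-01 00:00:00",
                                                tz = "UTC"),
                             seed = 1L) {
  set.seed(seed)
  ts <- seq(start, by = intervalMin * 60,
            length.out = days * 24 * 60 / intervalMin)
  tod <- (as.numeric(ts) / 60) %% 1440   # minutes of day
  temp <- meanC + amplitudeC * cos(2 * pi * (tod - 14 * 60) / 1440) +
    stats::rnorm(length(ts), 0, noiseSd)
  data.frame(timestamp = ts, temp_c = temp)
}

#' Default movement and selection configuration for synthetic tracks
#'
#' The configuration mirrors the study's sampling design (5-min daytime
#' fixes from 5:45 to 18:30, 30-min decision scale, 10-ish candidate
#' choice sets) with selection strengths of the magnitude estimated for
#' the tracked hornbills.
#'
#' @param trueBeta named selection coefficients on standardized covariates
#'   (plus raw binary swamp).
#' @param interactionSlope swamp-by-standardized-temperature slope.
#' @param betaLogSl,betaCosTa movement-term coefficients.
#' @param nAnimals,nSteps animals and 30-min decision steps per animal.
#' @param slShape,slRate,taMu,taKappa tentative kernel parameters (step
#'   length m at the 30-min scale; turn angle radians).
#' @param nCandidates choice-set size used when simulating.
#' @param fixIntervalMin emitted GPS fix interval, minutes.
#' @return a named list understood by [synthTracks()].
#' @export
synthTrackConfig <- function(trueBeta = c(canopy_height = 0.3, vci = 0.15,
                                          dist_gap_small = 0,
                                          dist_gap_large = 0, swamp = 0.4),
                             interactionSlope = 0,
                             betaLogSl = 0, betaCosTa = -0.2,
                             nAnimals = 5, nSteps = 600,
                             slShape = 1.3, slRate = 0.006,
                             taMu = 0, taKappa = 0.3,
                             nCandidates = 50, fixIntervalMin = 5) {
  list(trueBeta = trueBeta, interactionSlope = interactionSlope,
       betaLogSl = betaLogSl, betaCosTa = betaCosTa,
       nAnimals = nAnimals, nSteps = nSteps, slShape = slShape,
       slRate = slRate, taMu = taMu, taKappa = taKappa,
       nCandidates = nCandidates, fixIntervalMin = fixIntervalMin)
}

#' Landscape-wide covariate standardization table
#'
#' Mean and sample SD of each continuous covariate over all cells of the
#' stack (plus, optionally, the temperature series): the scale on which
#' synthetic ground-truth coefficients are expressed, and a drop-in
#' `standardization` table for population-level redistribution kernels.
#'
#' @param stack a [LandscapeStack-class].
#' @param tempSeries optional temperature data.frame (`timestamp`,
#'   `temp_c`).
#' @return data.frame with `variable`, `mean`, `sd`.
#' @export
stackStandardization <- function(stack, tempSeries = NULL) {
  vars <- c("canopy_height", "vci", "dist_gap_small", "dist_gap_large")
  recs <- lapply(vars, function(v) {
    x <- landscapeLayer(stack, v)@values
    data.frame(variable = v, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE))
  })
  if (!is.null(tempSeries))
    recs <- c(recs, list(data.frame(variable = "temperature",
                                    mean = mean(tempSeries$temp_c),
                                    sd = stats::sd(tempSeries$temp_c))))
  do.call(rbind, recs)
}

## choose one of n candidate endpoints under the true selection function
.chooseCandidate <- function(eta, valid) {
  s <- exp(eta - max(eta[valid]))
  s[!valid] <- 0
  sample.int(length(s), 1L, prob = s)
}

#' Simulate GPS tracks under a known selection function
#'
#' Each animal walks at a 30-min decision scale: at every step a choice set
#' of candidate endpoints is drawn from the tentative kernel and one is
#' selected with probability proportional to the exponential selection
#' function evaluated with the true coefficients (including, optionally, a
#' temperature-by-swamp interaction driven by the temperature series).
#' 5-min fixes are emitted along each step within the daytime tracking
#' window (5:45 to 18:30 local), so the downstream resampling, step
#' building and refitting machinery is exercised end to end.
#'
#' @param config list from [synthTrackConfig()].
#' @param stack a [LandscapeStack-class] to move over.
#' @param tempSeries optional temperature data.frame (required when the
#'   interaction slope is non-zero).
#' @param seed RNG seed.
#' @param startDate midnight UTC of the first tracking day (local time =
#'   UTC + 1h).
#' @return list with `fixes` (data.frame ready for [resampleTrack()]) and
#'   `truth` (true coefficients, standardization table, tentative kernel).
#' @export
synthTracks <- function(config = synthTrackConfig(), stack,
                        tempSeries = NULL, seed = 1L,
                        startDate = as.POSIXct("2023-01-01 00:00:00",
                                               tz = "UTC")) {
  set.seed(seed)
  std <- stackStandardization(stack, tempSeries)
  beta <- config$trueBeta
  tk <- new("TentativeKernel", slShape = config$slShape,
            slRate = config$slRate, taMu = config$taMu,
            taKappa = config$taKappa, degenerate = FALSE)
  stepsPerDay <- 25L    # 05:45 + 25 x 30 min = 18:15 local
  nDays <- ceiling(config$nSteps / stepsPerDay)
  nr <- nrow(stack@canopyHeight@values); nc <- ncol(stack@canopyHeight@values)
  s <- stack@canopyHeight@cellSize
  org <- stack@canopyHeight@origin
  tempAt <- NULL
  if (!is.null(tempSeries)) {
    st <- as.numeric(tempSeries$timestamp)
    tempAt <- function(when) {
      i <- pmax(1L, pmin(length(st), findInterval(as.numeric(when), st)))
      tempSeries$temp_c[i]
    }
    tmean <- std$mean[std$variable == "temperature"]
    tsd <- std$sd[std$variable == "temperature"]
  }
  zscore <- function(v, x) {
    i <- match(v, std$variable)
    (x - std$mean[i]) / std$sd[i]
  }
  habitat <- intersect(names(beta),
                       c("canopy_height", "vci", "dist_gap_small",
                         "dist_gap_large"))

  allFixes <- list()
  for (a in seq_len(config$nAnimals)) {
    id <- sprintf("A%02d", a)
    species <- if (a %% 2 == 1) "BCH" else "WTH"
    ## start well inside the raster
    pos <- c(org[1] + stats::runif(1, 0.25, 0.75) * nc * s,
             org[2] - stats::runif(1, 0.25, 0.75) * nr * s)
    heading <- stats::runif(1, -pi, pi)
    stepCount <- 0L
    fixes <- list()
    for (day in seq_len(nDays)) {
      ## local 05:45 = 04:45 UTC
      t0 <- startDate + (day - 1) * 86400 + (4 * 60 + 45) * 60
      fixes[[length(fixes) + 1L]] <-
        data.frame(t = t0, x = pos[1], y = pos[2])
      for (k in seq_len(stepsPerDay)) {
        if (stepCount >= config$nSteps) break
        tEnd <- t0 + k * 1800
        K <- config$nCandidates
        sl <- stats::rgamma(K, shape = tk@slShape, rate = tk@slRate)
        ta <- rvonmises(K, tk@taMu, tk@taKappa)
        hd <- heading + ta
        ex <- pos[1] + sl * cos(hd); ey <- pos[2] + sl * sin(hd)
        covs <- extractCovariates(stack, cbind(ex, ey))
        eta <- config$betaLogSl * log(sl + 1) + config$betaCosTa * cos(ta)
        for (v in habitat) eta <- eta + beta[[v]] * zscore(v, covs[[v]])
        swampTerm <- if ("swamp" %in% names(beta)) beta[["swamp"]] else 0
        if (!is.null(tempAt) && config$interactionSlope != 0) {
          tz <- (tempAt(tEnd) - tmean) / tsd
          swampTerm <- swampTerm + config$interactionSlope * tz
        }
        eta <- eta + swampTerm * covs$swamp
        valid <- rowSums(is.na(covs)) == 0
        if (!any(valid)) next   # stuck this step; stay put
        i <- .chooseCandidate(eta, valid)
        ## 5-min fixes interpolated along the chosen step
        nSub <- as.integer(1800 / (config$fixIntervalMin * 60))
        frac <- seq_len(nSub) / nSub
        fixes[[length(fixes) + 1L]] <- data.frame(
          t = t0 + (k - 1) * 1800 + frac * 1800,
          x = pos[1] + frac * (ex[i] - pos[1]),
          y = pos[2] + frac * (ey[i] - pos[2]))
        pos <- c(ex[i], ey[i]); heading <- hd[i]
        stepCount <- stepCount + 1L
      }
      if (stepCount >= config$nSteps) break
    }
    f <- do.call(rbind, fixes)
    allFixes[[a]] <- data.frame(animal_id = id, timestamp = f$t,
                                x = f$x, y = f$y, species = species)
  }
  fixes <- do.call(rbind, allFixes)
  rownames(fixes) <- NULL
  list(fixes = fixes,
       truth = list(beta = beta, interactionSlope = config$interactionSlope,
                    betaLogSl = config$betaLogSl,
                    betaCosTa = config$betaCosTa,
                    standardization = std, tentative = tk))
}

#' Simulate iSSA strata directly from the conditional model
#'
#' Draws strata straight from the data-generating process of the
#' conditional logistic likelihood: for each stratum, `kControls + 1`
#' candidate endpoints are sampled from the tentative kernel at a random
#' on-raster start with a random previous heading, and the used step is
#' selected among them with probability proportional to
#' `exp(beta' x)`. Fast ground truth for estimator calibration (bias, CI
#' coverage) without the track-level machinery.
#'
#' @param stack a [LandscapeStack-class].
#' @param beta named true coefficients on globally standardized covariates
#'   (raw binary swamp); may include `log_sl1` and `cos_ta`.
#' @param nStrata strata to simulate.
#' @param kControls control steps per stratum.
#' @param tentative a [TentativeKernel-class].
#' @param interactionSlope optional swamp-by-standardized-temperature
#'   slope; stratum temperatures are drawn uniformly from `tempRange`.
#' @param tempRange stratum temperature range, degrees C.
#' @param animal,species identifiers stamped on the output.
#' @param seed RNG seed.
#' @return list with `strata` (data.frame in [buildStrata()] layout, raw
#'   covariates) and `standardization` (the global table the truth is
#'   expressed on).
#' @export
synthStrata <- function(stack, beta, nStrata = 300, kControls = 10,
                        tentative, interactionSlope = 0,
                        tempRange = c(18, 32), animal = "A01",
                        species = "BCH", seed = 1L) {
  set.seed(seed)
  std <- stackStandardization(stack)
  if (interactionSlope != 0) {
    tmid <- mean(tempRange); tsd <- diff(tempRange) / sqrt(12)
    std <- rbind(std, data.frame(variable = "temperature", mean = tmid,
                                 sd = tsd))
  }
  nr <- nrow(stack@canopyHeight@values); nc <- ncol(stack@canopyHeight@values)
  s <- stack@canopyHeight@cellSize; org <- stack@canopyHeight@origin
  habitat <- intersect(names(beta),
                       c("canopy_height", "vci", "dist_gap_small",
                         "dist_gap_large"))
  zscore <- function(v, x) {
    i <- match(v, std$variable)
    (x - std$mean[i]) / std$sd[i]
  }
  K1 <- kControls + 1L
  rows <- list()
  made <- 0L
  while (made < nStrata) {
    sx <- org[1] + stats::runif(1, 0.1, 0.9) * nc * s
    sy <- org[2] - stats::runif(1, 0.1, 0.9) * nr * s
    prevHead <- stats::runif(1, -pi, pi)
    sl <- stats::rgamma(K1, shape = tentative@slShape,
                        rate = tentative@slRate)
    ta <- rvonmises(K1, tentative@taMu, tentative@taKappa)
    hd <- prevHead + ta
    ex <- sx + sl * cos(hd); ey <- sy + sl * sin(hd)
    covs <- extractCovariates(stack, cbind(ex, ey))
    if (any(is.na(covs))) next
    temp <- stats::runif(1, tempRange[1], tempRange[2])
    eta <- numeric(K1)
    if ("log_sl1" %in% names(beta)) eta <- eta + beta[["log_sl1"]] * log(sl + 1)
    if ("cos_ta" %in% names(beta)) eta <- eta + beta[["cos_ta"]] * cos(ta)
    for (v in habitat) eta <- eta + beta[[v]] * zscore(v, covs[[v]])
    swampTerm <- if ("swamp" %in% names(beta)) beta[["swamp"]] else 0
    if (interactionSlope != 0)
      swampTerm <- swampTerm + interactionSlope * zscore("temperature", temp)
    eta <- eta + swampTerm * covs$swamp
    i <- .chooseCandidate(eta, rep(TRUE, K1))
    made <- made + 1L
    rows[[made]] <- data.frame(
      animal_id = animal, species = species, stratum_id = made,
      case = as.integer(seq_len(K1) == i),
      x_start = sx, y_start = sy, x_end = ex, y_end = ey,
      sl = sl, ta = ta, temperature = temp, covs)
  }
  strata <- do.call(rbind, rows)
  strata$stratum_id <- paste(animal, strata$stratum_id, sep = ".")
  list(strata = strata, standardization = std)
}

#' Generate synthetic tri-axial accelerometer bursts
#'
#' 20-sample bursts with per-axis gravity offsets and Gaussian dynamic
#' noise calibrated so the expected ODBA of a burst equals the requested
#' level (the finite-sample bias of mean-centring is corrected for).
#'
#' @param n number of bursts.
#' @param level expected ODBA per burst, g (scalar or length-`n`).
#' @param nSamples samples per axis (default 20, one per second).
#' @param seed RNG seed.
#' @return 3-D array `[n, nSamples, 3]`; requested levels in
#'   `attr(, "level")`.
#' @export
synthBursts <- function(n, level = 0.3, nSamples = 20L, seed = 1L) {
  set.seed(seed)
  level <- rep(level, length.out = n)
  ## per-axis |deviation| target is level/3; solve for the noise SD given
  ## E|x - xbar| = sd * sqrt((n-1)/n) * sqrt(2/pi)
  sigma <- (level / 3) / (sqrt(2 / pi) * sqrt((nSamples - 1) / nSamples))
  out <- array(0, c(n, nSamples, 3))
  gravity <- c(0, 0, 1)
  for (i in seq_len(n))
    out[i, , ] <- rep(gravity, each = nSamples) +
      stats::rnorm(nSamples * 3, 0, sigma[i])
  attr(out, "level") <- level
  out
}
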