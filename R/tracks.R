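#' Read GPS fixes from a Movebank-style CSV
#'
#' Accepts either projected `x`/`y` columns (metres, in the landscape CRS)
#' or `location-long`/`location-lat`, which are projected onto a local
#' tangent plane (equirectangular about the track centroid) -- adequate at
#' study-area scale. Duplicate animal/timestamp records are dropped and
#' fixes sorted in time.
#'
#' @param path CSV file path.
#' @param columns named list mapping the internal names `animal`,
#'   `timestamp`, `x`, `y`, `lon`, `lat`, `species` to file column names.
#' @param species fallback species label when the file has no species
#'   column.
#' @return data.frame with columns `animal_id`, `timestamp` (POSIXct UTC),
#'   `x`, `y`, `species`.
#' @export
readFixes <- function(path,
                      columns = list(animal = "individual-local-identifier",
                                     timestamp = "timestamp",
                                     x = "x", y = "y",
                                     lon = "location-long",
                                     lat = "location-lat",
                                     species = "species"),
                      species = NA_character_) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  get <- function(key) if (!is.null(columns[[key]]) &&
                           columns[[key]] %in% names(d))
    d[[columns[[key]]]] else NULL
  animal <- get("animal")
  ts <- get("timestamp")
  if (is.null(animal) || is.null(ts))
    stop("animal and timestamp columns are required")
  ts <- as.POSIXct(ts, tz = "UTC")
  x <- get("x"); y <- get("y")
  if (is.null(x) || is.null(y)) {
    lon <- get("lon"); lat <- get("lat")
    if (is.null(lon) || is.null(lat))
      stop("need projected x/y or location-long/location-lat columns")
    xy <- lonlatToLocal(lon, lat)
    x <- xy[, 1]; y <- xy[, 2]
  }
  sp <- get("species")
  if (is.null(sp)) sp <- rep(species, length(animal))
  out <- data.frame(animal_id = as.character(animal), timestamp = ts,
                    x = as.numeric(x), y = as.numeric(y),
                    species = as.character(sp))
  out <- out[order(out$animal_id, out$timestamp), ]
  dup <- duplicated(out[, c("animal_id", "timestamp")])
  out <- out[!dup, ]
  rownames(out) <- NULL
  out
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular projection about a reference point (default: the data
#' centroid). Suitable only for extents of a few tens of kilometres.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param ref optional `(lon0, lat0)` reference; defaults to the centroid.
#' @return two-column matrix of x/y metres.
#' @export
lonlatToLocal <- function(lon, lat, ref = NULL) {
  if (is.null(ref)) ref <- c(mean(lon), mean(lat))
  Rearth <- 6371008.8
  x <- (lon - ref[1]) * pi / 180 * Rearth * cos(ref[2] * pi / 180)
  y <- (lat - ref[2]) * pi / 180 * Rearth
  cbind(x = x, y = y)
}

#' Keep animals with enough fixes inside the study area
#'
#' @param fixes data.frame as returned by [readFixes()].
#' @param minFixes minimum number of in-area fixes per animal (default 1000,
#'   the eligibility cut used for the tracked hornbills).
#' @param polygon optional two-column matrix of study-area vertices; `NULL`
#'   counts every fix.
#' @return filtered fixes; per-animal counts in `attr(, "counts")`.
#' @export
filterEligible <- function(fixes, minFixes = 1000, polygon = NULL) {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L) {
      warning("degenerate study polygon: all animals excluded")
      inside <- rep(FALSE, nrow(fixes))
    } else {
      inside <- mgcv::in.out(polygon, cbind(fixes$x, fixes$y))
    }
  } else inside <- rep(TRUE, nrow(fixes))
  counts <- tapply(inside, fixes$animal_id, sum)
  counts[is.na(counts)] <- 0
  keep <- names(counts)[counts >= minFixes]
  out <- fixes[fixes$animal_id %in% keep, ]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

## minutes between consecutive timestamps
.gapMinutes <- function(ts) as.numeric(difftime(ts, ts[1], units = "mins"))

#' Resample a track to a regular fix rate
#'
#' Greedy forward pass per animal: from each kept fix, the next kept fix is
#' the one whose time gap lies within `targetRate +/- tol` minutes, choosing
#' the gap closest to the target (ties to the earlier fix). When no fix
#' falls in the window the burst ends and a new one starts at the first fix
#' beyond it. Bursts shorter than `minBurst` fixes are dropped.
#'
#' @param fixes data.frame of fixes (see [readFixes()]).
#' @param targetRate target fix interval, minutes (default 30).
#' @param tol admissible deviation, minutes (default 5).
#' @param minBurst minimum fixes per retained burst (default 3: a turn angle
#'   needs two consecutive steps).
#' @return resampled fixes with an added integer `burst` column.
#' @export
resampleTrack <- function(fixes, targetRate = 30, tol = 5, minBurst = 3) {
  stopifnot(targetRate > 0, tol >= 0)
  pieces <- lapply(split(fixes, fixes$animal_id), function(d) {
    d <- d[order(d$timestamp), ]
    n <- nrow(d)
    t <- as.numeric(d$timestamp) / 60   # minutes
    keep <- integer(0); burst <- integer(0)
    i <- 1L; b <- 1L
    keep <- c(keep, i); burst <- c(burst, b)
    while (i < n) {
      gap <- t[(i + 1L):n] - t[i]
      adm <- which(gap >= targetRate - tol & gap <= targetRate + tol)
      if (length(adm)) {
        j <- adm[which.min(abs(gap[adm] - targetRate))]
        i <- i + j
      } else {
        beyond <- which(gap > targetRate + tol)
        if (!length(beyond)) break
        i <- i + beyond[1L]
        b <- b + 1L
      }
      keep <- c(keep, i); burst <- c(burst, b)
    }
    d <- d[keep, ]
    d$burst <- burst
    sizes <- table(burst)
    d[d$burst %in% as.integer(names(sizes)[sizes >= minBurst]), ]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

## local-time minutes-of-day; tracking devices are off 18:30 -> 5:45
.dayMinutes <- function(ts, tzOffsetMin = 60)
  (as.numeric(ts) / 60 + tzOffsetMin) %% 1440

#' Build steps from resampled fixes
#'
#' Consecutive within-burst fixes become steps with length, absolute
#' heading (radians, counter-clockwise from +x) and turn angle (wrapped
#' heading difference; undefined for a burst's first step). Steps spanning
#' the nightly tracking-off window (18:30 to 5:45 local) are excluded.
#'
#' @param fixes resampled fixes with a `burst` column.
#' @param tzOffsetMin local-time offset from UTC in minutes (default 60,
#'   Central Africa).
#' @param nightStart,nightEnd local minutes-of-day bounding the device-off
#'   window.
#' @return data.frame of steps: start/end coordinates, `t_start`, `t_end`,
#'   `duration` (min), `sl` (m), `heading`, `ta` (radians).
#' @export
trackSteps <- function(fixes, tzOffsetMin = 60,
                       nightStart = 18 * 60 + 30, nightEnd = 5 * 60 + 45) {
  pieces <- lapply(split(fixes,
                         list(fixes$animal_id, fixes$burst), drop = TRUE),
                   function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    d <- d[order(d$timestamp), ]
    dx <- diff(d$x); dy <- diff(d$y)
    heading <- atan2(dy, dx)
    ta <- c(NA_real_, wrapAngle(diff(heading)))
    data.frame(animal_id = d$animal_id[-n], species = d$species[-n],
               burst = d$burst[-n],
               x_start = d$x[-n], y_start = d$y[-n],
               x_end = d$x[-1], y_end = d$y[-1],
               t_start = d$timestamp[-n], t_end = d$timestamp[-1],
               duration = as.numeric(difftime(d$timestamp[-1],
                                              d$timestamp[-n],
                                              units = "mins")),
               sl = sqrt(dx^2 + dy^2), heading = heading, ta = ta)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(out)
  m0 <- .dayMinutes(out$t_start, tzOffsetMin)
  m1 <- m0 + out$duration
  ## a step is nocturnal when its interval reaches past nightStart (18:30)
  ## or wraps past midnight into the pre-dawn window
  night <- (m0 < nightStart & m1 > nightStart) | m1 > 1440 + nightEnd |
    (m0 > nightStart & m0 < 1440)
  out <- out[!night | is.na(night), ]
  out <- out[order(out$animal_id, out$t_start), ]
  rownames(out) <- NULL
  out
}

#' Attach the nearest weather-station temperature to each step
#'
#' Each step receives the temperature of the record closest in time to the
#' step's end; ties go to the earlier record. Records farther than `maxGap`
#' minutes leave the temperature missing (such steps are excluded from any
#' model containing temperature terms).
#'
#' @param steps data.frame with a `t_end` column (or `t_start` fallback).
#' @param series data.frame with `timestamp` (POSIXct) and `temp_c`.
#' @param maxGap largest admissible time gap, minutes (default 60, the
#'   station's maximum recording interval).
#' @return `steps` with a `temperature` column.
#' @export
attachTemperature <- function(steps, series, maxGap = 60) {
  stopifnot(nrow(series) > 0)
  series <- series[order(series$timestamp), ]
  st <- as.numeric(series$timestamp)
  when <- as.numeric(if ("t_end" %in% names(steps)) steps$t_end
                     else steps$t_start)
  pos <- findInterval(when, st)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(st))
  dlo <- abs(when - st[lo]); dhi <- abs(when - st[hi])
  pick <- ifelse(pos < 1L, hi, ifelse(dhi < dlo, hi, lo))  # earlier wins ties
  gap <- abs(when - st[pick]) / 60
  temp <- series$temp_c[pick]
  temp[gap > maxGap] <- NA_real_
  steps$temperature <- temp
  steps
}

#' Build iSSA strata: one used step plus K control steps
#'
#' For every observed step with a defined previous heading, `kControls`
#' control steps are drawn from the tentative movement kernel (gamma step
#' length, von Mises turn angle applied to the previous heading), all
#' sharing the used step's start point and time. Covariates are extracted
#' at every endpoint from the landscape stack; strata with any endpoint off
#' the raster or on nodata are dropped and counted.
#'
#' @param steps data.frame from [trackSteps()] (optionally with a
#'   `temperature` column from [attachTemperature()]).
#' @param stack a [LandscapeStack-class].
#' @param tentative a [TentativeKernel-class] (see [fitTentative()]).
#' @param kControls control steps per stratum (default 10).
#' @param seed RNG seed; fixed seed gives bit-identical strata.
#' @return data.frame with `stratum_id`, `case` (1 used / 0 control), step
#'   geometry, covariate columns and `temperature`; the number of dropped
#'   strata in `attr(, "dropped")`.
#' @export
buildStrata <- function(steps, stack, tentative, kControls = 10,
                        seed = 1L) {
  if (kControls < 1L) stop("kControls must be >= 1")
  set.seed(seed)
  eligible <- which(!is.na(steps$ta))
  prev <- eligible - 1L   # previous step within same animal/burst
  ok <- prev >= 1L & steps$animal_id[prev] == steps$animal_id[eligible] &
    steps$burst[prev] == steps$burst[eligible]
  eligible <- eligible[ok]; prev <- prev[ok]
  n <- length(eligible)
  if (!n) stop("no steps with a defined previous heading")
  K <- kControls
  sl <- stats::rgamma(n * K, shape = tentative@slShape,
                      rate = tentative@slRate)
  ta <- rvonmises(n * K, tentative@taMu, tentative@taKappa)
  prevHead <- rep(steps$heading[prev], each = K)
  head <- prevHead + ta
  sx <- rep(steps$x_start[eligible], each = K)
  sy <- rep(steps$y_start[eligible], each = K)
  ex <- sx + sl * cos(head); ey <- sy + sl * sin(head)

  used <- steps[eligible, ]
  ctrl <- data.frame(
    animal_id = rep(used$animal_id, each = K),
    species = rep(used$species, each = K),
    stratum_id = rep(seq_len(n), each = K),
    case = 0L, x_start = sx, y_start = sy, x_end = ex, y_end = ey,
    t_start = rep(used$t_start, each = K),
    sl = sl, ta = ta,
    temperature = if ("temperature" %in% names(used))
      rep(used$temperature, each = K) else NA_real_)
  usd <- data.frame(
    animal_id = used$animal_id, species = used$species,
    stratum_id = seq_len(n), case = 1L,
    x_start = used$x_start, y_start = used$y_start,
    x_end = used$x_end, y_end = used$y_end, t_start = used$t_start,
    sl = used$sl, ta = used$ta,
    temperature = if ("temperature" %in% names(used))
      used$temperature else NA_real_)
  all <- rbind(usd, ctrl)
  cov <- extractCovariates(stack, cbind(all$x_end, all$y_end))
  all <- cbind(all, cov)
  bad <- rowSums(is.na(cov)) > 0
  badStrata <- unique(all$stratum_id[bad])
  out <- all[!(all$stratum_id %in% badStrata), ]
  out <- out[order(out$animal_id, out$stratum_id, -out$case), ]
  ## stratum ids globally unique across animals
  out$stratum_id <- paste(out$animal_id, out$stratum_id, sep = ".")
  rownames(out) <- NULL
  attr(out, "dropped") <- length(badStrata)
  out
}

#' Centre and scale covariates per animal
#'
#' Standardizes each listed covariate to mean 0, sample SD 1 (n-1
#' denominator) using moments over ALL steps (used and control) of each
#' animal, and stores the parameters for back-transformation and for reuse
#' when simulating from the fitted model. Binary covariates (e.g. swamp)
#' should not be listed.
#'
#' @param strata data.frame from [buildStrata()].
#' @param vars covariate column names to scale.
#' @return list with `data` (scaled strata) and `standardization`
#'   (data.frame `animal_id`, `variable`, `mean`, `sd`).
#' @export
standardizeCovariates <- function(strata,
                                  vars = c("canopy_height", "vci",
                                           "dist_gap_small",
                                           "dist_gap_large",
                                           "temperature")) {
  vars <- intersect(vars, names(strata))
  recs <- list()
  for (a in unique(strata$animal_id)) {
    idx <- strata$animal_id == a
    for (v in vars) {
      x <- strata[[v]][idx]
      if (all(is.na(x))) next    # covariate absent for this animal
      m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop("zero variance in covariate '", v, "' for animal ", a)
      strata[[v]][idx] <- (x - m) / s
      recs[[length(recs) + 1L]] <-
        data.frame(animal_id = a, variable = v, mean = m, sd = s)
    }
  }
  list(data = strata, standardization = do.call(rbind, recs))
}
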