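#' Pool individual selection coefficients by inverse-variance weighting
#'
#' Fixed-effect pooling of per-individual estimates:
#' `beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = (sum 1/se_i^2)^(-1/2)`. Only converged fits containing the
#' covariate contribute.
#'
#' @param fits list of [SelectionModel-class] objects.
#' @param covariate coefficient name to pool.
#' @return data.frame with `covariate`, `beta`, `se`, `n`, `method`.
#' @export
poolInverseVariance <- function(fits, covariate) {
  fits <- Filter(function(f) f@converged && covariate %in% names(f@coef),
                 fits)
  if (length(fits) < 2L)
    stop("need at least 2 converged fits containing '", covariate, "'")
  b <- vapply(fits, function(f) f@coef[[covariate]], 0)
  s <- vapply(fits, function(f) f@se[[covariate]], 0)
  if (any(s == 0)) stop("zero standard error in an individual fit")
  w <- 1 / s^2
  data.frame(covariate = covariate, beta = sum(w * b) / sum(w),
             se = sqrt(1 / sum(w)), n = length(fits),
             method = "inverse_variance")
}

#' Temperature bin membership
#'
#' Four left-closed, half-open bins roughly matching the quartiles of
#' temperatures experienced on the study site: `(-inf, 22)`, `[22, 25)`,
#' `[25, 27)`, `[27, inf)` degrees C. Every finite temperature maps to
#' exactly one bin.
#'
#' @param temp temperatures in degrees C.
#' @param breaks interior bin boundaries.
#' @return integer bin index 1-4 (`NA` for missing temperatures).
#' @export
temperatureBin <- function(temp, breaks = c(22, 25, 27))
  findInterval(temp, breaks) + 1L

#' Swamp selection per temperature bin
#'
#' Refits swamp selection within each temperature bin: strata whose used
#' step's temperature falls in the bin are kept, a conditional logistic
#' model with swamp and movement terms is fitted per individual, and
#' individual coefficients are pooled per species by inverse variance.
#' Mirrors the temperature-stratified view of the swamp-by-temperature
#' interaction.
#'
#' @param strata standardized strata data.frame (multiple animals; needs
#'   `species`, `temperature`, `swamp` columns).
#' @param terms model terms for the per-bin refit (must include `"swamp"`).
#' @param breaks interior temperature-bin boundaries, degrees C.
#' @param minStrata minimum strata per animal and bin to attempt a fit.
#' @return data.frame with `species`, `bin`, `lo`, `hi`, `beta`, `se`,
#'   `lo95`, `hi95`, `n_individuals`, `n_strata`; bins that cannot be
#'   estimated are reported with `NA` estimates.
#' @export
binTemperatureEstimates <- function(strata,
                                    terms = c("swamp", "log_sl1", "cos_ta"),
                                    breaks = c(22, 25, 27),
                                    minStrata = 30L) {
  stopifnot("swamp" %in% terms)
  usedTemp <- strata$temperature[strata$case == 1L]
  names(usedTemp) <- strata$stratum_id[strata$case == 1L]
  strata$bin <- temperatureBin(usedTemp[strata$stratum_id])
  bounds <- cbind(lo = c(-Inf, breaks), hi = c(breaks, Inf))
  out <- list()
  for (sp in unique(strata$species)) {
    for (b in 1:4) {
      sub <- strata[strata$species == sp & !is.na(strata$bin) &
                      strata$bin == b, ]
      fits <- list()
      nStr <- 0L
      for (a in unique(sub$animal_id)) {
        da <- sub[sub$animal_id == a, ]
        if (length(unique(da$stratum_id)) < minStrata) next
        fit <- tryCatch(fitClogit(da, terms = terms),
                        error = function(e) NULL)
        if (!is.null(fit) && fit@converged) {
          fits[[length(fits) + 1L]] <- fit
          nStr <- nStr + fit@nStrata
        }
      }
      row <- data.frame(species = sp, bin = b, lo = bounds[b, 1],
                        hi = bounds[b, 2], beta = NA_real_, se = NA_real_,
                        lo95 = NA_real_, hi95 = NA_real_,
                        n_individuals = length(fits), n_strata = nStr)
      if (length(fits) >= 2L) {
        pool <- poolInverseVariance(fits, "swamp")
        row$beta <- pool$beta; row$se <- pool$se
        row$lo95 <- pool$beta - 1.96 * pool$se
        row$hi95 <- pool$beta + 1.96 * pool$se
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Test for a species difference in a selection coefficient
#'
#' Weighted least squares of individual coefficients on a species
#' indicator, weights `1 / se_i^2`; the F statistic of the species term is
#' reported with denominator df `n - 2`.
#'
#' @param fits list of [SelectionModel-class] objects with their `species`
#'   slot set.
#' @param covariate coefficient name to compare.
#' @return data.frame with `covariate`, `F`, `df1`, `df2`, `p`.
#' @export
compareSpecies <- function(fits, covariate) {
  fits <- Filter(function(f) f@converged && covariate %in% names(f@coef) &&
                   !is.na(f@species), fits)
  sp <- vapply(fits, function(f) f@species, "")
  if (length(unique(sp)) < 2L) stop("need at least 2 species")
  if (min(table(sp)) < 2L) stop("need at least 2 individuals per species")
  b <- vapply(fits, function(f) f@coef[[covariate]], 0)
  w <- 1 / vapply(fits, function(f) f@se[[covariate]], 0)^2
  ## explicit WLS decomposition (robust when the fit is exact)
  mu <- sum(w * b) / sum(w)
  groups <- split(seq_along(b), sp)
  gMean <- vapply(groups, function(i) sum(w[i] * b[i]) / sum(w[i]), 0)
  gW <- vapply(groups, function(i) sum(w[i]), 0)
  ssB <- sum(gW * (gMean - mu)^2)
  ssW <- sum(w * (b - gMean[sp])^2)
  df1 <- length(groups) - 1L
  df2 <- length(b) - length(groups)
  tot <- ssB + ssW
  F <- if (ssB <= 1e-12 * (tot + 1)) 0 else (ssB / df1) / (ssW / df2)
  data.frame(covariate = covariate, F = F, df1 = df1, df2 = df2,
             p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Population model with per-individual random slopes (optional extension)
#'
#' Poisson reformulation of the conditional logistic model (Muff et al.
#' style): used/control indicators are modelled as Poisson counts with a
#' per-stratum intercept whose variance is fixed very large (making the
#' stratum totals ancillary) and per-individual Gaussian random slopes on
#' each covariate. Requires the `glmmTMB` package; without it (or on a
#' failed fit) the function falls back to two-stage inverse-variance
#' pooling with a warning.
#'
#' @param strata standardized multi-animal strata data.frame.
#' @param terms model terms (derived movement terms handled as in
#'   [fitClogit()]).
#' @return data.frame with one row per term: `beta`, `se`, `method`.
#' @export
fitPopulationModel <- function(strata,
                               terms = c("canopy_height", "vci",
                                         "dist_gap_small", "dist_gap_large",
                                         "swamp", "log_sl1", "cos_ta")) {
  fallback <- function(reason) {
    warning("population GLMM unavailable (", reason,
            "); falling back to two-stage pooling")
    fits <- fitClogitPerAnimal(strata, terms)
    do.call(rbind, lapply(terms, function(tm) {
      p <- poolInverseVariance(fits, tm)
      data.frame(term = tm, beta = p$beta, se = p$se,
                 method = "inverse_variance")
    }))
  }
  if (!requireNamespace("glmmTMB", quietly = TRUE))
    return(fallback("glmmTMB not installed"))
  d <- strata
  if ("log_sl1" %in% terms && is.null(d$log_sl1)) d$log_sl1 <- log(d$sl + 1)
  if ("cos_ta" %in% terms && is.null(d$cos_ta)) d$cos_ta <- cos(d$ta)
  if ("temp_swamp" %in% terms && is.null(d$temp_swamp))
    d$temp_swamp <- d$temperature * d$swamp
  d <- d[stats::complete.cases(d[, c(terms, "case", "stratum_id",
                                     "animal_id")]), ]
  d$stratum_id <- factor(d$stratum_id)
  d$animal_id <- factor(d$animal_id)
  ranSlopes <- paste(sprintf("(0 + %s | animal_id)", terms),
                     collapse = " + ")
  form <- stats::as.formula(paste(
    "case ~ -1 +", paste(terms, collapse = " + "),
    "+ (1 | stratum_id) +", ranSlopes))
  nRE <- length(terms) + 1L
  fit <- tryCatch(
    glmmTMB::glmmTMB(
      form, data = d, family = stats::poisson,
      ## stratum-intercept variance fixed at exp(2*log(1e3)) = 1e6 so the
      ## Poisson trick reproduces the conditional likelihood
      map = list(theta = factor(c(NA, seq_len(nRE - 1L)))),
      start = list(theta = c(log(1e3), rep(0, nRE - 1L)))),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(fallback("fit failed"))
  est <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(stats::vcov(fit)$cond))
  data.frame(term = terms, beta = unname(est[terms]),
             se = unname(se[terms]), method = "glmm_poisson_reform")
}

#' Fit one conditional logistic model per animal
#'
#' Convenience wrapper running [fitClogit()] per individual and collecting
#' the converged fits; failures are dropped with a message.
#'
#' @inheritParams fitPopulationModel
#' @param standardization optional standardization table; per-animal rows
#'   are stored with each fit.
#' @return list of [SelectionModel-class] objects.
#' @export
fitClogitPerAnimal <- function(strata,
                               terms = c("canopy_height", "vci",
                                         "dist_gap_small", "dist_gap_large",
                                         "swamp", "log_sl1", "cos_ta"),
                               standardization = data.frame()) {
  fits <- list()
  for (a in unique(strata$animal_id)) {
    da <- strata[strata$animal_id == a, ]
    std <- if (nrow(standardization))
      standardization[standardization$animal_id == a, ] else data.frame()
    fit <- tryCatch(fitClogit(da, terms = terms, standardization = std),
                    error = function(e) {
                      message("animal ", a, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) fits[[a]] <- fit
  }
  fits
}
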