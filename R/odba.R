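#' Overall dynamic body acceleration of a tri-axial burst
#'
#' Per axis, the burst mean (the static, gravitational component) is
#' subtracted, absolute deviations are averaged over samples, and ODBA is
#' the non-vectorial sum of the three per-axis means. Invariant to adding a
#' constant to any axis; scales linearly with dynamic amplitude.
#'
#' @param burst numeric matrix with 3 columns (x, y, z axes) of calibrated
#'   accelerations in g, or raw counts with `calibration` supplied.
#' @param calibration optional list of per-axis `slope` and `intercept`
#'   (length-3 each) converting counts to g; default identity.
#' @return ODBA in g.
#' @export
computeODBA <- function(burst, calibration = NULL) {
  burst <- as.matrix(burst)
  if (ncol(burst) != 3L) stop("burst must have 3 axis columns")
  if (nrow(burst) < 2L) stop("need at least 2 samples per axis")
  if (!is.null(calibration)) {
    burst <- sweep(sweep(burst, 2, calibration$slope, `*`),
                   2, calibration$intercept, `+`)
  }
  dyn <- sweep(burst, 2, colMeans(burst))
  sum(colMeans(abs(dyn)))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank activity models over all predictor subsets
#'
#' Fits every subset of `predictors` (including the intercept-only model)
#' as a linear model of ODBA with a per-animal random intercept, by maximum
#' likelihood so AICc is comparable across fixed-effect structures, and
#' ranks the candidates by AICc. `k` counts fixed effects + intercept + 2
#' variance parameters (random-intercept and residual). With a single
#' animal the random intercept is degenerate and an ordinary linear model
#' is used (same `k` convention, so the ranking equals the OLS ranking).
#'
#' @param records data.frame with `odba`, `animal_id` and the predictor
#'   columns; rows must be complete cases for all candidate predictors.
#' @param predictors character vector of candidate predictor columns
#'   (at least 2).
#' @return data.frame with one row per candidate (`model`, `loglik`, `k`,
#'   `AICc`, `dAICc`), sorted ascending by AICc; rank-deficient subsets are
#'   dropped with a message.
#' @export
rankActivityModels <- function(records, predictors) {
  if (length(predictors) < 2L) stop("need at least 2 predictors")
  need <- c("odba", "animal_id", predictors)
  records <- records[stats::complete.cases(records[, need]), ]
  oneAnimal <- length(unique(records$animal_id)) < 2L
  n <- nrow(records)
  subsets <- unlist(lapply(0:length(predictors), function(m)
    utils::combn(predictors, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(vars) {
    rhs <- if (length(vars)) paste(vars, collapse = " + ") else "1"
    k <- length(vars) + 1L + 2L
    ll <- tryCatch({
      if (oneAnimal) {
        fit <- stats::lm(stats::as.formula(paste("odba ~", rhs)),
                         data = records)
        if (fit$rank < length(vars) + 1L) stop("rank deficient")
        as.numeric(stats::logLik(fit))
      } else {
        fit <- lme4::lmer(
          stats::as.formula(paste("odba ~", rhs, "+ (1 | animal_id)")),
          data = records, REML = FALSE,
          control = lme4::lmerControl(check.conv.singular = "ignore"))
        as.numeric(stats::logLik(fit))
      }
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) {
      message("dropping rank-deficient subset: ", rhs)
      return(NULL)
    }
    data.frame(model = rhs, loglik = ll, k = k,
               AICc = aicc(ll, k, n))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), ]
  out$dAICc <- out$AICc - out$AICc[1]
  rownames(out) <- NULL
  out
}
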