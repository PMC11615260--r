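#' Fit the tentative (selection-free) movement kernel
#'
#' Maximum-likelihood gamma fit to observed step lengths (zero lengths are
#' offset by half a cell so the likelihood is defined) and maximum-
#' likelihood von Mises fit to observed turn angles. The result proposes
#' control and candidate steps.
#'
#' @param steps data.frame with `sl` (m) and `ta` (radians) columns; only
#'   rows with a defined turn angle are used for the angular fit.
#' @param cellSize raster cell size (m) used for the zero-length offset.
#' @param minSteps minimum number of usable steps (default 30).
#' @return a [TentativeKernel-class].
#' @export
fitTentative <- function(steps, cellSize = 10, minSteps = 30) {
  sl <- steps$sl[is.finite(steps$sl)]
  ta <- steps$ta[is.finite(steps$ta)]
  if (length(sl) < minSteps || length(ta) < minSteps)
    stop("need at least ", minSteps, " steps with defined turn angles")
  sl[sl <= 0] <- cellSize / 2
  g <- .fitGammaML(sl)
  vm <- fitVonMises(ta)
  new("TentativeKernel", slShape = g$shape,
      slRate = g$rate, taMu = vm$mu,
      taKappa = vm$kappa, degenerate = vm$degenerate)
}

## gamma MLE: Newton on the shape from the profile likelihood
## (rate profiles out as shape/mean); standard closed-form start
.fitGammaML <- function(x, maxIter = 50L) {
  s <- log(mean(x)) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(maxIter)) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    kNew <- k - step
    if (kNew <= 0) kNew <- k / 2
    if (abs(kNew - k) < 1e-10 * k) { k <- kNew; break }
    k <- kNew
  }
  list(shape = k, rate = k / mean(x))
}

setMethod("show", "TentativeKernel", function(object) {
  cat(sprintf(
    "TentativeKernel: sl ~ gamma(shape %.3g, rate %.3g) [mean %.1f m]\n",
    object@slShape, object@slRate, object@slShape / object@slRate))
  cat(sprintf("                 ta ~ vonMises(mu %.3f, kappa %.3g)%s\n",
              object@taMu, object@taKappa,
              if (object@degenerate) " [degenerate]" else ""))
})

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations over all (used and control) steps; pairs
#' with `|r|` strictly above the threshold are flagged so they are not
#' entered in one model together. Constant covariates have undefined
#' correlation and are reported as such.
#'
#' @param strata data.frame of steps with covariate columns.
#' @param vars covariate names to screen.
#' @param threshold exclusion threshold on `|r|` (default 0.6; strict `>`).
#' @return list with `r` (correlation matrix), `excluded` (data.frame of
#'   flagged pairs) and `undefined` (constant covariates).
#' @export
screenCorrelation <- function(strata, vars, threshold = 0.6) {
  X <- as.matrix(strata[, vars, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 observations")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  undefined <- vars[!is.finite(sds) | sds == 0]
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(r) <- 1
  pairs <- which(upper.tri(r) & abs(r) > threshold & is.finite(r),
                 arr.ind = TRUE)
  excluded <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                         r = r[pairs])
  list(r = r, excluded = excluded, undefined = undefined,
       threshold = threshold)
}

## ---- conditional logistic likelihood (the iSSA core) ----

## X: design matrix; y: 1 used / 0 control; sid: integer stratum index.
## Returns loglik, gradient, Hessian of
##   sum_s [ x_used' b - log sum_j exp(x_j' b) ]
.clogitDeriv <- function(beta, X, y, sid, nStrata) {
  eta <- drop(X %*% beta)
  eta <- eta - rep(tapply(eta, sid, max)[sid], 1)  # stratum-wise stabilizer
  w <- exp(eta)
  denom <- rowsum(w, sid)[, 1]
  p <- w / denom[sid]
  ll <- sum(eta[y == 1L]) - sum(log(denom))
  pX <- X * p
  Ebar <- rowsum(pX, sid)                       # per-stratum E[x]
  grad <- colSums(X[y == 1L, , drop = FALSE]) - colSums(Ebar)
  ## information: sum_s (E[xx'] - E[x]E[x]')
  info <- crossprod(X, pX) - crossprod(Ebar)
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a conditional logistic step-selection model
#'
#' Maximizes the stratified conditional likelihood
#' `sum_s [ beta' x_used - log sum_j exp(beta' x_j) ]` by Newton ascent with
#' step halving; the covariance of the estimates is the inverse observed
#' information at the optimum. This is the estimator behind the habitat
#' selection function `w(x) = exp(beta' x)`.
#'
#' Movement-kernel terms `log_sl1 = log(sl + 1)` (sl in metres) and
#' `cos_ta = cos(ta)` are derived automatically when requested in `terms`,
#' as is the `temp_swamp` interaction (standardized temperature times raw
#' binary swamp). Strata whose rows are all identical are degenerate and
#' dropped with a count; rows with missing values in any term drop their
#' whole stratum.
#'
#' Separation (a coefficient drifting beyond `separationBound` with a
#' non-vanishing gradient) and non-convergence are flagged via
#' `converged = FALSE`, never returned silently.
#'
#' @param strata data.frame from [buildStrata()] (standardized via
#'   [standardizeCovariates()]), with `stratum_id`, `case`, covariates,
#'   `sl`, `ta`.
#' @param terms character vector of model terms, in design order. Default:
#'   the full habitat + movement formula.
#' @param standardization optional standardization data.frame stored with
#'   the model for later simulation.
#' @param maxIter,tol Newton iteration cap and gradient max-norm tolerance.
#' @param separationBound `|beta|` beyond which separation is declared on
#'   standardized covariates.
#' @return a [SelectionModel-class].
#' @export
fitClogit <- function(strata,
                      terms = c("canopy_height", "vci", "dist_gap_small",
                                "dist_gap_large", "swamp", "temp_swamp",
                                "log_sl1", "cos_ta"),
                      standardization = data.frame(),
                      maxIter = 100L, tol = 1e-8, separationBound = 15) {
  d <- strata
  if ("log_sl1" %in% terms && is.null(d$log_sl1)) d$log_sl1 <- log(d$sl + 1)
  if ("cos_ta" %in% terms && is.null(d$cos_ta)) d$cos_ta <- cos(d$ta)
  if ("temp_swamp" %in% terms && is.null(d$temp_swamp))
    d$temp_swamp <- d$temperature * d$swamp
  missing <- setdiff(terms, names(d))
  if (length(missing))
    stop("terms not found in strata: ", paste(missing, collapse = ", "))

  X <- as.matrix(d[, terms, drop = FALSE])
  keep <- rowSums(is.na(X)) == 0
  badStrata <- unique(d$stratum_id[!keep])
  use <- !(d$stratum_id %in% badStrata)
  d <- d[use, ]; X <- X[use, , drop = FALSE]
  sid <- as.integer(factor(d$stratum_id))
  y <- as.integer(d$case)
  if (any(tapply(y, sid, sum) != 1L))
    stop("every stratum must contain exactly one used step")

  ## degenerate strata: no within-stratum variation in any term
  rng <- apply(X, 2, function(col) {
    tapply(col, sid, function(v) max(v) - min(v))
  })
  rng <- matrix(rng, ncol = ncol(X))
  flat <- rowSums(rng > 0) == 0
  nDegenerate <- sum(flat)
  if (any(flat)) {
    keepS <- which(!flat)
    use <- sid %in% keepS
    X <- X[use, , drop = FALSE]; y <- y[use]; sid <- sid[use]
    sid <- as.integer(factor(sid))
  }
  nStrata <- length(unique(sid))
  if (nStrata == 0L) stop("no informative strata")
  identifiable <- colSums(matrix(rng[!flat, , drop = FALSE] > 1e-12,
                                 ncol = ncol(X))) > 0
  if (any(!identifiable))
    stop("not identifiable: constant within every stratum: ",
         paste(terms[!identifiable], collapse = ", "))

  p <- ncol(X)
  beta <- numeric(p)
  cur <- .clogitDeriv(beta, X, y, sid, nStrata)
  converged <- FALSE; separated <- FALSE
  for (iter in seq_len(maxIter)) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step))
      step <- cur$grad / (max(abs(diag(cur$info))) + 1e-10)
    ## step halving to guarantee ascent
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      new <- .clogitDeriv(cand, X, y, sid, nStrata)
      if (new$loglik >= cur$loglik - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand; cur <- new
    if (max(abs(beta)) > separationBound) { separated <- TRUE; break }
  }
  if (separated && max(abs(cur$grad)) > tol) converged <- FALSE
  vcov <- tryCatch(solve(cur$info), error = function(e)
    matrix(NA_real_, p, p))
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(pmax(diag(vcov), 0))
  names(beta) <- terms; names(se) <- terms
  dimnames(vcov) <- list(terms, terms)
  mod <- new("SelectionModel", coef = beta, se = se, vcov = vcov,
             loglik = cur$loglik, nStrata = as.integer(nStrata),
             converged = converged, standardization = standardization,
             formula = terms,
             animal = if (length(unique(strata$animal_id)) == 1L)
               as.character(strata$animal_id[1]) else NA_character_,
             species = if (!is.null(strata$species) &&
                           length(unique(strata$species)) == 1L)
               as.character(strata$species[1]) else NA_character_)
  attr(mod, "nDegenerate") <- nDegenerate
  attr(mod, "separated") <- separated
  mod
}

#' @describeIn fitClogit named coefficient vector of a fitted model.
#' @param object,model a [SelectionModel-class].
#' @export
modelCoef <- function(model) model@coef

#' @describeIn fitClogit named standard errors.
#' @export
modelSE <- function(model) model@se

#' @describeIn fitClogit two-sided Wald p-values per coefficient.
#' @export
modelPvalues <- function(model)
  2 * stats::pnorm(-abs(model@coef / model@se))

setMethod("show", "SelectionModel", function(object) {
  cat("SelectionModel:", object@nStrata, "strata |",
      if (object@converged) "converged" else "NOT converged", "\n")
  if (!is.na(object@animal)) cat("  animal:", object@animal,
                                 if (!is.na(object@species))
                                   paste0("(", object@species, ")"), "\n")
  tab <- data.frame(beta = round(object@coef, 4),
                    se = round(object@se, 4),
                    p = signif(modelPvalues(object), 3))
  print(tab)
  cat("  loglik:", round(object@loglik, 3), "\n")
})

#' Relative selection strength between two locations
#'
#' `w(x1) / w(x2) = exp(beta' (x1 - x2))`: how many times more likely a
#' step ending at covariates `x1` is than one ending at `x2`, all else
#' equal.
#'
#' @param model a converged [SelectionModel-class].
#' @param x1,x2 named numeric vectors covering the model's terms.
#' @return the selection ratio (positive scalar).
#' @export
relativeSelection <- function(model, x1, x2) {
  if (!model@converged) stop("model did not converge")
  nm <- names(model@coef)
  if (!all(nm %in% names(x1)) || !all(nm %in% names(x2)))
    stop("x1 and x2 must provide every model term")
  exp(sum(model@coef * (x1[nm] - x2[nm])))
}

#' Serialize a selection model to JSON (and back)
#'
#' @param model a [SelectionModel-class].
#' @param path output file.
#' @return `writeSelectionModel` invisibly returns `path`;
#'   `readSelectionModel` returns the model.
#' @export
writeSelectionModel <- function(model, path) {
  obj <- list(coef = as.list(model@coef), se = as.list(model@se),
              vcov = model@vcov, loglik = model@loglik,
              n_strata = model@nStrata, converged = model@converged,
              formula = model@formula, animal = model@animal,
              species = model@species,
              standardization = model@standardization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSelectionModel
#' @export
readSelectionModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SelectionModel", coef = unlist(obj$coef), se = unlist(obj$se),
      vcov = matrix(unlist(obj$vcov), length(obj$coef),
                    dimnames = list(names(obj$coef), names(obj$coef))),
      loglik = obj$loglik, nStrata = as.integer(obj$n_strata),
      converged = obj$converged, formula = obj$formula,
      animal = as.character(obj$animal),
      species = as.character(obj$species),
      standardization = as.data.frame(obj$standardization))
}
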