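test_that("tentative kernel recovers known movement distributions", {
  set.seed(21)
  steps <- data.frame(sl = rgamma(5000, shape = 2, rate = 0.01),
                      ta = rvonmises(5000, 0, 0.8))
  tk <- fitTentative(steps)
  expect_lt(abs(tk@slShape - 2) / 2, 0.10)            # shape within 10%
  expect_lt(abs(tk@slShape / tk@slRate - 200) / 200, 0.05)
  expect_false(tk@degenerate)

  # uniform angles -> kappa ~ 0
  stepsU <- data.frame(sl = rgamma(5000, 2, 0.01),
                       ta = runif(5000, -pi, pi))
  expect_lt(fitTentative(stepsU)@taKappa, 0.05)

  # identical angles -> concentration cap, flagged degenerate
  stepsD <- data.frame(sl = rgamma(100, 2, 0.01), ta = rep(0, 100))
  expect_true(fitTentative(stepsD)@degenerate)

  expect_error(fitTentative(data.frame(sl = 1:5, ta = rep(0.1, 5))),
               "at least")
})

test_that("zero step lengths are offset by half a cell before the fit", {
  set.seed(22)
  sl <- rgamma(2000, 2, 0.01); sl[1:50] <- 0
  steps <- data.frame(sl = sl, ta = rvonmises(2000, 0, 0.5))
  tk <- fitTentative(steps, cellSize = 10)
  expect_true(tk@slShape > 0 && tk@slRate > 0)
})

test_that("correlation screen flags |r| strictly above the threshold", {
  set.seed(23)
  x <- rnorm(5000)
  d <- data.frame(a = x, b = 2 * x + 1, c = rnorm(5000))
  sc <- screenCorrelation(d, c("a", "b", "c"), 0.6)
  expect_true(any(sc$excluded$var1 == "a" & sc$excluded$var2 == "b"))
  expect_equal(sc$excluded$r[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(sc$r["c", c("a", "b")])), 0.05)  # independent vars

  # r exactly at the threshold is NOT excluded (strict >)
  n <- 100
  u <- rnorm(n)
  v <- 0.6 * scale(u)[, 1] + sqrt(1 - 0.36) * scale(resid(lm(rnorm(n) ~ u)))[, 1]
  d2 <- data.frame(a = scale(u)[, 1], b = v)
  stopifnot(abs(cor(d2$a, d2$b) - 0.6) < 1e-9)
  expect_equal(nrow(screenCorrelation(d2, c("a", "b"), 0.6)$excluded), 0)

  d3 <- data.frame(a = x, k = rep(1, 5000))
  expect_equal(screenCorrelation(d3, c("a", "k"))$undefined, "k")
})

test_that("mirror strata force the coefficient to zero", {
  d <- data.frame(animal_id = "A", stratum_id = rep(1:2, each = 3),
                  case = rep(c(1, 0, 0), 2),
                  x = c(1, 0, 0, 0, 1, 1))
  fit <- fitClogit(d, terms = "x")
  expect_true(fit@converged)
  expect_equal(unname(modelCoef(fit)), 0, tolerance = 1e-8)
})

test_that("Newton estimate matches the 1-D grid-search oracle", {
  # S1: used x=1 vs {0,0}; S2: used x=1 vs {0,2}
  d <- data.frame(animal_id = "A", stratum_id = rep(1:2, each = 3),
                  case = rep(c(1, 0, 0), 2),
                  x = c(1, 0, 0, 1, 0, 2))
  fit <- fitClogit(d, terms = "x")
  oracle <- gridSearchClogit1D(list(c(1, 0, 0), c(1, 0, 2)), c(1, 1))
  expect_lt(abs(unname(modelCoef(fit)) - oracle), 1e-3)
  # the oracle's own closed form: maximize e^b/(e^b+2) * e^b/(1+e^b+e^2b)
  ll <- function(b) b - log(exp(b) + 2) + b - log(1 + exp(b) + exp(2 * b))
  expect_equal(ll(unname(modelCoef(fit))), ll(oracle), tolerance = 1e-6)
})

test_that("2-covariate fits match grid search on tiny problems", {
  set.seed(31)
  d <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(animal_id = "A", stratum_id = s, case = c(1, 0, 0),
               x = rnorm(3), z = rnorm(3))
  }))
  fit <- fitClogit(d, terms = c("x", "z"))
  grid <- seq(-4, 4, 5e-2)
  ll <- function(b1, b2) {
    sum(vapply(1:3, function(s) {
      g <- d[d$stratum_id == s, ]
      eta <- b1 * g$x + b2 * g$z
      eta[1] - log(sum(exp(eta)))
    }, 0))
  }
  lls <- outer(grid, grid, Vectorize(ll))
  best <- which(lls == max(lls), arr.ind = TRUE)[1, ]
  coarse <- c(grid[best[1]], grid[best[2]])
  # refine 1e-3 around the coarse optimum
  g1 <- seq(coarse[1] - 6e-2, coarse[1] + 6e-2, 1e-3)
  g2 <- seq(coarse[2] - 6e-2, coarse[2] + 6e-2, 1e-3)
  lls <- outer(g1, g2, Vectorize(ll))
  best <- which(lls == max(lls), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(modelCoef(fit) - c(g1[best[1]], g2[best[2]]))), 1e-3)
})

test_that("estimates agree with survival::clogit on simulated strata", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(32)
  L <- synthLandscape(nr = 80, nc = 80, seed = 5)
  ss <- synthStrata(L$stack, beta = c(canopy_height = 0.4, swamp = 0.5),
                    nStrata = 200, kControls = 5,
                    tentative = defaultTentative(), seed = 6)
  d <- standardizeWith(ss$strata, ss$standardization)
  fit <- fitClogit(d, terms = c("canopy_height", "swamp"))
  sv <- survival::clogit(case ~ canopy_height + swamp +
                           survival::strata(stratum_id), data = d)
  expect_equal(unname(modelCoef(fit)), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(unname(modelSE(fit)), unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-4)
  expect_equal(fit@loglik, as.numeric(logLik(sv)), tolerance = 1e-6)
})

test_that("stratum-constant offsets leave the fit invariant", {
  set.seed(33)
  d <- do.call(rbind, lapply(1:20, function(s) {
    data.frame(animal_id = "A", stratum_id = s,
               case = sample(c(1, 0, 0, 0)), x = rnorm(4), z = rnorm(4))
  }))
  fit <- fitClogit(d, terms = c("x", "z"))
  d2 <- d
  offs <- rnorm(20)
  d2$x <- d2$x + offs[d2$stratum_id]   # constant within each stratum
  fit2 <- fitClogit(d2, terms = c("x", "z"))
  expect_equal(modelCoef(fit2), modelCoef(fit), tolerance = 1e-6)
  expect_equal(fit2@loglik, fit@loglik, tolerance = 1e-8)
})

test_that("separation and non-identifiability are flagged, never silent", {
  # single stratum, monotone likelihood
  d <- data.frame(animal_id = "A", stratum_id = 1, case = c(1, 0, 0),
                  x = c(1, 0, 0))
  fit <- fitClogit(d, terms = "x")
  expect_false(fit@converged)
  expect_true(attr(fit, "separated"))

  # covariate constant within every stratum
  d2 <- data.frame(animal_id = "A", stratum_id = rep(1:2, each = 3),
                   case = rep(c(1, 0, 0), 2), x = rep(c(3, 7), each = 3),
                   z = rnorm(6))
  expect_error(fitClogit(d2, terms = c("x", "z")), "not identifiable")
})

test_that("degenerate strata are dropped with a count", {
  d <- data.frame(animal_id = "A", stratum_id = rep(1:3, each = 3),
                  case = rep(c(1, 0, 0), 3),
                  x = c(1, 0, 0, 5, 5, 5, 0, 1, 1))
  fit <- fitClogit(d, terms = "x")
  expect_equal(attr(fit, "nDegenerate"), 1L)
  expect_equal(fit@nStrata, 2L)
})

test_that("relative selection strength is exp(beta' (x1 - x2))", {
  d <- data.frame(animal_id = "A", stratum_id = rep(1:2, each = 3),
                  case = rep(c(1, 0, 0), 2),
                  x = c(1, 0, 0, 0, 1, 1))
  fit <- fitClogit(d, terms = "x")
  expect_equal(relativeSelection(fit, c(x = 3), c(x = 3)), 1)

  fit@coef <- c(x = log(2)); fit@converged <- TRUE
  expect_equal(relativeSelection(fit, c(x = 1), c(x = 0)), 2)

  set.seed(34)
  b <- rnorm(1); fit@coef <- c(x = b)
  x1 <- c(x = rnorm(1)); x2 <- c(x = rnorm(1))
  expect_equal(relativeSelection(fit, x1, x2),
               exp(sum(b * (x1 - x2))), tolerance = 1e-12)
  expect_error(relativeSelection(fit, c(y = 1), c(x = 0)), "term")
})

test_that("model JSON round-trips coefficients and covariance", {
  d <- data.frame(animal_id = "A", stratum_id = rep(1:10, each = 3),
                  case = rep(c(1, 0, 0), 10), x = rnorm(30), z = rnorm(30))
  fit <- fitClogit(d, terms = c("x", "z"))
  p <- withr::local_tempfile(fileext = ".json")
  writeSelectionModel(fit, p)
  back <- readSelectionModel(p)
  expect_equal(modelCoef(back), modelCoef(fit))
  expect_equal(back@vcov, fit@vcov, tolerance = 1e-12)
  expect_equal(back@loglik, fit@loglik)
})
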