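# REML engine: design construction, OLS boundary, oracle optimality,
# Wald calibration, R2 behaviour.

test_that("design matrix has the expected dummy-coded columns", {
  h <- makeHerdDesign(61, seed = 1)
  # intercept + 2 breed + 3 pen + age + cov1 = 8
  expect_equal(ncol(h$design@X), 8)
  expect_equal(h$design@rank, 8)
  expect_length(h$design@droppedColumns, 0)
  # Z: 12 one-hot columns
  expect_equal(ncol(h$design@Z), 12)
  expect_true(all(rowSums(h$design@Z) == 1))
  expect_true(all(h$design@Z %in% c(0, 1)))
})

test_that("exactly collinear columns are dropped and recorded", {
  h <- makeHerdDesign(61, seed = 2, extraCov = FALSE)
  meta <- h$meta
  # pen redefined as an exact copy of breed's partition
  meta$pen <- factor(paste0("P", as.integer(meta$breed)))
  d <- buildDesign(meta, covariates = data.frame(age = meta$age))
  expect_gt(length(d@droppedColumns), 0)
  expect_true(all(grepl("^pen", d@droppedColumns)))
  expect_equal(d@rank, ncol(d@X))
  # constant covariate dropped with a warning, not an error
  expect_warning(
    buildDesign(meta, covariates = data.frame(age = meta$age, k = 1)),
    "constant")
  # single-level factor errors
  meta$breed <- factor("B1")
  expect_error(buildDesign(meta), "fewer than 2 levels")
})

test_that("REML reduces exactly to OLS when sire effects are absent", {
  h <- makeHerdDesign(61, seed = 3)
  d <- h$design
  set.seed(10)
  # noise orthogonal to both X and Z: the profile is maximized at the
  # lambda = 0 boundary deterministically
  e <- qr.resid(qr(cbind(d@X, d@Z)), rnorm(61))
  y <- drop(d@X %*% rnorm(ncol(d@X))) + e
  fit <- fitREML(y, d)
  expect_equal(fit@sigma2Sire, 0)
  ols <- lm.fit(d@X, y)
  expect_equal(unname(fit@beta), unname(ols$coefficients),
               tolerance = 1e-8)
  # Wald p equals the OLS t-test p
  olsFit <- lm(y ~ d@X - 1)
  pOls <- suppressWarnings(summary(olsFit))$coefficients["d@Xage", 4]
  expect_equal(waldP(fit, "age"), unname(pOls), tolerance = 1e-8)
})

test_that("fit satisfies its internal identities", {
  h <- makeHerdDesign(61, seed = 4)
  y <- simulateResponse(h$design, h$meta, s2s = 0.01, s2e = 0.03, seed = 4)
  fit <- fitREML(y, h$design)
  expect_equal(fit@residConditional + fit@fittedConditional, y)
  # conditional residuals orthogonal to every retained X column
  expect_lt(max(abs(crossprod(h$design@X, fit@residConditional))), 1e-7)
  expect_lt(abs(mean(fit@residConditional)), 1e-8 * sd(fit@residConditional))
  expect_gte(fit@sigma2Sire, 0)
  expect_gt(fit@sigma2Resid, 0)
})

test_that("REML loglik agrees with lme4 on the same data", {
  skip_if_not_installed("lme4")
  h <- makeHerdDesign(61, seed = 5)
  y <- simulateResponse(h$design, h$meta, s2s = 0.02, s2e = 0.03, seed = 5)
  fit <- fitREML(y, h$design)
  df <- data.frame(y = y, h$meta, cov1 = h$design@X[, "cov1"])
  lf <- lme4::lmer(y ~ breed + pen + age + cov1 + (1 | sire), data = df,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit@sigma2Sire, vc$vcov[vc$grp == "sire"], tolerance = 1e-3)
  expect_equal(fit@sigma2Resid, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-3)
  expect_equal(unname(fit@beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(unname(sort(fit@u)),
               unname(sort(lme4::ranef(lf)$sire[, 1])), tolerance = 1e-3)
})

test_that("returned optimum beats a brute-force variance grid", {
  for (s in 1:3) {
    h <- makeHerdDesign(40, seed = 20 + s, nSires = 8)
    y <- simulateResponse(h$design, h$meta, s2s = 0.01, s2e = 0.03,
                          seed = 20 + s)
    fit <- fitREML(y, h$design)
    v <- var(y)
    grid <- expand.grid(s2s = seq(0, v, length.out = 50),
                        s2e = seq(v / 50, 2 * v, length.out = 50))
    ll <- mapply(function(a, b)
      oracleREMLLoglik(y, h$design@X, h$design@Z, a, b),
      grid$s2s, grid$s2e)
    expect_gte(fit@remlLoglik, max(ll) - 1e-6)
  }
})

test_that("sample permutation permutes residuals identically", {
  h <- makeHerdDesign(61, seed = 6)
  y <- simulateResponse(h$design, h$meta, s2s = 0.01, s2e = 0.03, seed = 6)
  fit <- fitREML(y, h$design)
  set.seed(99)
  perm <- sample.int(61)
  metaP <- h$meta[perm, ]
  covP <- data.frame(age = metaP$age, cov1 = h$design@X[perm, "cov1"])
  fitP <- fitREML(y[perm], buildDesign(metaP, covariates = covP))
  expect_equal(fitP@residConditional, fit@residConditional[perm],
               tolerance = 1e-8)
  expect_equal(fitP@sigma2Sire, fit@sigma2Sire, tolerance = 1e-8)
})

test_that("Wald p is 1 at a zero coefficient and calibrated under the null", {
  h <- makeHerdDesign(61, seed = 7, extraCov = FALSE)
  # response orthogonal to an added covariate column of exact zeros effect:
  # force beta = 0 by making y orthogonal to the covariate within the model
  d <- h$design
  y <- drop(d@X %*% rep(1, ncol(d@X)))
  covs <- data.frame(age = h$meta$age,
                     probe = qr.resid(qr(cbind(d@X, d@Z)), rnorm(61)))
  d2 <- buildDesign(h$meta, covariates = covs)
  fit <- fitREML(y + covs$probe * 0, d2)
  expect_equal(waldP(fit, "probe"), 1, tolerance = 1e-6)
  # dropped-column lookup names the aliasing
  meta <- h$meta
  covs2 <- data.frame(age = meta$age, ageCopy = meta$age)
  d3 <- buildDesign(meta, covariates = covs2)
  dropped <- d3@droppedColumns[1]
  fit3 <- fitREML(rnorm(61), d3)
  expect_error(waldP(fit3, dropped), "aliased")

  # type-I error of the nominal p over independent null replicates:
  # y is generated without any probe effect, then tested with the probe in
  # the model
  dBase <- buildDesign(h$meta, covariates = data.frame(age = h$meta$age))
  reject <- logical(1000)
  for (r in 1:1000) {
    set.seed(3000 + r)
    probe <- rnorm(61)
    dR <- buildDesign(h$meta,
                      covariates = data.frame(age = h$meta$age,
                                              probe = probe))
    yR <- simulateResponse(dBase, h$meta, s2s = 0.01, s2e = 0.03,
                           seed = 40000 + r)
    reject[r] <- waldP(fitREML(yR, dR), "probe") < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("variance components are recovered on moderate samples", {
  est <- t(sapply(1:5, function(s) {
    cfg <- simConfig(nAnimals = 500, nSires = 50, nPens = 8, seed = 50 + s)
    meta <- simulateHerd(cfg)
    d <- buildDesign(meta, covariates = data.frame(age = meta$age))
    y <- simulateResponse(d, meta, s2s = 0.01, s2e = 0.03, seed = 70 + s)
    fit <- fitREML(y, d)
    c(fit@sigma2Sire, fit@sigma2Resid)
  }))
  expect_lt(abs(mean(est[, 1]) - 0.01) / 0.01, 0.5)
  expect_lt(abs(mean(est[, 2]) - 0.03) / 0.03, 0.1)
})

test_that("model R2 behaves at its extremes and under the null", {
  h <- makeHerdDesign(61, seed = 8, extraCov = FALSE)
  # exact linear function of the design: R2 = 1
  y <- drop(h$design@X %*% c(1, 0.5, -0.2, 0.3, 0.1, -0.4, 0.01))
  fit <- fitREML(y + qr.resid(qr(cbind(h$design@X, h$design@Z)),
                              rnorm(61)) * 1e-8, h$design)
  expect_equal(modelR2(fit, y), 1, tolerance = 1e-6)
  expect_error(modelR2(fit, rep(1, 61)), "zero variance")

  # independent response: R2 stays small at n = 1000 (19/20 seeds)
  ok <- 0L
  for (s in 1:20) {
    cfg <- simConfig(nAnimals = 1000, nSires = 20, nPens = 6, seed = 600 + s)
    meta <- simulateHerd(cfg)
    d <- buildDesign(meta, covariates = data.frame(age = meta$age))
    set.seed(900 + s)
    yN <- rnorm(1000)
    if (modelR2(fitREML(yN, d), yN) < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("adding a truly linked covariate never lowers conditional R2", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- simConfig(nAnimals = 200, nSires = 12, seed = 700 + s)
    meta <- simulateHerd(cfg)
    set.seed(800 + s)
    x <- rnorm(200)
    dBase <- buildDesign(meta, covariates = data.frame(age = meta$age))
    y <- simulateResponse(dBase, meta, s2s = 0.01, s2e = 0.03,
                          seed = 850 + s) + 0.1 * x
    dFull <- buildDesign(meta,
                         covariates = data.frame(age = meta$age, x = x))
    r2b <- modelR2(fitREML(y, dBase), y)
    r2f <- modelR2(fitREML(y, dFull), y)
    if (r2f >= r2b - 1e-10) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("input validation catches malformed responses", {
  h <- makeHerdDesign(61, seed = 9)
  expect_error(fitREML(c(rnorm(60), NA), h$design), "non-finite")
  expect_error(fitREML(rnorm(10), h$design), "match")
})
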