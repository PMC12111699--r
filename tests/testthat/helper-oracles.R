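# Independent brute-force oracles, coded without reference to the package
# internals, plus small fixture builders shared across test files.

# median-of-ratios, geometric mean via prod()^(1/n)
oracleSizeFactors <- function(counts) {
  pos <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[pos, , drop = FALSE]
  ref <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  apply(sub, 2, function(cs) median(cs / ref))
}

# Benjamini-Hochberg step-up from the definition
oracleBH <- function(p, m = length(p)) {
  k <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adjSorted <- vapply(seq_len(k), function(i) {
    min(1, min(m * sorted[i:k] / seq(i, k)))
  }, numeric(1))
  adj <- numeric(k)
  adj[ord] <- adjSorted
  adj
}

# sample PCA scores via eigendecomposition of the sample covariance
oraclePCAScores <- function(lognorm, k = 2) {
  X <- t(lognorm)                      # samples x genes
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(Xc), symmetric = TRUE)
  Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
}

# dense REML log-likelihood of the single-random-effect model at fixed
# variance components (same constant convention as a Gaussian restricted
# likelihood)
oracleREMLLoglik <- function(y, X, Z, s2s, s2e) {
  n <- length(y); p <- ncol(X)
  V <- s2e * diag(n) + s2s * tcrossprod(Z)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtVX)$modulus) +
            as.numeric(t(r) %*% Vi %*% r))
}

# small herd + design fixture used by several mixed-model tests
makeHerdDesign <- function(n = 61, seed = 1, nSires = 12, extraCov = TRUE) {
  cfg <- simConfig(nAnimals = n, nSires = nSires, seed = seed)
  meta <- simulateHerd(cfg)
  covs <- data.frame(age = meta$age)
  if (extraCov) {
    set.seed(seed + 7)
    covs$cov1 <- rnorm(n)
  }
  list(meta = meta, design = buildDesign(meta, covariates = covs), cfg = cfg)
}

# simulate y = X beta + sire effects + noise against a given design
simulateResponse <- function(d, meta, s2s, s2e, beta = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- rnorm(ncol(d@X), 0, 0.2)
  sire <- rnorm(ncol(d@Z), 0, sqrt(s2s))
  drop(d@X %*% beta) + drop(d@Z %*% sire) + rnorm(nrow(d@X), 0, sqrt(s2e))
}

# compact config for fast end-to-end differential-expression runs
deConfig <- function(seed, nGenes = 2000, nPlanted = 20,
                     plantedEffect = 0.6) {
  simConfig(seed = seed, nGenes = nGenes, nPlanted = nPlanted,
            plantedEffect = plantedEffect)
}

# one full synthetic DE run; returns the DE table and the ground truth
runSyntheticDE <- function(cfg, trait = "GF") {
  se <- simulateStudy(cfg)
  prep <- prepCounts(se)
  list(de = runDE(prep, trait = trait, meta = se, cbc = se),
       truth = S4Vectors::metadata(se)$groundTruth,
       prep = prep)
}
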