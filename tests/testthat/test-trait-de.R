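# Double-residualization differential expression: cell-proportion
# covariates, confounder adjustment, correlation inference, BH control.

test_that("cell proportions are fractions of WBC, RBC stays absolute", {
  cbc <- data.frame(WBC = 9.56, NEU = 3.55, LYM = 5.24, MONO = 0.57,
                    EOS = 0.11, BAS = 0.08, RBC = 9.21)
  cp <- cellProportionCovariates(cbc)
  expect_equal(cp$NEU, 3.55 / 9.56, tolerance = 1e-12)
  expect_equal(round(cp$NEU, 4), 0.3713)
  expect_equal(cp$RBC, 9.21)
  # differentials summing to WBC give fractions summing exactly to 1
  cbc2 <- transform(cbc, WBC = NEU + LYM + MONO + EOS + BAS)
  cp2 <- cellProportionCovariates(cbc2)
  expect_equal(cp2$NEU + cp2$LYM + cp2$MONO + cp2$EOS + cp2$BAS, 1,
               tolerance = 1e-12)
  expect_error(cellProportionCovariates(transform(cbc, WBC = 0)), "WBC")
  expect_error(cellProportionCovariates(cbc[, -2]), "NEU")
})

test_that("identical CBC across animals aliases out in the design", {
  cfg <- simConfig(seed = 41)
  meta <- simulateHerd(cfg)
  cbc <- simulateCBC(meta, cfg)
  cbc[cbcParameterNames()] <- lapply(cbc[cbcParameterNames()],
                                     function(x) rep(x[1], nrow(cbc)))
  cp <- cellProportionCovariates(cbc)
  d <- suppressWarnings(
    buildDesign(meta, covariates = cbind(data.frame(age = meta$age), cp)))
  expect_false(any(c("NEU", "LYM", "RBC") %in% d@xNames))
})

test_that("adjustment annihilates exact confounders and centers residuals", {
  cfg <- simConfig(seed = 42)
  meta <- simulateHerd(cfg)
  cbc <- simulateCBC(meta, cfg)
  cp <- cellProportionCovariates(cbc)
  set.seed(42)
  expr <- matrix(rnorm(40 * 61), 40, 61,
                 dimnames = list(sprintf("g%02d", 1:40), meta$animal_id))
  expr[1, ] <- 3 + 2 * cp$LYM          # exact linear function of a covariate
  trait <- rnorm(61)
  adj <- adjustForConfounders(expr, trait, meta, cp)
  expect_lt(max(abs(adj@residExpr[1, ])), 1e-6)
  # every residual vector is centered
  expect_lt(max(abs(rowMeans(adj@residExpr))),
            1e-8 * max(apply(adj@residExpr, 1, sd)))
  expect_lt(abs(mean(adj@residTrait)), 1e-8 * sd(adj@residTrait))
  # trait residuals orthogonal to every retained design column
  d <- buildDesign(meta,
                   covariates = cbind(data.frame(age = meta$age), cp))
  ortho <- abs(cor(adj@residTrait, d@X[, -1]))
  expect_lt(max(ortho), 1e-8)
})

test_that("adjustment removes cell-composition confounding from genes", {
  # a real hematology-trait link makes confounded (but not trait-linked)
  # genes correlate with the raw trait; the double residualization must
  # break that path
  eff <- matrix(0, 15, 2,
                dimnames = list(cbcParameterNames(), c("ADG", "ADFI")))
  eff["LYM", "ADG"] <- -0.10
  better <- 0L
  for (s in 1:20) {
    cfg <- simConfig(seed = 430 + s, nGenes = 200, nPlanted = 0,
                     plantedEffect = 0, confoundStrength = 0.5,
                     confoundFrac = 0.5, nOutlierSamples = 0,
                     cbcEffects = eff)
    se <- simulateStudy(cfg)
    truth <- S4Vectors::metadata(se)$groundTruth
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    counts <- SummarizedExperiment::assay(se)
    conf <- truth@confoundedGenes
    lg <- log2(counts[conf, ] + 1)
    lg <- lg[apply(lg, 1, sd) > 0, ]
    meta <- cd[, c("animal_id", "breed", "pen", "sire", "age")]
    cp <- cellProportionCovariates(cd)
    adj <- adjustForConfounders(lg, cd$ADG, meta, cp)
    pre <- abs(apply(lg, 1, cor, y = cd$ADG))
    post <- abs(apply(adj@residExpr, 1, cor, y = adj@residTrait))
    if (median(post) < median(pre)) better <- better + 1L
  }
  expect_gte(better, 18L)
})

test_that("correlation inference: extremes, degeneracy, permutation oracle", {
  cfg <- simConfig(seed = 44, nGenes = 600, nPlanted = 5)
  se <- simulateStudy(cfg)
  prep <- prepCounts(se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- retainedSamples(prep)
  meta <- cd[match(keep, cd$animal_id),
             c("animal_id", "breed", "pen", "sire", "age")]
  cbc <- cd[match(keep, cd$animal_id), c("animal_id", cbcParameterNames())]
  ex <- logNorm(prep)[, keep]
  adj <- adjustForConfounders(ex, cd$GF[match(keep, cd$animal_id)], meta,
                              cellProportionCovariates(cbc))
  # self-correlation: a gene whose residuals are the trait residuals
  adj2 <- adj
  adj2@residExpr[1, ] <- adj@residTrait
  adj2@residExpr[2, ] <- 0              # zero-variance gene
  cr <- correlateResiduals(adj2)
  expect_equal(cr$reg[1], 1, tolerance = 1e-12)
  expect_lt(cr$p[1], 1e-30)
  expect_true(cr$degenerate[2])
  expect_true(is.na(cr$reg[2]))
  expect_equal(cr$p[2], 1)
  expect_true(all(abs(cr$reg) <= 1, na.rm = TRUE))

  # permutation-null oracle for the t-based r -> p map on 20 genes.
  # Permuting residual entries destroys their confinement to the
  # residual subspace, so the permutation null is exchangeable entries --
  # exactly the null of the classic n - 2 convention, which is the one
  # compared here.  (The subspace-corrected default df is validated
  # separately through the measured null variance and FDR control.)
  n <- length(adj@residTrait)
  B <- 100000
  set.seed(123)
  tstd <- scale(adj@residTrait)[, 1]
  P <- replicate(B, sample(tstd))               # n x B permuted traits
  genes <- seq_len(20)
  crAll <- correlateResiduals(adj, dfMethod = "classic")
  for (g in genes) {
    gv <- adj@residExpr[g, ]
    if (sd(gv) == 0) next
    gstd <- (gv - mean(gv)) / sd(gv)
    rPerm <- drop(gstd %*% P) / (n - 1)
    rObs <- cor(gv, adj@residTrait)
    pPerm <- (1 + sum(abs(rPerm) >= abs(rObs))) / (B + 1)
    tol <- 3 * sqrt(pPerm * (1 - pPerm) / B) + 2e-3
    expect_lt(abs(crAll$p[g] - pPerm), tol + 1e-12)
  }
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  set.seed(7)
  p <- runif(100)
  expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-14)
  # adjusting a subset against a larger total test count
  psub <- sort(p)[1:10]
  expect_equal(bhAdjust(psub, mTotal = 100), oracleBH(psub, m = 100),
               tolerance = 1e-14)
  # identity for a single test
  expect_equal(bhAdjust(0.37, mTotal = 1), 0.37)
  # elementwise dominance and permutation equivariance
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  perm <- sample(100)
  expect_equal(bhAdjust(p[perm]), adj[perm])
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(p, mTotal = 50), "mTotal")
})

test_that("runDE output contract holds and planted genes surface", {
  cfg <- simConfig(seed = 45, nGenes = 1500, nPlanted = 10)
  se <- simulateStudy(cfg)
  prep <- prepCounts(se)
  de <- runDE(prep, trait = "GF", meta = se, cbc = se)
  expect_true(all(de$p_fdr >= de$p_nominal))
  expect_true(!is.unsorted(de$p_fdr))
  expect_true(all(abs(de$reg) <= 1, na.rm = TRUE))
  expect_setequal(de$gene_id, prep@keptGenes)
  expect_equal(de$significant, de$p_fdr < 0.1)
  truth <- S4Vectors::metadata(se)$groundTruth
  hits <- intersect(de$gene_id[de$significant], plantedGenes(truth))
  expect_gte(length(hits), 7)
  # recovered signs match the planted directions
  sg <- sign(de$reg[match(hits, de$gene_id)])
  expect_equal(unname(sg), unname(plantedDirections(truth)[hits]))
})

test_that("a pure confounder signal added to all genes changes nothing", {
  cfg <- simConfig(seed = 46, nGenes = 800, nPlanted = 6)
  se <- simulateStudy(cfg)
  prep <- prepCounts(se)
  de1 <- runDE(prep, trait = "GF", meta = se, cbc = se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cp <- cellProportionCovariates(cd)
  z <- 2 * scale(cp$LYM)[, 1] - scale(cp$RBC)[, 1]
  prep2 <- prep
  set.seed(46)
  prep2@logNorm <- prep@logNorm +
    outer(rnorm(nrow(prep@logNorm)), z[match(colnames(prep@logNorm),
                                             cd$animal_id)])
  de2 <- runDE(prep2, trait = "GF", meta = se, cbc = se)
  expect_identical(de2$gene_id[de2$significant],
                   de1$gene_id[de1$significant])
  # identical up to optimizer jitter on the per-gene variance ratio
  expect_equal(de2$p_nominal, de1$p_nominal, tolerance = 1e-5)
})

test_that("with no planted genes nothing is declared significant", {
  cfg <- simConfig(seed = 47, nGenes = 1200, nPlanted = 0, plantedEffect = 0)
  se <- simulateStudy(cfg)
  prep <- prepCounts(se)
  de <- runDE(prep, trait = "ADFI", meta = se, cbc = se)
  expect_equal(sum(de$significant), 0)
})
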