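# Synthetic herd generator: metadata, CBC panels, growth/intake, counts.
# Every stage draws from its own child seed derived from the master seed, so
# stages are reproducible independently of each other.

.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (2^31 - 1))
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.defaultCBCAnchors <- function() {
  data.frame(
    parameter = cbcParameterNames(),
    mean = c(9.56, 3.55, 5.24, 0.57, 0.11, 0.08, 9.21, 12.57, 37.31,
             40.80, 13.73, 33.69, 23.18, 641.77, 4.80),
    sd = c(2.53, 1.75, 1.11, 0.19, 0.04, 0.03, 1.08, 1.19, 3.61,
           3.74, 1.26, 0.76, 1.38, 146.08, 0.35)
  )
}

.defaultTraitAnchors <- function() {
  data.frame(trait = c("ADG", "ADFI", "GF"),
             mean = c(0.8, 7.5, 0.11),
             sd = c(0.2, 1.2, 0.03))
}

.defaultWeightAnchors <- function() {
  data.frame(day = c(0, 21, 42, 63, 84),
             mean = c(283.0, 306.5, 315.2, 333.5, 347.4))
}

.defaultCBCEffects <- function() {
  eff <- matrix(0, nrow = 15L, ncol = 2L,
                dimnames = list(cbcParameterNames(), c("ADG", "ADFI")))
  # modest hematology-to-trait slopes: lymphocytes down / hemoglobin
  # concentration up with gain; red-cell count down with intake
  eff["LYM", "ADG"] <- -0.05
  eff["MCHC", "ADG"] <- 0.10
  eff["RBC", "ADFI"] <- -0.35
  eff["MCHC", "ADFI"] <- 0.50
  eff
}

#' Build a synthetic-study configuration
#'
#' Returns a [SimConfig-class] whose defaults emulate the study conditions:
#' 61 heifers of 3 breeds from 12 sires in 4 pens, CBC anchors and trait
#' anchors at the published herd means/SDs, a 34k-gene count matrix of which
#' roughly 15k pass the low-expression filter, cell-composition confounding
#' on 30 percent of genes, 20 planted trait-associated genes at partial
#' correlation 0.6 on G:F, and 2 planted expression-outlier samples (so the
#' default study retains 59 samples after the ellipse screen).
#'
#' @param nAnimals,nBreeds,nSires,nPens herd structure.
#' @param seed master seed; all stage seeds derive from it.
#' @param nGenes,nPlanted count-matrix size and number of planted genes.
#' @param plantedEffect target partial correlation magnitude in [0, 1).
#' @param plantedTrait trait the planted genes track.
#' @param confoundStrength,confoundFrac cell-composition effect scale and
#'   the fraction of genes carrying it.
#' @param nbDispersion negative-binomial dispersion; 0 gives Poisson counts.
#' @param libSizeSD log-scale SD of library-size factors.
#' @param nOutlierSamples,outlierScale planted expression-outlier samples
#'   and the log-scale SD of their per-gene shift.
#' @param traitAnchors,cbcAnchors,weightAnchors anchor tables; see
#'   [SimConfig-class].
#' @param cbcEffects 15 x 2 slope matrix (ADG, ADFI columns).
#' @param sireVariance named sire variance components for ADG and ADFI.
#' @param breedSD,penSD,ageSlope,ageMean,ageSD design-effect scales.
#' @param weightStartSD,weightNoiseSD day-0 weight SD and scale noise (kg).
#' @param baselineLogMean,baselineLogSD,plantedLogMean,plantedLogSD
#'   natural-log baseline expression distributions.
#'
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(nAnimals = 61, nBreeds = 3, nSires = 12, nPens = 4,
                      seed = 1,
                      nGenes = 34000, nPlanted = 20,
                      plantedEffect = 0.6, plantedTrait = "GF",
                      confoundStrength = 0.3, confoundFrac = 0.3,
                      nbDispersion = 0.05, libSizeSD = 0.15,
                      nOutlierSamples = 2, outlierScale = 1.0,
                      traitAnchors = .defaultTraitAnchors(),
                      cbcAnchors = .defaultCBCAnchors(),
                      weightAnchors = .defaultWeightAnchors(),
                      cbcEffects = .defaultCBCEffects(),
                      sireVariance = c(ADG = 0.01, ADFI = 0.10),
                      breedSD = c(ADG = 0.04, ADFI = 0.20),
                      penSD = c(ADG = 0.02, ADFI = 0.10),
                      ageSlope = c(ADG = 0.001, ADFI = 0.004),
                      ageMean = 240, ageSD = 15,
                      weightStartSD = 27.3, weightNoiseSD = 3,
                      baselineLogMean = log(8), baselineLogSD = 2.2,
                      plantedLogMean = log(300), plantedLogSD = 0.5) {
  new("SimConfig",
      nAnimals = as.integer(nAnimals), nBreeds = as.integer(nBreeds),
      nSires = as.integer(nSires), nPens = as.integer(nPens),
      seed = as.integer(seed),
      nGenes = as.integer(nGenes), nPlanted = as.integer(nPlanted),
      plantedEffect = plantedEffect, plantedTrait = plantedTrait,
      confoundStrength = confoundStrength, confoundFrac = confoundFrac,
      nbDispersion = nbDispersion, libSizeSD = libSizeSD,
      nOutlierSamples = as.integer(nOutlierSamples),
      outlierScale = outlierScale,
      traitAnchors = traitAnchors, cbcAnchors = cbcAnchors,
      weightAnchors = weightAnchors, cbcEffects = cbcEffects,
      sireVariance = sireVariance, breedSD = breedSD, penSD = penSD,
      ageSlope = ageSlope, ageMean = ageMean, ageSD = ageSD,
      weightStartSD = weightStartSD, weightNoiseSD = weightNoiseSD,
      baselineLogMean = baselineLogMean, baselineLogSD = baselineLogSD,
      plantedLogMean = plantedLogMean, plantedLogSD = plantedLogSD)
}

#' Simulate herd metadata
#'
#' Assigns each animal a breed, a sire nested within breed, a pen, and an
#' age.  Sires are split over breeds in blocks balanced within one; animals
#' are dealt round-robin over sires in breed-interleaved order, so both sire
#' and breed level counts are balanced within one.
#'
#' @param cfg a [SimConfig-class].
#' @return data.frame with columns `animal_id`, `breed`, `pen`, `sire`,
#'   `age` (days); factors for breed, pen, sire.
#' @examples
#' meta <- simulateHerd(simConfig(seed = 1))
#' table(meta$breed)
#' @export
simulateHerd <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  n <- cfg@nAnimals
  .withSeed(.childSeed(cfg@seed, 101), {
    # sires in blocks per breed, sized within +/- 1
    sirePerBreed <- rep(cfg@nSires %/% cfg@nBreeds, cfg@nBreeds)
    extra <- cfg@nSires %% cfg@nBreeds
    if (extra) sirePerBreed[seq_len(extra)] <- sirePerBreed[seq_len(extra)] + 1L
    sireBreed <- rep(seq_len(cfg@nBreeds), times = sirePerBreed)
    # interleave breeds so the round-robin remainder spreads across breeds
    interleaved <- order(stats::ave(sireBreed, sireBreed, FUN = seq_along),
                         sireBreed)
    sireSeq <- interleaved[((seq_len(n) - 1L) %% cfg@nSires) + 1L]
    perm <- sample.int(n)
    sire <- sireSeq[perm]
    breed <- sireBreed[sire]
    pen <- rep_len(seq_len(cfg@nPens), n)[sample.int(n)]
    age <- round(stats::rnorm(n, cfg@ageMean, cfg@ageSD))
    data.frame(
      animal_id = sprintf("A%04d", seq_len(n)),
      breed = factor(paste0("B", breed)),
      pen = factor(paste0("P", pen)),
      sire = factor(sprintf("S%02d", sire)),
      age = as.numeric(age),
      stringsAsFactors = FALSE
    )
  })
}

# log-normal parameters matching a target mean/sd
.lnormPar <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a complete-blood-count panel
#'
#' The five leukocyte differential counts (NEU, LYM, MONO, EOS, BAS) are
#' independent log-normals moment-matched to their anchors, and WBC is
#' defined as their sum, so the instrument identity WBC = NEU + LYM + MONO +
#' EOS + BAS holds exactly.  The erythrocyte series is generated as a
#' trivariate log-normal on (RBC, MCV, MCHC) whose log-scale correlations
#' are solved in closed form so that the derived indices HCT = RBC * MCV /
#' 10, HGB = MCHC * HCT / 100 and MCH = MCHC * MCV / 100 hit their anchor
#' means; the arithmetic identities a hematology analyzer guarantees
#' (e.g. MCHC = HGB / HCT * 100) hold exactly by construction.  RDW, PLT and
#' MPV are independent log-normals.
#'
#' When every anchor SD is zero the panel degenerates to the anchor means
#' themselves (a noise-free pinning mode used for testing); the derived-index
#' identities then hold only to the precision of the anchors.
#'
#' @param meta herd metadata from [simulateHerd()].
#' @param cfg a [SimConfig-class]; anchor SDs must be non-negative.
#' @return data.frame with `animal_id` plus the 15 CBC parameters.
#' @export
simulateCBC <- function(meta, cfg) {
  stopifnot(is(cfg, "SimConfig"))
  a <- cfg@cbcAnchors
  rownames(a) <- a$parameter
  n <- nrow(meta)
  if (all(a$sd == 0)) {
    out <- as.data.frame(matrix(rep(a[cbcParameterNames(), "mean"],
                                    each = n), nrow = n))
    names(out) <- cbcParameterNames()
    return(cbind(data.frame(animal_id = meta$animal_id), out))
  }
  .withSeed(.childSeed(cfg@seed, 202), {
    drawLn <- function(p) {
      m <- a[p, "mean"]; s <- a[p, "sd"]
      if (s == 0) return(rep(m, n))
      par <- .lnormPar(m, s)
      stats::rlnorm(n, par$meanlog, par$sdlog)
    }
    NEU <- drawLn("NEU"); LYM <- drawLn("LYM"); MONO <- drawLn("MONO")
    EOS <- drawLn("EOS"); BAS <- drawLn("BAS")
    WBC <- NEU + LYM + MONO + EOS + BAS

    # erythrocyte block: calibrated trivariate log-normal
    pr <- .lnormPar(a["RBC", "mean"], a["RBC", "sd"])
    pv <- .lnormPar(a["MCV", "mean"], a["MCV", "sd"])
    pc <- .lnormPar(a["MCHC", "mean"], a["MCHC", "sd"])
    # covariances on the log scale that reproduce the derived anchor means
    sRM <- log(a["HCT", "mean"] * 10 / (a["RBC", "mean"] * a["MCV", "mean"]))
    sCM <- log(a["MCH", "mean"] * 100 / (a["MCHC", "mean"] * a["MCV", "mean"]))
    Sig <- matrix(c(pr$sdlog^2, sRM, 0,
                    sRM, pv$sdlog^2, sCM,
                    0, sCM, pc$sdlog^2), 3, 3)
    ev <- eigen(Sig, symmetric = TRUE)
    if (any(ev$values < -1e-12))
      stop("CBC anchor set implies an invalid erythrocyte covariance")
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    zz <- matrix(stats::rnorm(3 * n), n, 3) %*% L
    RBC <- exp(pr$meanlog + zz[, 1])
    MCV <- exp(pv$meanlog + zz[, 2])
    MCHC <- exp(pc$meanlog + zz[, 3])
    HCT <- RBC * MCV / 10
    HGB <- MCHC * HCT / 100
    MCH <- MCHC * MCV / 100

    data.frame(animal_id = meta$animal_id,
               WBC = WBC, NEU = NEU, LYM = LYM, MONO = MONO, EOS = EOS,
               BAS = BAS, RBC = RBC, HGB = HGB, HCT = HCT, MCV = MCV,
               MCH = MCH, MCHC = MCHC,
               RDW = drawLn("RDW"), PLT = drawLn("PLT"), MPV = drawLn("MPV"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate serial body weights, feed intake and latent traits
#'
#' Per-animal latent ADG is composed of the anchor mean, breed/pen/age fixed
#' effects, a sire random effect with the configured variance, linear CBC
#' effects (slopes times the parameter's deviation from its anchor mean),
#' and a residual whose variance is chosen so the total matches the anchor
#' SD.  ADFI is built the same way; G:F = ADG / ADFI per animal.  Body
#' weights follow a quadratic growth curve whose curvature comes from a
#' quadratic fit of the population weight anchors and whose linear term is
#' set per animal so that the fitted day-84 minus day-0 gain equals
#' 84 * ADG; weigh-scale noise is added on measurement days 0, 1, 21, 42,
#' 63, 84.
#'
#' @param meta herd metadata.
#' @param cbc CBC panel from [simulateCBC()] (CBC-to-trait effects flow
#'   through the configured slope matrix).
#' @param cfg a [SimConfig-class].
#' @return list with `weights` (long data.frame: animal_id, day, weight),
#'   `traits` (data.frame: animal_id, ADG, ADFI, GF), and the per-level
#'   design effects used (`sireEffects`).
#' @export
simulateGrowth <- function(meta, cbc, cfg) {
  stopifnot(is(cfg, "SimConfig"), identical(meta$animal_id, cbc$animal_id))
  ta <- cfg@traitAnchors
  rownames(ta) <- ta$trait
  ca <- cfg@cbcAnchors
  rownames(ca) <- ca$parameter
  n <- nrow(meta)
  .withSeed(.childSeed(cfg@seed, 303), {
    cbcDev <- as.matrix(cbc[, cbcParameterNames()]) -
      matrix(ca[cbcParameterNames(), "mean"], n, 15L, byrow = TRUE)
    sireLv <- levels(meta$sire); breedLv <- levels(meta$breed)
    penLv <- levels(meta$pen)
    # level effects are centered (sum-to-zero) so they shift variance, not
    # the herd mean, and the anchor means stay identifiable
    drawEff <- function(levels, sds) {
      e <- sapply(c("ADG", "ADFI"), function(tr)
        stats::rnorm(length(levels), 0, sds[tr]))
      e <- sweep(matrix(e, ncol = 2L,
                        dimnames = list(levels, c("ADG", "ADFI"))),
                 2, colMeans(matrix(e, ncol = 2L)))
      e
    }
    sireEff <- drawEff(sireLv, sqrt(cfg@sireVariance))
    breedEff <- drawEff(breedLv, cfg@breedSD)
    penEff <- drawEff(penLv, cfg@penSD)

    makeTrait <- function(tr) {
      mu <- ta[tr, "mean"] +
        breedEff[as.character(meta$breed), tr] +
        penEff[as.character(meta$pen), tr] +
        cfg@ageSlope[tr] * (meta$age - cfg@ageMean) +
        drop(cbcDev %*% cfg@cbcEffects[, tr]) +
        sireEff[as.character(meta$sire), tr]
      explained <- cfg@sireVariance[tr] + cfg@breedSD[tr]^2 +
        cfg@penSD[tr]^2 + (cfg@ageSlope[tr] * cfg@ageSD)^2 +
        sum((cfg@cbcEffects[, tr] * ca[cbcParameterNames(), "sd"])^2)
      residVar <- ta[tr, "sd"]^2 - explained
      if (residVar < 0.25 * ta[tr, "sd"]^2) {
        warning("configured effects explain most of the ", tr,
                " variance; residual floored")
        residVar <- 0.25 * ta[tr, "sd"]^2
      }
      mu + stats::rnorm(n, 0, sqrt(residVar))
    }
    ADG <- makeTrait("ADG")
    ADFI <- pmax(makeTrait("ADFI"), 0.5)
    traits <- data.frame(animal_id = meta$animal_id,
                         ADG = ADG, ADFI = ADFI, GF = ADG / ADFI,
                         stringsAsFactors = FALSE)

    # growth curve: population curvature, per-animal linear term
    wa <- cfg@weightAnchors
    qf <- stats::lm(mean ~ day + I(day^2), data = wa)
    cq <- unname(coef(qf)[3])
    span <- max(wa$day) - min(wa$day)
    b <- ADG - cq * span
    w0 <- stats::rnorm(n, wa$mean[which.min(wa$day)], cfg@weightStartSD)
    days <- c(0, 1, 21, 42, 63, 84)
    weights <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(animal_id = meta$animal_id[i], day = days,
                 weight = w0[i] + b[i] * days + cq * days^2 +
                   stats::rnorm(length(days), 0, cfg@weightNoiseSD),
                 stringsAsFactors = FALSE)
    }))
    list(weights = weights, traits = traits, sireEffects = sireEff)
  })
}

#' Simulate an RNA-seq count matrix with known structure
#'
#' Counts are negative binomial around `mu = exp(baseline + log library
#' factor + cell-composition term + trait term)`.  A configured fraction of
#' genes has its log-mean linearly tied to the standardized blood cell-type
#' proportions (confounded genes); planted genes are additionally tied to
#' the design-and-composition-residualized trait with the configured sign,
#' their log-scale effect sized so the post-adjustment partial correlation
#' targets `plantedEffect`.  With dispersion 0 sampling reduces to Poisson.
#' Planted outlier samples receive an independent per-gene log-normal shift
#' that displaces them in PCA space without moving their median-of-ratios
#' size factor.
#'
#' @param meta,cbc,traits aligned outputs of the earlier stages.
#' @param cfg a [SimConfig-class].
#' @return list with `counts` (gene x sample integer matrix), and ground
#'   truth fields: `plantedGenes`, `plantedDirections`, `confoundedGenes`,
#'   `outlierSamples`, `libSizeFactors`.
#' @export
simulateCounts <- function(meta, cbc, traits, cfg) {
  stopifnot(is(cfg, "SimConfig"), cfg@nGenes >= 100L)
  n <- nrow(meta)
  G <- cfg@nGenes
  .withSeed(.childSeed(cfg@seed, 404), {
    geneIds <- sprintf("G%05d", seq_len(G))
    baseLog <- stats::rnorm(G, cfg@baselineLogMean, cfg@baselineLogSD)
    planted <- sort(sample.int(G, cfg@nPlanted))
    if (cfg@nPlanted > 0)
      baseLog[planted] <- stats::rnorm(cfg@nPlanted, cfg@plantedLogMean,
                                       cfg@plantedLogSD)
    dirs <- if (cfg@nPlanted > 0)
      sample(c(-1, 1), cfg@nPlanted, replace = TRUE) else numeric(0)

    libFac <- exp(stats::rnorm(n, 0, cfg@libSizeSD))
    libFac <- libFac / exp(mean(log(libFac)))
    names(libFac) <- meta$animal_id

    # standardized cell-type proportions driving the confounding
    props <- cellProportionCovariates(cbc)
    Zc <- scale(as.matrix(props))
    Zc[, attr(Zc, "scaled:scale") == 0] <- 0

    nConf <- round(cfg@confoundFrac * G)
    confounded <- sort(sample(setdiff(seq_len(G), planted), nConf))
    eta <- matrix(0, G, n)
    if (nConf > 0 && cfg@confoundStrength > 0) {
      W <- matrix(stats::rnorm(nConf * ncol(Zc)), nConf)
      W <- W / sqrt(rowSums(W^2))
      eta[confounded, ] <- cfg@confoundStrength * (W %*% t(Zc))
    }

    if (cfg@nPlanted > 0 && cfg@plantedEffect > 0) {
      # residualize the target trait on the full confounder design (fixed
      # effects incl. sire), standardize, and inject with calibrated size
      y <- traits[[cfg@plantedTrait]]
      # sire dummies absorb breed (sires are nested within breeds)
      D <- stats::model.matrix(~ sire + pen + age, data = meta)
      D <- cbind(D, as.matrix(props))
      tt <- qr.resid(qr(D), y)
      tt <- tt / stats::sd(tt)
      noiseSD <- sqrt(1 / exp(baseLog[planted]) + cfg@nbDispersion)
      delta <- dirs * cfg@plantedEffect / sqrt(1 - cfg@plantedEffect^2) *
        noiseSD
      eta[planted, ] <- eta[planted, , drop = FALSE] +
        outer(delta, tt)
    }

    outlierIdx <- integer(0)
    if (cfg@nOutlierSamples > 0) {
      outlierIdx <- sort(sample.int(n, cfg@nOutlierSamples))
      for (o in outlierIdx)
        eta[, o] <- eta[, o] + stats::rnorm(G, 0, cfg@outlierScale)
    }

    mu <- exp(baseLog + eta +
                matrix(log(libFac), G, n, byrow = TRUE))
    counts <- if (cfg@nbDispersion > 0) {
      matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg@nbDispersion),
             G, n)
    } else {
      matrix(stats::rpois(G * n, lambda = mu), G, n)
    }
    dimnames(counts) <- list(geneIds, meta$animal_id)
    dirsNamed <- dirs
    names(dirsNamed) <- geneIds[planted]
    list(counts = counts,
         plantedGenes = geneIds[planted],
         plantedDirections = dirsNamed,
         confoundedGenes = geneIds[confounded],
         outlierSamples = meta$animal_id[outlierIdx],
         libSizeFactors = libFac)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulateHerd()], [simulateCBC()], [simulateGrowth()] and
#' [simulateCounts()] and assembles the result as a
#' [SummarizedExperiment::SummarizedExperiment] with the count matrix as its
#' assay, the metadata/CBC/trait columns as `colData`, and the
#' [GroundTruth-class] plus the body-weight series and the configuration in
#' `metadata()`.
#'
#' @param cfg a [SimConfig-class].
#' @return a `SummarizedExperiment`.
#' @examples
#' se <- simulateStudy(simConfig(seed = 1, nGenes = 500, nPlanted = 5))
#' dim(se)
#' @export
simulateStudy <- function(cfg = simConfig()) {
  meta <- simulateHerd(cfg)
  cbc <- simulateCBC(meta, cfg)
  gr <- simulateGrowth(meta, cbc, cfg)
  cs <- simulateCounts(meta, cbc, gr$traits, cfg)
  truth <- new("GroundTruth",
               plantedGenes = cs$plantedGenes,
               plantedDirections = cs$plantedDirections,
               confoundedGenes = cs$confoundedGenes,
               sireVariance = cfg@sireVariance,
               cbcEffects = cfg@cbcEffects,
               traits = gr$traits,
               outlierSamples = cs$outlierSamples,
               libSizeFactors = cs$libSizeFactors)
  cd <- S4Vectors::DataFrame(
    merge(merge(meta, cbc, by = "animal_id"), gr$traits, by = "animal_id"),
    row.names = meta$animal_id)
  cd <- cd[colnames(cs$counts), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cs$counts),
    colData = cd,
    metadata = list(groundTruth = truth, weights = gr$weights, config = cfg))
}
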