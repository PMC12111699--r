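#' @import methods
#' @importFrom stats coef fitted residuals
NULL

#' Configuration for the synthetic herd generator
#'
#' A `SimConfig` bundles every knob of the synthetic-data generator: herd
#' structure (animals, breeds, sires, pens), the anchor means/SDs for the
#' feed-efficiency traits and the 15 hematology parameters, the generative
#' parameters of the RNA-seq count model (baseline expression, library-size
#' spread, negative-binomial dispersion, cell-composition confounding,
#' planted trait-associated genes), and the master seed from which all
#' module-level seeds are derived.
#'
#' Trait units: ADG and ADFI in kg/d, G:F in kg gain per kg feed.  CBC units
#' follow the instrument panel (leukocyte counts 10^9/L, RBC 10^12/L, HGB and
#' MCHC g/dL, HCT %, MCV and MPV fL, MCH pg, RDW %, PLT 10^9/L).
#'
#' @slot nAnimals,nBreeds,nSires,nPens integer herd structure.
#' @slot seed integer master seed; fully determines all output.
#' @slot nGenes,nPlanted integer count-matrix dimensions; `nPlanted < nGenes`.
#' @slot plantedEffect target partial correlation magnitude in [0, 1) between
#'   a planted gene's residualized log expression and the residualized trait.
#' @slot plantedTrait which trait the planted genes track ("ADG", "ADFI", "GF").
#' @slot confoundStrength log-scale SD of the cell-composition effect on the
#'   expression of confounded genes.
#' @slot confoundFrac fraction of genes receiving a cell-composition effect.
#' @slot nbDispersion negative-binomial dispersion (variance = mu + disp*mu^2);
#'   0 gives Poisson sampling.
#' @slot libSizeSD log-scale SD of per-sample library-size factors.
#' @slot baselineLogMean,baselineLogSD natural-log mean/SD of baseline gene
#'   expression levels; defaults give roughly 45 percent of genes a mean
#'   count of 10 or more, emulating 15k of 34k genes surviving filtering.
#' @slot plantedLogMean,plantedLogSD baseline log expression for planted genes
#'   (kept well-expressed so the planted correlation is realizable).
#' @slot nOutlierSamples number of samples given an aberrant expression
#'   profile so the PCA ellipse screen has true outliers to find (default 2,
#'   so the default herd of 61 retains 59).
#' @slot outlierScale natural-log SD of the per-gene shift applied to
#'   outlier samples.
#' @slot traitAnchors data.frame (trait, mean, sd) for ADG, ADFI, GF.
#' @slot cbcAnchors data.frame (parameter, mean, sd) for the 15 CBC
#'   parameters.
#' @slot weightAnchors data.frame (day, mean) of the population body-weight
#'   curve; a quadratic fit of these supplies the latent growth curvature.
#' @slot weightStartSD between-animal SD of day-0 body weight (kg).
#' @slot weightNoiseSD weigh-scale measurement noise SD (kg).
#' @slot cbcEffects 15 x 2 matrix (rows = CBC parameters, columns ADG, ADFI)
#'   of linear slopes through which hematology influences the traits.
#' @slot sireVariance named numeric, sire variance components for ADG and
#'   ADFI in squared trait units.
#' @slot breedSD,penSD named numeric (ADG, ADFI): SD of breed and pen fixed
#'   effects drawn once per level.
#' @slot ageSlope named numeric (ADG, ADFI): trait change per day of age
#'   deviation.
#' @slot ageMean,ageSD mean and SD of animal age (days) at the start of the
#'   trial.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    nAnimals = "integer", nBreeds = "integer", nSires = "integer",
    nPens = "integer", seed = "integer",
    nGenes = "integer", nPlanted = "integer",
    plantedEffect = "numeric", plantedTrait = "character",
    confoundStrength = "numeric", confoundFrac = "numeric",
    nbDispersion = "numeric", libSizeSD = "numeric",
    baselineLogMean = "numeric", baselineLogSD = "numeric",
    plantedLogMean = "numeric", plantedLogSD = "numeric",
    nOutlierSamples = "integer", outlierScale = "numeric",
    traitAnchors = "data.frame", cbcAnchors = "data.frame",
    weightAnchors = "data.frame", weightStartSD = "numeric",
    weightNoiseSD = "numeric",
    cbcEffects = "matrix", sireVariance = "numeric",
    breedSD = "numeric", penSD = "numeric", ageSlope = "numeric",
    ageMean = "numeric", ageSD = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be positive")
  if (object@nBreeds < 1L || object@nSires < 1L || object@nPens < 1L)
    msg <- c(msg, "nBreeds, nSires and nPens must be positive")
  if (object@nBreeds > object@nSires)
    msg <- c(msg, "nBreeds > nSires: sires cannot be nested within breeds")
  if (object@nSires > object@nAnimals)
    msg <- c(msg, "nSires must not exceed nAnimals")
  if (object@nPlanted >= object@nGenes)
    msg <- c(msg, "nPlanted must be smaller than nGenes")
  if (object@plantedEffect < 0 || object@plantedEffect >= 1)
    msg <- c(msg, "plantedEffect must lie in [0, 1)")
  if (!object@plantedTrait %in% c("ADG", "ADFI", "GF"))
    msg <- c(msg, "plantedTrait must be one of 'ADG', 'ADFI', 'GF'")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (any(object@traitAnchors$sd < 0) || any(object@cbcAnchors$sd < 0))
    msg <- c(msg, "anchor SDs must be non-negative")
  if (!setequal(object@cbcAnchors$parameter, cbcParameterNames()))
    msg <- c(msg, "cbcAnchors must cover exactly the 15 CBC parameters")
  if (!setequal(object@traitAnchors$trait, c("ADG", "ADFI", "GF")))
    msg <- c(msg, "traitAnchors must cover ADG, ADFI and GF")
  if (nrow(object@weightAnchors) < 3L)
    msg <- c(msg, "weightAnchors needs at least 3 (day, mean) points")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic study
#'
#' Records everything the generator knows that a real study would not:
#' which genes were planted and with which sign, which genes carry
#' cell-composition confounding, the true sire variance components, the true
#' CBC-to-trait slopes, the latent per-animal traits, the true library-size
#' factors, and which samples were made outliers.  Tests score recovery
#' against this object.
#'
#' @slot plantedGenes character gene identifiers with a trait association.
#' @slot plantedDirections named numeric of +1/-1, one per planted gene.
#' @slot confoundedGenes character gene identifiers with cell-composition
#'   effects.
#' @slot sireVariance named numeric (ADG, ADFI), squared trait units.
#' @slot cbcEffects 15 x 2 slope matrix as simulated.
#' @slot traits data.frame of latent per-animal ADG, ADFI, GF.
#' @slot outlierSamples character sample ids planted as expression outliers.
#' @slot libSizeFactors named numeric true library-size factors.
#' @export
setClass("GroundTruth",
  representation(
    plantedGenes = "character", plantedDirections = "numeric",
    confoundedGenes = "character", sireVariance = "numeric",
    cbcEffects = "matrix", traits = "data.frame",
    outlierSamples = "character", libSizeFactors = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (length(object@plantedGenes) != length(object@plantedDirections))
    return("one direction per planted gene required")
  if (length(object@plantedDirections) &&
      !all(object@plantedDirections %in% c(-1, 1)))
    return("plantedDirections must be +1 or -1")
  TRUE
})

#' Fixed- and random-effect design matrices
#'
#' Result of [buildDesign()]: a full-column-rank fixed-effect matrix `X`
#' (intercept, dummy-coded factors, numeric covariates) with aliased columns
#' dropped after a numerical rank check, and a one-hot random-effect
#' indicator matrix `Z` (one column per sire).
#'
#' @slot X numeric matrix, n x p, full column rank.
#' @slot Z numeric 0/1 matrix, n x q, rows summing to one.
#' @slot xNames,zNames column labels of X and Z.
#' @slot rank numerical rank of X (equals ncol(X) after dropping).
#' @slot droppedColumns labels of aliased columns removed from X.
#' @export
setClass("DesignMatrices",
  representation(
    X = "matrix", Z = "matrix", xNames = "character", zNames = "character",
    rank = "integer", droppedColumns = "character"
  )
)

setValidity("DesignMatrices", function(object) {
  if (nrow(object@X) != nrow(object@Z))
    return("X and Z must have the same number of rows")
  if (!all(object@Z %in% c(0, 1)) || !all(rowSums(object@Z) == 1))
    return("Z must be a one-hot indicator matrix")
  if (object@rank != ncol(object@X))
    return("rank must equal ncol(X) after aliased columns are dropped")
  TRUE
})

#' Fitted single-random-effect linear mixed model
#'
#' REML fit of y = X beta + Z u + e with u ~ N(0, sigma2Sire I) and
#' e ~ N(0, sigma2Resid I), estimated by profiling the variance ratio
#' lambda = sigma2Sire / sigma2Resid.  At the lambda = 0 boundary the fit
#' reduces exactly to ordinary least squares.
#'
#' @slot beta named fixed-effect coefficients (trait units per design unit).
#' @slot seBeta their standard errors.
#' @slot u named sire BLUPs (trait units).
#' @slot sigma2Sire,sigma2Resid variance components (trait units squared).
#' @slot lambda fitted variance ratio sigma2Sire / sigma2Resid.
#' @slot fittedMarginal X beta.
#' @slot fittedConditional X beta + Z u.
#' @slot residConditional y - X beta - Z u.
#' @slot remlLoglik restricted log-likelihood at the optimum (includes the
#'   (n - p) log 2 pi constant, so values are comparable with a direct
#'   evaluation of the REML density).
#' @slot converged FALSE when the golden-section refinement hit its
#'   iteration cap; the best grid point is returned in that case.
#' @slot design the [DesignMatrices-class] used.
#' @export
setClass("LMMFit",
  representation(
    beta = "numeric", seBeta = "numeric", u = "numeric",
    sigma2Sire = "numeric", sigma2Resid = "numeric", lambda = "numeric",
    fittedMarginal = "numeric", fittedConditional = "numeric",
    residConditional = "numeric", remlLoglik = "numeric",
    converged = "logical", design = "DesignMatrices"
  )
)

setValidity("LMMFit", function(object) {
  if (object@sigma2Sire < 0) return("sigma2Sire must be >= 0")
  if (object@sigma2Resid <= 0) return("sigma2Resid must be > 0")
  TRUE
})

#' Preprocessed count matrix
#'
#' Output of [prepCounts()]: the genes retained by the low-expression
#' filter, median-of-ratios size factors, the log2 normalized matrix, PCA
#' scores and explained variance of the retained high-variance genes, and
#' the sample partition induced by the confidence-ellipse outlier screen.
#'
#' @slot keptGenes gene identifiers surviving the low-expression filter.
#' @slot removedByMean,removedByZero per-criterion removal counts (a gene
#'   failing both is counted in both).
#' @slot sizeFactors named per-sample median-of-ratios factors.
#' @slot logNorm log2(count / factor + 1) matrix, kept genes x all samples.
#' @slot pcScores sample x component score matrix.
#' @slot pcVarExp fraction of variance per component.
#' @slot outliers,retained disjoint sample-id partition from the ellipse
#'   screen.
#' @export
setClass("CountsPrep",
  representation(
    keptGenes = "character", removedByMean = "integer",
    removedByZero = "integer", sizeFactors = "numeric", logNorm = "matrix",
    pcScores = "matrix", pcVarExp = "numeric",
    outliers = "character", retained = "character"
  )
)

setValidity("CountsPrep", function(object) {
  if (length(intersect(object@outliers, object@retained)))
    return("outliers and retained must be disjoint")
  if (any(object@sizeFactors <= 0)) return("size factors must be positive")
  TRUE
})

#' Expression and trait residualized on the shared confounder design
#'
#' Both the trait and every gene's log-normalized expression are adjusted
#' with the same mixed model (breed + pen fixed, sire random, age and blood
#' cell-type proportions as covariates); conditional residuals
#' (y - X beta - Z u) are stored.
#'
#' @slot residExpr gene x sample conditional-residual matrix.
#' @slot residTrait per-sample conditional residual of the trait.
#' @slot covariateSet labels of the confounders adjusted for.
#' @slot nCovariates number of non-intercept fixed-design columns absorbed
#'   by the residualization; [correlateResiduals()] charges these against
#'   the correlation degrees of freedom.
#' @slot lambda per-gene fitted variance ratio (diagnostic).
#' @export
setClass("AdjustedData",
  representation(
    residExpr = "matrix", residTrait = "numeric",
    covariateSet = "character", nCovariates = "numeric",
    lambda = "numeric"
  ),
  prototype(nCovariates = 0)
)

# ---- accessors & show methods ------------------------------------------

#' @describeIn GroundTruth-class planted gene identifiers
#' @param x a `GroundTruth`
#' @export
plantedGenes <- function(x) x@plantedGenes

#' @describeIn GroundTruth-class named vector of planted directions (+1/-1)
#' @export
plantedDirections <- function(x) x@plantedDirections

#' @describeIn GroundTruth-class latent per-animal trait table
#' @export
trueTraits <- function(x) x@traits

#' @describeIn CountsPrep-class sample ids kept after the ellipse screen
#' @param x a `CountsPrep`
#' @export
retainedSamples <- function(x) x@retained

#' @describeIn CountsPrep-class sample ids flagged outside the ellipse
#' @export
outlierSamples <- function(x) x@outliers

#' @describeIn CountsPrep-class log2 normalized expression matrix
#' @export
logNorm <- function(x) x@logNorm

#' @describeIn CountsPrep-class median-of-ratios size factors
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "CountsPrep",
          function(object) object@sizeFactors)

#' @describeIn LMMFit-class fixed-effect coefficients
#' @param object an `LMMFit`
#' @export
setMethod("coef", "LMMFit", function(object) object@beta)

#' @describeIn LMMFit-class conditional residuals y - X beta - Z u
#' @export
setMethod("residuals", "LMMFit", function(object) object@residConditional)

#' @describeIn LMMFit-class conditional fitted values X beta + Z u
#' @export
setMethod("fitted", "LMMFit", function(object) object@fittedConditional)

#' @describeIn LMMFit-class sire BLUPs
#' @export
sireBLUPs <- function(object) object@u

#' @describeIn LMMFit-class variance components as a named vector
#' @export
varianceComponents <- function(object)
  c(sire = object@sigma2Sire, residual = object@sigma2Resid)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nAnimals, "animals,", object@nBreeds, "breeds,",
      object@nSires, "sires,", object@nPens, "pens; seed", object@seed, "\n")
  cat("  genes:", object@nGenes, "(", object@nPlanted, "planted on",
      object@plantedTrait, "at |r| =", object@plantedEffect, ")\n")
  cat("  confounding:", round(100 * object@confoundFrac), "% of genes at",
      "strength", object@confoundStrength, "; NB dispersion",
      object@nbDispersion, "\n")
})

setMethod("show", "LMMFit", function(object) {
  cat("LMMFit:", length(object@beta), "fixed coefficients,",
      length(object@u), "sire BLUPs\n")
  cat(sprintf("  sigma2_sire = %.6g, sigma2_resid = %.6g (lambda = %.4g)\n",
              object@sigma2Sire, object@sigma2Resid, object@lambda))
  cat(sprintf("  REML loglik = %.4f, converged = %s\n",
              object@remlLoglik, object@converged))
  print(round(rbind(estimate = object@beta, se = object@seBeta), 5))
})

setMethod("show", "CountsPrep", function(object) {
  nS <- length(object@sizeFactors)
  cat("CountsPrep:", length(object@keptGenes), "genes kept,",
      nS, "samples\n")
  cat("  removed by mean filter:", object@removedByMean,
      "; by zero-fraction filter:", object@removedByZero, "\n")
  cat("  PC1/PC2 variance explained:",
      paste(sprintf("%.1f%%", 100 * object@pcVarExp[1:2]), collapse = " / "),
      "\n")
  cat("  outliers (", length(object@outliers), "):",
      paste(object@outliers, collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@plantedGenes), "planted genes,",
      length(object@confoundedGenes), "confounded genes,",
      length(object@outlierSamples), "planted outlier samples\n")
})

#' Canonical CBC parameter names in instrument-panel order
#'
#' @return character vector of the 15 parameter names, in the order used
#'   throughout reporting (leukocyte series, erythrocyte series, platelets).
#' @export
cbcParameterNames <- function() {
  c("WBC", "NEU", "LYM", "MONO", "EOS", "BAS", "RBC", "HGB", "HCT",
    "MCV", "MCH", "MCHC", "RDW", "PLT", "MPV")
}
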