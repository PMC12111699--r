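# Continuous-trait differential expression: residualize expression and
# trait on the shared confounder design (herd factors + blood cell-type
# proportions) with the mixed-model engine, correlate gene-by-gene, adjust
# with Benjamini-Hochberg, and flag FDR < 0.1.

#' Blood cell-type proportion covariates
#'
#' The five leukocyte differential counts are converted to fractions of the
#' white-cell total (NEU, LYM, MONO, EOS, BAS each divided by WBC); the red
#' blood cell count enters as its absolute concentration (10^12/L), since a
#' proportion of WBC is meaningless for erythrocytes.
#'
#' @param cbc CBC panel data.frame; WBC must be positive for every animal.
#' @return data.frame with six numeric columns NEU, LYM, MONO, EOS, BAS
#'   (fractions) and RBC (absolute count).
#' @export
cellProportionCovariates <- function(cbc) {
  need <- c("WBC", "NEU", "LYM", "MONO", "EOS", "BAS", "RBC")
  if (!all(need %in% names(cbc)))
    stop("CBC panel is missing: ",
         paste(setdiff(need, names(cbc)), collapse = ", "))
  if (any(cbc$WBC <= 0)) stop("WBC must be positive for every animal")
  data.frame(NEU = cbc$NEU / cbc$WBC, LYM = cbc$LYM / cbc$WBC,
             MONO = cbc$MONO / cbc$WBC, EOS = cbc$EOS / cbc$WBC,
             BAS = cbc$BAS / cbc$WBC, RBC = cbc$RBC)
}

#' Residualize expression and trait on the confounder design
#'
#' Fits the same mixed model (breed and pen fixed, sire random, age and the
#' six cell-type covariates) to the trait and, independently, to every
#' gene's log-normalized expression, and stores the conditional residuals
#' y - X beta - Z u as the adjusted values.  Because the intercept is in X
#' and conditional residuals satisfy X' V0^-1-weighted orthogonality
#' exactly, every residual vector has mean zero to numerical precision.
#'
#' @param exprLognorm gene x sample matrix of log-normalized expression
#'   (retained samples only, after outlier removal).
#' @param trait numeric trait vector aligned with the columns.
#' @param meta herd metadata aligned with the columns.
#' @param cellProps output of [cellProportionCovariates()], same alignment.
#' @return an [AdjustedData-class].
#' @export
adjustForConfounders <- function(exprLognorm, trait, meta, cellProps) {
  stopifnot(ncol(exprLognorm) == nrow(meta),
            length(trait) == nrow(meta),
            nrow(cellProps) == nrow(meta))
  covs <- cbind(data.frame(age = meta$age), cellProps)
  d <- buildDesign(meta, covariates = covs)
  traitFit <- fitREML(trait, d)
  batch <- .fitREMLBatch(t(exprLognorm), d)
  new("AdjustedData",
      residExpr = t(batch$residConditional),
      residTrait = unname(traitFit@residConditional),
      covariateSet = c(d@xNames, "sire"),
      nCovariates = d@rank - 1,
      lambda = batch$lambda)
}

#' Gene-wise correlation of adjusted expression with the adjusted trait
#'
#' Pearson correlation per gene between the expression residuals and the
#' trait residuals, with a two-sided p-value from t = r sqrt(df / (1 -
#' r^2)).  Correlating residuals is a partial correlation: after k
#' non-intercept design columns are absorbed, both residual vectors are
#' confined to an (n - k - 1)-dimensional subspace and the null
#' distribution of r is that of an ordinary correlation on n - k samples.
#' The default `dfMethod = "adjusted"` therefore uses df = n - 2 - k
#' (k taken from the [AdjustedData-class]), which keeps the test calibrated
#' and the downstream FDR controlled; `"classic"` uses the uncorrected
#' df = n - 2 of a plain correlation, the convention matched by the
#' genome-scale worked examples where no covariates are absorbed.  Genes
#' with zero residual variance get r = NA, p = 1 and a degenerate flag.
#'
#' @param adj an [AdjustedData-class].
#' @param dfMethod `"adjusted"` (default) or `"classic"`, see above.
#' @return data.frame with columns `gene_id`, `reg` (the correlation), `p`,
#'   `df`, `degenerate`.
#' @export
correlateResiduals <- function(adj, dfMethod = c("adjusted", "classic")) {
  stopifnot(is(adj, "AdjustedData"))
  dfMethod <- match.arg(dfMethod)
  n <- length(adj@residTrait)
  if (n < 4L) stop("need at least 4 retained samples")
  df <- if (dfMethod == "adjusted") n - 2 - adj@nCovariates else n - 2
  if (df < 1) stop("non-positive correlation degrees of freedom")
  tv <- adj@residTrait
  tSd <- stats::sd(tv)
  gSd <- apply(adj@residExpr, 1, stats::sd)
  degenerate <- gSd == 0 | tSd == 0
  r <- rep(NA_real_, nrow(adj@residExpr))
  ok <- !degenerate
  if (any(ok)) {
    tc <- tv - mean(tv)
    E <- adj@residExpr[ok, , drop = FALSE]
    Ec <- E - rowMeans(E)
    r[ok] <- drop(Ec %*% tc) / (sqrt(rowSums(Ec^2)) * sqrt(sum(tc^2)))
  }
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[degenerate] <- 1
  data.frame(gene_id = rownames(adj@residExpr), reg = r, p = p, df = df,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, adj_(i) =
#' min(1, min_{j >= i} mTotal * p_(j) / j), mapped back to input order.
#' `mTotal` may exceed the number of supplied p-values, which adjusts a
#' printed subset against the full number of tests performed.
#'
#' @param p numeric p-values in [0, 1].
#' @param mTotal total number of tests (>= length(p)).
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(1.78e-6, 7.85e-6), mTotal = 15315)
#' @export
bhAdjust <- function(p, mTotal = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (mTotal < length(p))
    stop("mTotal must be at least length(p)")
  stats::p.adjust(p, method = "BH", n = mTotal)
}

#' Continuous-trait differential expression
#'
#' End-to-end: restrict to the retained samples from preprocessing, adjust
#' expression and trait for confounders ([adjustForConfounders()]),
#' correlate gene-by-gene ([correlateResiduals()]), adjust for false
#' discovery ([bhAdjust()] with mTotal = number of genes tested), and flag
#' genes with FDR-adjusted p below `fdr`.
#'
#' @param prep a [CountsPrep-class].
#' @param trait named numeric trait vector (names = sample/animal ids).
#' @param meta herd metadata.
#' @param cbc CBC panel.
#' @param fdr significance threshold on the adjusted p-value (default 0.1).
#' @param mTotal override for the BH test count (defaults to genes tested).
#' @param dfMethod correlation df convention, see [correlateResiduals()].
#' @return data.frame sorted by adjusted then nominal p: `gene_id`, `reg`,
#'   `p_nominal`, `p_fdr`, `significant`.
#' @examples
#' se <- simulateStudy(simConfig(seed = 1, nGenes = 600, nPlanted = 5))
#' prep <- prepCounts(se)
#' de <- runDE(prep, trait = "GF", meta = se, cbc = se)
#' head(de)
#' @export
runDE <- function(prep, trait, meta, cbc, fdr = 0.1, mTotal = NULL,
                  dfMethod = c("adjusted", "classic")) {
  stopifnot(is(prep, "CountsPrep"))
  if (is(meta, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(meta))
    if (is.character(trait) && length(trait) == 1L)
      trait <- stats::setNames(cd[[trait]], cd$animal_id)
    if (is(cbc, "SummarizedExperiment"))
      cbc <- cd[, c("animal_id", cbcParameterNames())]
    meta <- cd[, c("animal_id", "breed", "pen", "sire", "age")]
  }
  keep <- prep@retained
  ex <- prep@logNorm[, keep, drop = FALSE]
  meta <- meta[match(keep, meta$animal_id), ]
  cbc <- cbc[match(keep, cbc$animal_id), ]
  y <- trait[keep]
  if (anyNA(y)) stop("trait values missing for some retained samples")
  meta$breed <- droplevels(factor(meta$breed))
  meta$pen <- droplevels(factor(meta$pen))
  meta$sire <- droplevels(factor(meta$sire))
  adj <- adjustForConfounders(ex, y, meta, cellProportionCovariates(cbc))
  cr <- correlateResiduals(adj, dfMethod = dfMethod)
  if (is.null(mTotal)) mTotal <- nrow(cr)
  res <- data.frame(gene_id = cr$gene_id, reg = cr$reg,
                    p_nominal = cr$p,
                    p_fdr = bhAdjust(cr$p, mTotal = mTotal),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_fdr < fdr
  res[order(res$p_fdr, res$p_nominal, res$gene_id), , drop = FALSE]
}
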