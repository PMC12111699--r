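# Count-matrix preprocessing: low-expression filter, median-of-ratios
# normalization, log transform, variance filter + PCA, and the
# confidence-ellipse sample outlier screen.

#' Low-expression gene filter
#'
#' A gene is removed if its mean count across samples is below `meanThresh`
#' or (default logic) the fraction of samples with a zero count exceeds
#' `zeroFrac`.  The removal rule can be switched to requiring both criteria
#' (`logic = "and"`); per-criterion removal counts are returned as
#' attributes either way so the variants are auditable.
#'
#' @param counts gene x sample non-negative count matrix.
#' @param meanThresh mean-count threshold (default 10).
#' @param zeroFrac zero-count sample-fraction threshold (default 0.8).
#' @param logic `"or"` removes a gene failing either criterion; `"and"`
#'   requires both.
#' @return logical keep-mask of length nrow(counts), with attributes
#'   `removedByMean` and `removedByZero`.
#' @examples
#' m <- rbind(a = c(120, rep(0, 9)), b = rep(10, 10))
#' filterLowExpression(m)  # a removed (zero fraction 0.9), b kept
#' @export
filterLowExpression <- function(counts, meanThresh = 10, zeroFrac = 0.8,
                                logic = c("or", "and")) {
  logic <- match.arg(logic)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lowMean <- rowMeans(counts) < meanThresh
  manyZero <- rowMeans(counts == 0) > zeroFrac
  removed <- if (logic == "or") lowMean | manyZero else lowMean & manyZero
  keep <- !removed
  attr(keep, "removedByMean") <- sum(lowMean)
  attr(keep, "removedByZero") <- sum(manyZero)
  keep
}

#' Median-of-ratios size factors
#'
#' The reference pseudo-sample is the gene-wise geometric mean over samples,
#' computed on the genes with a nonzero count in every sample; each sample's
#' factor is the median over those genes of count / reference.  Factors are
#' not rescaled afterwards.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
morSizeFactors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (!any(pos))
    stop("no gene has nonzero counts in every sample; ",
         "apply filterLowExpression first")
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(cs) stats::median(cs / ref))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Log2 normalization
#'
#' value = log2(count / sizeFactor + 1); a zero count maps to exactly 0 and
#' the transform is invariant to jointly scaling a sample's counts and its
#' factor.
#'
#' @param counts gene x sample count matrix.
#' @param sf per-sample positive size factors.
#' @return matrix of the same shape.
#' @export
logNormalize <- function(counts, sf) {
  if (any(sf <= 0)) stop("size factors must be positive")
  if (length(sf) != ncol(counts))
    stop("one size factor per sample required")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' PCA of samples after a gene variance filter
#'
#' Drops the `dropFrac` lowest-variance genes, centers each remaining gene,
#' and computes sample principal-component scores by singular value
#' decomposition.  Components are ordered by decreasing explained variance;
#' the sign of each component is fixed so that its largest-magnitude gene
#' loading is positive.
#'
#' @param lognorm gene x sample matrix of log-normalized values.
#' @param dropFrac fraction of genes dropped from the bottom of the
#'   variance ranking (default 0.10).
#' @param nComponents number of components to return.
#' @return list with `scores` (sample x component, rownames = sample ids)
#'   and `varexp` (fraction of variance per returned component).
#' @export
pcaVarianceFilter <- function(lognorm, dropFrac = 0.10, nComponents = 2) {
  v <- apply(lognorm, 1, stats::var)
  nDrop <- floor(dropFrac * nrow(lognorm))
  keep <- rank(v, ties.method = "first") > nDrop
  if (sum(keep) < 10L) stop("fewer than 10 genes left after variance filter")
  M <- lognorm[keep, , drop = FALSE]
  if (all(apply(M, 1, stats::var) == 0))
    stop("matrix is constant; PCA undefined")
  Mc <- M - rowMeans(M)
  sv <- svd(t(Mc))            # samples x genes
  k <- min(nComponents, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(colnames(lognorm), paste0("PC", seq_len(k)))
  list(scores = scores, varexp = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Confidence-ellipse outlier screen in PC space
#'
#' Flags samples whose squared Mahalanobis distance of (PC1, PC2) from the
#' sample mean, under the sample covariance, exceeds the chi-squared
#' (2 df) quantile at `level`.  Under bivariate normality the flagged
#' fraction converges to 1 - level.
#'
#' @param pcScores sample x 2 score matrix with sample ids as rownames.
#' @param level confidence level of the ellipse (default 0.985).
#' @return sorted character vector of outlying sample ids.
#' @export
ellipseOutliers <- function(pcScores, level = 0.985) {
  if (nrow(pcScores) < 10L) stop("need at least 10 samples")
  if (ncol(pcScores) != 2L) stop("exactly 2 components required")
  S <- stats::cov(pcScores)
  if (!is.finite(determinant(S)$modulus) ||
      rcond(S) < .Machine$double.eps * 100)
    stop("degenerate score covariance; ellipse undefined")
  d2 <- stats::mahalanobis(pcScores, colMeans(pcScores), S)
  sort(rownames(pcScores)[d2 > stats::qchisq(level, df = 2)])
}

#' Full count preprocessing
#'
#' Chains the low-expression filter, median-of-ratios normalization, log2
#' transform, variance-filtered PCA and the confidence-ellipse outlier
#' screen into a [CountsPrep-class].
#'
#' @param counts gene x sample count matrix with dimnames, or a
#'   `SummarizedExperiment` carrying a `counts` assay.
#' @param meanThresh,zeroFrac,filterLogic passed to [filterLowExpression()].
#' @param dropFrac passed to [pcaVarianceFilter()].
#' @param ellipseLevel passed to [ellipseOutliers()].
#' @return a [CountsPrep-class].
#' @examples
#' se <- simulateStudy(simConfig(seed = 1, nGenes = 800, nPlanted = 5))
#' prep <- prepCounts(se)
#' prep
#' @export
prepCounts <- function(counts, meanThresh = 10, zeroFrac = 0.8,
                       filterLogic = "or", dropFrac = 0.10,
                       ellipseLevel = 0.985) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample identifiers")
  keep <- filterLowExpression(counts, meanThresh, zeroFrac, filterLogic)
  kept <- counts[keep, , drop = FALSE]
  sf <- morSizeFactors(kept)
  ln <- logNormalize(kept, sf)
  pca <- pcaVarianceFilter(ln, dropFrac = dropFrac)
  out <- ellipseOutliers(pca$scores, level = ellipseLevel)
  new("CountsPrep",
      keptGenes = rownames(kept),
      removedByMean = as.integer(attr(keep, "removedByMean")),
      removedByZero = as.integer(attr(keep, "removedByZero")),
      sizeFactors = sf, logNorm = ln,
      pcScores = pca$scores, pcVarExp = pca$varexp,
      outliers = out,
      retained = sort(setdiff(colnames(counts), out)))
}
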