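# Single-random-effect linear mixed model engine.
#
# Model: y = X beta + Z u + e,  u ~ N(0, sigma2_s I_q),  e ~ N(0, sigma2_e I_n)
# with Z a one-hot grouping indicator (one column per sire).  The marginal
# covariance is V = sigma2_e (I + lambda Z Z'), lambda = sigma2_s / sigma2_e.
# Because Z'Z = diag(group sizes m), Woodbury gives
#   V0^-1      = I - Z diag(lambda / (1 + lambda m)) Z'
#   log|V0|    = sum_j log(1 + lambda m_j)
# so the whole REML profile needs only the summary statistics X'X, X'y,
# Z'X, Z'y, y'y and m -- O(q p^2) per lambda evaluation regardless of n.
# sigma2_e is profiled out analytically; lambda is maximized on a log grid
# (61 points over 1e-6..1e3, plus the exact lambda = 0 boundary, where the
# fit reduces to ordinary least squares) followed by golden-section
# refinement.

#' Build fixed- and random-effect design matrices
#'
#' Constructs `X` as intercept + reference-level dummy coding of the fixed
#' factors (first level lexicographically is the reference) + the supplied
#' numeric covariates, then checks its numerical rank by singular value
#' decomposition and drops aliased columns (recorded, never silently lost)
#' so the returned `X` has full column rank.  `Z` is the one-hot indicator
#' of the random grouping factor.
#'
#' @param meta sample metadata with the factor columns and unique
#'   `animal_id`; no missing values allowed.
#' @param covariates data.frame (or NULL) of numeric covariates, same row
#'   order as `meta`.  All-constant covariates are dropped with a warning.
#' @param fixedFactors names of the fixed-effect factor columns.
#' @param randomFactor name of the grouping factor for the random effect.
#' @return a [DesignMatrices-class].
#' @examples
#' meta <- simulateHerd(simConfig(seed = 1))
#' d <- buildDesign(meta, covariates = data.frame(age = meta$age))
#' ncol(d@X)  # 1 + 2 breed + 3 pen + 1 age = 7
#' @export
buildDesign <- function(meta, covariates = NULL,
                        fixedFactors = c("breed", "pen"),
                        randomFactor = "sire") {
  if (anyNA(meta[c(fixedFactors, randomFactor)]))
    stop("metadata contains missing values")
  cols <- list(`(Intercept)` = rep(1, nrow(meta)))
  for (f in fixedFactors) {
    v <- droplevels(factor(meta[[f]]))
    if (nlevels(v) < 2L)
      stop("factor '", f, "' has fewer than 2 levels after subsetting")
    for (lv in levels(v)[-1L]) cols[[paste0(f, lv)]] <- as.numeric(v == lv)
  }
  if (!is.null(covariates)) {
    if (anyNA(covariates)) stop("covariates contain missing values")
    for (nm in names(covariates)) {
      x <- as.numeric(covariates[[nm]])
      if (stats::sd(x) == 0) {
        warning("covariate '", nm, "' is constant and was dropped")
        next
      }
      cols[[nm]] <- x
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  # SVD rank check on column-scaled X; drop aliased columns via pivoted QR
  sc <- apply(X, 2, function(c) max(abs(c)))
  sv <- svd(sweep(X, 2, sc, "/"), nu = 0, nv = 0)$d
  rank <- sum(sv > max(dim(X)) * .Machine$double.eps * sv[1])
  dropped <- character(0)
  if (rank < ncol(X)) {
    qrX <- qr(X)
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
    rank <- ncol(X)
  }

  g <- droplevels(factor(meta[[randomFactor]]))
  if (nlevels(g) < 2L)
    stop("random factor '", randomFactor, "' has fewer than 2 levels")
  Z <- matrix(0, nrow(meta), nlevels(g),
              dimnames = list(NULL, levels(g)))
  Z[cbind(seq_len(nrow(meta)), as.integer(g))] <- 1
  new("DesignMatrices", X = X, Z = Z, xNames = colnames(X),
      zNames = colnames(Z), rank = as.integer(rank),
      droppedColumns = dropped)
}

# summary statistics shared by every lambda evaluation
.remlSums <- function(y, d) {
  list(n = length(y), p = ncol(d@X), q = ncol(d@Z),
       XtX = crossprod(d@X), Xty = drop(crossprod(d@X, y)),
       ZtX = crossprod(d@Z, d@X), Zty = drop(crossprod(d@Z, y)),
       yty = sum(y^2), m = colSums(d@Z))
}

# profiled REML criterion at one lambda; returns -2 loglik and GLS pieces
.remlEval <- function(lambda, S) {
  cvec <- lambda / (1 + lambda * S$m)
  cZtX <- cvec * S$ZtX
  A <- S$XtX - crossprod(S$ZtX, cZtX)
  b <- S$Xty - drop(crossprod(cZtX, S$Zty))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(neg2 = Inf))
  beta <- backsolve(R, forwardsolve(t(R), b))
  yVy <- S$yty - sum(cvec * S$Zty^2)
  rss <- yVy - sum(b * beta)
  rss <- max(rss, .Machine$double.eps * S$yty)
  np <- S$n - S$p
  s2e <- rss / np
  neg2 <- np * (log(2 * pi) + 1) + np * log(s2e) +
    sum(log1p(lambda * S$m)) + 2 * sum(log(diag(R)))
  list(neg2 = neg2, beta = beta, s2e = s2e, R = R)
}

#' Fit the mixed model by REML
#'
#' Maximizes the restricted likelihood of the single-random-effect model by
#' profiling the variance ratio lambda = sigma2_sire / sigma2_resid over
#' [0, Inf): the exact lambda = 0 boundary (ordinary least squares) plus a
#' 61-point log grid over 1e-6..1e3, refined by golden section to an
#' absolute tolerance of 1e-8 on lambda.  beta is the GLS solution at the
#' optimum and the sire BLUPs are u = lambda (I + lambda Z'Z)^-1 Z'(y - X
#' beta).
#'
#' @param y numeric response, finite, `length(y) >= ncol(X) + 2`.
#' @param d a [DesignMatrices-class] from [buildDesign()].
#' @param tol absolute convergence tolerance on lambda.
#' @return an [LMMFit-class].
#' @examples
#' meta <- simulateHerd(simConfig(seed = 1))
#' d <- buildDesign(meta, covariates = data.frame(age = meta$age))
#' y <- rnorm(nrow(meta))
#' fit <- fitREML(y, d)
#' varianceComponents(fit)
#' @export
fitREML <- function(y, d, tol = 1e-8) {
  stopifnot(is(d, "DesignMatrices"))
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (length(y) != nrow(d@X)) stop("length(y) must match nrow(X)")
  if (length(y) < ncol(d@X) + 2L)
    stop("need at least ncol(X) + 2 observations")
  S <- .remlSums(y, d)

  grid <- c(0, 10^seq(-6, 3, length.out = 61))
  neg2 <- vapply(grid, function(l) .remlEval(l, S)$neg2, numeric(1))
  best <- which.min(neg2)
  lambda <- grid[best]
  converged <- TRUE

  if (best > 1L) {
    # golden-section refinement on log10(lambda) between grid neighbours
    lo <- if (best == 2L) log10(grid[2]) - 1 else log10(grid[best - 1L])
    hi <- if (best == length(grid)) log10(grid[best])
          else log10(grid[best + 1L])
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- .remlEval(10^x1, S)$neg2; f2 <- .remlEval(10^x2, S)$neg2
    iter <- 0L
    while (10^hi - 10^lo > tol) {
      if (iter >= 200L) { converged <- FALSE; break }
      if (f1 <= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- .remlEval(10^x1, S)$neg2
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- .remlEval(10^x2, S)$neg2
      }
      iter <- iter + 1L
    }
    cand <- 10^((lo + hi) / 2)
    if (.remlEval(cand, S)$neg2 <= neg2[best]) lambda <- cand
    # boundary check: OLS may still win after refinement
    if (neg2[1] <= .remlEval(lambda, S)$neg2) lambda <- 0
  }

  .lmmFitFromLambda(y, d, S, lambda, converged)
}

# assemble the LMMFit object at a given lambda
.lmmFitFromLambda <- function(y, d, S, lambda, converged) {
  ev <- .remlEval(lambda, S)
  beta <- drop(ev$beta)
  names(beta) <- d@xNames
  covU <- chol2inv(ev$R) * ev$s2e
  se <- sqrt(diag(covU))
  names(se) <- d@xNames
  residM <- y - drop(d@X %*% beta)
  u <- lambda / (1 + lambda * S$m) * drop(crossprod(d@Z, residM))
  names(u) <- d@zNames
  fittedC <- drop(d@X %*% beta) + drop(d@Z %*% u)
  new("LMMFit", beta = beta, seBeta = se, u = u,
      sigma2Sire = lambda * ev$s2e, sigma2Resid = ev$s2e, lambda = lambda,
      fittedMarginal = drop(d@X %*% beta),
      fittedConditional = fittedC,
      residConditional = y - fittedC,
      remlLoglik = -0.5 * ev$neg2, converged = converged, design = d)
}

#' Wald test for a fixed-effect coefficient
#'
#' Two-sided p-value from t = beta / SE with denominator degrees of freedom
#' n - rank(X).  This is a deliberate, documented approximation (no
#' Satterthwaite correction); at the lambda = 0 boundary it reduces exactly
#' to the ordinary least-squares t-test.
#'
#' @param fit an [LMMFit-class].
#' @param coefName name of a retained X column.
#' @return p-value in (0, 1].
#' @export
waldP <- function(fit, coefName) {
  stopifnot(is(fit, "LMMFit"))
  if (coefName %in% fit@design@droppedColumns)
    stop("coefficient '", coefName,
         "' was dropped as aliased with other design columns")
  if (!coefName %in% names(fit@beta))
    stop("unknown coefficient '", coefName, "'")
  df <- length(fit@residConditional) - fit@design@rank
  tstat <- fit@beta[coefName] / fit@seBeta[coefName]
  unname(2 * stats::pt(-abs(tstat), df))
}

#' Model R-squared of a mixed-model fit
#'
#' Conditional R2 (the default) is the squared Pearson correlation between
#' the observations and the conditional fitted values X beta + Z u, i.e. it
#' credits the sire BLUPs; marginal R2 uses X beta only.  Both are exposed
#' because R2 has no unique definition for mixed models.
#'
#' @param fit an [LMMFit-class].
#' @param y the response the model was fitted to.
#' @param type `"conditional"` or `"marginal"`.
#' @return R-squared in [0, 1].
#' @export
modelR2 <- function(fit, y, type = c("conditional", "marginal")) {
  type <- match.arg(type)
  if (stats::sd(y) == 0) stop("R2 undefined: y has zero variance")
  f <- if (type == "conditional") fit@fittedConditional else fit@fittedMarginal
  if (stats::sd(f) == 0) return(0)
  stats::cor(y, f)^2
}

#' One-line text summary of a mixed-model fit
#'
#' @param fit an [LMMFit-class].
#' @param y the response (for R2).
#' @return invisibly, the printed character vector.
#' @export
lmmSummary <- function(fit, y) {
  lines <- c(
    sprintf("sigma2_sire=%.6g sigma2_resid=%.6g lambda=%.4g loglik=%.4f",
            fit@sigma2Sire, fit@sigma2Resid, fit@lambda, fit@remlLoglik),
    sprintf("R2_conditional=%.4f R2_marginal=%.4f",
            modelR2(fit, y), modelR2(fit, y, "marginal")),
    paste(sprintf("%s=%.5g(%.3g)", names(fit@beta), fit@beta, fit@seBeta),
          collapse = " "))
  writeLines(lines)
  invisible(lines)
}

# ---- batch REML over many responses sharing one design ------------------
#
# Used by the differential-expression adjustment, where thousands of genes
# are fitted against the same X and Z.  The lambda grid is evaluated for
# all responses at once with dense linear algebra; genes whose optimum sits
# at the lambda = 0 boundary are finished vectorized as OLS, the rest are
# refined gene-by-gene by the same golden-section rule as fitREML.
.fitREMLBatch <- function(Y, d, tol = 1e-8) {
  n <- nrow(Y); G <- ncol(Y); p <- ncol(d@X)
  XtX <- crossprod(d@X); ZtX <- crossprod(d@Z, d@X)
  XtY <- crossprod(d@X, Y); ZtY <- crossprod(d@Z, Y)
  yty <- colSums(Y^2); m <- colSums(d@Z)
  np <- n - p
  grid <- c(0, 10^seq(-6, 3, length.out = 61))
  neg2 <- matrix(NA_real_, length(grid), G)
  for (k in seq_along(grid)) {
    lambda <- grid[k]
    cvec <- lambda / (1 + lambda * m)
    A <- XtX - crossprod(ZtX, cvec * ZtX)
    R <- chol(A)
    B <- XtY - crossprod(cvec * ZtX, ZtY)
    beta <- backsolve(R, forwardsolve(t(R), B))
    yVy <- yty - colSums((cvec * ZtY) * ZtY)
    rss <- pmax(yVy - colSums(B * beta), .Machine$double.eps * yty)
    neg2[k, ] <- np * (log(2 * pi) + 1) + np * log(rss / np) +
      sum(log1p(lambda * m)) + 2 * sum(log(diag(R)))
  }
  best <- max.col(-t(neg2), ties.method = "first")

  lambdas <- numeric(G)
  resid <- matrix(NA_real_, n, G, dimnames = dimnames(Y))

  atBoundary <- best == 1L
  if (any(atBoundary)) {
    A0 <- XtX
    beta0 <- solve(A0, XtY[, atBoundary, drop = FALSE])
    resid[, atBoundary] <- Y[, atBoundary, drop = FALSE] - d@X %*% beta0
  }
  for (g in which(!atBoundary)) {
    S <- list(n = n, p = p, XtX = XtX, Xty = XtY[, g], ZtX = ZtX,
              Zty = ZtY[, g], yty = yty[g], m = m)
    b <- best[g]
    lo <- if (b == 2L) log10(grid[2]) - 1 else log10(grid[b - 1L])
    hi <- if (b == length(grid)) log10(grid[b]) else log10(grid[b + 1L])
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- .remlEval(10^x1, S)$neg2; f2 <- .remlEval(10^x2, S)$neg2
    iter <- 0L
    while (10^hi - 10^lo > tol && iter < 200L) {
      if (f1 <= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- .remlEval(10^x1, S)$neg2
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- .remlEval(10^x2, S)$neg2
      }
      iter <- iter + 1L
    }
    lambda <- 10^((lo + hi) / 2)
    if (.remlEval(lambda, S)$neg2 > neg2[b, g]) lambda <- grid[b]
    if (neg2[1L, g] <= .remlEval(lambda, S)$neg2) lambda <- 0
    lambdas[g] <- lambda
    ev <- .remlEval(lambda, S)
    residM <- Y[, g] - drop(d@X %*% ev$beta)
    u <- lambda / (1 + lambda * m) * drop(crossprod(d@Z, residM))
    resid[, g] <- residM - drop(d@Z %*% u)
  }
  list(residConditional = resid, lambda = lambdas)
}
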