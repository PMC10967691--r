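## Negative-binomial GLM machinery shared by the differential-expression and
## allele-specific-expression tests: median-of-ratios size factors,
## method-of-moments gene-wise dispersion with a floor, log-link IRLS
## fitting, Wald tests on single coefficients and likelihood-ratio tests
## between nested designs. The NB2 parameterization is used throughout:
## Var(Y) = mu + alpha * mu^2.

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's size factor is the median ratio
#' of its counts to the row geometric means, over genes with a positive
#' geometric mean. For allele-level tables both alleles of a sample share the
#' library, so size factors are computed across all alleles jointly.
#' Implemented as a method on the [BiocGenerics::sizeFactors()] generic for
#' plain count matrices.
#'
#' @param object Genes (or alleles) x samples integer matrix.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
setMethod("sizeFactors", "matrix", function(object) {
  medianOfRatios(object)
})

#' Re-exported generics
#'
#' The [BiocGenerics::sizeFactors()] generic, re-exported so the matrix
#' method is callable without attaching BiocGenerics.
#' @name sizeFactors
#' @export
#' @importFrom BiocGenerics sizeFactors
NULL

medianOfRatios <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  use <- is.finite(geo) & geo > 0
  if (!any(use)) stop("no gene with all-positive counts")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(x)
    median(x / geo[use], na.rm = TRUE))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf / exp(mean(log(sf)))
}

#' Method-of-moments NB dispersion
#'
#' Gene-wise dispersion estimated from normalized counts within groups of
#' identical design rows: `alpha = (var - mean * mean(1/sf)) / mean^2`,
#' averaged over groups, floored at `floor_alpha`.
#'
#' @param counts Genes x samples matrix.
#' @param group Factor of design groups (same length as columns).
#' @param sf Size factors.
#' @param floor_alpha Lower bound (default 1e-4).
#' @param ceiling_alpha Upper bound (default 10).
#' @return Numeric vector of per-gene dispersions.
#' @export
estimateDispersion <- function(counts, group, sf = sizeFactors(counts),
                               floor_alpha = 1e-4, ceiling_alpha = 10) {
  q <- sweep(counts, 2L, sf, "/")
  group <- as.factor(group)
  num <- matrix(0, nrow(counts), nlevels(group))
  den <- matrix(0, nrow(counts), nlevels(group))
  for (j in seq_len(nlevels(group))) {
    sel <- group == levels(group)[j]
    if (sum(sel) < 2L) next
    m <- rowMeans(q[, sel, drop = FALSE])
    v <- apply(q[, sel, drop = FALSE], 1L, var)
    shot <- m * mean(1 / sf[sel])
    num[, j] <- ifelse(m > 0, (v - shot) / m^2, 0)
    den[, j] <- as.numeric(sum(sel) >= 2L & m > 0)
  }
  a <- rowSums(num * den) / pmax(rowSums(den), 1)
  pmin(pmax(a, floor_alpha), ceiling_alpha)
}

#' Fit a negative-binomial GLM with log link
#'
#' IRLS fit of `y ~ exp(X beta + log(sf))` at fixed dispersion `alpha`
#' (NB2 variance). Converges on a coefficient-change tolerance of 1e-8
#' within 100 iterations or is flagged non-convergent.
#'
#' @param y Integer counts.
#' @param X Full-rank design matrix.
#' @param sf Size factors (offsets are `log(sf)`).
#' @param alpha Dispersion (> 0); `alpha = 0` is the Poisson limit.
#' @param max_iter,tol IRLS controls.
#' @return List: `coefficients`, `se`, `mu`, `loglik`, `converged`, `cov`
#'   (coefficient covariance), `alpha`.
#' @export
fitNbGlm <- function(y, X, sf = rep(1, length(y)), alpha = 0.05,
                     max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  if (all(y == 0)) stop("at least one positive count required")
  off <- log(sf)
  beta <- qr.solve(X, log((y + 0.5) / sf))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    newbeta <- fit$coefficients
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta
      converged <- TRUE
      break
    }
    beta <- newbeta
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_,
                                                          ncol(X), ncol(X)))
  ll <- nbLogLik(y, mu, alpha)
  list(coefficients = beta, se = sqrt(diag(cov)), mu = mu, loglik = ll,
       converged = converged, cov = cov, alpha = alpha)
}

## NB2 log-likelihood; alpha = 0 falls back to Poisson.
nbLogLik <- function(y, mu, alpha) {
  if (alpha <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

## Vectorized two-group NB fit across many genes by Newton iteration on the
## two group log-means (the groups are orthogonal under the saturated
## parameterization). counts: genes x samples; group: logical/0-1 vector for
## group 2. Returns log fold change (nat log, group2/group1), its Wald SE,
## per-group fitted means and the per-gene log-likelihood.
nbTwoGroupFit <- function(counts, group2, sf, alpha, max_iter = 50L,
                          tol = 1e-10) {
  fitGroup <- function(y, s, a) {
    ## y: genes x reps, s: size factors, a: per-gene alpha
    m <- pmax(rowMeans(sweep(y, 2L, s, "/")), 1e-8)
    lm_ <- log(m)
    for (it in seq_len(max_iter)) {
      mu <- exp(lm_) %o% s
      denom <- 1 + a * mu
      U <- rowSums((y - mu) / denom)
      I <- rowSums(mu / denom)
      stepv <- U / pmax(I, 1e-12)
      stepv <- pmin(pmax(stepv, -5), 5)
      lm_ <- lm_ + stepv
      if (max(abs(stepv)) < tol) break
    }
    mu <- exp(lm_) %o% s
    I <- rowSums(mu / (1 + a * mu))
    list(logmean = lm_, info = I, mu = mu)
  }
  g2 <- as.logical(group2)
  f1 <- fitGroup(counts[, !g2, drop = FALSE], sf[!g2], alpha)
  f2 <- fitGroup(counts[, g2, drop = FALSE], sf[g2], alpha)
  lfc <- f2$logmean - f1$logmean
  se <- sqrt(1 / f1$info + 1 / f2$info)
  ll <- numeric(nrow(counts))
  mu <- matrix(0, nrow(counts), ncol(counts))
  mu[, !g2] <- f1$mu
  mu[, g2] <- f2$mu
  size <- 1 / alpha
  ll <- rowSums(dnbinom(counts, size = size, mu = pmax(mu, 1e-12),
                        log = TRUE))
  list(log_fc = lfc, se = se, mu = mu, loglik = ll,
       logmean1 = f1$logmean, logmean2 = f2$logmean)
}

## Vectorized intercept-only NB fit (for LRT nulls).
nbInterceptFit <- function(counts, sf, alpha, max_iter = 50L, tol = 1e-10) {
  f <- nbTwoGroupFitGroupOnly(counts, sf, alpha, max_iter, tol)
  f
}

nbTwoGroupFitGroupOnly <- function(counts, sf, alpha, max_iter = 50L,
                                   tol = 1e-10) {
  m <- pmax(rowMeans(sweep(counts, 2L, sf, "/")), 1e-8)
  lm_ <- log(m)
  for (it in seq_len(max_iter)) {
    mu <- exp(lm_) %o% sf
    denom <- 1 + alpha * mu
    U <- rowSums((counts - mu) / denom)
    I <- rowSums(mu / denom)
    stepv <- pmin(pmax(U / pmax(I, 1e-12), -5), 5)
    lm_ <- lm_ + stepv
    if (max(abs(stepv)) < tol) break
  }
  mu <- exp(lm_) %o% sf
  ll <- rowSums(dnbinom(counts, size = 1 / alpha, mu = pmax(mu, 1e-12),
                        log = TRUE))
  list(logmean = lm_, loglik = ll, mu = mu)
}

## Two-group Wald test, vectorized over genes. Returns data.table with
## log2_fc, se (log2), p.
nbTwoGroupWald <- function(counts, group2, sf, alpha) {
  fit <- nbTwoGroupFit(counts, group2, sf, alpha)
  z <- fit$log_fc / fit$se
  p <- 2 * pnorm(-abs(z))
  data.table(log2_fc = fit$log_fc / log(2), se_log2 = fit$se / log(2), p = p)
}
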