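## Simplified short time-series profile clustering in the style of STEM:
## candidate model profiles are integer-step trajectories starting at 0 with
## per-step changes in -c..c, greedily reduced to a representative subset;
## each series is assigned to the profile with the highest Pearson
## correlation and profile significance is assessed by permuting the time
## order of every series.

## All integer-step trajectories of T points starting at 0.
candidateProfiles <- function(T, c = 2L) {
  steps <- as.matrix(expand.grid(rep(list(seq.int(-c, c)), T - 1L)))
  prof <- cbind(0L, t(apply(steps, 1L, cumsum)))
  dimnames(prof) <- NULL
  prof
}

## Greedy max-min-distance reduction to n profiles, always keeping the flat
## profile first (deterministic ties: lowest row index wins).
reduceProfiles <- function(profiles, n = 50L) {
  if (nrow(profiles) <= n) return(profiles)
  flat <- which(rowSums(abs(profiles)) == 0)[1]
  chosen <- flat
  d <- as.matrix(stats::dist(profiles))
  mind <- d[, flat]
  for (i in seq_len(n - 1L)) {
    cand <- which.max(mind)
    chosen <- c(chosen, cand)
    mind <- pmin(mind, d[, cand])
  }
  profiles[chosen, , drop = FALSE]
}

## Row-standardize to zero mean / unit variance; constant rows become all-0.
zRows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2))
  ok <- s > 0
  xc[ok, ] <- xc[ok, , drop = FALSE] / s[ok]
  xc[!ok, ] <- 0
  list(z = xc, constant = !ok)
}

#' STEM-style time-course profile clustering
#'
#' Assigns each series (e.g. a DMR's methylation level across ordered
#' phases) to the closest of a reduced library of integer-step model
#' profiles, and scores each profile's assigned count against a permutation
#' null in which every series' time order is shuffled independently.
#' Series are standardized to start at 0. A constant series has undefined
#' correlation and is assigned to the flat profile by the zero-distance rule.
#'
#' @param series Numeric matrix, one row per series, T >= 3 ordered columns
#'   (T in 3..5 supported).
#' @param c Maximum per-step unit change of model profiles (default 2).
#' @param n_candidate_profiles Library size after greedy reduction
#'   (default 50).
#' @param n_permutations Permutations for profile significance
#'   (default 1000).
#' @param seed Seed for the permutation draw (default 1).
#' @return List: `profiles` (matrix, row 1..n; flat profile included),
#'   `assignment` (profile index per series), `profile_stats` (data.table
#'   profile, n_assigned, expected, p).
#' @export
stemCluster <- function(series, c = 2L, n_candidate_profiles = 50L,
                        n_permutations = 1000L, seed = 1L) {
  series <- as.matrix(series)
  T <- ncol(series)
  if (T < 3L) stop("need at least 3 time points")
  prof <- reduceProfiles(candidateProfiles(T, c), n_candidate_profiles)
  flat <- which(rowSums(abs(prof)) == 0)[1]
  nprof <- nrow(prof)
  pz <- zRows(prof)
  n <- nrow(series)
  sz <- zRows(series - series[, 1L])
  assignZ <- function(z, constant) {
    r <- z %*% t(pz$z)
    r[, pz$constant] <- -Inf
    a <- max.col(r, ties.method = "first")
    a[constant] <- flat
    a
  }
  assignment <- assignZ(sz$z, sz$constant)
  obs <- tabulate(assignment, nprof)
  ## permutation null: shuffle each series' time order (Pearson correlation
  ## is invariant to the start-at-0 shift, so permuting z-scored rows is
  ## equivalent to permuting raw series)
  set.seed(seed)
  allperm <- as.matrix(expand.grid(rep(list(seq_len(T)), T)))
  allperm <- allperm[apply(allperm, 1, function(x) !anyDuplicated(x)), ,
                     drop = FALSE]
  rows <- rep(seq_len(n), T)
  perm_counts <- matrix(0L, n_permutations, nprof)
  for (b in seq_len(n_permutations)) {
    k <- sample.int(nrow(allperm), n, replace = TRUE)
    idx <- allperm[k, , drop = FALSE]
    zp <- matrix(sz$z[cbind(rows, as.vector(idx))], n)
    pa <- assignZ(zp, sz$constant)
    perm_counts[b, ] <- tabulate(pa, nprof)
  }
  expected <- colMeans(perm_counts)
  pvals <- vapply(seq_len(nprof), function(j)
    (1 + sum(perm_counts[, j] >= obs[j])) / (n_permutations + 1), numeric(1))
  list(profiles = prof, assignment = assignment,
       profile_stats = data.table(profile = seq_len(nprof),
                                  n_assigned = obs, expected = expected,
                                  p = pvals))
}
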