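## NB GLM core and the allele-specific expression tests.

test_that("the NB GLM reproduces simple oracles", {
  ## equal counts in both groups -> allele coefficient 0
  y <- c(20, 20, 20, 20, 20, 20)
  X <- cbind(1, rep(c(0, 1), each = 3))
  f <- fitNbGlm(y, X, alpha = 0.05)
  expect_equal(unname(f$coefficients[2]), 0, tolerance = 1e-6)
  expect_true(f$converged)

  ## dispersion -> 0 limit matches the Poisson GLM
  set.seed(2)
  y2 <- rpois(6, exp(X %*% c(3, 1)))
  fnb <- fitNbGlm(y2, X, alpha = 1e-8)
  fpo <- glm.fit(X, y2, family = poisson())
  expect_equal(unname(fnb$coefficients), unname(fpo$coefficients),
               tolerance = 1e-3)

  ## maternal (40,44,36) vs paternal (10,9,11): log2FC within 0.15 of 2
  ym <- c(10, 9, 11, 40, 44, 36)
  fr <- fitNbGlm(ym, X, alpha = 0.05)
  expect_equal(unname(fr$coefficients[2]) / log(2), 2, tolerance = 0.15)

  expect_error(fitNbGlm(c(0, 0, 0), cbind(1, c(0, 1, 1))), "positive")
  expect_error(fitNbGlm(y, cbind(1, 1)), "rank")
})

test_that("the vectorized two-group fit agrees with the per-gene IRLS", {
  set.seed(4)
  n <- 30
  y <- cbind(matrix(rnbinom(3 * n, mu = 100, size = 20), n),
             matrix(rnbinom(3 * n, mu = 220, size = 20), n))
  sf <- rep(1, 6)
  g2 <- rep(c(FALSE, TRUE), each = 3)
  vec <- alleleMeth:::nbTwoGroupFit(y, g2, sf, rep(0.05, n))
  X <- cbind(1, as.numeric(g2))
  for (i in c(1, 7, 19)) {
    f <- fitNbGlm(y[i, ], X, sf, alpha = 0.05)
    expect_equal(unname(vec$log_fc[i]), unname(f$coefficients[2]),
                 tolerance = 1e-6)
    expect_equal(unname(vec$se[i]), unname(f$se[2]), tolerance = 1e-6)
  }
})

test_that("per-phase ASE testing recovers bias, controls the null, and is
           symmetric", {
  set.seed(6)
  n <- 500
  true_biased <- seq_len(100)
  mu_m <- rep(100, n); mu_p <- rep(100, n)
  mu_m[true_biased] <- 100 * 2   # log2FC = 2
  mu_p[true_biased] <- 100 / 2
  mk <- function(mu) matrix(rnbinom(3 * n, mu = mu, size = 1 / 0.05), n,
                            dimnames = list(paste0("pr", 1:n), NULL))
  m <- mk(mu_m); p_ <- mk(mu_p)
  res <- testAsePerPhase(m, p_, phase = "LE")
  called <- res[pair %in% paste0("pr", true_biased)]
  expect_gte(mean(called$bias == "maternal"), 0.9)
  null <- res[!pair %in% paste0("pr", true_biased)]
  expect_lte(mean(null$bias != "none"), 0.01)
  ## label swap negates log2FC, keeps FDR
  swap <- testAsePerPhase(p_, m, phase = "LE")
  expect_equal(swap$log2_fc, -res$log2_fc, tolerance = 1e-8)
  expect_equal(swap$fdr, res$fdr, tolerance = 1e-8)
  expect_equal(sum(swap$bias == "paternal"), sum(res$bias == "maternal"))
})

test_that("phase-dependent interaction tests recover the designed grid", {
  set.seed(7)
  n_per <- 60
  effects <- c(0, 1, 2)
  mu <- 150
  phases <- rep(c("LE", "DP1"), each = 3)
  m_list <- list(); p_list <- list(); truth <- numeric()
  for (e in effects) {
    ## bias 0 at LE, e at DP1
    mm <- cbind(matrix(rnbinom(3 * n_per, mu = mu, size = 20), n_per),
                matrix(rnbinom(3 * n_per, mu = mu * 2^(e / 2), size = 20),
                       n_per))
    pp <- cbind(matrix(rnbinom(3 * n_per, mu = mu, size = 20), n_per),
                matrix(rnbinom(3 * n_per, mu = mu * 2^(-e / 2), size = 20),
                       n_per))
    m_list[[as.character(e)]] <- mm
    p_list[[as.character(e)]] <- pp
    truth <- c(truth, rep(e, n_per))
  }
  m <- do.call(rbind, m_list); p_ <- do.call(rbind, p_list)
  rownames(m) <- rownames(p_) <- paste0("pr", seq_len(nrow(m)))
  res <- testPhaseDependentAse(m, p_, phases)
  res[, true_effect := truth[match(pair, paste0("pr", seq_len(nrow(m))))]]
  est <- res[, .(mean_est = mean(interaction_log2),
                 flagged = mean(phase_dependent)), by = true_effect]
  expect_equal(est[true_effect == 0]$mean_est, 0, tolerance = 0.3)
  expect_equal(est[true_effect == 1]$mean_est, 1, tolerance = 0.3)
  expect_equal(est[true_effect == 2]$mean_est, 2, tolerance = 0.3)
  expect_lte(est[true_effect == 0]$flagged, 0.01)
  expect_gte(est[true_effect == 2]$flagged, 0.8)
  ## constant bias in all phases is not phase-dependent
  set.seed(8)
  mc <- matrix(rnbinom(6 * 50, mu = 400, size = 20), 50)
  pc <- matrix(rnbinom(6 * 50, mu = 100, size = 20), 50)
  rownames(mc) <- rownames(pc) <- paste0("c", 1:50)
  resc <- testPhaseDependentAse(mc, pc, phases)
  expect_lte(mean(resc$phase_dependent), 0.02)
  expect_error(testPhaseDependentAse(mc, pc, rep("DP1", 6)), "baseline")
})

test_that("consistency classification follows the stated rules", {
  tab <- data.table(
    pair = rep(c("a", "b", "c", "d"), each = 3),
    phase = rep(c("LE", "DP1", "DP2"), 4),
    bias = c("maternal", "maternal", "maternal",
             "maternal", "none", "paternal",
             "none", "none", "none",
             "none", "paternal", "paternal"))
  out <- classifyConsistency(tab)
  expect_equal(out[pair == "a"]$label, "consistent_maternal")
  expect_equal(out[pair == "b"]$label, "shifting")
  expect_equal(out[pair == "c"]$label, "unbiased")
  expect_equal(out[pair == "d"]$label, "phase_specific")
})

test_that("allele PCA separates a strong subgenome effect on PC1", {
  set.seed(9)
  base <- matrix(rnorm(40 * 12, 5, 1), 40, 12)
  eff <- rep(c(0, 3), each = 20)
  x <- base + eff
  rownames(x) <- paste0("al", 1:40)
  parent <- rep(c("maternal", "paternal"), each = 20)
  out <- allelePca(x, parent)
  expect_equal(names(out$scores), c("allele", "parent", "PC1", "PC2"))
  ## identical profiles -> identical scores
  x2 <- rbind(a = x[1, ], b = x[1, ], c = x[5, ])
  s2 <- allelePca(x2, c("m", "m", "p"))$scores
  expect_equal(s2$PC1[1], s2$PC1[2])
  ## variance explained non-increasing
  expect_true(all(diff(out$variance_explained) <= 1e-12))
  ## silhouette of the parent split on PC1 > 0
  pc1 <- out$scores$PC1
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[parent == parent[i] &
                                   seq_along(pc1) != i]))
    oth <- mean(abs(pc1[i] - pc1[parent != parent[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_error(allelePca(x[1, , drop = FALSE], "m"), ">= 2")
})
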