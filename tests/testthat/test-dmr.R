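## The DMR test: replicate-aware binomial-logistic LRT with per-context
## difference thresholds, plus bin filtering, annotation, clustering and
## enrichment.

grp <- function(mC, uC) list(mC = as.matrix(mC), uC = as.matrix(uC))

test_that("bin filtering requires five cytosines in all samples", {
  bins <- makeSlidingBins(c(c1 = 400))
  ## replicate 1 has 5 CG sites in bin 1, replicate 2 only 4
  r1 <- makeRecords("c1", c(10, 20, 30, 40, 50, 250, 260, 270, 280, 290),
                    mC = 8, uC = 2)
  r2 <- makeRecords("c1", c(10, 20, 30, 40, 250, 260, 270, 280, 290),
                    mC = 3, uC = 7)
  bc <- binCounts(list(r1, r2), bins, "CG")
  expect_false(any(start(bc$bins) == 1L))   # bin [0,200) dropped
  ## pooling within replicate
  r3 <- makeRecords("c1", c(10, 20, 30, 40, 50), mC = c(8, 3, 0, 0, 0),
                    uC = c(2, 7, 1, 1, 1))
  bc3 <- binCounts(list(r3), makeSlidingBins(c(c1 = 200)), "CG")
  expect_equal(unname(bc3$mC[1, 1]), 11L)
  expect_equal(unname(bc3$uC[1, 1]), 12L)
  ## nothing passes -> empty result, zero DMRs downstream
  bc4 <- binCounts(list(r3[1:2]), makeSlidingBins(c(c1 = 200)), "CG")
  expect_equal(nrow(bc4$mC), 0L)
})

test_that("the LRT flags strong differences and honours thresholds", {
  ## identical groups: difference 0, not a DMR
  g <- grp(cbind(25, 25), cbind(25, 25))
  r0 <- testDmr(g, g, "CG")
  expect_equal(r0$difference, 0)
  expect_false(r0$dmr)

  ## 90/10 vs 10/90 in 3 balanced replicates: difference -0.8, p < 1e-10
  g1 <- grp(matrix(30, 1, 3), matrix(c(3, 4, 3), 1))
  g2 <- grp(matrix(c(3, 4, 3), 1), matrix(30, 1, 3))
  r <- testDmr(g1, g2, "CG")
  expect_equal(r$difference, 10 / 100 - 90 / 100, tolerance = 1e-6)
  expect_lt(r$p, 1e-10)
  expect_true(r$dmr)
  ## Fisher-exact oracle bounds the order of magnitude
  fp <- fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value
  expect_lt(abs(log10(r$p) - log10(fp)), 1.5)

  ## a 0.2 difference: DMR in CHH, not in CG (threshold table)
  mk <- function(p1, p2, n = 4000) {
    list(g1 = grp(cbind(round(n * p1)), cbind(round(n * (1 - p1)))),
         g2 = grp(cbind(round(n * p2)), cbind(round(n * (1 - p2)))))
  }
  x <- mk(0.4, 0.6)
  expect_true(testDmr(x$g1, x$g2, "CHH")$dmr)
  expect_false(testDmr(x$g1, x$g2, "CG")$dmr)
})

test_that("swapping group labels negates differences, p unchanged", {
  set.seed(3)
  n <- 50
  g1 <- grp(matrix(rbinom(3 * n, 40, 0.3), n), matrix(rbinom(3 * n, 40, 0.5), n))
  g2 <- grp(matrix(rbinom(3 * n, 40, 0.6), n), matrix(rbinom(3 * n, 40, 0.3), n))
  a <- testDmr(g1, g2, "CG")
  b <- testDmr(g2, g1, "CG")
  expect_equal(a$difference, -b$difference)
  expect_equal(a$p, b$p)
})

test_that("LRT p agrees with the Fisher oracle within an order of magnitude", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    n1 <- sample(10:100, 1); n2 <- sample(10:100, 1)
    p1 <- runif(1, 0.1, 0.9)
    p2 <- if (i %% 2) p1 else min(max(p1 + runif(1, -0.3, 0.3), 0.02), 0.98)
    m1 <- rbinom(1, n1, p1); m2 <- rbinom(1, n2, p2)
    lrt <- testDmr(grp(cbind(m1), cbind(n1 - m1)),
                   grp(cbind(m2), cbind(n2 - m2)), "CG")
    fis <- fisher.test(matrix(c(m1, n1 - m1, m2, n2 - m2), 2,
                              byrow = TRUE))$p.value
    worst <- max(worst, abs(log10(max(lrt$p, 1e-300)) - log10(fis)))
  }
  expect_lte(worst, 1)
})

test_that("DMR annotation follows promoter > body > downstream precedence", {
  genes <- GRanges("c1", IRanges(c(10001, 40001), c(14000, 44000)),
                   strand = c("+", "-"), gene_id = c("gA", "gB"))
  dmrs <- data.table(
    chrom = "c1",
    start = c(11000, 9500, 44500, 9000, 13950),
    end = c(11200, 9700, 44700, 9200, 14150))
  ## gB is "-": its promoter is [44001, 46000]
  ann <- annotateDmg(dmrs, genes)
  expect_equal(ann$dmrs$primary_feature,
               c("gene_body", "promoter", "promoter", "promoter",
                 "gene_body"))
  expect_true(all(c("gA", "gB") %in% ann$dmgs$gene_id))
  ## a DMR overlapping promoter of one gene and body of another counts once
  expect_equal(sum(ann$feature_fractions$n), nrow(dmrs))
})

test_that("hypergeometric enrichment matches the brute-force tail sum", {
  universe <- paste0("g", 1:100)
  selected <- paste0("g", 1:10)
  sets <- list(S1 = paste0("g", c(1:5, 51:55)),    # overlap 5
               S2 = paste0("g", 90:99),            # overlap 0
               S3 = universe)                      # p = 1
  res <- enrichGeneSets(selected, universe, sets)
  expect_equal(res[set == "S1"]$p, bruteHyper(5, 10, 100, 10),
               tolerance = 1e-10)
  expect_equal(res[set == "S1"]$p, 6.4e-4, tolerance = 0.05)
  expect_gt(res[set == "S2"]$p, 0.6)
  expect_equal(res[set == "S3"]$p, 1)
  expect_error(enrichGeneSets(selected, character(), sets), "universe")
})

test_that("profile clustering assigns monotone and flat series sensibly", {
  series <- rbind(c(0.9, 0.6, 0.3),           # decreasing
                  c(0.2, 0.5, 0.8),           # increasing
                  c(0.5, 0.5, 0.5))           # constant
  st <- stemCluster(series, n_permutations = 50, seed = 2)
  prof <- st$profiles
  expect_true(all(diff(prof[st$assignment[1], ]) <= 0))
  expect_true(all(diff(prof[st$assignment[2], ]) >= 0))
  expect_equal(unname(rowSums(abs(prof))[st$assignment[3]]), 0)
  expect_error(stemCluster(series[, 1:2, drop = FALSE]), "3 time points")
  ## deterministic under a fixed seed
  st2 <- stemCluster(series, n_permutations = 50, seed = 2)
  expect_identical(st$profile_stats$p, st2$profile_stats$p)
  ## a coherent batch of decreasing series makes that profile significant
  set.seed(9)
  batch <- t(replicate(60, sort(runif(4), decreasing = TRUE)))
  stb <- stemCluster(batch, n_permutations = 200, seed = 3)
  dec <- which(apply(stb$profiles, 1, function(x) all(diff(x) < 0)))
  top <- stb$profile_stats[profile %in% dec]
  expect_lt(min(top[n_assigned > 0]$p), 0.05)
})
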