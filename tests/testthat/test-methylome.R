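test_that("site levels apply the coverage floor", {
  rec <- makeRecords("c1", c(10, 20, 30), mC = c(8, 2, 0),
                     uC = c(2, 2, 10))
  lv <- siteLevels(rec)
  expect_equal(length(lv), 2L)   # (2,2) dropped: coverage 4 < 5
  expect_equal(lv$level, c(0.8, 0))
})

test_that("weighted region levels pool counts and flag empty intervals", {
  rec <- makeRecords("c1", c(10, 20), mC = c(8, 0), uC = c(2, 10))
  r <- weightedRegionLevel(rec, GRanges("c1", IRanges(1, 100)))
  expect_equal(r$weighted_level, 8 / 20)
  expect_equal(r$n_cytosines, 2L)
  empty <- weightedRegionLevel(rec, GRanges("c1", IRanges(500, 600)))
  expect_true(is.na(empty$weighted_level))
  one <- weightedRegionLevel(makeRecords("c1", 10, mC = 5, uC = 0),
                             GRanges("c1", IRanges(1, 100)))
  expect_equal(one$weighted_level, 1)
})

test_that("union of disjoint intervals equals count-pooled level of parts", {
  set.seed(1)
  rec <- makeRecords("c1", seq(10, 400, by = 7),
                     mC = rpois(56, 5), uC = rpois(56, 5))
  a <- weightedRegionLevel(rec, GRanges("c1", IRanges(1, 200)))
  b <- weightedRegionLevel(rec, GRanges("c1", IRanges(201, 400)))
  ab <- weightedRegionLevel(rec, GRanges("c1", IRanges(1, 400)))
  pooled <- (a$weighted_level * a$total_coverage +
               b$weighted_level * b$total_coverage) /
    (a$total_coverage + b$total_coverage)
  expect_equal(ab$weighted_level, pooled)
})

test_that("global summary bands and binomial methylated-site calls behave", {
  rec <- makeRecords("c1", 1:3, mC = c(1, 5, 9), uC = c(9, 5, 1))
  gs <- globalSummary(rec)
  expect_equal(gs$band_low, 1 / 3)
  expect_equal(gs$band_mid, 1 / 3)
  expect_equal(gs$band_high, 1 / 3)
  ## fully methylated sites -> high band 1
  gs2 <- globalSummary(makeRecords("c1", 1:4, mC = 10, uC = 0))
  expect_equal(gs2$band_high, 1)
  ## 1,000 unmethylated sites at 30x with e = 0.005: call rate <= 0.01
  set.seed(42)
  cov <- rpois(1000, 30)
  mC <- rbinom(1000, cov, 0.005)
  gs3 <- globalSummary(makeRecords("c1", seq_len(1000), mC = mC,
                                   uC = cov - mC))
  expect_lte(gs3$frac_methylated, 0.01)
})

test_that("sliding bins follow the 200/100 scheme with clipped tails", {
  expect_equal(length(makeSlidingBins(c(c1 = 1000))), 9L)
  b <- makeSlidingBins(c(c1 = 150))
  expect_equal(length(b), 1L)
  expect_equal(c(start(b), end(b)), c(1L, 150L))
  expect_equal(length(makeSlidingBins(c(c1 = 200))), 1L)
  expect_error(makeSlidingBins(c(c1 = 1000), length = 100, step = 200),
               "step")
  ## coverage property: every position covered >= 1 and <= ceiling(l/s)
  for (L in c(250, 999, 1001, 1234)) {
    bb <- makeSlidingBins(setNames(L, "c"))
    cover <- coverage(bb)$c
    expect_equal(sum(runLength(cover)[runValue(cover) == 0]), 0)
    expect_lte(max(cover), 2L)
  }
})

test_that("the 80-bin scheme is strand-aware with 20/40/20 geometry", {
  plus <- GRanges("c1", IRanges(10001, 14000), strand = "+")  # [10000,14000)
  bp <- geneBinScheme(plus)
  expect_equal(length(bp), 80L)
  expect_equal(start(bp)[1] - 1L, 8000L)   # first bin [8000,8100)
  expect_equal(end(bp)[1], 8100L)
  expect_true(all(width(bp[bp$zone == "body"]) == 100L))
  expect_equal(end(bp)[80], 16000L)

  minus <- GRanges("c1", IRanges(10001, 14000), strand = "-")
  bm <- geneBinScheme(minus)
  expect_equal(start(bm)[1] - 1L, 15900L)  # first bin [15900,16000)
  expect_equal(end(bm)[1], 16000L)
  expect_equal(start(bm)[80] - 1L, 8000L)

  ## 40-bp gene: 1-bp body bins
  tiny <- geneBinScheme(GRanges("c1", IRanges(5001, 5040), strand = "+"))
  expect_true(all(width(tiny[tiny$zone == "body"]) == 1L))
  expect_error(geneBinScheme(GRanges("c1", IRanges(1, 30))), "shorter")
  expect_warning(
    geneBinSchemes(GRanges("c1", IRanges(c(5001, 1), c(9000, 30)),
                           gene_id = c("a", "b"))), "excluded")
})

test_that("metagene profiles average per-feature bin levels", {
  genes <- GRanges("c1", IRanges(c(10001, 30001), c(14000, 34000)),
                   strand = c("+", "-"), gene_id = c("g1", "g2"))
  ## fully methylated everywhere -> flat profile at 1
  pos <- seq(6000, 38000, by = 97)
  rec <- makeRecords("c1", pos, mC = 10, uC = 0)
  prof <- metageneProfile(genes, rec, "CG")
  expect_true(all(abs(prof$mean_level[prof$n_features > 0] - 1) < 1e-12))
  ## single feature: profile equals that feature's own levels
  p1 <- metageneProfile(genes[1], rec, "CG")
  expect_true(all(p1$n_features <= 1L))
  ## body-only methylation -> body bins exceed flank bins
  inbody <- pos >= 10001 & pos <= 14000 | pos >= 30001 & pos <= 34000
  rec2 <- makeRecords("c1", pos, mC = ifelse(inbody, 10, 0),
                      uC = ifelse(inbody, 0, 10))
  prof2 <- metageneProfile(genes, rec2, "CG")
  expect_gt(mean(prof2$mean_level[prof2$zone == "body"], na.rm = TRUE),
            mean(prof2$mean_level[prof2$zone != "body"], na.rm = TRUE))
})

test_that("strand reversal leaves profiles unchanged for symmetric data", {
  genes <- GRanges("c1", IRanges(c(10001, 30001), c(14000, 34000)),
                   strand = c("+", "-"), gene_id = c("g1", "g2"))
  set.seed(7)
  pos <- seq(6000, 38000, by = 11)
  rec <- makeRecords("c1", pos, mC = rpois(length(pos), 8),
                     uC = rpois(length(pos), 8))
  flipped <- genes
  strand(flipped) <- ifelse(as.character(strand(genes)) == "+", "-", "+")
  a <- metageneProfile(genes, rec, "CG")
  b <- metageneProfile(flipped, rec, "CG")
  ## flipping all strands reverses bin order; profiles are mirror images up
  ## to the asymmetric site layout, so compare sorted level multisets
  expect_equal(sort(round(a$mean_level, 10)), sort(round(b$mean_level, 10)))
})
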