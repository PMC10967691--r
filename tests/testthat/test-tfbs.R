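sharpPwm <- function(word) {
  base <- c(A = 1, C = 2, G = 3, T = 4)
  m <- matrix(0.04, 4, nchar(word), dimnames = list(names(base), NULL))
  idx <- base[strsplit(word, "")[[1]]]
  m[cbind(idx, seq_along(idx))] <- 0.88
  m
}

test_that("DP tail probabilities equal brute-force enumeration", {
  for (word in c("ACG", "ACGT", "ACGTA", "CGTACG")) {
    pwm <- sharpPwm(word)
    model <- alleleMeth:::pwmScoreModel(pwm)
    for (q in c(0.999, 0.9, 0.5, 0.1, 1e-3)) {
      s <- model$offset +
        which(model$tail_p <= q)[1] - 1L
      if (is.na(s)) next
      expect_equal(alleleMeth:::pwmTailP(model, s),
                   brutePwmTail(pwm, s), tolerance = 1e-12)
    }
    ## total probability mass is 1
    expect_equal(sum(model$dist), 1, tolerance = 1e-12)
  }
})

test_that("scanning finds embedded consensus words on both strands", {
  set.seed(14)
  pwm <- sharpPwm("ACGTACGT")
  bgseq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  target <- paste0(substr(bgseq, 1, 100), "ACGTACGT",
                   substr(bgseq, 109, 500))
  seqs <- DNAStringSet(c(p1 = target))
  hits <- scanPwm(seqs, pwm)
  expect_true(any(hits$pos == 101 & hits$strand == "+"))
  expect_true(all(hits$p < 1e-4))
  ## reverse-complemented promoter: same footprint on the opposite strand
  rc <- reverseComplement(seqs)
  names(rc) <- "p1"
  hits_rc <- scanPwm(rc, pwm)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_true(any(hits_rc$pos == 500 - 101 - 8 + 2 &
                    hits_rc$strand == "-"))
  ## sequence shorter than the motif: no hits, no error
  expect_equal(nrow(scanPwm(DNAStringSet(c(s = "ACG")), pwm)), 0L)
})

test_that("presence vectors and cosine similarity follow the definitions", {
  hits <- data.table(seq = c("p1", "p1", "p1", "p2"),
                     motif = c("M1", "M1", "M2", "M2"),
                     pos = 1L, strand = "+", score = 1, p = 1e-6)
  v <- promoterVectors(hits, c("p1", "p2", "p3"), c("M1", "M2", "M3"))
  expect_equal(dim(v), c(3L, 3L))
  expect_equal(unname(v["p1", ]), c(1L, 1L, 0L))  # presence, not count
  expect_equal(unname(v["p3", ]), c(0L, 0L, 0L))
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosineSimilarity(c(1, 1), c(1, 1)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(0, 0), c(0, 0)), 1)  # identical absence
  expect_error(cosineSimilarity(1, c(1, 0)), "length")
})

test_that("CS classes use the stated breakpoints", {
  expect_equal(as.character(csClasses(c(0, 0.19, 0.2, 0.59, 0.6, 0.8, 1))),
               c("I", "I", "II", "III", "IV", "V", "V"))
})

test_that("class-wise expression correlation compares groups by Fisher z", {
  ## closed-form z for r1=0.9 (n=500) vs r2=0.5 (n=200)
  p <- alleleMeth:::fisherZTest(0.9, 500, 0.5, 200)
  z <- (atanh(0.9) - atanh(0.5)) / sqrt(1 / 497 + 1 / 197)
  expect_equal(p, 2 * pnorm(-abs(z)))
  expect_lt(p, 0.001)
  ## equal r and n: p = 1
  expect_equal(alleleMeth:::fisherZTest(0.4, 100, 0.4, 100), 1)
  ## identical allele expression: r = 1 in every populated class
  cs <- data.table(maternal_id = paste0("m", 1:30),
                   paternal_id = paste0("p", 1:30),
                   cs = runif(30), both_zero = FALSE)
  cs[, cs_class := csClasses(cs)]
  em <- setNames(rnorm(30, 5), paste0("m", 1:30))
  ep <- setNames(em, paste0("p", 1:30))
  out <- classExpressionCorrelation(cs, em, ep, group2_pairs = paste0("m", 1:10))
  filled <- out[!is.na(r_all)]
  expect_true(all(abs(filled$r_all - 1) < 1e-12))
})

test_that("TFBS methylation pools counts like weightedRegionLevel", {
  prom <- GRanges("c1", IRanges(1001, 3000), strand = "+")
  names(prom) <- "p1"
  prom$gene_id <- "p1"
  hits <- data.table(seq = "p1", motif = "M1", pos = 101L, strand = "+",
                     score = 5, p = 1e-6)
  ## footprint is [1101, 1108] for an 8-wide motif
  rec <- makeRecords("c1", c(1102, 1105, 2000), mC = c(3, 1, 50),
                     uC = c(7, 9, 0))
  out <- tfbsMethylation(hits, prom, rec, c(M1 = 8L))
  expect_equal(out$per_hit$weighted_level, 4 / 20)
  ref <- weightedRegionLevel(rec, GRanges("c1", IRanges(1101, 1108)))
  expect_equal(out$per_hit$weighted_level, ref$weighted_level)
  ## no covered cytosines -> excluded from the summary
  rec2 <- makeRecords("c1", 2000, mC = 5, uC = 5)
  out2 <- tfbsMethylation(hits, prom, rec2, c(M1 = 8L))
  expect_true(is.na(out2$per_hit$weighted_level))
  expect_true(all(is.na(out2$summary$fraction)) ||
                sum(out2$summary$n) == 0)
  ## minus-strand promoters map positions back correctly
  promm <- GRanges("c1", IRanges(1001, 3000), strand = "-")
  names(promm) <- "p1"
  ## pos 101 on the minus promoter starts at genomic end - 101 + 1 = 2900
  outm <- tfbsMethylation(hits, promm,
                          makeRecords("c1", 2895, mC = 6, uC = 4),
                          c(M1 = 8L))
  expect_equal(outm$per_hit$weighted_level, 0.6)
})

test_that("motif placement truth and scanning agree in the degenerate cases", {
  ## zero divergence + zero flips: allele vectors identical, CS = 1
  cfg <- SimConfig(n_gene_pairs = 12L, n_chromosomes = 1L, snp_rate = 0,
                   relocation_fraction = 0, motif_flip_prob = 0,
                   aseg_flip_prob = 0, seed = 41L)
  gen <- simulateGenomes(cfg)
  lib <- toyMotifLibrary()
  pm <- placeMotifs(gen$bundle, gen$pair_truth, cfg, lib)
  expect_identical(unname(pm$presence_truth$maternal),
                   unname(pm$presence_truth$paternal))
  proms <- promoterSeqs(pm$bundle)
  hits <- scanMotifLibrary(proms, lib)
  vecs <- promoterVectors(hits, names(proms), names(lib))
  cs <- pairCosineSimilarity(vecs, gen$pair_truth)
  expect_true(all(cs$cs == 1))
  ## scanning recovers the placed motifs (presence implies a hit)
  pl <- pm$placements
  found <- unique(hits[, paste(seq, motif)])
  expect_gte(mean(paste(pl$gene_id, pl$motif) %in% found), 0.95)
  ## determinism
  pm2 <- placeMotifs(gen$bundle, gen$pair_truth, cfg, lib)
  expect_identical(pm$placements, pm2$placements)
})
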