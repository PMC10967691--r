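randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
mutate <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(runif(length(v)) < rate)
  v[idx] <- sample(c("A", "C", "G", "T"), length(idx), TRUE)
  paste(v, collapse = "")
}

test_that("homology scoring seeds on shared k-mers and ranks by divergence", {
  set.seed(21)
  a1 <- randSeq(600)
  seqs_a <- DNAStringSet(c(x1 = a1))
  seqs_b <- DNAStringSet(c(y1 = mutate(a1, 0.01), y2 = mutate(a1, 0.5),
                           y3 = randSeq(60)))
  hits <- scoreHomology(seqs_a, seqs_b)
  ## identical-ish sequence scores far above the 50%-diverged one
  s1 <- hits[query == "x1" & subject == "y1"]$score
  s2 <- hits[query == "x1" & subject == "y2"]$score
  expect_gt(s1, s2)
  ## symmetric self-comparison gives equal best both ways
  self <- scoreHomology(seqs_a, DNAStringSet(c(z = a1)))
  expect_equal(self$score, 2L * 600L)
  ## no shared 8-mers -> no hit at all
  none <- scoreHomology(DNAStringSet(c(q = strrep("A", 200))),
                        DNAStringSet(c(s = strrep("C", 200))))
  expect_equal(nrow(none), 0L)
})

test_that("the c-score filter keeps near-reciprocal-best hits", {
  hits <- data.table(query = c("a", "a", "b"),
                     subject = c("X", "Y", "Y"),
                     score = c(100, 100, 200))
  kept <- cscoreFilter(hits, 0.99)
  expect_true(nrow(kept[query == "a" & subject == "X"]) == 1L)
  ## (a, Y): score 100 < 0.99 * bestscore(Y) = 198 -> dropped
  expect_equal(nrow(kept[query == "a" & subject == "Y"]), 0L)
  expect_equal(nrow(cscoreFilter(hits, 0)), 3L)
})

test_that("synteny chaining finds collinear and inverted blocks", {
  ## perfectly collinear 30 anchors -> one block with all pairs
  anchors <- data.table(query = paste0("m", 1:30),
                        subject = paste0("p", 1:30),
                        a_chrom = "A1", b_chrom = "B1",
                        a_rank = 1:30, b_rank = 1:30)
  syn <- chainSynteny(anchors)
  expect_equal(nrow(syn$pairs), 30L)
  expect_equal(length(unique(syn$blocks$block)), 1L)
  ## 3 collinear anchors below min_block -> nothing
  expect_equal(nrow(chainSynteny(anchors[1:3])$pairs), 0L)
  ## an inverted 5-anchor segment chains in reverse orientation
  inv <- data.table(query = paste0("m", 1:10),
                    subject = paste0("p", 1:10),
                    a_chrom = "A1", b_chrom = "B1",
                    a_rank = 1:10,
                    b_rank = c(1:5, 10:6))
  syn2 <- chainSynteny(inv, min_block = 4)
  orient <- unique(syn2$blocks[, .(block, orientation)])
  expect_true("reverse" %in% orient$orientation)
  expect_gte(nrow(syn2$pairs), 9L)
})

test_that("BBH keeps mutual bests with deterministic tie breaks", {
  hits <- data.table(query = c("a", "a", "b", "c"),
                     subject = c("X", "Y", "X", "Z"),
                     score = c(10, 5, 8, 7))
  out <- suppressWarnings(bbh(hits))
  expect_true(nrow(out[query == "a" & subject == "X"]) == 1L)
  expect_false("b" %in% out$query)  # b's best X belongs to a
  expect_true("c" %in% out$query)
  ## exact tie -> deterministic lexicographic winner with a warning
  tie <- data.table(query = "a", subject = c("X", "Y"), score = c(5, 5))
  expect_warning(b1 <- bbh(tie), "tie")
  expect_equal(b1$subject, "X")
})

test_that("merging enforces precedence and the partial-matching invariant", {
  syn_pairs <- data.table(query = "m1", subject = "p1", block = 1L)
  hits <- data.table(query = c("m1", "m1", "m2", "m3"),
                     subject = c("p1", "p2", "p2", "p3"),
                     score = c(100, 90, 80, 60))
  out <- mergeAllelePairs(syn_pairs, hits)
  expect_equal(out[maternal_id == "m1"]$evidence, "synteny")
  expect_equal(out[maternal_id == "m2"]$paternal_id, "p2")  # residual BBH
  expect_equal(out[maternal_id == "m3"]$evidence %in%
                 c("bbh", "single_copy"), TRUE)
  expect_false(anyDuplicated(out$maternal_id) > 0)
  expect_false(anyDuplicated(out$paternal_id) > 0)
})

test_that("allele pairing on simulated genomes recovers the truth", {
  cfg <- SimConfig(n_gene_pairs = 60L, n_chromosomes = 1L,
                   relocation_fraction = 0.1, snp_rate = 0.01, seed = 31L)
  gen <- simulateGenomes(cfg)
  pairs <- findAllelePairs(gen$bundle)
  truth_key <- paste(gen$pair_truth$maternal_id, gen$pair_truth$paternal_id)
  found_key <- paste(pairs$maternal_id, pairs$paternal_id)
  expect_gte(mean(truth_key %in% found_key), 0.95)
  expect_equal(sum(!found_key %in% truth_key), 0L)
  ## relocated pairs are recovered, mostly by the non-synteny tiers (a
  ## relocated gene can legitimately rejoin a chain when its displacement
  ## stays within the rank gap)
  rel <- gen$pair_truth[relocated == TRUE]$maternal_id
  ev <- pairs[maternal_id %in% rel]$evidence
  expect_gte(length(ev), length(rel) - 1L)
  expect_true(any(ev %in% c("bbh", "single_copy")))
  ## zero divergence, no relocation: everything is synteny evidence
  cfg0 <- SimConfig(n_gene_pairs = 20L, n_chromosomes = 1L,
                    relocation_fraction = 0, snp_rate = 0, seed = 32L)
  gen0 <- simulateGenomes(cfg0)
  p0 <- findAllelePairs(gen0$bundle)
  expect_equal(nrow(p0), 20L)
  expect_true(all(p0$evidence == "synteny"))
})
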