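test_that("genome simulation is deterministic and respects its knobs", {
  cfg <- tinyConfig()
  g1 <- simulateGenomes(cfg)
  g2 <- simulateGenomes(cfg)
  expect_identical(as.character(genomeSequences(g1$bundle)),
                   as.character(genomeSequences(g2$bundle)))
  expect_identical(g1$pair_truth, g2$pair_truth)
  ## divergence 0: allele gene sequences identical
  cfg0 <- SimConfig(n_gene_pairs = 10L, n_chromosomes = 1L, snp_rate = 0,
                    relocation_fraction = 0, seed = 2L)
  g0 <- simulateGenomes(cfg0)
  genes <- geneModels(g0$bundle)
  chars <- as.character(genomeSequences(g0$bundle))
  seqOf <- function(gid) {
    g <- genes[genes$gene_id == gid]
    substring(chars[as.character(seqnames(g))], start(g), end(g))
  }
  expect_identical(unname(seqOf("alba_g0001")),
                   unname(seqOf("glan_g0001")))
  ## relocation fraction materializes in the truth table
  cfgr <- SimConfig(n_gene_pairs = 100L, n_chromosomes = 1L,
                    relocation_fraction = 0.1, seed = 3L)
  expect_equal(sum(simulateGenomes(cfgr)$pair_truth$relocated), 10L)
  ## infeasible packing errors out
  cfgbad <- SimConfig(n_gene_pairs = 50L, n_chromosomes = 1L,
                      max_chromosome_length = 1e4, seed = 4L)
  expect_error(simulateGenomes(cfgbad), "packing")
})

test_that("simulated genomes round-trip through the on-disk formats", {
  cfg <- SimConfig(n_gene_pairs = 6L, n_chromosomes = 1L, seed = 6L)
  gen <- simulateGenomes(cfg)
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "genome.fa")
  writeXStringSet(genomeSequences(gen$bundle), fa)
  back <- readDNAStringSet(fa)
  expect_identical(as.character(back),
                   as.character(genomeSequences(gen$bundle)))
  gff <- file.path(td, "genes.gff3")
  writeGFF3(geneModels(gen$bundle), gff)
  gm <- readGFF3(gff)$genes
  expect_equal(gm$gene_id, geneModels(gen$bundle)$gene_id)
  expect_equal(start(gm), start(geneModels(gen$bundle)))
  bed <- file.path(td, "tes.bed")
  tes <- teAnnotation(gen$bundle)
  tes$name <- tes$te_class
  writeBED(tes, bed)
  tb <- readBED(bed)
  expect_equal(start(tb), start(tes))
  meth <- simulateMethylomes(gen$bundle, cfg, gen$pair_truth, gen$slot_map,
                             phases = "LE")
  rep1 <- meth$samples[["LE_r1"]]
  cr <- file.path(td, "le_r1.cov.tsv")
  writeCytosineReport(rep1, cr)
  back2 <- readCytosineReport(cr)
  expect_equal(start(back2), start(rep1))
  expect_equal(back2$mC, rep1$mC)
  expect_equal(back2$context, rep1$context)
})

test_that("methylome observations match closed-form expectations", {
  ## non-conversion 0.5 with true p = 0: expected observed level 0.5
  cfg <- SimConfig(n_gene_pairs = 6L, n_chromosomes = 1L,
                   non_conversion = 0.5, ctx_frac_meth = c(CG = 0, CHG = 0,
                                                           CHH = 0),
                   beta_lo = c(1e-4, 1e4),  # true p ~ 0
                   n_dmr_windows = 0L, asmg_fraction = 0, seed = 7L)
  gen <- simulateGenomes(cfg)
  meth <- simulateMethylomes(gen$bundle, cfg, gen$pair_truth, gen$slot_map,
                             phases = "LE")
  rec <- meth$samples[["LE_r1"]]
  lvl <- sum(rec$mC) / sum(rec$mC + rec$uC)
  expect_equal(lvl, 0.5, tolerance = 0.01)
  ## true p = 0.8 at 30x: observed mean within 0.01 of 0.8(1-e) + 0.2e
  cfg2 <- SimConfig(n_gene_pairs = 6L, n_chromosomes = 1L,
                    ctx_frac_meth = c(CG = 1, CHG = 1, CHH = 1),
                    ctx_beta_hi = list(CG = c(8e4, 2e4), CHG = c(8e4, 2e4),
                                       CHH = c(8e4, 2e4)),  # p ~ 0.8
                    n_dmr_windows = 0L, asmg_fraction = 0, seed = 8L)
  gen2 <- simulateGenomes(cfg2)
  meth2 <- simulateMethylomes(gen2$bundle, cfg2, gen2$pair_truth,
                              gen2$slot_map, phases = "LE")
  rec2 <- meth2$samples[["LE_r1"]]
  expected <- 0.8 * (1 - 0.005) + 0.2 * 0.005
  expect_equal(sum(rec2$mC) / sum(rec2$mC + rec2$uC), expected,
               tolerance = 0.01)
  ## phase factors 1 and no offsets -> empty DMR truth
  expect_equal(nrow(meth2$dmr_truth), 0L)
  ## unknown phase label rejected
  expect_error(simulateMethylomes(gen2$bundle, cfg2, gen2$pair_truth,
                                  gen2$slot_map, phases = "XX"), "phase")
})

test_that("allele methylomes are exchangeable without allelic offsets", {
  cfg <- SimConfig(n_gene_pairs = 30L, n_chromosomes = 1L,
                   asmg_fraction = 0, n_dmr_windows = 0L, snp_rate = 0.01,
                   seed = 9L)
  gen <- simulateGenomes(cfg)
  meth <- simulateMethylomes(gen$bundle, cfg, gen$pair_truth, gen$slot_map,
                             phases = "LE")
  ## gene-level levels per allele should be tightly coupled
  rec <- do.call(c, lapply(meth$samples, function(x) x))  # pool 3 reps
  genes <- geneModels(gen$bundle)
  lev <- vapply(genes$gene_id, function(gid) {
    g <- genes[genes$gene_id == gid]
    sub <- meth$samples[["LE_r1"]]
    sub <- sub[IRanges::overlapsAny(sub, g, ignore.strand = TRUE)]
    sum(sub$mC) / sum(sub$mC + sub$uC)
  }, numeric(1))
  m <- lev[gen$pair_truth$maternal_id]
  p_ <- lev[gen$pair_truth$paternal_id]
  expect_gt(cor(m, p_), 0.95)
  expect_lt(abs(mean(m - p_)), 0.02)
})

test_that("expression simulation matches its closed forms and truth", {
  cfg <- SimConfig(n_gene_pairs = 200L, n_chromosomes = 1L,
                   aseg_fraction = 0, phase_dep_fraction = 0,
                   silent_fraction = 0, seed = 10L)
  gen <- simulateGenomes(cfg)
  ex <- simulateExpression(gen$pair_truth, cfg)
  expect_true(all(ex$phase_log2fc == 0))   # no ASEGs -> all true log2FC 0
  ## designated pair with log2FC 2 at mu 100: allele means 200 and 50
  cfg2 <- SimConfig(n_gene_pairs = 300L, n_chromosomes = 1L,
                    aseg_fraction = 1, aseg_log2fc_range = c(2, 2),
                    phase_dep_fraction = 0, silent_fraction = 0,
                    mu_meanlog = log(100), mu_sdlog = 1e-9,
                    library_size_range = c(1, 1), seed = 11L)
  gen2 <- simulateGenomes(cfg2)
  ex2 <- simulateExpression(gen2$pair_truth, cfg2)
  up <- ex2$aseg_truth$log2_fc > 0
  m_mean <- rowMeans(ex2$maternal)
  expect_equal(mean(m_mean[up]), 200, tolerance = 0.05)
  expect_equal(mean(m_mean[!up]), 50, tolerance = 0.05)
  ## same seed -> identical tables
  ex3 <- simulateExpression(gen2$pair_truth, cfg2)
  expect_identical(ex2$maternal, ex3$maternal)
  expect_error(simulateExpression(gen2$pair_truth,
                                  SimConfig(dispersion = 0)), "dispersion")
})

test_that("downstream DMR recall is monotone in the simulated offset", {
  recalls <- vapply(c(0.12, 0.25, 0.45), function(off) {
    cfg <- SimConfig(n_gene_pairs = 40L, n_chromosomes = 1L,
                     n_dmr_windows = 25L, dmr_offset = off,
                     asmg_fraction = 0, seed = 12L)
    gen <- simulateGenomes(cfg)
    meth <- simulateMethylomes(gen$bundle, cfg, gen$pair_truth,
                               gen$slot_map, phases = c("LE", "DP1"))
    sizes <- setNames(Biostrings::width(genomeSequences(gen$bundle)),
                      names(genomeSequences(gen$bundle)))
    bins <- makeSlidingBins(sizes)
    le <- lapply(paste0("LE_r", 1:3), function(n) meth$samples[[n]])
    dp <- lapply(paste0("DP1_r", 1:3), function(n) meth$samples[[n]])
    tw <- meth$dmr_truth[context == "CG"]
    bc_all <- binCounts(c(le, dp), bins, "CG")
    g1 <- list(mC = bc_all$mC[, 1:3], uC = bc_all$uC[, 1:3])
    g2 <- list(mC = bc_all$mC[, 4:6], uC = bc_all$uC[, 4:6])
    d <- testDmr(g1, g2, "CG", bins = bc_all$bins)
    sig <- d[dmr == TRUE]
    if (nrow(tw) == 0L) return(NA_real_)
    found <- GRanges(sig$chrom, IRanges(sig$start, sig$end))
    mean(IRanges::overlapsAny(GRanges(tw$chrom, IRanges(tw$start, tw$end)),
                              found))
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_gt(recalls[3], recalls[1])
})
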