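## End-to-end run on a synthetic configuration: simulate the hybrid system,
## then exercise every analysis stage and write one TSV per result table
## under a run directory. Deterministic given (config, seed): a repeated run
## produces byte-identical tables.

#' Run the full synthetic analysis pipeline
#'
#' Simulates genomes, promoter motifs, methylomes and allele expression from
#' one seed, then runs: per-sample methylome summaries; metagene/TE
#' profiles; sliding-window DMR calling over the successive phase contrasts
#' (LE-DP1, DP1-DP2, LE-IP1, IP1-IP2, IP2-IP3) with DMG annotation,
#' STEM-style clustering and toy gene-set enrichment; TPM, DEG and
#' expression classes with class-wise methylation comparison and bin-level
#' methylation-expression correlation; allele pairing from sequence;
#' per-phase and phase-dependent ASE with consistency classes and PCA;
#' per-phase ASMR calling with ASMG summary, bias-shift fraction and the
#' ASMR-count comparison; promoter TFBS scanning with cosine-similarity
#' classes, class-wise expression correlation and TFBS methylation levels.
#' Ground-truth recovery rates (DMR/ASE/ASMR recall, allele-pair recovery)
#' are computed against the generator's truth tables.
#'
#' @param config A [SimConfig-class] (defaults to `SimConfig()`).
#' @param outdir Run directory for result TSVs (created); `NULL` skips
#'   writing.
#' @param seed Master seed; all stage seeds derive from it.
#' @param stem_permutations Permutations for the profile clustering
#'   (default 200).
#' @return Invisibly, a list with every result table (see the TSVs written).
#' @export
runPipeline <- function(config = SimConfig(), outdir = NULL, seed = 1L,
                        stem_permutations = 200L) {
  t0 <- Sys.time()
  p <- simParams(config)
  res <- list(seed = seed)

  ## ---- simulation ----
  gen <- simulateGenomes(config, seed = seed)
  expr <- simulateExpression(gen$pair_truth, config, seed = seed + 2L)
  dep_pairs <- expr$aseg_truth[phase_dependent == TRUE]$maternal_id
  motifs <- toyMotifLibrary()
  pm <- placeMotifs(gen$bundle, gen$pair_truth, config, motifs,
                    flip_pairs = dep_pairs, seed = seed + 3L)
  bundle <- pm$bundle
  genes <- geneModels(bundle)
  pair_truth <- gen$pair_truth
  res$pair_truth <- pair_truth
  res$aseg_truth <- expr$aseg_truth

  ## ---- precomputed maps over the fixed site set ----
  sites0 <- bundleCytosineSites(bundle)
  site_gr <- GRanges(sites0$chrom, IRanges(sites0$pos, width = 1L))
  chrom_sizes <- setNames(Biostrings::width(genomeSequences(bundle)),
                          names(genomeSequences(bundle)))
  slid_bins <- makeSlidingBins(chrom_sizes)
  sch <- geneBinSchemes(genes)         # 80-bin scheme for every allele
  n_sch <- length(sch)
  ctx_rows <- split(seq_len(nrow(sites0)), sites0$context)
  maps <- lapply(CONTEXTS, function(ctx) {
    rows <- ctx_rows[[ctx]]
    sub <- site_gr[rows]
    ovb <- findOverlaps(sub, slid_bins, ignore.strand = TRUE)
    ovs <- findOverlaps(sub, sch, ignore.strand = TRUE)
    list(rows = rows,
         bin_site = rows[queryHits(ovb)], bin_idx = subjectHits(ovb),
         sch_site = rows[queryHits(ovs)], sch_idx = subjectHits(ovs),
         bin_ncy = tabulate(subjectHits(ovb), length(slid_bins)),
         sch_ncy = tabulate(subjectHits(ovs), n_sch))
  })
  names(maps) <- CONTEXTS

  ## ---- methylome simulation with on-the-fly aggregation ----
  nrep <- p$n_reps_meth
  sample_names <- as.vector(t(outer(METH_PHASES, paste0("_r", seq_len(nrep)),
                                    paste0)))
  agg <- new.env()
  agg$global <- list()
  agg$slid_m <- lapply(CONTEXTS, function(x)
    matrix(0, length(slid_bins), length(sample_names),
           dimnames = list(NULL, sample_names)))
  agg$slid_u <- lapply(CONTEXTS, function(x)
    matrix(0, length(slid_bins), length(sample_names),
           dimnames = list(NULL, sample_names)))
  agg$sch_m <- lapply(CONTEXTS, function(x)
    matrix(0, n_sch, length(sample_names),
           dimnames = list(NULL, sample_names)))
  agg$sch_u <- lapply(CONTEXTS, function(x)
    matrix(0, n_sch, length(sample_names),
           dimnames = list(NULL, sample_names)))
  names(agg$slid_m) <- names(agg$slid_u) <- CONTEXTS
  names(agg$sch_m) <- names(agg$sch_u) <- CONTEXTS
  agg$pool_m <- lapply(METH_PHASES, function(x) numeric(nrow(sites0)))
  agg$pool_u <- lapply(METH_PHASES, function(x) numeric(nrow(sites0)))
  names(agg$pool_m) <- names(agg$pool_u) <- METH_PHASES
  sumBy2 <- function(m, u, grp, nbins) {
    s <- rowsum(cbind(m, u), grp)
    out <- matrix(0, nbins, 2L)
    out[as.integer(rownames(s)), ] <- s
    out
  }
  cb <- function(ph, r, rec) {
    nm <- paste0(ph, "_r", r)
    gs <- globalSummary(rec, non_conversion = p$non_conversion)
    gs[, sample := nm]
    gs[, phase := ph]
    agg$global[[nm]] <- gs
    mC <- rec$mC
    uC <- rec$uC
    for (ctx in CONTEXTS) {
      mp <- maps[[ctx]]
      s <- sumBy2(mC[mp$bin_site], uC[mp$bin_site], mp$bin_idx,
                  length(slid_bins))
      agg$slid_m[[ctx]][, nm] <- s[, 1]
      agg$slid_u[[ctx]][, nm] <- s[, 2]
      s <- sumBy2(mC[mp$sch_site], uC[mp$sch_site], mp$sch_idx, n_sch)
      agg$sch_m[[ctx]][, nm] <- s[, 1]
      agg$sch_u[[ctx]][, nm] <- s[, 2]
    }
    agg$pool_m[[ph]] <- agg$pool_m[[ph]] + mC
    agg$pool_u[[ph]] <- agg$pool_u[[ph]] + uC
    invisible(NULL)
  }
  meth <- simulateMethylomes(bundle, config, pair_truth, gen$slot_map,
                             seed = seed + 1L, sample_callback = cb)
  res$dmr_truth <- meth$dmr_truth
  res$asmr_truth <- meth$asmr_truth
  res$global_summary <- rbindlist(agg$global)

  pooledRecords <- function(ph) {
    gr <- site_gr
    gr$mC <- as.integer(agg$pool_m[[ph]])
    gr$uC <- as.integer(agg$pool_u[[ph]])
    gr$context <- sites0$context
    gr
  }

  ## ---- metagene / TE profiles (pooled replicates, LE and DP1) ----
  tes <- teAnnotation(bundle)
  te_bins <- list()
  if (length(tes)) {
    for (cl in sort(unique(tes$te_class))) {
      sel <- tes[tes$te_class == cl]
      sel$name <- paste0(cl, "_", seq_along(sel))
      te_bins[[cl]] <- tryCatch(
        list(features = sel, bins = suppressWarnings(geneBinSchemes(sel))),
        error = function(e) NULL)
    }
  }
  prof <- list()
  for (ph in c("LE", "DP1")) {
    recs <- pooledRecords(ph)
    for (ctx in CONTEXTS) {
      prof[[length(prof) + 1L]] <-
        metageneProfile(genes, recs, ctx, bins = sch)[
          , `:=`(phase = ph, context = ctx, feature_type = "gene")]
      for (cl in names(te_bins)) {
        tb <- te_bins[[cl]]
        if (is.null(tb) || !length(tb$bins)) next
        pr <- tryCatch(metageneProfile(tb$features, recs, ctx,
                                       bins = tb$bins),
                       error = function(e) NULL)
        if (!is.null(pr))
          prof[[length(prof) + 1L]] <-
            pr[, `:=`(phase = ph, context = ctx, feature_type = cl)]
      }
    }
  }
  res$metagene_profiles <- rbindlist(prof)

  ## ---- DMR calling over successive phase contrasts ----
  contrasts <- list(c("LE", "DP1"), c("DP1", "DP2"), c("LE", "IP1"),
                    c("IP1", "IP2"), c("IP2", "IP3"))
  repcols <- function(ph) paste0(ph, "_r", seq_len(nrep))
  dmr_all <- list()
  for (ct in contrasts) {
    for (ctx in CONTEXTS) {
      keep <- maps[[ctx]]$bin_ncy >= 5L
      g1 <- list(mC = agg$slid_m[[ctx]][keep, repcols(ct[1]), drop = FALSE],
                 uC = agg$slid_u[[ctx]][keep, repcols(ct[1]), drop = FALSE])
      g2 <- list(mC = agg$slid_m[[ctx]][keep, repcols(ct[2]), drop = FALSE],
                 uC = agg$slid_u[[ctx]][keep, repcols(ct[2]), drop = FALSE])
      d <- testDmr(g1, g2, ctx, bins = slid_bins[keep])
      d[, contrast := paste0(ct[1], "_vs_", ct[2])]
      dmr_all[[length(dmr_all) + 1L]] <- d
    }
  }
  dmr_all <- rbindlist(dmr_all)
  res$dmr <- dmr_all[dmr == TRUE]
  res$dmr_counts <- dmr_all[, .(n_tested = .N, n_dmr = sum(dmr)),
                            by = .(contrast, context)]

  ## truth recovery on the LE vs DP1 contrast (offsets act from DP1 on)
  truth_gr <- GRanges(meth$dmr_truth$chrom,
                      IRanges(meth$dmr_truth$start, meth$dmr_truth$end),
                      context = meth$dmr_truth$context)
  rec_tab <- rbindlist(lapply(CONTEXTS, function(ctx) {
    tw <- truth_gr[truth_gr$context == ctx]
    if (!length(tw)) return(NULL)
    found <- dmr_all[dmr == TRUE & context == ctx &
                       contrast == "LE_vs_DP1"]
    if (nrow(found)) {
      fg <- GRanges(found$chrom, IRanges(found$start, found$end))
      hit <- IRanges::overlapsAny(tw, fg)
    } else hit <- rep(FALSE, length(tw))
    data.table(context = ctx, n_truth = length(tw), n_found = sum(hit),
               recall = mean(hit))
  }))
  res$dmr_recall <- rec_tab

  ## ---- DMG annotation + enrichment ----
  ann <- annotateDmg(res$dmr, genes)
  res$dmg <- ann$dmgs
  res$dmr_feature_fractions <- ann$feature_fractions
  set.seed(seed + 4L)
  universe <- genes$gene_id
  toy_sets <- lapply(seq_len(10L), function(i)
    sample(universe, min(40L, length(universe))))
  names(toy_sets) <- sprintf("SET%02d", seq_len(10L))
  if (nrow(ann$dmgs) >= 10L)
    toy_sets$SET_DMG <- sample(ann$dmgs$gene_id,
                               min(40L, nrow(ann$dmgs)))
  res$enrichment <- enrichGeneSets(ann$dmgs$gene_id, universe, toy_sets)

  ## ---- STEM-style clustering of DMR level series ----
  stem_out <- list()
  series_sets <- list(direct = c("LE", "DP1", "DP2"),
                      indirect = c("LE", "IP1", "IP2", "IP3"))
  for (nm in names(series_sets)) {
    phs <- series_sets[[nm]]
    for (ctx in CONTEXTS) {
      sig <- unique(dmr_all[dmr == TRUE & context == ctx &
                              contrast %in% c("LE_vs_DP1", "DP1_vs_DP2",
                                              "LE_vs_IP1", "IP1_vs_IP2",
                                              "IP2_vs_IP3")]$bin_id)
      idx <- which(slid_bins$bin_id %in% sig)
      if (length(idx) < 10L) next
      lev <- vapply(phs, function(ph) {
        m <- rowSums(agg$slid_m[[ctx]][idx, repcols(ph), drop = FALSE])
        u <- rowSums(agg$slid_u[[ctx]][idx, repcols(ph), drop = FALSE])
        m / pmax(m + u, 1)
      }, numeric(length(idx)))
      st <- stemCluster(lev, n_permutations = stem_permutations,
                        seed = seed + 5L)
      tab <- st$profile_stats
      tab[, `:=`(series = nm, context = ctx)]
      stem_out[[length(stem_out) + 1L]] <- tab[n_assigned > 0]
    }
  }
  res$stem_profiles <- rbindlist(stem_out)

  ## ---- expression: TPM, DEG, classes ----
  counts_alleles <- rbind(expr$maternal, expr$paternal)
  lens <- setNames(genes$exon_length, genes$gene_id)[rownames(counts_alleles)]
  tpm_alleles <- tpm(counts_alleles, lens)
  res$tpm <- data.table(gene_id = rownames(tpm_alleles),
                        as.data.table(tpm_alleles))
  deg_out <- list()
  for (ph in setdiff(EXPR_PHASES, "LE")) {
    cols <- c(paste0("LE_r", seq_len(p$n_reps_expr)),
              paste0(ph, "_r", seq_len(p$n_reps_expr)))
    td <- testDeg(counts_alleles[, cols],
                  rep(c("LE", ph), each = p$n_reps_expr))
    td$results[, contrast := paste0("LE_vs_", ph)]
    deg_out[[ph]] <- td$results
  }
  res$deg <- rbindlist(deg_out)

  ## per-phase replicate-mean TPM over the WGBS phases
  phase_tpm <- vapply(METH_PHASES, function(ph)
    rowMeans(tpm_alleles[, paste0(ph, "_r", seq_len(p$n_reps_expr)),
                         drop = FALSE]), numeric(nrow(tpm_alleles)))
  res$tpm_classes <- data.table(gene_id = rownames(phase_tpm),
                                class = tpmClasses(phase_tpm[, "LE"]))

  ## ---- class-wise methylation comparison (LE, per zone x context) ----
  zone_of <- sch$zone
  feat_of <- sch$feature_id
  cmp_rows <- list()
  le_cols <- repcols("LE")
  for (ctx in CONTEXTS) {
    m_le <- rowSums(agg$sch_m[[ctx]][, le_cols, drop = FALSE])
    u_le <- rowSums(agg$sch_u[[ctx]][, le_cols, drop = FALSE])
    dt <- data.table(gene_id = feat_of, zone = zone_of, m = m_le, u = u_le)
    reg <- dt[, .(level = ifelse(sum(m + u) > 0, sum(m) / sum(m + u),
                                 NA_real_)), by = .(gene_id, zone)]
    for (z in c("upstream", "body", "downstream")) {
      sub <- reg[zone == z]
      cls <- res$tpm_classes[match(sub$gene_id, gene_id)]$class
      cmp <- tryCatch(classMethylationComparison(cls, sub$level),
                      error = function(e) NULL)
      if (!is.null(cmp)) {
        lt <- cmp$letters
        lt[, `:=`(context = ctx, zone = z)]
        cmp_rows[[length(cmp_rows) + 1L]] <- lt
      }
    }
  }
  res$class_methylation <- rbindlist(cmp_rows)

  ## ---- bin-level methylation-expression correlation ----
  corr_rows <- list()
  sign_rows <- list()
  for (ctx in CONTEXTS) {
    lev <- vapply(METH_PHASES, function(ph) {
      m <- rowSums(agg$sch_m[[ctx]][, repcols(ph), drop = FALSE])
      u <- rowSums(agg$sch_u[[ctx]][, repcols(ph), drop = FALSE])
      ifelse(m + u > 0, m / (m + u), NA_real_)
    }, numeric(n_sch))
    bc <- binExpressionCorrelation(lev, feat_of, sch$bin, phase_tpm,
                                   context = ctx)
    corr_rows[[ctx]] <- bc$records[significant == TRUE]
    gs <- bc$gene_summary[n_significant_bins > 0]
    sign_rows[[ctx]] <- data.table(
      context = ctx, n_genes_significant = nrow(gs),
      n_negative = sum(gs$sign == "negative"),
      n_positive = sum(gs$sign == "positive"),
      frac_negative = if (nrow(gs)) mean(gs$sign == "negative") else NA_real_)
  }
  res$bin_correlation <- rbindlist(corr_rows)
  res$correlation_sign_summary <- rbindlist(sign_rows)

  ## ---- allele pairing ----
  pairs <- findAllelePairs(bundle)
  res$allele_pairs <- pairs
  truth_key <- paste(pair_truth$maternal_id, pair_truth$paternal_id)
  found_key <- paste(pairs$maternal_id, pairs$paternal_id)
  res$pair_recovery <- data.table(
    n_truth = nrow(pair_truth), n_found = nrow(pairs),
    n_correct = sum(found_key %in% truth_key),
    recall = sum(found_key %in% truth_key) / nrow(pair_truth),
    false_pairs = sum(!found_key %in% truth_key))

  ## ---- ASE ----
  m_of <- expr$maternal[pairs$maternal_id, , drop = FALSE]
  p_of <- expr$paternal[pairs$paternal_id, , drop = FALSE]
  sf_all <- sizeFactors(rbind(m_of, p_of))
  ase_rows <- list()
  for (ph in EXPR_PHASES) {
    cols <- paste0(ph, "_r", seq_len(p$n_reps_expr))
    ase_rows[[ph]] <- testAsePerPhase(m_of[, cols, drop = FALSE],
                                      p_of[, cols, drop = FALSE],
                                      phase = ph, sf = sf_all[cols])
  }
  ase <- rbindlist(ase_rows)
  res$ase <- ase
  res$ase_consistency <- classifyConsistency(ase)
  phase_assign <- sub("_r[0-9]+$", "", colnames(m_of))
  res$phase_ase <- testPhaseDependentAse(m_of, p_of, phase_assign,
                                         baseline = "LE", sf = sf_all)
  dep_detected <- unique(res$phase_ase[phase_dependent == TRUE]$pair)
  res$phase_ase_summary <- data.table(
    n_pairs_tested = length(unique(res$phase_ase$pair)),
    n_phase_dependent = length(dep_detected))
  ## ASE truth recovery at the per-phase level
  truth_fc <- expr$phase_log2fc
  ase_truth_eval <- ase[, {
    tl <- truth_fc[pair, phase]
    list(true_l2fc = tl)
  }, by = .(pair, phase, log2_fc, bias)]
  res$ase_recall <- ase_truth_eval[abs(true_l2fc) > 1,
                                   .(n_true = .N,
                                     n_called = sum(bias != "none"),
                                     recall = mean(bias != "none"))]
  ## PCA of allele expression
  lt <- log2(tpm_alleles + 1)
  parent <- ifelse(rownames(lt) %in% pair_truth$maternal_id, "maternal",
                   "paternal")
  res$pca <- allelePca(lt, parent)$scores

  ## ---- ASMR ----
  sch_dt <- data.table(row = seq_len(n_sch), gene_id = feat_of,
                       bin = sch$bin)
  mrow <- sch_dt[match(paste(rep(pairs$maternal_id, each = 80L),
                             rep(1:80, nrow(pairs))),
                       paste(gene_id, bin))]$row
  prow <- sch_dt[match(paste(rep(pairs$paternal_id, each = 80L),
                             rep(1:80, nrow(pairs))),
                       paste(gene_id, bin))]$row
  unit_pair <- rep(pairs$maternal_id, each = 80L)
  unit_bin <- rep(1:80, nrow(pairs))
  ok_unit <- !is.na(mrow) & !is.na(prow)
  asmr_rows <- list()
  for (ph in METH_PHASES) {
    cols <- repcols(ph)
    for (ctx in CONTEXTS) {
      keep <- ok_unit & maps[[ctx]]$sch_ncy[mrow] >= 5L &
        maps[[ctx]]$sch_ncy[prow] >= 5L
      keep[is.na(keep)] <- FALSE
      mm <- list(mC = agg$sch_m[[ctx]][mrow[keep], cols, drop = FALSE],
                 uC = agg$sch_u[[ctx]][mrow[keep], cols, drop = FALSE])
      pp <- list(mC = agg$sch_m[[ctx]][prow[keep], cols, drop = FALSE],
                 uC = agg$sch_u[[ctx]][prow[keep], cols, drop = FALSE])
      asmr_rows[[length(asmr_rows) + 1L]] <-
        testAsmr(mm, pp, unit_pair[keep], unit_bin[keep], ctx, phase = ph)
    }
  }
  asmr <- rbindlist(asmr_rows)
  res$asmr <- asmr[asmr == TRUE]
  res$asmr_counts <- asmr[, .(n_tested = .N, n_asmr = sum(asmr)),
                          by = .(phase, context)]
  res$asmg <- asmgTable(asmr)
  res$bias_shift <- biasShiftFraction(asmr)
  ## truth recovery (any phase)
  at <- meth$asmr_truth
  if (nrow(at)) {
    at_units <- at[, .(pair = maternal_id, context,
                       bin = seq(first_bin, last_bin)), by = .(row = .I)]
    sig_key <- unique(asmr[asmr == TRUE, paste(pair, context, bin)])
    res$asmr_recall <- at_units[, .(
      n_truth_bins = .N,
      n_found = sum(paste(pair, context, bin) %in% sig_key)),
      by = context][, recall := n_found / n_truth_bins][]
  } else res$asmr_recall <- data.table()
  ## ASMR-count comparison: detected phase-dependent ASEGs vs other ASMGs
  asmg_pairs <- unique(res$asmg$pair)
  g1 <- intersect(dep_detected, asmg_pairs)
  g2 <- setdiff(asmg_pairs, dep_detected)
  res$asmr_count_comparison <- if (length(g1) && length(g2))
    asmrCountComparison(res$asmg, g1, g2,
                        group_names = c("phase_dependent", "other_asmgs"))
  else data.table()

  ## ---- TFBS / cosine similarity ----
  proms <- promoterSeqs(bundle, genes)
  bg <- promoterBackground(proms)
  hits <- scanMotifLibrary(proms, motifs, background = bg)
  res$tfbs_hits <- hits
  vecs <- promoterVectors(hits, names(proms), names(motifs))
  res$cs <- pairCosineSimilarity(vecs, pairs)
  res$cs_class_counts <- res$cs[, .N, by = cs_class][order(cs_class)]
  expr_mean <- rowMeans(log2(tpm_alleles + 1))
  res$cs_expression_correlation <- classExpressionCorrelation(
    res$cs, expr_mean[pairs$maternal_id], expr_mean[pairs$paternal_id],
    group2_pairs = dep_detected)
  widths <- vapply(motifs, ncol, integer(1))
  tm <- tfbsMethylation(hits, attr(proms, "promoter_ranges"),
                        pooledRecords("LE"),
                        widths)
  res$tfbs_methylation <- tm$summary
  res$tfbs_methylation_per_hit <- tm$per_hit[
    , .(seq, motif, pos, strand, weighted_level, n_cytosines)]

  res$run_info <- data.table(
    parameter = c("package_version", "r_version", "seed", "n_gene_pairs",
            "n_chromosomes", "coverage_mean", "elapsed_sec"),
    value = c(as.character(packageVersion("alleleMeth")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.character(seed), as.character(p$n_gene_pairs),
              as.character(p$n_chromosomes), as.character(p$coverage_mean),
              sprintf("%.1f", as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")))))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writable <- c("global_summary", "metagene_profiles", "dmr", "dmr_counts",
                  "dmr_recall", "dmg", "dmr_feature_fractions", "enrichment",
                  "stem_profiles", "tpm", "deg", "tpm_classes",
                  "class_methylation", "bin_correlation",
                  "correlation_sign_summary", "allele_pairs",
                  "pair_recovery", "ase", "ase_consistency", "phase_ase",
                  "phase_ase_summary", "ase_recall", "pca", "asmr",
                  "asmr_counts", "asmg", "bias_shift", "asmr_recall",
                  "asmr_count_comparison", "tfbs_hits", "cs",
                  "cs_class_counts", "cs_expression_correlation",
                  "tfbs_methylation", "tfbs_methylation_per_hit",
                  "dmr_truth", "asmr_truth", "pair_truth", "aseg_truth",
                  "run_info")
    for (nm in writable) {
      x <- res[[nm]]
      if (is.null(x) || !is.data.frame(x)) next
      fwrite(x, file.path(outdir, paste0(nm, ".tsv")), sep = "\t",
             quote = FALSE)
    }
  }
  invisible(res)
}
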