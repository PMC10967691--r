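## Synthetic diploid-hybrid generator: two collinear subgenomes with
## diverged allele pairs, phase-structured replicate methylomes, NB
## allele-resolved expression with configurable phase-dependent bias, and
## motif-divergent promoters -- each with complete ground-truth tables, so
## every downstream stage is testable without external data.

DNA_BASES <- c("A", "C", "G", "T")

randomDnaVec <- function(n) sample(DNA_BASES, n, replace = TRUE)

## Substitute bases at the given per-base rate (always to a different base).
mutateVec <- function(v, rate) {
  if (rate <= 0) return(v)
  n <- rbinom(1L, length(v), rate)
  if (n == 0L) return(v)
  idx <- sample.int(length(v), n)
  old <- match(v[idx], DNA_BASES)
  v[idx] <- DNA_BASES[(old + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L]
  v
}

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Simulate the two-subgenome hybrid genome
#'
#' Gene pairs are placed collinearly (identical order on homologous
#' chromosomes) except a configurable fraction of relocated pairs whose
#' order is cyclically permuted within the paternal chromosome (exercising
#' the BBH/orthology fallback of allele pairing). Each pair occupies a
#' "slot" (intergenic gap + 2-kb flank + gene body + 2-kb flank) of
#' identical length on both subgenomes; paternal slot sequences derive from
#' the maternal ones by substitution at the SNP divergence rate. TEs are
#' placed in intergenic gaps at homologous positions on both subgenomes.
#'
#' @param config A [SimConfig-class].
#' @param seed Seed (default: the config's seed).
#' @return List: `bundle` ([GenomeBundle-class]), `pair_truth` (data.table
#'   maternal_id, paternal_id, strand, gene_length, relocated) and
#'   `slot_map` (per pair and subgenome, the slot's chromosome span; allele
#'   positions correspond through equal within-slot offsets).
#' @export
simulateGenomes <- function(config, seed = simParam(config, "seed")) {
  p <- simParams(config)
  set.seed(seed)
  sgs <- names(p$subgenomes)
  npairs <- p$n_gene_pairs
  nchrom <- p$n_chromosomes
  chrom_of <- sort(rep(seq_len(nchrom), length.out = npairs))
  glen <- pmin(pmax(round(rlnorm(npairs, p$gene_length_meanlog,
                                 p$gene_length_sdlog)),
                    p$gene_length_range[1]), p$gene_length_range[2])
  gaps <- round(runif(npairs, p$intergenic_range[1], p$intergenic_range[2]))
  strands <- sample(c("+", "-"), npairs, replace = TRUE)
  flank <- p$promoter_length
  slot_len <- gaps + 2L * flank + glen
  if (!is.null(p$max_chromosome_length) && !is.na(p$max_chromosome_length)) {
    per <- tapply(slot_len, chrom_of, sum)
    if (any(per > p$max_chromosome_length))
      stop("infeasible packing: genes and promoters exceed chromosome length")
  }
  ## TE placement inside gaps, shared across subgenomes
  te_len <- round(runif(npairs, p$te_length_range[1], p$te_length_range[2]))
  te_has <- runif(npairs) < p$te_density & gaps >= te_len + 20L
  te_at <- ifelse(te_has, floor(runif(npairs) * (gaps - te_len)) + 1L, NA_integer_)
  te_class <- sample(names(p$te_class_mix), npairs, replace = TRUE,
                     prob = p$te_class_mix)
  relocated <- rep(FALSE, npairs)
  if (p$relocation_fraction > 0) {
    for (ch in seq_len(nchrom)) {
      on_ch <- which(chrom_of == ch)
      k <- round(length(on_ch) * p$relocation_fraction)
      if (k >= 2L) relocated[sample(on_ch, k)] <- TRUE
    }
  }
  slots <- lapply(slot_len, randomDnaVec)
  mat_id <- sprintf("%s_g%04d", sgs[1], seq_len(npairs))
  pat_id <- sprintf("%s_g%04d", sgs[2], seq_len(npairs))
  gene_ids <- cbind(mat_id, pat_id)
  seqs <- list()
  gene_rows <- list()
  te_rows <- list()
  slot_rows <- list()
  subgenomeOf <- character()
  for (si in 1:2) {
    sg <- sgs[si]
    for (ch in seq_len(nchrom)) {
      on_ch <- which(chrom_of == ch)
      order_ch <- on_ch
      if (si == 2L) {
        rel <- on_ch[relocated[on_ch]]
        if (length(rel) >= 2L) {
          perm <- c(rel[-1], rel[1])  # cyclic shift
          order_ch[match(rel, on_ch)] <- perm
        }
      }
      chrom <- paste0(sg, "_chr", ch)
      subgenomeOf[chrom] <- sg
      offset <- 0L
      parts <- vector("list", length(order_ch))
      for (k in seq_along(order_ch)) {
        i <- order_ch[k]
        v <- slots[[i]]
        if (si == 2L) v <- mutateVec(v, p$snp_rate)
        parts[[k]] <- v
        gs <- offset + gaps[i] + flank + 1L
        gene_rows[[length(gene_rows) + 1L]] <- data.table(
          chrom = chrom, start = gs, end = gs + glen[i] - 1L,
          strand = strands[i], gene_id = gene_ids[i, si], subgenome = sg)
        slot_rows[[length(slot_rows) + 1L]] <- data.table(
          pair = i, subgenome = sg, chrom = chrom,
          slot_start = offset + 1L, slot_end = offset + slot_len[i])
        if (te_has[i])
          te_rows[[length(te_rows) + 1L]] <- data.table(
            chrom = chrom, start = offset + te_at[i],
            end = offset + te_at[i] + te_len[i] - 1L,
            te_class = te_class[i], subgenome = sg)
        offset <- offset + slot_len[i]
      }
      seqs[[chrom]] <- paste(unlist(parts), collapse = "")
    }
  }
  genes_dt <- rbindlist(gene_rows)
  tes_dt <- rbindlist(te_rows)
  sequences <- DNAStringSet(unlist(seqs))
  genes <- GRanges(genes_dt$chrom, IRanges(genes_dt$start, genes_dt$end),
                   strand = genes_dt$strand, gene_id = genes_dt$gene_id,
                   subgenome = genes_dt$subgenome,
                   exon_length = genes_dt$end - genes_dt$start + 1L)
  tes <- if (nrow(tes_dt)) GRanges(tes_dt$chrom,
                                   IRanges(tes_dt$start, tes_dt$end),
                                   te_class = tes_dt$te_class,
                                   subgenome = tes_dt$subgenome) else GRanges()
  bundle <- GenomeBundle(sequences = sequences, genes = genes, tes = tes,
                         subgenomeOf = subgenomeOf, parentOf = p$subgenomes)
  pair_truth <- data.table(maternal_id = mat_id, paternal_id = pat_id,
                           strand = strands, gene_length = glen,
                           relocated = relocated)
  list(bundle = bundle, pair_truth = pair_truth,
       slot_map = rbindlist(slot_rows))
}

## All cytosine sites (both strands) of a chromosome character vector.
cytosineSitesVec <- function(v) {
  L <- length(v)
  nxt1 <- c(v[-1L], "N")
  nxt2 <- if (L > 2L) c(v[-(1:2)], "N", "N") else rep("N", L)
  prv1 <- c("N", v[-L])
  prv2 <- if (L > 2L) c("N", "N", v[seq_len(L - 2L)]) else rep("N", L)
  cp <- which(v == "C")
  cm <- which(v == "G")
  ctx_p <- ifelse(nxt1[cp] == "G", "CG",
                  ifelse(nxt2[cp] == "G", "CHG", "CHH"))
  ctx_m <- ifelse(prv1[cm] == "C", "CG",
                  ifelse(prv2[cm] == "C", "CHG", "CHH"))
  data.table(pos = c(cp, cm),
             strand = rep(c("+", "-"), c(length(cp), length(cm))),
             context = c(ctx_p, ctx_m))
}

## Site table for a whole bundle with feature annotation (TE class beats
## gene body; everything else intergenic).
bundleCytosineSites <- function(bundle) {
  seqs <- genomeSequences(bundle)
  sites <- rbindlist(lapply(names(seqs), function(chrom) {
    dt <- cytosineSitesVec(strsplit(as.character(seqs[[chrom]]), "")[[1]])
    dt[, chrom := chrom]
    dt
  }))
  gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  sites[, feature := "intergenic"]
  ovg <- findOverlaps(gr, geneModels(bundle), ignore.strand = TRUE)
  sites$feature[queryHits(ovg)] <- "gene"
  tes <- teAnnotation(bundle)
  if (length(tes)) {
    ovt <- findOverlaps(gr, tes, ignore.strand = TRUE)
    sites$feature[queryHits(ovt)] <- paste0("TE_",
                                            tes$te_class[subjectHits(ovt)])
  }
  sites[]
}

## Numeric site key shared between alleles: maternal chromosome index and
## position (paternal positions are mapped through the slot table), doubled
## for strand. Exact in doubles for any desk-scale genome.
sharedSiteKeys <- function(sites, bundle, slot_map, pair_truth) {
  sgs <- c(maternalSubgenome(bundle), paternalSubgenome(bundle))
  chroms <- names(genomeSequences(bundle))
  mat_chrom <- sites$chrom
  mat_pos <- sites$pos
  pat_rows <- which(subgenomeOf(bundle)[sites$chrom] == sgs[2])
  if (length(pat_rows)) {
    ps <- slot_map[subgenome == sgs[2]]
    ms <- slot_map[subgenome == sgs[1]]
    setorder(ps, chrom, slot_start)
    m_by_pair_start <- setNames(ms$slot_start, ms$pair)
    m_by_pair_chrom <- setNames(ms$chrom, ms$pair)
    for (pc in unique(ps$chrom)) {
      rows <- pat_rows[sites$chrom[pat_rows] == pc]
      if (!length(rows)) next
      sl <- ps[chrom == pc]
      k <- findInterval(sites$pos[rows], sl$slot_start)
      mat_pos[rows] <- sites$pos[rows] - sl$slot_start[k] +
        m_by_pair_start[as.character(sl$pair[k])]
      mat_chrom[rows] <- m_by_pair_chrom[as.character(sl$pair[k])]
    }
  }
  (match(mat_chrom, chroms) * 6e8 + mat_pos) * 2 +
    (sites$strand == "+")
}

#' Simulate phase-structured replicate methylomes
#'
#' Every cytosine site receives a true methylation probability: with
#' probability `f(context, feature)` the site belongs to the methylated
#' Beta component, otherwise to the near-zero component; TE sites have `f`
#' elevated per class (SINE highest). Allele pairs share the underlying
#' random draws position-by-position through the slot map, so with no
#' configured allelic offset the two subgenomes' methylomes are
#' exchangeable. Phase effects multiply the true probability (global
#' hypomethylation at DP1/IP1, a CHH decrease-then-increase trajectory);
#' designated true DMR windows receive an additive offset from the first
#' induction phases onward, and designated ASMG genes a constant allelic
#' offset over a run of their 80-scheme bins. Observed data per replicate:
#' Beta replicate jitter around the true probability, Poisson coverage, and
#' binomial methylated counts at `p(1-e) + (1-p)e` for non-conversion error
#' `e` (simulated, never corrected downstream).
#'
#' @param bundle,pair_truth,slot_map From [simulateGenomes()].
#' @param config [SimConfig-class].
#' @param phases Phases to emit (default the six methylome phases).
#' @param seed Seed (default config seed + 1).
#' @param sample_callback Optional `function(phase, rep, records)`; when
#'   given, samples are passed one at a time and not accumulated.
#' @return List: `samples` (named list `phase_r<k>` -> cytosine GRanges;
#'   empty when a callback is used), `dmr_truth`, `asmr_truth`, `sites`
#'   (annotated site table with true base probabilities).
#' @export
simulateMethylomes <- function(bundle, config, pair_truth, slot_map,
                               phases = METH_PHASES,
                               seed = simParam(config, "seed") + 1L,
                               sample_callback = NULL) {
  p <- simParams(config)
  if (!all(phases %in% METH_PHASES)) stop("unknown methylome phase")
  set.seed(seed)
  sites <- bundleCytosineSites(bundle)
  genes <- geneModels(bundle)
  key <- sharedSiteKeys(sites, bundle, slot_map, pair_truth)
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  u_ind <- runif(sum(uniq))[idx]
  u_beta <- runif(sum(uniq))[idx]
  ## methylated-class fraction by context x feature
  f <- p$ctx_frac_meth[sites$context]
  is_te <- startsWith(sites$feature, "TE_")
  f[is_te] <- pmin(f[is_te] *
                     p$te_frac_factor[sub("^TE_", "", sites$feature[is_te])], 1)
  hi <- u_ind < f
  pb <- numeric(nrow(sites))
  for (ctx in CONTEXTS) {
    sel <- hi & sites$context == ctx
    ab <- p$ctx_beta_hi[[ctx]]
    pb[sel] <- stats::qbeta(u_beta[sel], ab[1], ab[2])
  }
  pb[!hi] <- stats::qbeta(u_beta[!hi], p$beta_lo[1], p$beta_lo[2])
  site_ctx <- sites$context
  asmr_delta <- numeric(nrow(sites))
  dmr_delta <- numeric(nrow(sites))
  site_gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  ## ASMG truth: constant allelic offsets on a run of 80-scheme bins
  asmr_truth <- data.table(pair = integer(), maternal_id = character(),
                           paternal_id = character(), context = character(),
                           target_allele = character(), first_bin = integer(),
                           last_bin = integer(), offset = numeric())
  n_asmg <- round(nrow(pair_truth) * p$asmg_fraction)
  if (n_asmg > 0L) {
    picks <- sort(sample.int(nrow(pair_truth), n_asmg))
    ## offsets sit in the promoter-proximal upstream bins (8..20), where
    ## cytosine density passes the per-bin filters in every context
    first_bin <- sample(8:16, n_asmg, replace = TRUE)
    asmr_truth <- data.table(
      pair = picks,
      maternal_id = pair_truth$maternal_id[picks],
      paternal_id = pair_truth$paternal_id[picks],
      context = sample(CONTEXTS, n_asmg, replace = TRUE),
      target_allele = sample(c("maternal", "paternal"), n_asmg,
                             replace = TRUE),
      first_bin = first_bin,
      last_bin = pmin(first_bin + p$asmr_n_bins - 1L, 20L),
      offset = p$asmr_offset)
    for (j in seq_len(n_asmg)) {
      gid <- if (asmr_truth$target_allele[j] == "maternal")
        asmr_truth$maternal_id[j] else asmr_truth$paternal_id[j]
      g <- genes[genes$gene_id == gid]
      sch <- geneBinScheme(g)
      sch <- sch[sch$bin >= asmr_truth$first_bin[j] &
                   sch$bin <= asmr_truth$last_bin[j]]
      ov <- findOverlaps(site_gr, sch, ignore.strand = TRUE)
      hit <- unique(queryHits(ov))
      hit <- hit[site_ctx[hit] == asmr_truth$context[j]]
      asmr_delta[hit] <- p$asmr_offset
    }
  }
  ## DMR truth: offset windows on the 200-bp grid, active from DP1/IP1 on
  chrom_sizes <- setNames(Biostrings::width(genomeSequences(bundle)),
                          names(genomeSequences(bundle)))
  dmr_truth <- data.table(chrom = character(), start = integer(),
                          end = integer(), context = character(),
                          direction = character(), offset = numeric())
  if (p$n_dmr_windows > 0L) {
    all_bins <- makeSlidingBins(chrom_sizes)
    cand <- all_bins[seq(1L, length(all_bins), by = 2L)]  # non-overlapping
    off <- p$dmr_offset
    ## per-window additive offset, calibrated by bisection so the realized
    ## pooled difference equals the nominal offset despite [0,1] clipping;
    ## windows where neither direction can express the offset are skipped
    calibrate <- function(pv, sign) {
      g <- function(d) mean(clip01(pv + sign * d)) - mean(pv) - sign * off
      lo <- off
      hi <- 1
      if (sign * g(hi) < 0) return(NA_real_)
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (sign * g(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    for (ctx in CONTEXTS) {
      n_w <- min(p$n_dmr_windows * 2L, length(cand))
      pick <- sort(sample.int(length(cand), n_w))
      win <- cand[pick]
      prefer_hypo <- runif(n_w) < p$dmr_hypo_fraction
      ov <- findOverlaps(site_gr, win, ignore.strand = TRUE)
      qh <- queryHits(ov)[site_ctx[queryHits(ov)] == ctx]
      sh <- subjectHits(ov)[site_ctx[queryHits(ov)] == ctx]
      rows_by_win <- split(qh, sh)
      taken <- 0L
      for (wi in seq_len(n_w)) {
        if (taken >= p$n_dmr_windows) break
        rows <- rows_by_win[[as.character(wi)]]
        if (is.null(rows) || length(rows) < 3L) next
        pv <- pb[rows]
        for (dirn in if (prefer_hypo[wi]) c("hypo", "hyper") else
             c("hyper", "hypo")) {
          sgn <- if (dirn == "hyper") 1 else -1
          d <- calibrate(pv, sgn)
          if (!is.na(d)) {
            dmr_delta[rows] <- clip01(pv + sgn * d) - pv
            dmr_truth <- rbind(dmr_truth, data.table(
              chrom = as.character(seqnames(win[wi])),
              start = start(win[wi]), end = end(win[wi]), context = ctx,
              direction = dirn, offset = off))
            taken <- taken + 1L
            break
          }
        }
      }
    }
  }
  ## emit samples
  conc <- p$replicate_concentration
  eps <- p$non_conversion
  fac <- p$phase_factors
  samples <- list()
  site_gr_out <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                         strand = sites$strand)
  n <- nrow(sites)
  ctx_i <- match(site_ctx, CONTEXTS)
  for (ph in phases) {
    ph_i <- match(ph, METH_PHASES)
    p_phase <- clip01(pb * fac[ctx_i + (ph_i - 1L) * 3L] + asmr_delta +
                        (if (ph == "LE") 0 else dmr_delta))
    for (r in seq_len(p$n_reps_meth)) {
      p_rep <- rbeta(n, p_phase * conc, (1 - p_phase) * conc)
      p_obs <- p_rep * (1 - eps) + (1 - p_rep) * eps
      cov <- rpois(n, p$coverage_mean)
      mC <- rbinom(n, cov, p_obs)
      rec <- site_gr_out
      rec$mC <- mC
      rec$uC <- cov - mC
      rec$context <- site_ctx
      nm <- paste0(ph, "_r", r)
      if (is.null(sample_callback)) samples[[nm]] <- rec
      else sample_callback(ph, r, rec)
    }
  }
  sites[, `:=`(p_base = pb, asmr_delta = asmr_delta, dmr_delta = dmr_delta)]
  list(samples = samples, dmr_truth = dmr_truth[], asmr_truth = asmr_truth[],
       sites = sites[])
}

#' Simulate allele-resolved expression counts
#'
#' Counts are negative binomial with pair-level baseline means
#' `mu ~ lognormal`; a fraction of pairs are ASEGs with allele means
#' `mu 2^(+-log2FC/2)`. Phase-dependent ASEGs either acquire their bias only
#' from a designated onset phase (absent at LE) or flip its direction there.
#' Per-sample library factors scale all means. The per-phase true log2 fold
#' change table is emitted as ground truth.
#'
#' @param pair_truth From [simulateGenomes()].
#' @param config [SimConfig-class].
#' @param phases Default: the eight expression phases.
#' @param seed Seed (default config seed + 2).
#' @return List: `maternal`/`paternal` (pairs x samples count matrices;
#'   columns `phase_r<k>`), `samples` (data.table sample, phase, rep,
#'   library_factor), `aseg_truth` (pair-level: aseg, log2_fc,
#'   phase_dependent, type, onset_phase), `phase_log2fc` (pairs x phases
#'   true log2FC matrix).
#' @export
simulateExpression <- function(pair_truth, config, phases = EXPR_PHASES,
                               seed = simParam(config, "seed") + 2L) {
  p <- simParams(config)
  set.seed(seed)
  npairs <- nrow(pair_truth)
  mu <- rlnorm(npairs, p$mu_meanlog, p$mu_sdlog)
  silent <- runif(npairs) < p$silent_fraction
  mu[silent] <- 0.02
  aseg <- runif(npairs) < p$aseg_fraction
  aseg[silent] <- FALSE
  l2fc <- ifelse(aseg,
                 sample(c(-1, 1), npairs, replace = TRUE) *
                   runif(npairs, p$aseg_log2fc_range[1],
                         p$aseg_log2fc_range[2]), 0)
  phase_dep <- runif(npairs) < p$phase_dep_fraction & !silent
  dep_type <- ifelse(phase_dep,
                     sample(c("appear", "flip"), npairs, replace = TRUE),
                     NA_character_)
  ## appearing bias needs a magnitude even for non-ASEG pairs
  dep_mag <- sample(c(-1, 1), npairs, replace = TRUE) *
    runif(npairs, p$aseg_log2fc_range[1], p$aseg_log2fc_range[2])
  onset <- sample(setdiff(phases, "LE"), npairs, replace = TRUE)
  fc <- matrix(rep(l2fc, length(phases)), npairs,
               dimnames = list(pair_truth$maternal_id, phases))
  for (i in which(phase_dep)) {
    from <- match(onset[i], phases)
    late <- seq(from, length(phases))
    if (dep_type[i] == "appear") {
      fc[i, ] <- 0
      fc[i, late] <- dep_mag[i]
    } else {
      fc[i, ] <- dep_mag[i]
      fc[i, late] <- -dep_mag[i]
    }
  }
  nr <- p$n_reps_expr
  sample_names <- as.vector(t(outer(phases, paste0("_r", seq_len(nr)),
                                    paste0)))
  libf <- runif(length(sample_names), p$library_size_range[1],
                p$library_size_range[2])
  maternal <- matrix(0L, npairs, length(sample_names),
                     dimnames = list(pair_truth$maternal_id, sample_names))
  paternal <- matrix(0L, npairs, length(sample_names),
                     dimnames = list(pair_truth$paternal_id, sample_names))
  for (j in seq_along(sample_names)) {
    ph <- sub("_r[0-9]+$", "", sample_names[j])
    mu_m <- libf[j] * mu * 2^(fc[, ph] / 2)
    mu_p <- libf[j] * mu * 2^(-fc[, ph] / 2)
    maternal[, j] <- rnbinom(npairs, mu = mu_m, size = 1 / p$dispersion)
    paternal[, j] <- rnbinom(npairs, mu = mu_p, size = 1 / p$dispersion)
  }
  samples <- data.table(sample = sample_names,
                        phase = sub("_r[0-9]+$", "", sample_names),
                        rep = as.integer(sub("^.*_r", "", sample_names)),
                        library_factor = libf)
  aseg_truth <- data.table(maternal_id = pair_truth$maternal_id,
                           paternal_id = pair_truth$paternal_id,
                           base_mu = mu, silent = silent, aseg = aseg,
                           log2_fc = l2fc,
                           phase_dependent = phase_dep, type = dep_type,
                           onset_phase = ifelse(phase_dep, onset,
                                                NA_character_))
  list(maternal = maternal, paternal = paternal, samples = samples,
       aseg_truth = aseg_truth, phase_log2fc = fc)
}

#' Embed motif instances into allele promoters
#'
#' For every pair and motif: the motif is present with the configured
#' probability, and its presence flips between the two alleles (one allele
#' only, chosen at random) with the flip probability -- elevated for
#' designated pairs (typically the phase-dependent ASEGs), coupling promoter
#' motif divergence to allelic expression divergence. Present motifs are
#' written as consensus words at non-overlapping random positions of the
#' strand-aware 2-kb promoter, modifying the chromosome sequences in place.
#'
#' @param bundle,pair_truth From [simulateGenomes()].
#' @param config [SimConfig-class].
#' @param motifs Named list of PWMs (default: the bundled toy library).
#' @param flip_pairs Maternal ids of pairs with the elevated flip
#'   probability.
#' @param seed Seed (default config seed + 3).
#' @return List: `bundle` (sequences updated), `placements` (data.table
#'   gene_id, motif, promoter_pos), `presence_truth` (list of two binary
#'   matrices, maternal and paternal, pairs x motifs).
#' @export
placeMotifs <- function(bundle, pair_truth, config,
                        motifs = toyMotifLibrary(),
                        flip_pairs = character(),
                        seed = simParam(config, "seed") + 3L) {
  p <- simParams(config)
  set.seed(seed)
  widths <- vapply(motifs, ncol, integer(1))
  if (any(widths > p$promoter_length)) stop("motif wider than promoter")
  consensus <- lapply(motifs, function(pm)
    DNA_BASES[apply(pm, 2L, which.max)])
  genes <- geneModels(bundle)
  gene_at <- setNames(seq_along(genes), genes$gene_id)
  npairs <- nrow(pair_truth)
  nm <- length(motifs)
  present <- matrix(runif(npairs * nm) < p$motif_presence_prob, npairs, nm)
  flip_p <- ifelse(pair_truth$maternal_id %in% flip_pairs,
                   p$aseg_flip_prob, p$motif_flip_prob)
  flips <- matrix(runif(npairs * nm) < flip_p, npairs, nm)
  flip_allele <- matrix(sample(1:2, npairs * nm, replace = TRUE), npairs, nm)
  pres_m <- present
  pres_p <- present
  ## a flip makes the motif allele-specific: present on exactly one allele
  pres_m[flips] <- flip_allele[flips] == 1L
  pres_p[flips] <- flip_allele[flips] == 2L
  seq_chars <- lapply(as.character(genomeSequences(bundle)),
                      function(s) strsplit(s, "")[[1]])
  placements <- list()
  presence <- list(maternal = pres_m * 1L, paternal = pres_p * 1L)
  dimnames(presence$maternal) <- list(pair_truth$maternal_id, names(motifs))
  dimnames(presence$paternal) <- list(pair_truth$paternal_id, names(motifs))
  for (i in seq_len(npairs)) {
    ## common positions per motif so unflipped motifs sit at homologous spots
    pos_try <- floor(runif(nm) * (p$promoter_length - widths)) + 1L
    ## greedy collision avoidance within the promoter
    used <- matrix(0L, 0, 2)
    pos <- rep(NA_integer_, nm)
    for (mi in order(widths, decreasing = TRUE)) {
      if (!pres_m[i, mi] && !pres_p[i, mi]) next
      cand <- pos_try[mi]
      for (try in seq_len(50L)) {
        lo <- cand
        hi <- cand + widths[mi] - 1L
        if (!nrow(used) || all(hi < used[, 1] | lo > used[, 2])) break
        cand <- floor(runif(1) * (p$promoter_length - widths[mi])) + 1L
      }
      pos[mi] <- cand
      used <- rbind(used, c(cand, cand + widths[mi] - 1L))
    }
    for (side in 1:2) {
      gid <- if (side == 1L) pair_truth$maternal_id[i] else
        pair_truth$paternal_id[i]
      pres <- if (side == 1L) pres_m else pres_p
      g <- genes[gene_at[[gid]]]
      chrom <- as.character(seqnames(g))
      minus <- as.character(strand(g)) == "-"
      for (mi in seq_len(nm)) {
        if (!pres[i, mi] || is.na(pos[mi])) next
        word <- consensus[[mi]]
        w <- widths[mi]
        if (!minus) {
          gstart <- start(g) - p$promoter_length + pos[mi] - 1L
          if (gstart < 1L) next
          seq_chars[[chrom]][gstart:(gstart + w - 1L)] <- word
        } else {
          gend <- end(g) + p$promoter_length - pos[mi] + 1L
          comp <- c(A = "T", C = "G", G = "C", T = "A")[rev(word)]
          seq_chars[[chrom]][(gend - w + 1L):gend] <- comp
        }
        placements[[length(placements) + 1L]] <- data.table(
          gene_id = gid, motif = names(motifs)[mi], promoter_pos = pos[mi])
      }
    }
  }
  newseqs <- DNAStringSet(vapply(seq_chars, paste, character(1),
                                 collapse = ""))
  names(newseqs) <- names(genomeSequences(bundle))
  bundle@sequences <- newseqs
  validObject(bundle)
  list(bundle = bundle,
       placements = if (length(placements)) rbindlist(placements) else
         data.table(gene_id = character(), motif = character(),
                    promoter_pos = integer()),
       presence_truth = presence)
}

#' Bundled toy motif library
#'
#' 24 sharp synthetic PWMs of widths 7-12 shipped as a MEME minimal file
#' under `inst/extdata/toy_motifs_synthetic.meme` (a constructed stand-in
#' library, not derived from any motif database).
#'
#' @return Named list of PWMs (see [readMemeMotifs()]).
#' @export
toyMotifLibrary <- function() {
  readMemeMotifs(system.file("extdata", "toy_motifs_synthetic.meme",
                             package = "alleleMeth", mustWork = TRUE))
}

#' Extract strand-aware promoter sequences
#'
#' The 2-kb sequence upstream of each gene's TSS, 5'->3' on the gene strand
#' (reverse-complemented for `-` genes).
#'
#' @param bundle [GenomeBundle-class].
#' @param genes Genes to extract (default: all in the bundle).
#' @param length Promoter length (default 2000).
#' @return Named DNAStringSet plus a `promoter_ranges` attribute (GRanges of
#'   the genomic promoter intervals, strand-aware).
#' @export
promoterSeqs <- function(bundle, genes = geneModels(bundle), length = 2000L) {
  pr <- promoters(genes, upstream = length, downstream = 0L)
  pr <- restrict(pr, start = 1L)
  chars <- as.character(genomeSequences(bundle))
  out <- DNAStringSet(substring(chars[as.character(seqnames(pr))],
                                start(pr), end(pr)))
  minus <- as.character(strand(pr)) == "-"
  if (any(minus)) out[minus] <- reverseComplement(out[minus])
  names(out) <- genes$gene_id
  pr$gene_id <- genes$gene_id
  names(pr) <- genes$gene_id
  attr(out, "promoter_ranges") <- pr
  out
}
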