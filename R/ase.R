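## Allele-specific expression: per-phase allelic-bias Wald tests,
## phase-dependent interaction tests against the explant baseline (LRT),
## consistency classification across phases, and PCA of allele expression.
## Counts are organized as an AlleleCountSet: maternal and paternal count
## matrices (pairs x samples) with a phase label per sample. Size factors
## are computed across all alleles jointly per sample: both alleles of a
## pair share the library, so per-allele normalization must not distort the
## allelic ratio.

## Assemble the joint matrix used for size factors: alleles (2 x pairs) x
## samples.
jointAlleleMatrix <- function(maternal, paternal) {
  rbind(maternal, paternal)
}

#' Per-phase allele-specific expression test
#'
#' For each allele pair within one phase, fits the negative-binomial GLM
#' `count ~ allele` over the replicates of both alleles (shared per-sample
#' size factors computed over all alleles; method-of-moments dispersion per
#' pair, floored at 1e-4) and Wald-tests the allele coefficient. BH across
#' pairs within the phase. Bias is called when `|log2FC| > 1` and
#' `FDR < 0.05`; log2FC is maternal over paternal.
#'
#' @param maternal,paternal Pairs x replicates count matrices for one phase
#'   (same pair order; rownames = pair ids).
#' @param phase Phase label carried into the result.
#' @param sf Size factors per replicate (default: median-of-ratios on the
#'   stacked allele matrix).
#' @return data.table: pair, phase, log2_fc, p, fdr, bias in
#'   {maternal, paternal, none}. All-zero pairs are excluded.
#' @export
testAsePerPhase <- function(maternal, paternal, phase = NA_character_,
                            sf = NULL) {
  stopifnot(nrow(maternal) == nrow(paternal),
            ncol(maternal) == ncol(paternal))
  if (ncol(maternal) < 2L) stop("need >= 2 replicates")
  if (is.null(sf)) sf <- sizeFactors(jointAlleleMatrix(maternal, paternal))
  zero <- rowSums(maternal) + rowSums(paternal) == 0
  ids <- rownames(maternal)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(maternal)))
  y <- cbind(paternal, maternal)[!zero, , drop = FALSE]  # group2 = maternal
  sf2 <- c(sf, sf)
  grp <- rep(c(FALSE, TRUE), each = ncol(maternal))
  alpha <- estimateDispersion(y, grp, sf2)
  wald <- nbTwoGroupWald(y, grp, sf2, alpha)
  res <- data.table(pair = ids[!zero], phase = phase,
                    log2_fc = wald$log2_fc, p = wald$p)
  res[, fdr := p.adjust(p, method = "BH")]
  res[, bias := ifelse(abs(log2_fc) > 1 & fdr < 0.05,
                       ifelse(log2_fc > 0, "maternal", "paternal"), "none")]
  res[]
}

#' Phase-dependent allele-specific expression (interaction test)
#'
#' For each allele pair and each non-baseline phase, fits the
#' negative-binomial model `count ~ phase + allele + phase:allele` on the
#' samples of the baseline (LE) and that phase, and compares it to the
#' no-interaction model by likelihood ratio (1 df). The interaction effect
#' is the allelic log2 fold change in the phase minus that at baseline. BH
#' across pairs x contrasts; a pair is flagged phase-dependent when
#' `|interaction effect| > 1` and `FDR < 0.05`.
#'
#' @param maternal,paternal Pairs x samples count matrices across phases.
#' @param phases Character vector assigning each column to a phase.
#' @param baseline Baseline phase (default "LE").
#' @param sf Size factors per sample (default from the stacked matrix).
#' @return data.table: pair, contrast (phase vs baseline), interaction_log2,
#'   p, fdr, phase_dependent.
#' @export
testPhaseDependentAse <- function(maternal, paternal, phases,
                                  baseline = "LE", sf = NULL) {
  stopifnot(ncol(maternal) == length(phases),
            nrow(maternal) == nrow(paternal))
  if (!baseline %in% phases) stop("baseline phase missing")
  if (is.null(sf)) sf <- sizeFactors(jointAlleleMatrix(maternal, paternal))
  ids <- rownames(maternal)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(maternal)))
  others <- setdiff(unique(phases), baseline)
  res <- rbindlist(lapply(others, function(ph) {
    sel <- phases %in% c(baseline, ph)
    m <- maternal[, sel, drop = FALSE]
    p_ <- paternal[, sel, drop = FALSE]
    s <- sf[sel]
    is_ph <- phases[sel] == ph
    ## stack alleles: samples duplicated, allele indicator
    y <- cbind(p_, m)
    s2 <- c(s, s)
    allele <- rep(c(0L, 1L), each = sum(sel))
    phase_i <- c(is_ph, is_ph)
    zero <- rowSums(y) == 0
    y <- y[!zero, , drop = FALSE]
    cellg <- interaction(allele, phase_i)
    alpha <- estimateDispersion(y, cellg, s2)
    ## full model: saturated cell means (4 cells) - fit each cell
    fitCell <- function(cols) nbTwoGroupFitGroupOnly(
      y[, cols, drop = FALSE], s2[cols], alpha)
    c00 <- fitCell(which(allele == 0L & !phase_i))
    c10 <- fitCell(which(allele == 1L & !phase_i))
    c01 <- fitCell(which(allele == 0L & phase_i))
    c11 <- fitCell(which(allele == 1L & phase_i))
    ll_full <- c00$loglik + c10$loglik + c01$loglik + c11$loglik
    inter <- (c11$logmean - c01$logmean) - (c10$logmean - c00$logmean)
    ## reduced model: phase + allele, no interaction (per-gene IRLS)
    X <- cbind(1, phase_i, allele)
    ll_red <- vapply(seq_len(nrow(y)), function(i) {
      f <- tryCatch(fitNbGlm(y[i, ], X, s2, alpha[i]),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$loglik
    }, numeric(1))
    stat <- pmax(2 * (ll_full - ll_red), 0)
    pv <- pchisq(stat, df = 1L, lower.tail = FALSE)
    data.table(pair = ids[!zero], contrast = paste0(ph, "_vs_", baseline),
               interaction_log2 = inter / log(2), p = pv)
  }))
  res[, fdr := p.adjust(p, method = "BH")]
  res[, phase_dependent := !is.na(fdr) & abs(interaction_log2) > 1 &
        fdr < 0.05]
  res[]
}

#' Classify allelic-bias consistency across phases
#'
#' Per pair over its per-phase bias calls: `consistent_maternal` /
#' `consistent_paternal` when the same non-none bias occurs in every phase;
#' `shifting` when both maternal and paternal calls occur; `phase_specific`
#' when biased in at least one but not all phases in a single direction;
#' `unbiased` otherwise.
#'
#' @param ase_results data.table from [testAsePerPhase()] rows across phases
#'   (columns pair, phase, bias).
#' @return data.table: pair, n_phases, label.
#' @export
classifyConsistency <- function(ase_results) {
  ase_results[, {
    b <- bias
    has_m <- any(b == "maternal")
    has_p <- any(b == "paternal")
    label <- if (has_m && has_p) "shifting"
    else if (has_m && all(b == "maternal")) "consistent_maternal"
    else if (has_p && all(b == "paternal")) "consistent_paternal"
    else if (has_m || has_p) "phase_specific"
    else "unbiased"
    list(n_phases = .N, label = label)
  }, by = pair]
}

#' PCA of allele expression
#'
#' Centred principal component analysis of a `log2(TPM + 1)` matrix with
#' alleles as observations (rows) and samples as variables, returning scores
#' on the first components with the parent-of-origin label attached.
#'
#' @param log_tpm Alleles x samples matrix.
#' @param parent Character vector per allele ("maternal"/"paternal").
#' @param n_components Components to return (default 2).
#' @return List: `scores` (data.table allele, parent, PC1, PC2, ...),
#'   `variance_explained` (per component).
#' @export
allelePca <- function(log_tpm, parent, n_components = 2L) {
  if (nrow(log_tpm) < 2L) stop("need >= 2 alleles")
  pc <- prcomp(log_tpm, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  sc <- data.table(allele = rownames(log_tpm), parent = parent)
  for (j in seq_len(k)) sc[[paste0("PC", j)]] <- pc$x[, j]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sc, variance_explained = ve)
}
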