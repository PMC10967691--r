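## TPM quantification, differential expression (re-implemented NB GLM Wald
## test), expression-class stratification of methylation, and bin-level
## methylation-expression correlation.

#' Transcripts per million
#'
#' `TPM_g = (count_g / length_g) / sum(count / length) * 1e6` per sample;
#' every column sums to 1e6.
#'
#' @param counts Genes x samples matrix.
#' @param lengths Exon-union gene lengths in bp (> 0), aligned to rows.
#' @return TPM matrix.
#' @export
#' @examples
#' tpm(matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'     c(1000, 2000))
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (length(lengths) != nrow(counts)) stop("lengths must match rows")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with all-zero counts")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Differential expression by NB GLM Wald test
#'
#' Per-gene negative-binomial test between two conditions: median-of-ratios
#' size factors over the full matrix, gene-wise method-of-moments dispersion
#' (floored at 1e-4), Wald test on the condition log fold change, BH FDR.
#' A gene is flagged when `|log2FC| > 1` and `FDR < 0.05`. Genes with
#' all-zero counts across both conditions are excluded and reported.
#'
#' @param counts Genes x samples matrix.
#' @param condition Factor/character of length ncol: two levels; fold change
#'   is level2 / level1.
#' @param sf Optional size factors (default: computed from `counts`).
#' @return List: `results` (data.table gene, base_mean, log2_fc, p, fdr,
#'   flag), `excluded` (all-zero gene ids).
#' @export
testDeg <- function(counts, condition, sf = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  if (min(table(condition)) < 2L) stop("need >= 2 replicates per condition")
  if (is.null(sf)) sf <- sizeFactors(counts)
  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  y <- counts[!zero, , drop = FALSE]
  alpha <- estimateDispersion(y, condition, sf)
  g2 <- condition == levels(condition)[2L]
  wald <- nbTwoGroupWald(y, g2, sf, alpha)
  res <- data.table(gene = rownames(y),
                    base_mean = rowMeans(sweep(y, 2L, sf, "/")),
                    log2_fc = wald$log2_fc, p = wald$p)
  res[, fdr := p.adjust(p, method = "BH")]
  res[, flag := abs(log2_fc) > 1 & fdr < 0.05]
  list(results = res[], excluded = excluded)
}

#' Expression classes I-V from TPM
#'
#' Class I: TPM = 0; II: 0 < TPM <= 1; III: 1 < TPM <= 10; IV:
#' 10 < TPM <= 100; V: TPM > 100.
#'
#' @param tpm_values Numeric vector of TPM (>= 0).
#' @return Factor with levels I..V.
#' @export
#' @examples
#' tpmClasses(c(0, 1, 10.0001, 100, 100.1))
tpmClasses <- function(tpm_values) {
  if (any(tpm_values < 0)) stop("negative TPM")
  cut(tpm_values, breaks = c(-Inf, 0, 1, 10, 100, Inf),
      labels = c("I", "II", "III", "IV", "V"))
}

#' Compare methylation levels between expression classes
#'
#' Pairwise Wilcoxon-Mann-Whitney tests of per-gene region methylation
#' levels between expression classes, with a compact letter display at
#' p < 0.05. The exact distribution is used when both classes have at most 8
#' genes (and no ties); otherwise the normal approximation with tie
#' correction. Classes with fewer than 2 members are excluded.
#'
#' @param classes Factor of expression classes per gene.
#' @param levels_ Numeric per-gene methylation level (same order); NAs
#'   dropped.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List: `pairwise` (data.table class1, class2, p), `letters`
#'   (data.table class, n, median_level, letters).
#' @export
classMethylationComparison <- function(classes, levels_, alpha = 0.05) {
  ok <- !is.na(levels_) & !is.na(classes)
  classes <- droplevels(as.factor(classes[ok]))
  levels_ <- levels_[ok]
  sizes <- table(classes)
  keep <- names(sizes)[sizes >= 2L]
  if (length(keep) < 2L) stop("need >= 2 classes with >= 2 members")
  classes <- droplevels(factor(classes, levels = keep))
  levels_ <- levels_[!is.na(classes)]
  classes <- classes[!is.na(classes)]
  cls <- levels(classes)
  pw <- rbindlist(lapply(seq_len(length(cls) - 1L), function(i) {
    rbindlist(lapply(seq.int(i + 1L, length(cls)), function(j) {
      x <- levels_[classes == cls[i]]
      y <- levels_[classes == cls[j]]
      exact <- length(x) <= 8L && length(y) <= 8L
      p <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                        correct = TRUE)$p.value)
      data.table(class1 = cls[i], class2 = cls[j], p = p)
    }))
  }))
  ## compact letter display: order classes by median; maximal consecutive
  ## runs in which all pairs are non-significant share a letter
  med <- vapply(cls, function(k) median(levels_[classes == k]), numeric(1))
  ord <- cls[order(med)]
  sig <- function(a, b) {
    r <- pw[(class1 == a & class2 == b) | (class1 == b & class2 == a)]
    r$p[1] < alpha
  }
  runs <- list()
  for (i in seq_along(ord)) {
    j <- i
    while (j < length(ord) &&
           all(!vapply(i:j, function(k) sig(ord[k], ord[j + 1L]), logical(1))))
      j <- j + 1L
    runs[[length(runs) + 1L]] <- ord[i:j]
  }
  ## drop runs fully contained in another
  keep_run <- vapply(seq_along(runs), function(a)
    !any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[keep_run]
  lets <- vapply(cls, function(k)
    paste(letters[which(vapply(runs, function(r) k %in% r, logical(1)))],
          collapse = ""), character(1))
  letter_tab <- data.table(class = cls, n = as.integer(table(classes)[cls]),
                           median_level = med[cls], letters = lets[cls])
  list(pairwise = pw[], letters = letter_tab)
}

#' Correlate per-bin methylation with expression across phases
#'
#' Pearson correlation between a gene's expression (one value per phase,
#' e.g. replicate-mean TPM) and the methylation level of each of its 80 bins
#' across the same phases. Significance requires both `|r| > r_threshold`
#' and `p < p_threshold` (two-sided t-transform of r). Bins with undefined
#' levels in any phase, or constant in either variable, are skipped; genes
#' need at least `min_phases` phases.
#'
#' @param bin_levels Numeric matrix (rows = gene x bin combinations, columns
#'   = phases) of methylation levels; rownames ignored.
#' @param gene Character vector mapping each row to a gene.
#' @param bin Integer vector (1..80) mapping each row to a bin.
#' @param expression Genes x phases matrix of expression (same phase order).
#' @param context Context label carried through.
#' @param r_threshold,p_threshold Significance gates (defaults 0.6, 0.05).
#' @param min_phases Minimum phases with defined values (default 3).
#' @return List: `records` (data.table gene, bin, context, r, p,
#'   significant, sign), `gene_summary` (per-gene: any significant bin and
#'   the sign of its strongest significant bin).
#' @export
binExpressionCorrelation <- function(bin_levels, gene, bin, expression,
                                     context = NA_character_,
                                     r_threshold = 0.6, p_threshold = 0.05,
                                     min_phases = 3L) {
  stopifnot(nrow(bin_levels) == length(gene), length(gene) == length(bin))
  ex <- expression[gene, , drop = FALSE]
  ok_row <- rowSums(!is.na(bin_levels)) == ncol(bin_levels) &
    rowSums(!is.na(ex)) == ncol(ex)
  n <- ncol(bin_levels)
  if (n < min_phases) stop("fewer than ", min_phases, " phases")
  x <- bin_levels
  y <- ex
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  r[!ok_row | sx == 0 | sy == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  rec <- data.table(gene = gene, bin = bin, context = context, r = r, p = p)
  rec <- rec[!is.na(r)]
  rec[, significant := abs(r) > r_threshold & p < p_threshold]
  rec[, sign := ifelse(r > 0, "positive", "negative")]
  gs <- rec[, {
    s <- .SD[significant == TRUE]
    if (nrow(s)) {
      best <- s[which.max(abs(r))]
      list(n_significant_bins = nrow(s), sign = best$sign)
    } else list(n_significant_bins = 0L, sign = NA_character_)
  }, by = gene]
  list(records = rec[], gene_summary = gs[])
}

#' @importFrom stats pt
NULL
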