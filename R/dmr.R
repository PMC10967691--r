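## Differential methylation between phases on 200-bp sliding bins.
## The test models each replicate's methylated/unmethylated counts in a bin
## as binomial observations with a common within-group proportion and
## compares the two-group logistic model against an intercept-only model by
## likelihood ratio. With a single group covariate the group MLEs are the
## pooled proportions, so the statistic has closed form and is vectorized
## over bins. Q-values are Benjamini-Hochberg (deliberate replacement of
## methylKit's SLIM).

DMR_THRESHOLDS <- c(CG = 0.25, CHG = 0.25, CHH = 0.15)

#' Per-context DMR methylation-difference thresholds
#'
#' @return Named vector: 0.25 (CG), 0.25 (CHG), 0.15 (CHH).
#' @export
dmrThresholds <- function() DMR_THRESHOLDS

#' Aggregate replicate cytosine counts into bins
#'
#' Pools methylated/unmethylated counts of one context per bin per replicate
#' and applies the coverage filter: only bins containing at least
#' `min_cytosines` cytosines of that context in *all* samples are retained.
#'
#' @param tracks List of cytosine GRanges, one per replicate (both groups
#'   together or one group; filtering is across all supplied tracks).
#' @param bins GRanges from [makeSlidingBins()].
#' @param context Cytosine context.
#' @param min_cytosines Minimum cytosines per bin per sample (default 5).
#' @return List with `mC` and `uC` (bins x replicates matrices),
#'   `n_cytosines` matrix, and `bins` (the retained GRanges).
#' @export
binCounts <- function(tracks, bins, context, min_cytosines = 5L) {
  n <- length(tracks)
  nb <- length(bins)
  mC <- matrix(0L, nb, n)
  uC <- matrix(0L, nb, n)
  ncy <- matrix(0L, nb, n)
  for (i in seq_len(n)) {
    bc <- binSiteCounts(tracks[[i]], bins, context)
    mC[bc$bin, i] <- bc$mC
    uC[bc$bin, i] <- bc$uC
    ncy[bc$bin, i] <- bc$n_cytosines
  }
  keep <- rowSums(ncy >= min_cytosines) == n
  list(mC = mC[keep, , drop = FALSE], uC = uC[keep, , drop = FALSE],
       n_cytosines = ncy[keep, , drop = FALSE], bins = bins[keep])
}

## Closed-form binomial-logistic LRT for two groups on pooled counts.
## Returns the two-sided chi-square(1) p-value. Zero-coverage bins give NA.
binomialLrt <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1
  n2 <- m2 + u2
  p1 <- m1 / n1
  p2 <- m2 / n2
  p0 <- (m1 + m2) / (n1 + n2)
  ll <- function(m, u, p) {
    out <- numeric(length(m))
    ok <- p > 0 & p < 1
    out[ok] <- m[ok] * log(p[ok]) + u[ok] * log1p(-p[ok])
    out[!ok] <- 0  # saturated at 0 or 1: likelihood 1
    out
  }
  stat <- 2 * (ll(m1, u1, p1) + ll(m2, u2, p2) - ll(m1 + m2, u1 + u2, p0))
  stat <- pmax(stat, 0)
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  p[n1 == 0 | n2 == 0] <- NA_real_
  list(stat = stat, p = p)
}

#' Test bins for differential methylation between two groups
#'
#' Replicate-aware binomial-logistic likelihood-ratio test per bin with BH
#' q-values; the methylation difference is computed on pooled counts
#' (group2 - group1). A bin is flagged as DMR when `|difference|` exceeds the
#' per-context threshold (0.25/0.25/0.15 for CG/CHG/CHH) and `q < 0.05`.
#' Optional beta-binomial overdispersion correction divides the LRT statistic
#' by a method-of-moments variance-inflation factor estimated from replicate
#' heterogeneity across all bins.
#'
#' @param group1,group2 Lists with `mC`/`uC` bins x replicates matrices over
#'   the same bins (e.g. from [binCounts()] columns split by group).
#' @param context Cytosine context (selects the difference threshold).
#' @param bins Optional GRanges of the tested bins, carried into the result.
#' @param qvalue_cutoff Significance level on BH q (default 0.05).
#' @param overdispersion Apply the variance-inflation correction
#'   (default FALSE).
#' @return data.table with per-bin levels, difference, p, q, `dmr` flag,
#'   direction (hyper = group2 above group1), and transition flags
#'   `to_high` (group2 level > 0.8) / `to_low` (group2 level < 0.2).
#' @export
testDmr <- function(group1, group2, context, bins = NULL,
                    qvalue_cutoff = 0.05, overdispersion = FALSE) {
  m1 <- rowSums(group1$mC)
  u1 <- rowSums(group1$uC)
  m2 <- rowSums(group2$mC)
  u2 <- rowSums(group2$uC)
  lrt <- binomialLrt(m1, u1, m2, u2)
  stat <- lrt$stat
  if (overdispersion) {
    phi <- estimateInflation(cbind(group1$mC, group2$mC),
                             cbind(group1$uC, group2$uC),
                             cbind(group1$mC * 0 + 1L, group2$mC * 0 + 2L))
    stat <- stat / max(phi, 1)
  }
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  p[(m1 + u1) == 0 | (m2 + u2) == 0] <- NA_real_
  level1 <- m1 / (m1 + u1)
  level2 <- m2 / (m2 + u2)
  diff <- level2 - level1
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  thr <- DMR_THRESHOLDS[[context]]
  dmr <- !is.na(q) & q < qvalue_cutoff & abs(diff) > thr
  out <- data.table(
    context = context, level1 = level1, level2 = level2, difference = diff,
    p = p, q = q, dmr = dmr,
    direction = ifelse(diff > 0, "hyper", ifelse(diff < 0, "hypo", "none")),
    to_high = dmr & level2 > 0.8, to_low = dmr & level2 < 0.2)
  if (!is.null(bins)) {
    out[, `:=`(chrom = as.character(seqnames(bins)), start = start(bins),
               end = end(bins), bin_id = bins$bin_id)]
  }
  out[]
}

## Method-of-moments variance inflation from replicate heterogeneity:
## chi-square statistic of replicates vs their group pooled proportion,
## averaged over bins, relative to its degrees of freedom.
estimateInflation <- function(mC, uC, group) {
  grp <- group[1, ]
  num <- 0
  df <- 0
  for (g in unique(grp)) {
    m <- mC[, grp == g, drop = FALSE]
    u <- uC[, grp == g, drop = FALSE]
    n <- m + u
    p <- rowSums(m) / pmax(rowSums(n), 1)
    e <- n * p
    v <- n * p * (1 - p)
    ok <- v > 0
    num <- num + sum(((m - e)^2 / ifelse(ok, v, 1))[ok])
    df <- df + sum(ok) - sum(rowSums(ok) > 0)
  }
  if (df <= 0) return(1)
  num / df
}

#' Annotate DMRs to genes
#'
#' Assigns every DMR to all features it overlaps by at least 1 bp: the
#' strand-aware 2-kb promoter, gene body, 2-kb downstream flank; anything
#' else is intergenic. The per-DMR primary feature follows the precedence
#' promoter > gene_body > downstream > intergenic. Genes with one or more
#' DMRs in body or either flank are differentially methylated genes (DMGs).
#'
#' @param dmrs data.table from [testDmr()] with chrom/start/end, or GRanges.
#' @param genes GRanges with `gene_id` and strand.
#' @param flank Flank size (default 2000).
#' @return List: `dmrs` (input plus `primary_feature`), `dmgs` (data.table
#'   gene_id, n_dmrs, features), `feature_fractions` (primary-feature
#'   distribution).
#' @export
annotateDmg <- function(dmrs, genes, flank = 2000L) {
  gr <- if (is(dmrs, "GRanges")) dmrs else
    GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  prom <- promoters(genes, upstream = flank, downstream = 0L)
  prom <- restrict(prom, start = 1L)
  down <- flank(genes, width = flank, start = FALSE)
  down <- restrict(down, start = 1L)
  hitsOf <- function(feat) {
    ov <- findOverlaps(gr, feat, ignore.strand = TRUE)
    data.table(dmr = queryHits(ov), gene_id = feat$gene_id[subjectHits(ov)])
  }
  hp <- hitsOf(prom)
  hb <- hitsOf(genes)
  hd <- hitsOf(down)
  assign_tab <- rbindlist(list(
    if (nrow(hp)) hp[, .(dmr, gene_id, feature = "promoter")],
    if (nrow(hb)) hb[, .(dmr, gene_id, feature = "gene_body")],
    if (nrow(hd)) hd[, .(dmr, gene_id, feature = "downstream")]))
  prec <- c(promoter = 1L, gene_body = 2L, downstream = 3L)
  primary <- rep("intergenic", length(gr))
  if (nrow(assign_tab)) {
    best <- assign_tab[, .(r = min(prec[feature])), by = dmr]
    primary[best$dmr] <- names(prec)[best$r]
  }
  out_dmrs <- if (is(dmrs, "GRanges")) {
    d <- as.data.table(dmrs)[, .(chrom = as.character(seqnames), start, end)]
    d
  } else copy_dt(dmrs)
  out_dmrs$primary_feature <- primary
  dmgs <- if (nrow(assign_tab)) {
    assign_tab[, .(n_dmrs = length(unique(dmr)),
                   features = paste(sort(unique(feature)), collapse = ",")),
               by = gene_id]
  } else data.table(gene_id = character(), n_dmrs = integer(),
                    features = character())
  fr <- as.data.table(table(factor(primary, levels = c(names(prec),
                                                       "intergenic"))))
  setnames(fr, c("feature", "n"))
  fr[, fraction := n / max(sum(n), 1L)]
  list(dmrs = out_dmrs, dmgs = dmgs[], feature_fractions = fr[])
}

copy_dt <- function(x) as.data.table(as.data.frame(x))

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric test per set (probability of drawing at least the
#' observed overlap), BH-corrected across sets. Database-agnostic: sets are a
#' named list of gene vectors.
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param universe Character vector of all genes.
#' @param gene_sets Named list: set name -> gene ids.
#' @return data.table with set, set_size, overlap, p, q.
#' @export
#' @examples
#' enrichGeneSets(paste0("g", 1:10), paste0("g", 1:100),
#'                list(S = paste0("g", c(1:5, 50:54))))
enrichGeneSets <- function(selected, universe, gene_sets) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  selected <- unique(intersect(selected, universe))
  n_sel <- length(selected)
  res <- rbindlist(lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, selected))
    p <- phyper(k - 1L, length(set), length(universe) - length(set), n_sel,
                lower.tail = FALSE)
    data.table(set = nm, set_size = length(set), overlap = k, p = p)
  }))
  res[, q := p.adjust(p, method = "BH")]
  res[]
}
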