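## Per-site methylation levels, genome-wide context summaries, weighted
## region levels, sliding-window bins, and 80-bin metagene/TE profiles.
## A methylation level is always (methylated reads)/(total reads); region
## levels are coverage-weighted: sum(mC)/sum(mC + uC) over qualifying sites.

#' Per-site methylation levels
#'
#' Computes `mC / (mC + uC)` for every cytosine covered at least `min_cov`
#' times; sites below the coverage floor are excluded.
#'
#' @param records Cytosine GRanges (see [readCytosineReport()]).
#' @param min_cov Minimum read coverage for a site to qualify (default 5).
#' @return The qualifying records with an added `level` metadata column.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'                              mC = c(8L, 2L), uC = c(2L, 2L),
#'                              context = c("CG", "CG"))
#' siteLevels(gr)  # second site dropped: coverage 4 < 5
siteLevels <- function(records, min_cov = 5L) {
  cov <- records$mC + records$uC
  keep <- records[cov >= min_cov]
  keep$level <- keep$mC / (keep$mC + keep$uC)
  keep
}

#' Genome-wide per-context methylation summary
#'
#' For one sample's cytosine records, computes per context: the mean per-site
#' level, the fraction of sites called methylated, and a histogram of site
#' levels over the bands `[0, 0.2)`, `[0.2, 0.8]`, `(0.8, 1]`. A site is
#' called methylated when a one-sided binomial test of its methylated count
#' against the bisulfite non-conversion rate, BH-adjusted within context, is
#' below `call_alpha`.
#'
#' @param records Cytosine GRanges.
#' @param min_cov Coverage floor (default 5).
#' @param non_conversion Non-conversion error rate (default 0.005).
#' @param call_alpha Adjusted-p threshold for the methylated-site call
#'   (default 0.01).
#' @return data.table with columns context, n_sites, mean_level,
#'   frac_methylated, band_low, band_mid, band_high.
#' @export
globalSummary <- function(records, min_cov = 5L, non_conversion = 0.005,
                          call_alpha = 0.01) {
  recs <- siteLevels(records, min_cov)
  dt <- data.table(context = recs$context, mC = recs$mC,
                   cov = recs$mC + recs$uC, level = recs$level)
  ## one-sided binomial tail P(X >= mC) under the non-conversion rate
  dt[, p := pbinom(mC - 1L, cov, non_conversion, lower.tail = FALSE)]
  dt[, q := p.adjust(p, method = "BH"), by = context]
  out <- dt[, .(
    n_sites = .N,
    mean_level = mean(level),
    frac_methylated = mean(q < call_alpha),
    band_low = mean(level < 0.2),
    band_mid = mean(level >= 0.2 & level <= 0.8),
    band_high = mean(level > 0.8)
  ), by = context]
  setorder(out, context)
  out[]
}

#' Coverage-weighted methylation level of a region
#'
#' @param records Cytosine GRanges for one sample.
#' @param interval A single-interval GRanges (one chromosome).
#' @param context Context to restrict to (`"CG"`, `"CHG"`, `"CHH"`), or
#'   `NULL` for all.
#' @param min_cov Coverage floor per site (default 5).
#' @return data.table with `weighted_level` (NA when no qualifying site:
#'   undefined, not 0), `n_cytosines`, `total_coverage`.
#' @export
weightedRegionLevel <- function(records, interval, context = NULL,
                                min_cov = 5L) {
  stopifnot(length(interval) == 1L)
  recs <- siteLevels(records, min_cov)
  if (!is.null(context)) recs <- recs[recs$context == context]
  hit <- recs[IRanges::overlapsAny(recs, interval, ignore.strand = TRUE)]
  n <- length(hit)
  tot <- sum(hit$mC + hit$uC)
  data.table(context = if (is.null(context)) NA_character_ else context,
             weighted_level = if (n == 0L) NA_real_ else sum(hit$mC) / tot,
             n_cytosines = n, total_coverage = tot)
}

#' Sliding genomic bins
#'
#' Half-open 200-bp windows advanced by 100 bp (defaults). A trailing partial
#' bin is kept only when it is at least `step` long and covers chromosome
#' tail positions not covered by the last full bin.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param length Window length in bp (default 200).
#' @param step Slide in bp (default 100); must be <= length.
#' @return GRanges of bins (1-based, inclusive ends internally).
#' @export
#' @examples
#' length(makeSlidingBins(c(chr1 = 1000)))  # 9
makeSlidingBins <- function(chrom_sizes, length = 200L, step = 100L) {
  if (step > length) stop("step must not exceed window length")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be > 0")
  res <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    if (L >= length) {
      starts0 <- seq.int(0L, L - length, by = step)
      ends0 <- starts0 + length
    } else {
      starts0 <- integer()
      ends0 <- integer()
    }
    covered <- if (base::length(ends0)) max(ends0) else 0L
    ## trailing partial bin: next start on the grid, clipped at L
    cand <- if (base::length(starts0)) starts0[base::length(starts0)] + step else 0L
    if (L > covered && L - cand >= step) {
      starts0 <- c(starts0, cand)
      ends0 <- c(ends0, L)
    }
    GRanges(chr, IRanges(starts0 + 1L, ends0))
  })
  bins <- suppressWarnings(do.call(c, res))
  bins$bin_id <- paste0(as.character(seqnames(bins)), ":", start(bins) - 1L,
                        "-", end(bins))
  bins
}

#' 80-bin scheme for a gene or TE
#'
#' Splits a feature into 20 fixed-width upstream bins (2 kb flank), 40
#' proportional body bins and 20 fixed-width downstream bins, ordered along
#' the direction of transcription: bin 1 is the most distal upstream bin, bin
#' 80 the most distal downstream bin. For a `-` strand feature, upstream bins
#' come from higher genomic coordinates and the order is reversed. Features
#' shorter than `n_body_bins` bp are rejected (each body bin must be >= 1 bp).
#'
#' @param feature Single-range GRanges with strand.
#' @param flank Flank size in bp (default 2000).
#' @param n_flank_bins Bins per flank (default 20).
#' @param n_body_bins Body bins (default 40).
#' @return GRanges of 80 bins with metadata `bin` (1..80) and `zone`
#'   (`upstream`/`body`/`downstream`). Flank bins may be clipped or dropped at
#'   chromosome start (coordinates below 1 are clipped away).
#' @export
geneBinScheme <- function(feature, flank = 2000L, n_flank_bins = 20L,
                          n_body_bins = 40L) {
  stopifnot(length(feature) == 1L)
  if (width(feature) < n_body_bins)
    stop("feature shorter than ", n_body_bins, " bp; excluded from binning")
  geneBinSchemes(feature, flank, n_flank_bins, n_body_bins)
}

## 80-bin schemes for many features at once, as a single GRanges with
## feature_id/bin/zone metadata (vectorized). Features shorter than
## n_body_bins bp are dropped with a warning.
#' @rdname geneBinScheme
#' @param features GRanges of features with a `gene_id` (or `name`) column.
#' @export
geneBinSchemes <- function(features, flank = 2000L, n_flank_bins = 20L,
                           n_body_bins = 40L) {
  ids <- features$gene_id
  if (is.null(ids)) ids <- features$name
  if (is.null(ids)) ids <- as.character(seq_along(features))
  short <- width(features) < n_body_bins
  if (any(short)) {
    warning(sum(short), " feature(s) shorter than ", n_body_bins,
            " bp excluded from the 80-bin scheme")
    features <- features[!short]
    ids <- ids[!short]
  }
  if (!length(features)) return(GRanges())
  n <- length(features)
  nb <- 2L * n_flank_bins + n_body_bins
  fw <- flank %/% n_flank_bins
  len <- width(features)
  s0 <- start(features) - 1L   # 0-based feature start
  e0 <- end(features)          # 0-based exclusive end
  minus <- as.character(strand(features)) == "-"
  ## matrices bins x features (0-based half-open, transcription order)
  fidx <- seq_len(n_flank_bins) - 1L
  bb <- floor(outer(seq_len(n_body_bins), len) / n_body_bins)  # boundaries
  b0 <- rbind(0L, bb[-n_body_bins, , drop = FALSE])
  s0m <- rep(s0, each = n_flank_bins)
  e0m <- rep(e0, each = n_flank_bins)
  mns <- rep(minus, each = n_flank_bins)
  ## upstream
  up_s <- ifelse(mns, e0m + flank - fidx * fw - fw, s0m - flank + fidx * fw)
  up_e <- up_s + fw
  ## body
  s0b <- rep(s0, each = n_body_bins)
  e0b <- rep(e0, each = n_body_bins)
  mnb <- rep(minus, each = n_body_bins)
  body_s <- ifelse(mnb, e0b - as.vector(bb), s0b + as.vector(b0))
  body_e <- ifelse(mnb, e0b - as.vector(b0), s0b + as.vector(bb))
  ## downstream
  dn_s <- ifelse(mns, s0m - fidx * fw - fw, e0m + fidx * fw)
  dn_e <- dn_s + fw
  ## assemble in feature-major order: 20 up, 40 body, 20 down per feature
  sU <- matrix(up_s, n_flank_bins)
  eU <- matrix(up_e, n_flank_bins)
  sB <- matrix(body_s, n_body_bins)
  eB <- matrix(body_e, n_body_bins)
  sD <- matrix(dn_s, n_flank_bins)
  eD <- matrix(dn_e, n_flank_bins)
  all_s <- as.vector(rbind(sU, sB, sD))
  all_e <- as.vector(rbind(eU, eB, eD))
  keep <- all_e > 0L
  all_s <- pmax(all_s, 0L)
  gr <- GRanges(rep(as.character(seqnames(features)), each = nb)[keep],
                IRanges(all_s[keep] + 1L, all_e[keep]),
                strand = rep(as.character(strand(features)), each = nb)[keep])
  gr$bin <- rep(seq_len(nb), n)[keep]
  gr$zone <- rep(c(rep("upstream", n_flank_bins), rep("body", n_body_bins),
                   rep("downstream", n_flank_bins)), n)[keep]
  gr$feature_id <- rep(ids, each = nb)[keep]
  gr
}

## Aggregate cytosine counts into arbitrary bins: returns data.table keyed by
## bin row index with pooled mC/uC and cytosine counts per context.
binSiteCounts <- function(records, bins, context = NULL) {
  recs <- records
  if (!is.null(context)) recs <- recs[recs$context == context]
  ov <- findOverlaps(recs, bins, ignore.strand = TRUE)
  dt <- data.table(bin = subjectHits(ov),
                   mC = recs$mC[queryHits(ov)],
                   uC = recs$uC[queryHits(ov)])
  dt[, .(mC = sum(mC), uC = sum(uC), n_cytosines = .N), by = bin]
}

#' Average methylation profile over the 80-bin scheme
#'
#' Computes the coverage-weighted level of each of the 80 bins per feature,
#' then averages each bin over the features for which it is defined.
#'
#' @param features GRanges of genes or TEs (with `gene_id` or `name`).
#' @param records Cytosine GRanges for one sample (or pooled replicates).
#' @param context Cytosine context to profile.
#' @param min_cov Per-site coverage floor (default 5).
#' @param flank,n_flank_bins,n_body_bins See [geneBinScheme()].
#' @param bins Optional precomputed [geneBinSchemes()] result for
#'   `features` (avoids recomputation across samples).
#' @return data.table with `bin` (1..80), `zone`, `mean_level`, `n_features`.
#' @export
metageneProfile <- function(features, records, context, min_cov = 5L,
                            flank = 2000L, n_flank_bins = 20L,
                            n_body_bins = 40L, bins = NULL) {
  if (is.null(bins))
    bins <- geneBinSchemes(features, flank, n_flank_bins, n_body_bins)
  if (!length(bins)) stop("no qualifying features")
  recs <- siteLevels(records, min_cov)
  recs <- recs[recs$context == context]
  ov <- findOverlaps(recs, bins, ignore.strand = TRUE)
  dt <- data.table(bin = bins$bin[subjectHits(ov)],
                   feature = bins$feature_id[subjectHits(ov)],
                   mC = recs$mC[queryHits(ov)],
                   uC = recs$uC[queryHits(ov)])
  per_feat <- dt[, .(level = sum(mC) / sum(mC + uC)), by = .(feature, bin)]
  prof <- per_feat[, .(mean_level = mean(level), n_features = .N), by = bin]
  zone <- c(rep("upstream", n_flank_bins), rep("body", n_body_bins),
            rep("downstream", n_flank_bins))
  out <- data.table(bin = seq_len(2L * n_flank_bins + n_body_bins),
                    zone = zone)
  out <- merge(out, prof, by = "bin", all.x = TRUE)
  out[is.na(n_features), n_features := 0L]
  setorder(out, bin)
  out[]
}
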