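## Promoter motif scanning and allele-promoter comparison. PWMs are scored
## as log2 odds against a 0-order background after pseudocount
## renormalization; scores are integerized (scale 1000) and the exact null
## distribution of the total score under the background is obtained by
## dynamic-programming convolution over columns, giving an exact p-value for
## every achievable score. Both strands are scanned; a motif's presence in a
## promoter is binary, and allele promoters are compared by the cosine
## similarity of their presence vectors over the motif library.

PWM_SCALE <- 1000

## Integerized log2-odds score matrix and the exact tail distribution of the
## total score under the background model.
pwmScoreModel <- function(pwm, background = c(A = 0.25, C = 0.25, G = 0.25,
                                              T = 0.25),
                          pseudocount = 0.1) {
  stopifnot(nrow(pwm) == 4L)
  bg <- background / sum(background)
  pp <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  lod <- log2(pp / bg)
  S <- round(lod * PWM_SCALE)
  w <- ncol(S)
  ## exact distribution of the total integer score under the background,
  ## built column by column; `offset` tracks the score of index 1
  dist <- 1
  offset <- 0L
  for (j in seq_len(w)) {
    cmin <- min(S[, j])
    newlen <- length(dist) + max(S[, j]) - cmin
    nd <- numeric(newlen)
    for (i in 1:4) {
      sh <- S[i, j] - cmin
      nd[(1L + sh):(length(dist) + sh)] <-
        nd[(1L + sh):(length(dist) + sh)] + dist * bg[i]
    }
    dist <- nd
    offset <- offset + cmin
  }
  tail_p <- rev(cumsum(rev(dist)))  # P(score >= offset + k - 1)
  list(S = S, dist = dist, offset = offset, tail_p = tail_p, width = w,
       background = bg)
}

## Exact p-value P(score >= s) for integer score(s) s.
pwmTailP <- function(model, s) {
  idx <- s - model$offset + 1L
  idx <- pmin(pmax(idx, 1L), length(model$tail_p))
  p <- model$tail_p[idx]
  p[s > model$offset + length(model$tail_p) - 1L] <- 0
  p[s < model$offset] <- 1
  p
}

## Minimal integer score with tail probability < p_threshold (Inf when no
## achievable score is that extreme).
pwmScoreThreshold <- function(model, p_threshold) {
  ok <- which(model$tail_p < p_threshold)
  if (!length(ok)) return(Inf)
  model$offset + ok[1L] - 1L
}

#' Scan promoter sequences with a PWM
#'
#' Log2-odds scan of both strands against a 0-order background with exact
#' DP-derived p-values; hits are positions where the score's exact p-value
#' is below `p_threshold`. Ambiguous bases contribute a score of 0
#' (background-neutral). Sequences shorter than the motif yield no hits.
#'
#' @param seqs Named [Biostrings::DNAStringSet] of promoters.
#' @param pwm 4 x width probability matrix (rows A,C,G,T).
#' @param p_threshold Exact p-value threshold (default 1e-4).
#' @param background Background nucleotide distribution (default uniform;
#'   [promoterBackground()] estimates it from the scanned set).
#' @param pseudocount Added to every PWM cell before renormalization
#'   (default 0.1).
#' @return data.table: seq (promoter name), pos (1-based start on the given
#'   sequence), strand, score (log2 odds), p.
#' @export
scanPwm <- function(seqs, pwm, p_threshold = 1e-4,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0.1) {
  model <- pwmScoreModel(pwm, background, pseudocount)
  w <- model$width
  thr <- pwmScoreThreshold(model, p_threshold)
  if (!is.finite(thr))
    return(data.table(seq = character(), pos = integer(),
                      strand = character(), score = numeric(), p = numeric()))
  ## concatenate sequences with N spacers; positions with N score NA
  lens <- Biostrings::width(seqs)
  spacer <- strrep("N", w)
  big <- paste(as.character(seqs), collapse = spacer)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)[strsplit(toupper(big), "")[[1]]]
  starts_off <- cumsum(c(0L, head(lens, -1L) + w))
  code_na <- is.na(code)
  code5 <- ifelse(code_na, 5L, code)
  scanStrand <- function(S) {
    L <- length(code5)
    if (L < w) return(NULL)
    P <- L - w + 1L
    S5 <- rbind(S, 0)  # row 5: ambiguous base scores 0
    sc <- numeric(P)
    na <- logical(P)
    for (j in seq_len(w)) {
      idx <- j:(j + P - 1L)
      na <- na | code_na[idx]
      sc <- sc + S5[code5[idx] + (j - 1L) * 5L]
    }
    hits <- which(!na & sc >= thr)
    list(pos = hits, score = sc[hits])
  }
  Src <- model$S[4:1, w:1, drop = FALSE]  # reverse-complement scan
  fw <- scanStrand(model$S)
  rv <- scanStrand(Src)
  mk <- function(h, strand_) {
    if (is.null(h) || !length(h$pos)) return(NULL)
    seq_idx <- findInterval(h$pos, starts_off + 1L)
    data.table(seq = names(seqs)[seq_idx],
               pos = h$pos - starts_off[seq_idx],
               strand = strand_, score = h$score / PWM_SCALE,
               p = pwmTailP(model, as.integer(round(h$score))))
  }
  out <- rbindlist(list(mk(fw, "+"), mk(rv, "-")))
  if (is.null(out) || nrow(out) == 0L)
    return(data.table(seq = character(), pos = integer(),
                      strand = character(), score = numeric(), p = numeric()))
  ## drop hits that straddle a spacer (pos beyond the sequence end)
  out <- out[pos >= 1L & pos + w - 1L <= lens[match(seq, names(seqs))]]
  setorder(out, seq, pos, strand)
  out[]
}

#' 0-order background from a promoter set
#'
#' Strand-symmetrized nucleotide frequencies (A with T, C with G), so that
#' the exact score null applies identically to both scanned strands.
#'
#' @param seqs DNAStringSet.
#' @return Named frequency vector over A,C,G,T.
#' @export
promoterBackground <- function(seqs) {
  f <- colSums(Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                                   drop = FALSE])
  f <- (f + f[c("T", "G", "C", "A")]) / 2
  names(f) <- c("A", "C", "G", "T")
  f / sum(f)
}

#' Scan a motif library over promoters
#'
#' @param seqs Named DNAStringSet of promoters.
#' @param motifs Named list of PWMs (see [readMemeMotifs()]).
#' @param p_threshold Hit threshold (default 1e-4).
#' @param background Default: estimated from `seqs`.
#' @param pseudocount PWM pseudocount (default 0.1).
#' @return data.table: seq, motif, pos, strand, score, p.
#' @export
scanMotifLibrary <- function(seqs, motifs, p_threshold = 1e-4,
                             background = promoterBackground(seqs),
                             pseudocount = 0.1) {
  rbindlist(lapply(names(motifs), function(id) {
    h <- scanPwm(seqs, motifs[[id]], p_threshold, background, pseudocount)
    if (nrow(h)) h$motif <- id
    h
  }), fill = TRUE)
}

#' Binary motif-presence vectors
#'
#' One row per promoter, one column per library motif; entry 1 iff the
#' promoter has at least one hit of that motif (presence, not count).
#'
#' @param hits [scanMotifLibrary()] output.
#' @param seq_names All promoter names (zero rows allowed).
#' @param motif_names The motif library order.
#' @return Binary integer matrix promoters x motifs.
#' @export
promoterVectors <- function(hits, seq_names, motif_names) {
  m <- matrix(0L, length(seq_names), length(motif_names),
              dimnames = list(seq_names, motif_names))
  if (nrow(hits)) {
    u <- unique(hits[, .(seq, motif)])
    m[cbind(match(u$seq, seq_names), match(u$motif, motif_names))] <- 1L
  }
  m
}

#' Cosine similarity of two binary motif vectors
#'
#' `dot(v1, v2) / (|v1| |v2|)`. When both vectors are all-zero the
#' similarity is defined as 1 (identical absence) and flagged via the
#' `"both_zero"` attribute of the vectorized form.
#'
#' @param v1,v2 Equal-length binary vectors.
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosineSimilarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("length mismatch")
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 && n2 == 0) return(1)
  if (n1 == 0 || n2 == 0) return(0)
  val <- min(max(sum(v1 * v2) / (n1 * n2), 0), 1)
  if (abs(val - 1) < 1e-12) val <- 1  # snap floating-point spill at the top
  val
}

#' Cosine similarity and CS classes for allele pairs
#'
#' @param vectors Promoter x motif binary matrix ([promoterVectors()]).
#' @param pairs data.table with maternal_id, paternal_id (promoter names
#'   follow gene names).
#' @return data.table: maternal_id, paternal_id, cs, both_zero, cs_class
#'   (I: `[0,0.2)` ... V: `[0.8,1]`).
#' @export
pairCosineSimilarity <- function(vectors, pairs) {
  cs <- vapply(seq_len(nrow(pairs)), function(i)
    cosineSimilarity(vectors[pairs$maternal_id[i], ],
                     vectors[pairs$paternal_id[i], ]), numeric(1))
  bz <- rowSums(vectors[pairs$maternal_id, , drop = FALSE]) == 0 &
    rowSums(vectors[pairs$paternal_id, , drop = FALSE]) == 0
  data.table(maternal_id = pairs$maternal_id,
             paternal_id = pairs$paternal_id, cs = cs, both_zero = bz,
             cs_class = csClasses(cs))
}

#' CS classes I-V
#'
#' Class I: `0 <= CS < 0.2`; II: `[0.2, 0.4)`; III: `[0.4, 0.6)`; IV:
#' `[0.6, 0.8)`; V: `[0.8, 1]`.
#'
#' @param cs Numeric cosine similarities in `[0, 1]`.
#' @return Factor with levels I..V.
#' @export
csClasses <- function(cs) {
  stopifnot(all(cs >= 0 & cs <= 1))
  cut(cs, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("I", "II", "III", "IV", "V"))
}

## Fisher r-to-z two-sample test of two correlations.
fisherZTest <- function(r1, n1, r2, n2) {
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z))
}

#' Correlation of allelic expression within CS classes, compared across
#' groups
#'
#' Within each CS class and each group of allele pairs, computes the Pearson
#' correlation between maternal and paternal expression (e.g. mean
#' `log2(TPM+1)` across phases) over the pairs of the class, and compares
#' the two groups' correlations per class with Fisher's r-to-z two-sample
#' test. Classes with fewer than 3 pairs in a group are skipped.
#'
#' @param cs_records [pairCosineSimilarity()] output for all pairs.
#' @param expr_maternal,expr_paternal Named numeric vectors of per-allele
#'   expression.
#' @param group2_pairs Maternal ids of the second group (e.g. phase-dependent
#'   ASEGs); group 1 is all pairs.
#' @param group_names Labels (default c("all", "phase_dependent")).
#' @return data.table per class: per-group n and r, z-test p.
#' @export
classExpressionCorrelation <- function(cs_records, expr_maternal,
                                       expr_paternal, group2_pairs,
                                       group_names = c("all",
                                                       "phase_dependent")) {
  groupR <- function(rec) {
    if (nrow(rec) < 3L) return(list(n = nrow(rec), r = NA_real_))
    list(n = nrow(rec), r = cor(expr_maternal[rec$maternal_id],
                                expr_paternal[rec$paternal_id]))
  }
  res <- rbindlist(lapply(levels(cs_records$cs_class), function(cl) {
    rec1 <- cs_records[cs_class == cl]
    rec2 <- rec1[maternal_id %in% group2_pairs]
    g1 <- groupR(rec1)
    g2 <- groupR(rec2)
    p <- if (!is.na(g1$r) && !is.na(g2$r) && g1$n > 3L && g2$n > 3L)
      fisherZTest(g1$r, g1$n, g2$r, g2$n) else NA_real_
    data.table(cs_class = cl, n_group1 = g1$n, r_group1 = g1$r,
               n_group2 = g2$n, r_group2 = g2$r, p = p)
  }))
  setnames(res, c("n_group1", "r_group1", "n_group2", "r_group2"),
           c(paste0("n_", group_names[1]), paste0("r_", group_names[1]),
             paste0("n_", group_names[2]), paste0("r_", group_names[2])))
  res[]
}

#' Methylation level of TFBS footprints
#'
#' Maps motif hits back to genomic coordinates and computes the
#' coverage-weighted methylation level over the cytosines inside each hit
#' footprint (shared pooling rule with [weightedRegionLevel()]). Hits whose
#' footprint contains no covered cytosine are excluded from the summary.
#'
#' @param hits [scanMotifLibrary()] output.
#' @param promoter_ranges Named GRanges giving each promoter's genomic
#'   interval and strand (names match `hits$seq`); hit positions are 1-based
#'   along the promoter sequence as scanned (5'->3' of the promoter strand).
#' @param records Cytosine GRanges for one sample.
#' @param motif_widths Named integer vector of motif widths.
#' @param context Optional context restriction.
#' @param min_cov Coverage floor (default 5).
#' @return List: `per_hit` (data.table with weighted level per hit; NA when
#'   undefined), `summary` (histogram of defined levels in bands
#'   `<=0.05`, `(0.05, 0.2]`, `> 0.2`).
#' @export
tfbsMethylation <- function(hits, promoter_ranges, records, motif_widths,
                            context = NULL, min_cov = 5L) {
  if (nrow(hits) == 0L) stop("no hits")
  w <- motif_widths[hits$motif]
  pr <- promoter_ranges[hits$seq]
  minus <- as.character(strand(pr)) == "-"
  gs <- ifelse(minus, end(pr) - hits$pos - w + 2L, start(pr) + hits$pos - 1L)
  ge <- gs + w - 1L
  foot <- GRanges(seqnames(pr), IRanges(gs, ge))
  recs <- siteLevels(records, min_cov)
  if (!is.null(context)) recs <- recs[recs$context == context]
  ov <- findOverlaps(recs, foot, ignore.strand = TRUE)
  agg <- data.table(hit = subjectHits(ov), mC = recs$mC[queryHits(ov)],
                    uC = recs$uC[queryHits(ov)])[
                      , .(level = sum(mC) / sum(mC + uC), n = .N), by = hit]
  per_hit <- copy_dt(hits)
  per_hit[, `:=`(weighted_level = NA_real_, n_cytosines = 0L)]
  if (nrow(agg)) {
    per_hit$weighted_level[agg$hit] <- agg$level
    per_hit$n_cytosines[agg$hit] <- agg$n
  }
  lv <- per_hit$weighted_level[!is.na(per_hit$weighted_level)]
  summary <- data.table(band = c("<=0.05", "(0.05,0.2]", ">0.2"),
                        n = c(sum(lv <= 0.05),
                              sum(lv > 0.05 & lv <= 0.2), sum(lv > 0.2)),
                        fraction = if (length(lv)) c(mean(lv <= 0.05),
                                                     mean(lv > 0.05 & lv <= 0.2),
                                                     mean(lv > 0.2)) else rep(NA_real_, 3))
  list(per_hit = per_hit[], summary = summary)
}
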