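## Maternal-paternal allele pairing between the two subgenomes: k-mer-seeded
## banded Smith-Waterman similarity scores, a c-score filter, collinear
## synteny-block chaining, bidirectional best hits (BBH), and a single-copy
## orthology fallback, merged with uniqueness guarantees in the precedence
## synteny > BBH > single-copy.

## Encode DNA as integers 0..3 (-1 for ambiguity).
encodeDna <- function(s) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- code[strsplit(toupper(as.character(s)), "")[[1]]]
  v[is.na(v)] <- -1L
  unname(v)
}

## Unique k-mers of an encoded sequence as integers (base-4 rolling value);
## windows containing ambiguity are skipped.
uniqueKmers <- function(code, k = 8L) {
  L <- length(code)
  if (L < k) return(integer())
  n <- L - k + 1L
  val <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cj <- code[j:(j + n - 1L)]
    ok <- ok & cj >= 0L
    val <- val * 4 + cj
  }
  unique(as.integer(val[ok]))
}

#' Similarity scores between two CDS sets
#'
#' Scores candidate gene pairs between two sequence sets by banded
#' Smith-Waterman local alignment. Candidates are seeded by shared 8-mers:
#' a pair is aligned when it shares at least `min_shared` k-mers, capped at
#' the `max_candidates` subjects with the most shared k-mers per gene in
#' either direction (an efficiency cap; near-best partners always rank at
#' the top of the shared-k-mer list).
#'
#' @param cds_a,cds_b Named [Biostrings::DNAStringSet]s (e.g. maternal and
#'   paternal CDS).
#' @param k K-mer size for seeding (default 8).
#' @param min_shared Minimum shared k-mers to seed a pair (default 3).
#' @param max_candidates Per-gene candidate cap (default 10).
#' @param min_shared_frac Additionally require a candidate to share at least
#'   this fraction of the best shared-k-mer count of query or subject, unless
#'   it ranks in the top 3 for either (default 0.5). Near-best partners are
#'   always retained; this prunes background-level pairs before alignment.
#' @param band Band half-width of the alignment (default 20; substitutions
#'   only need a narrow band).
#' @param match,mismatch,gap Alignment scores (defaults 2, -2, -3).
#' @return data.table with `query` (A gene), `subject` (B gene), `shared_kmers`,
#'   `score`. Symmetric: score(A,B) is reported once.
#' @export
scoreHomology <- function(cds_a, cds_b, k = 8L, min_shared = 3L,
                          max_candidates = 10L, min_shared_frac = 0.5,
                          band = 20L, match = 2L, mismatch = -2L,
                          gap = -3L) {
  if (length(cds_a) == 0L || length(cds_b) == 0L)
    return(data.table(query = character(), subject = character(),
                      shared_kmers = integer(), score = integer()))
  codes_a <- lapply(as.character(cds_a), encodeDna)
  codes_b <- lapply(as.character(cds_b), encodeDna)
  ka <- rbindlist(lapply(seq_along(codes_a), function(i)
    data.table(a = i, kmer = uniqueKmers(codes_a[[i]], k))))
  kb <- rbindlist(lapply(seq_along(codes_b), function(i)
    data.table(b = i, kmer = uniqueKmers(codes_b[[i]], k))))
  shared <- merge(ka, kb, by = "kmer", allow.cartesian = TRUE)[
    , .(shared_kmers = .N), by = .(a, b)]
  shared <- shared[shared_kmers >= min_shared]
  if (nrow(shared) == 0L)
    return(data.table(query = character(), subject = character(),
                      shared_kmers = integer(), score = integer()))
  ## candidate cap per gene on both sides (union keeps mutual-best pairs)
  setorder(shared, a, -shared_kmers, b)
  shared[, rank_a := seq_len(.N), by = a]
  shared[, best_a := shared_kmers[1L], by = a]
  setorder(shared, b, -shared_kmers, a)
  shared[, rank_b := seq_len(.N), by = b]
  shared[, best_b := shared_kmers[1L], by = b]
  cand <- shared[(rank_a <= max_candidates | rank_b <= max_candidates) &
                   (rank_a <= 3L | rank_b <= 3L |
                      shared_kmers >= min_shared_frac * pmin(best_a, best_b))]
  cand <- cand[, .(a, b, shared_kmers)]
  cand[, score := vapply(seq_len(.N), function(i)
    .bandedSW(codes_a[[a[i]]], codes_b[[b[i]]], as.integer(band),
              as.integer(match), as.integer(mismatch), as.integer(gap)),
    integer(1))]
  out <- cand[, .(query = names(cds_a)[a], subject = names(cds_b)[b],
                  shared_kmers, score)]
  setorder(out, query, subject)
  out[]
}

#' Read 12-column tabular alignment hits
#'
#' Accepts BLAST outfmt-6 style tables (query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore) as an
#' alternative to [scoreHomology()]; the bit score becomes the similarity
#' score. Multiple HSPs per ordered pair are collapsed to the best.
#'
#' @param path Tabular file.
#' @return data.table with query, subject, score.
#' @export
readTabularHits <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 12L) stop("expected 12 columns")
  setnames(dt, c(1L, 2L, 12L), c("query", "subject", "score"))
  dt[, .(score = max(score)), by = .(query, subject)]
}

#' c-score filter on homology hits
#'
#' Keeps a hit (A, B) iff `score >= c * max(bestscore(A), bestscore(B))`,
#' where a gene's best score is the maximum over all its hits.
#'
#' @param hits data.table with query, subject, score.
#' @param c Cutoff in `[0, 1]` (default 0.99).
#' @return Filtered hits.
#' @export
cscoreFilter <- function(hits, c = 0.99) {
  if (nrow(hits) == 0L) return(hits)
  best_q <- hits[, .(best = max(score)), by = query]
  best_s <- hits[, .(best = max(score)), by = subject]
  bq <- setNames(best_q$best, best_q$query)
  bs <- setNames(best_s$best, best_s$subject)
  hits[score >= c * pmax(bq[query], bs[subject])]
}

#' Chain collinear anchors into synteny blocks
#'
#' Per chromosome pair, repeatedly extracts the longest strictly monotonic
#' chain (both orientations, rank gaps at most `max_gap` on both genomes) by
#' dynamic programming; chains with at least `min_block` anchors become
#' blocks. Genes appearing in exactly one anchor of a block become synteny
#' allele pairs.
#'
#' @param anchors data.table with columns query, subject, a_chrom, b_chrom,
#'   a_rank, b_rank (gene order indices per chromosome) and optionally score.
#' @param min_block Minimum anchors per block (default 4).
#' @param max_gap Maximum gene-rank gap between consecutive anchors
#'   (default 20).
#' @return List: `blocks` (anchors with block id and orientation), `pairs`
#'   (data.table query, subject, block).
#' @export
chainSynteny <- function(anchors, min_block = 4L, max_gap = 20L) {
  if (nrow(anchors) == 0L)
    return(list(blocks = data.table(), pairs = data.table(
      query = character(), subject = character(), block = integer())))
  anchors <- copy_dt(anchors)
  anchors[, idx := .I]
  blocks <- list()
  block_id <- 0L
  bestChain <- function(dt, orient) {
    br <- if (orient == "forward") dt$b_rank else -dt$b_rank
    o <- order(dt$a_rank, br)
    ar <- dt$a_rank[o]
    br <- br[o]
    n <- length(o)
    f <- rep(1L, n)
    back <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (ar[j] < ar[i] && ar[i] - ar[j] <= max_gap &&
            br[j] < br[i] && br[i] - br[j] <= max_gap &&
            f[j] + 1L > f[i]) {
          f[i] <- f[j] + 1L
          back[i] <- j
        }
      }
    }
    top <- which.max(f)
    chain <- integer()
    while (top != 0L) {
      chain <- c(top, chain)
      top <- back[top]
    }
    dt$idx[o[chain]]
  }
  for (key in unique(paste(anchors$a_chrom, anchors$b_chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- anchors[a_chrom == parts[1] & b_chrom == parts[2]]
    repeat {
      if (nrow(sub) < min_block) break
      cf <- bestChain(sub, "forward")
      cr <- bestChain(sub, "reverse")
      chain <- if (length(cf) >= length(cr)) cf else cr
      orient <- if (length(cf) >= length(cr)) "forward" else "reverse"
      if (length(chain) < min_block) break
      block_id <- block_id + 1L
      blk <- anchors[idx %in% chain]
      blk[, `:=`(block = block_id, orientation = orient)]
      blocks[[block_id]] <- blk
      sub <- sub[!idx %in% chain]
    }
  }
  if (!length(blocks))
    return(list(blocks = data.table(), pairs = data.table(
      query = character(), subject = character(), block = integer())))
  blocks <- rbindlist(blocks)
  ## unique pairing within each block: drop genes hit more than once
  pairs <- blocks[, {
    qa <- table(query)
    sb <- table(subject)
    ok <- qa[query] == 1L & sb[subject] == 1L
    .SD[ok, .(query, subject)]
  }, by = block][, .(query, subject, block)]
  list(blocks = blocks[], pairs = pairs[])
}

#' Bidirectional best hits
#'
#' (A, B) is kept iff B is A's best-scoring subject and A is B's best-scoring
#' query. Score ties are broken deterministically by lexicographic partner
#' id and logged as a warning.
#'
#' @param hits data.table with query, subject, score.
#' @return data.table of BBH pairs (query, subject, score).
#' @export
bbh <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.table(query = character(), subject = character(),
                      score = numeric()))
  h <- copy_dt(hits)
  setorder(h, query, -score, subject)
  ties_q <- h[, .(tie = .N > 1L && score[1] == score[2]), by = query][tie == TRUE]
  best_q <- h[, .SD[1L], by = query]
  setorder(h, subject, -score, query)
  ties_s <- h[, .(tie = .N > 1L && score[1] == score[2]), by = subject][tie == TRUE]
  best_s <- h[, .SD[1L], by = subject]
  if (nrow(ties_q) || nrow(ties_s))
    warning("best-hit score ties broken lexicographically for ",
            nrow(ties_q) + nrow(ties_s), " gene(s)")
  m <- merge(best_q[, .(query, subject, score)],
             best_s[, .(query, subject)], by = c("query", "subject"))
  setorder(m, query)
  m[]
}

#' Merge synteny, BBH and single-copy pairs into the allele-pair table
#'
#' The three evidence tiers are computed on disjoint residual gene sets in
#' precedence order: genes paired by synteny are removed before BBH is run
#' on the remaining hits; single-copy orthologs are then BBH pairs restricted
#' to residual genes with exactly one hit each. Every gene ends up in at
#' most one pair.
#'
#' @param synteny_pairs data.table (query, subject, block) from
#'   [chainSynteny()].
#' @param hits Full hit table (query, subject, score).
#' @return data.table: maternal_id (query side), paternal_id (subject side),
#'   evidence in {synteny, bbh, single_copy}, block (NA unless synteny).
#' @export
mergeAllelePairs <- function(synteny_pairs, hits) {
  out <- list()
  if (nrow(synteny_pairs))
    out$synteny <- data.table(maternal_id = synteny_pairs$query,
                              paternal_id = synteny_pairs$subject,
                              evidence = "synteny",
                              block = synteny_pairs$block)
  used_q <- synteny_pairs$query
  used_s <- synteny_pairs$subject
  resid <- hits[!query %in% used_q & !subject %in% used_s]
  b <- suppressWarnings(bbh(resid))
  if (nrow(b))
    out$bbh <- data.table(maternal_id = b$query, paternal_id = b$subject,
                          evidence = "bbh", block = NA_integer_)
  used_q <- c(used_q, b$query)
  used_s <- c(used_s, b$subject)
  resid2 <- hits[!query %in% used_q & !subject %in% used_s]
  if (nrow(resid2)) {
    nq <- resid2[, .N, by = query]
    ns <- resid2[, .N, by = subject]
    single <- resid2[query %in% nq[N == 1L]$query &
                       subject %in% ns[N == 1L]$subject]
    sco <- suppressWarnings(bbh(single))
    if (nrow(sco))
      out$sco <- data.table(maternal_id = sco$query,
                            paternal_id = sco$subject,
                            evidence = "single_copy", block = NA_integer_)
  }
  res <- rbindlist(out)
  if (is.null(res) || nrow(res) == 0L)
    return(data.table(maternal_id = character(), paternal_id = character(),
                      evidence = character(), block = integer()))
  if (anyDuplicated(res$maternal_id) || anyDuplicated(res$paternal_id))
    stop("internal error: gene assigned to more than one allele pair")
  setorder(res, maternal_id)
  res[]
}

#' Pair alleles between the two subgenomes of a GenomeBundle
#'
#' End-to-end driver: extracts gene sequences, scores homology between the
#' maternal and paternal gene sets, applies the c-score filter, chains
#' synteny blocks using gene order along chromosomes, and merges
#' synteny/BBH/single-copy evidence into the final allele-pair table.
#'
#' @param bundle A [GenomeBundle-class].
#' @param cscore c-score cutoff (default 0.99).
#' @param min_block,max_gap Synteny chaining parameters (defaults 4, 20).
#' @param ... Passed to [scoreHomology()].
#' @return data.table as [mergeAllelePairs()].
#' @export
findAllelePairs <- function(bundle, cscore = 0.99, min_block = 4L,
                            max_gap = 20L, ...) {
  genes <- geneModels(bundle)
  mat_sg <- maternalSubgenome(bundle)
  pat_sg <- paternalSubgenome(bundle)
  gm <- genes[genes$subgenome == mat_sg]
  gp <- genes[genes$subgenome == pat_sg]
  chars <- as.character(genomeSequences(bundle))
  getSeqs <- function(g) {
    out <- DNAStringSet(substring(chars[as.character(seqnames(g))],
                                  start(g), end(g)))
    names(out) <- g$gene_id
    out
  }
  hits <- scoreHomology(getSeqs(gm), getSeqs(gp), ...)
  anchors <- cscoreFilter(hits, cscore)
  rank_of <- function(g) {
    dt <- data.table(gene_id = g$gene_id, chrom = as.character(seqnames(g)),
                     start = start(g))
    setorder(dt, chrom, start)
    dt[, rank := seq_len(.N), by = chrom]
    dt
  }
  rm_ <- rank_of(gm)
  rp <- rank_of(gp)
  anchors <- merge(anchors, rm_[, .(query = gene_id, a_chrom = chrom,
                                    a_rank = rank)], by = "query")
  anchors <- merge(anchors, rp[, .(subject = gene_id, b_chrom = chrom,
                                   b_rank = rank)], by = "subject")
  syn <- chainSynteny(anchors, min_block, max_gap)
  mergeAllelePairs(syn$pairs, hits)
}
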