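## Readers and writers for every on-disk format the pipeline touches.
## Interval formats: BED is 0-based half-open on disk, GFF3 and cytosine
## reports are 1-based; in memory everything is a 1-based GRanges.

#' Read a Bismark-style cytosine report
#'
#' Parses the 7-column tab-separated cytosine report layout
#' (chromosome, 1-based position, strand, methylated count, unmethylated
#' count, context, trinucleotide) into a width-1 [GenomicRanges::GRanges]
#' with metadata columns `mC`, `uC`, `context` and `trinucleotide`.
#' Record order is preserved. CG sites are not strand-merged: each cytosine
#' is an independent record.
#'
#' @param path Path to the report (TSV, no header).
#' @return GRanges of cytosine records.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t+\t8\t2\tCG\tCGT", f)
#' readCytosineReport(f)
readCytosineReport <- function(path) {
  empty <- GRanges(mC = integer(), uC = integer(), context = character(),
                   trinucleotide = character())
  if (file.size(path) == 0) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(
    character = c(1, 3, 6, 7), integer = c(2, 4, 5)), fill = TRUE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L) stop("cytosine report needs at least 6 columns")
  if (ncol(dt) == 6L) dt[[7]] <- NA_character_
  setnames(dt, seq_len(7), c("chrom", "pos", "strand", "mC", "uC", "context",
                             "trinucleotide"))
  bad <- which(is.na(dt$pos) | is.na(dt$mC) | is.na(dt$uC) | dt$pos < 1L |
                 dt$mC < 0L | dt$uC < 0L)
  if (length(bad))
    stop("malformed cytosine report line ", bad[1], " in ", path)
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", bad[1], " in ", path)
  bad <- which(!dt$context %in% CONTEXTS)
  if (length(bad))
    stop("unknown context '", dt$context[bad[1]], "' at line ", bad[1],
         " in ", path)
  GRanges(dt$chrom, IRanges(dt$pos, width = 1L), strand = dt$strand,
          mC = dt$mC, uC = dt$uC, context = dt$context,
          trinucleotide = dt$trinucleotide)
}

#' @rdname readCytosineReport
#' @param records GRanges as returned by [readCytosineReport()].
#' @export
writeCytosineReport <- function(records, path) {
  tri <- records$trinucleotide
  if (is.null(tri)) tri <- rep(NA_character_, length(records))
  dt <- data.table(chrom = as.character(seqnames(records)),
                   pos = start(records),
                   strand = as.character(strand(records)),
                   mC = records$mC, uC = records$uC,
                   context = records$context, trinucleotide = tri)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon features; one gene model per `gene` feature, with
#' the exon union defining `exon_length`. Strand is recorded; for a `-`
#' strand gene the TSS is at the higher genomic coordinate.
#'
#' @param path GFF3 file path.
#' @return A list with `genes` (GRanges; mcols `gene_id`, `exon_length`) and
#'   `exons` (GRangesList indexed by gene id).
#' @export
readGFF3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  genes$gene_id <- as.character(genes$ID)
  mrna <- gff[type == "mRNA"]
  mrna2gene <- setNames(as.character(unlist(mrna$Parent)),
                        as.character(mrna$ID))
  ex <- gff[type == "exon"]
  if (length(ex)) {
    par <- as.character(unlist(ex$Parent))
    gene_of <- ifelse(par %in% names(mrna2gene), mrna2gene[par], par)
    if (any(end(ex) < start(ex))) stop("exon with end < start")
    exl <- IRanges::reduce(S4Vectors::split(granges(ex),
                                            factor(gene_of, levels = genes$gene_id)))
    gspan <- setNames(seq_along(genes), genes$gene_id)
    for (gid in names(exl)[lengths(exl) > 0L]) {
      g <- genes[gspan[[gid]]]
      e <- exl[[gid]]
      if (any(start(e) < start(g)) || any(end(e) > end(g)))
        stop("exon outside parent gene span for ", gid)
    }
    genes$exon_length <- unname(sum(width(exl))[genes$gene_id])
    genes$exon_length[is.na(genes$exon_length) | genes$exon_length == 0] <-
      width(genes)[is.na(genes$exon_length) | genes$exon_length == 0]
  } else {
    exl <- NULL
    genes$exon_length <- width(genes)
  }
  mcols(genes) <- mcols(genes)[c("gene_id", "exon_length")]
  list(genes = genes, exons = exl)
}

#' @rdname readGFF3
#' @param genes GRanges with `gene_id` metadata (single-exon models).
#' @export
writeGFF3 <- function(genes, path) {
  gid <- genes$gene_id
  lines <- c("##gff-version 3",
             paste(as.character(seqnames(genes)), "alleleMeth", "gene",
                   start(genes), end(genes), ".", as.character(strand(genes)),
                   ".", paste0("ID=", gid), sep = "\t"),
             paste(as.character(seqnames(genes)), "alleleMeth", "mRNA",
                   start(genes), end(genes), ".", as.character(strand(genes)),
                   ".", paste0("ID=", gid, ".1;Parent=", gid), sep = "\t"),
             paste(as.character(seqnames(genes)), "alleleMeth", "exon",
                   start(genes), end(genes), ".", as.character(strand(genes)),
                   ".", paste0("ID=", gid, ".1.exon1;Parent=", gid, ".1"),
                   sep = "\t"))
  ord <- c(1L, 1L + as.vector(t(matrix(seq_len(3L * length(genes)),
                                       ncol = 3L))))
  writeLines(lines[ord], path)
  invisible(path)
}

#' Read/write BED6 intervals
#'
#' Thin wrappers around rtracklayer's BED support (0-based half-open on disk,
#' 1-based GRanges in memory).
#'
#' @param path BED file path.
#' @return GRanges with `name` and `score` columns when present.
#' @export
readBED <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' @rdname readBED
#' @param gr GRanges to write; the `name` metadata column is kept.
#' @export
writeBED <- function(gr, path) {
  if (is.null(gr$score)) gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read/write a gene x sample count table
#'
#' TSV with a header row `gene_id` followed by sample identifiers.
#'
#' @param path TSV path.
#' @return Integer matrix with gene ids as rownames.
#' @export
readCountTable <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  if (names(dt)[1] != "gene_id") stop("count table must start with gene_id")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountTable
#' @param counts Matrix with gene rownames.
#' @export
writeCountTable <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  for (j in colnames(counts)) dt[[j]] <- counts[, j]
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a MEME minimal-format motif library
#'
#' Parses letter-probability matrices over A,C,G,T. Each motif becomes a
#' 4 x width column-stochastic matrix (rows A,C,G,T). Rows whose
#' probabilities do not sum to 1 within `tol` are rejected.
#'
#' @param path MEME minimal file.
#' @param tol Tolerance on each position's probability sum (default 1e-3).
#' @return Named list of probability matrices; background frequencies (if
#'   present in the file) attached as `attr(,"background")`.
#' @export
readMemeMotifs <- function(path, tol = 1e-3) {
  lines <- readLines(path)
  lines <- trimws(lines)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1] + 1L], "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[c(2, 4, 6, 8)])
      names(vals) <- toks[c(1, 3, 5, 7)]
      background <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at)) stop("no MOTIF entries in ", path)
  out <- list()
  for (m in motif_at) {
    id <- strsplit(lines[m], "\\s+")[[1]][2]
    hdr <- m + which(grepl("^letter-probability matrix", lines[(m + 1):length(lines)]))[1]
    if (is.na(hdr)) stop("motif ", id, " lacks a letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1L) stop("motif ", id, ": invalid width")
    rows <- lines[(hdr + 1L):(hdr + w)]
    pm <- t(vapply(strsplit(rows, "\\s+"),
                   function(x) as.numeric(x[1:4]), numeric(4)))
    if (anyNA(pm)) stop("motif ", id, ": malformed probability row")
    sums <- rowSums(pm)
    if (any(abs(sums - 1) > tol))
      stop("motif ", id, ": probability row sums to ", sums[which.max(abs(sums - 1))])
    mat <- t(pm)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- mat
  }
  attr(out, "background") <- background
  out
}

#' @rdname readMemeMotifs
#' @param motifs Named list of 4 x width probability matrices.
#' @param background Background letter frequencies written to the header.
#' @export
writeMemeMotifs <- function(motifs, path,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", names(background), background),
                     collapse = " "), ""), con)
  for (id in names(motifs)) {
    pm <- motifs[[id]]
    writeLines(c(paste("MOTIF", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         ncol(pm)),
                 apply(pm, 2, function(col) paste(sprintf("%.6f", col),
                                                 collapse = "  ")),
                 ""), con)
  }
  invisible(path)
}

#' Load a simulator configuration from YAML
#'
#' Reads a flat YAML mapping of [SimConfig()] parameter overrides.
#'
#' @param path YAML file.
#' @return A [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  for (nm in c("te_class_mix", "ctx_frac_meth", "te_frac_factor", "subgenomes"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  if (!is.null(vals$phase_factors))
    vals$phase_factors <- do.call(rbind, vals$phase_factors)[CONTEXTS, METH_PHASES]
  do.call(SimConfig, vals)
}
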