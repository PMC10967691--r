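## Shared fixtures: all synthetic data is generated in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(data.table)
})

## A small simulator configuration for fast end-to-end checks.
tinyConfig <- function(...) {
  SimConfig(n_gene_pairs = 24L, n_chromosomes = 1L, n_dmr_windows = 8L,
            relocation_fraction = 0, seed = 11L, ...)
}

## Build a cytosine-record GRanges from parallel vectors.
makeRecords <- function(chrom, pos, strand = "+", mC, uC, context = "CG") {
  GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
          mC = as.integer(mC), uC = as.integer(uC),
          context = rep_len(context, length(pos)))
}

## Independent brute-force hypergeometric upper tail via lchoose.
bruteHyper <- function(overlap, set_size, universe, n_selected) {
  ks <- overlap:min(set_size, n_selected)
  sum(exp(lchoose(set_size, ks) +
            lchoose(universe - set_size, n_selected - ks) -
            lchoose(universe, n_selected)))
}

## Brute-force PWM tail probability by enumerating all words of width w
## (integerized scores, identical rounding to the scanner model).
brutePwmTail <- function(pwm, s, background = c(A = .25, C = .25, G = .25,
                                                T = .25),
                         pseudocount = 0.1) {
  w <- ncol(pwm)
  bg <- background / sum(background)
  pp <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  S <- round(log2(pp / bg) * 1000)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words)) + 1
  for (j in seq_len(w)) {
    sc <- sc + S[cbind(words[, j], j)]
    pr <- pr * bg[words[, j]]
  }
  sum(pr[sc >= s])
}
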