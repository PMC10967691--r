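## Allele-specific methylation: differential methylation between the two
## alleles of a pair over the shared 80-bin gene scheme. Bin i of the
## maternal gene is compared with bin i of the paternal gene by ordinal
## index (allele bodies differ in length, so correspondence is by scheme
## position, not coordinates). The test and the per-context significance
## rule are exactly the DMR ones (shared code path).

#' Test allele pairs for allele-specific methylation regions
#'
#' For one phase and context, compares maternal and paternal per-bin
#' replicate counts with the replicate-aware binomial-logistic LRT used for
#' DMRs. BH q-values across all tested (pair, bin) units; an ASMR requires
#' `|difference| >` the per-context threshold (0.25/0.25/0.15) and
#' `q < 0.05`. Direction is the sign of maternal minus paternal.
#'
#' @param maternal,paternal Lists with `mC`/`uC` matrices (rows = pair x bin
#'   units in identical order, columns = replicates).
#' @param pair Character vector mapping rows to allele-pair ids.
#' @param bin Integer vector (1..80) mapping rows to scheme bins.
#' @param context Cytosine context.
#' @param phase Phase label carried through.
#' @param qvalue_cutoff BH threshold (default 0.05).
#' @return data.table: pair, bin, context, phase, maternal_level,
#'   paternal_level, difference (maternal - paternal), p, q, asmr,
#'   direction in {maternal_hyper, paternal_hyper, none}.
#' @export
testAsmr <- function(maternal, paternal, pair, bin, context,
                     phase = NA_character_, qvalue_cutoff = 0.05) {
  ## group1 = paternal, group2 = maternal so difference = maternal - paternal
  res <- testDmr(paternal, maternal, context, qvalue_cutoff = qvalue_cutoff)
  out <- data.table(pair = pair, bin = bin, context = context, phase = phase,
                    maternal_level = res$level2, paternal_level = res$level1,
                    difference = res$difference, p = res$p, q = res$q,
                    asmr = res$dmr,
                    direction = ifelse(res$dmr,
                                       ifelse(res$difference > 0,
                                              "maternal_hyper",
                                              "paternal_hyper"), "none"))
  out[]
}

#' Summarize ASMRs into allele-specific methylation genes
#'
#' An ASMG is an allele pair carrying one or more ASMRs in a context.
#'
#' @param asmrs data.table of [testAsmr()] rows (possibly several phases).
#' @return data.table: pair, context, n_asmrs (distinct significant bins),
#'   phases observed.
#' @export
asmgTable <- function(asmrs) {
  sig <- asmrs[asmr == TRUE]
  if (nrow(sig) == 0L)
    return(data.table(pair = character(), context = character(),
                      n_asmrs = integer(), phases = character()))
  sig[, .(n_asmrs = length(unique(bin)),
          phases = paste(sort(unique(phase)), collapse = ",")),
      by = .(pair, context)]
}

#' Fraction of ASMRs whose allelic direction shifts between phases
#'
#' Matches ASMRs by (pair, bin, context) across phases. A region enters the
#' denominator when significant in at least two phases; it is shifted when
#' those significant calls include both directions. Regions significant in
#' only one phase are stable by default and counted in neither.
#'
#' @param asmrs [testAsmr()] rows across phases.
#' @return data.table per context: n_matched, n_shifted, fraction.
#' @export
biasShiftFraction <- function(asmrs) {
  sig <- asmrs[asmr == TRUE]
  per <- sig[, .(n_phases = length(unique(phase)),
                 n_dir = length(unique(direction))),
             by = .(pair, bin, context)]
  per <- per[n_phases >= 2L]
  out <- per[, .(n_matched = .N, n_shifted = sum(n_dir > 1L)), by = context]
  out[, fraction := ifelse(n_matched > 0, n_shifted / n_matched, NA_real_)]
  all_ctx <- data.table(context = CONTEXTS)
  out <- merge(all_ctx, out, by = "context", all.x = TRUE)
  out[is.na(n_matched), `:=`(n_matched = 0L, n_shifted = 0L)]
  out[]
}

#' Compare ASMR-count distributions between gene groups
#'
#' Distribution of per-gene ASMR counts (1, 2, >= 3) in two groups (e.g.
#' phase-dependent ASEGs vs the remaining ASMGs), with a two-sided test on
#' the >= 3 proportion per context: chi-square with continuity correction,
#' or Fisher's exact test when any expected cell is below 5. When the >= 3
#' category is empty in both groups the test is skipped with a notice.
#'
#' @param asmg [asmgTable()] output.
#' @param group1_pairs,group2_pairs Character vectors of pair ids defining
#'   the two groups.
#' @param group_names Labels (default c("group1", "group2")).
#' @return data.table per context: counts per category and group, test used,
#'   p.
#' @export
asmrCountComparison <- function(asmg, group1_pairs, group2_pairs,
                                group_names = c("group1", "group2")) {
  if (!length(group1_pairs) || !length(group2_pairs)) stop("empty group")
  res <- rbindlist(lapply(CONTEXTS, function(ctx) {
    sub <- asmg[context == ctx]
    catOf <- function(pairs) {
      n <- sub[pair %in% pairs]$n_asmrs
      c(`1` = sum(n == 1L), `2` = sum(n == 2L), `3+` = sum(n >= 3L))
    }
    c1 <- catOf(group1_pairs)
    c2 <- catOf(group2_pairs)
    n1 <- sum(c1)
    n2 <- sum(c2)
    if (n1 == 0L || n2 == 0L) {
      return(data.table(context = ctx, group = group_names,
                        n_1 = c(c1[1], c2[1]), n_2 = c(c1[2], c2[2]),
                        n_3plus = c(c1[3], c2[3]), test = "none",
                        p = NA_real_))
    }
    tab <- rbind(c(c1[["3+"]], n1 - c1[["3+"]]),
                 c(c2[["3+"]], n2 - c2[["3+"]]))
    if (sum(tab[, 1]) == 0L) {
      test <- "skipped (no gene with >= 3 ASMRs)"
      p <- NA_real_
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"
        p <- fisher.test(tab)$p.value
      } else {
        test <- "chisq"
        p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
      }
    }
    data.table(context = ctx, group = group_names,
               n_1 = c(c1[1], c2[1]), n_2 = c(c1[2], c2[2]),
               n_3plus = c(c1[3], c2[3]), test = test, p = p)
  }))
  res[]
}
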