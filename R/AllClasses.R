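#' @import methods BiocGenerics S4Vectors IRanges GenomicRanges
#' @importFrom stats p.adjust pchisq pnorm pbinom rbinom rpois rbeta rnbinom
#'   runif rnorm rlnorm phyper dhyper fisher.test chisq.test wilcox.test prcomp
#'   setNames cor.test rmultinom dnbinom qnorm
#' @importFrom utils packageVersion
#' @importFrom data.table data.table as.data.table setDT setnames fwrite fread
#'   rbindlist setorder :=
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString
#' @importFrom Rcpp evalCpp
#' @importClassesFrom GenomicRanges CompressedGRangesList
#' @importClassesFrom Biostrings DNAStringSet
#' @useDynLib alleleMeth, .registration = TRUE
NULL

.datatable.aware <- TRUE

## Phases with whole-genome bisulfite data (explant + two direct + three
## indirect organogenesis stages) and the larger RNA-seq phase set.
METH_PHASES <- c("LE", "DP1", "DP2", "IP1", "IP2", "IP3")
EXPR_PHASES <- c("LE", "DP1", "DP2", "IP0.5", "IP1", "IP1.5", "IP2", "IP3")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Methylome and expression phase labels
#'
#' The closed vocabulary of developmental phases used throughout the package:
#' `LE` (leaf explant), `DP1`/`DP2` (direct organogenesis stages) and
#' `IP0.5`--`IP3` (indirect organogenesis via callus). Methylomes exist for
#' the six phases returned by `methPhases()`; expression for the eight
#' returned by `exprPhases()`.
#'
#' @return A character vector of phase labels.
#' @export
#' @examples
#' methPhases()
methPhases <- function() METH_PHASES

#' @rdname methPhases
#' @export
exprPhases <- function() EXPR_PHASES

#' Cytosine sequence contexts
#'
#' @return `c("CG", "CHG", "CHH")`.
#' @export
contexts <- function() CONTEXTS

setClassUnion("GRangesList_OR_NULL", c("CompressedGRangesList", "NULL"))

#' GenomeBundle: a two-subgenome hybrid genome with annotation
#'
#' Container for the sequences, gene models and transposable-element (TE)
#' annotation of a hybrid genome whose chromosomes belong to one of two
#' subgenomes (maternal and paternal parents of the hybrid). Chromosome names
#' are unique across subgenomes; `subgenomeOf` maps each chromosome to its
#' subgenome and `parentOf` maps each subgenome to `"maternal"` or
#' `"paternal"`.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of all chromosomes.
#' @slot genes A [GenomicRanges::GRanges] of gene bodies with metadata columns
#'   `gene_id`, `subgenome` and `exon_length` (exon-union length in bp).
#' @slot exons Optional [GenomicRanges::GRangesList] of exons per gene (may be
#'   `NULL` for single-exon models).
#' @slot tes A [GenomicRanges::GRanges] of TEs with metadata columns
#'   `te_class` (LTR/LINE/SINE/DNA) and `subgenome`.
#' @slot subgenomeOf Named character: chromosome -> subgenome id.
#' @slot parentOf Named character: subgenome id -> "maternal"/"paternal".
#' @export
setClass("GenomeBundle", slots = c(
  sequences = "DNAStringSet",
  genes = "GRanges",
  exons = "GRangesList_OR_NULL",
  tes = "GRanges",
  subgenomeOf = "character",
  parentOf = "character"
))

setValidity("GenomeBundle", function(object) {
  msg <- character()
  sg <- unique(object@subgenomeOf)
  if (length(sg) != 2L) msg <- c(msg, "exactly two distinct subgenomes required")
  if (!setequal(sort(unname(object@parentOf)), c("maternal", "paternal")))
    msg <- c(msg, "parentOf must assign one maternal and one paternal subgenome")
  if (!all(names(object@subgenomeOf) %in% names(object@sequences)))
    msg <- c(msg, "subgenomeOf names must be chromosome names")
  g <- object@genes
  if (length(g)) {
    if (is.null(g$gene_id) || anyDuplicated(g$gene_id))
      msg <- c(msg, "genes need unique gene_id")
    chr <- as.character(seqnames(g))
    if (!all(chr %in% names(object@sequences))) {
      msg <- c(msg, "gene on unknown chromosome")
    } else {
      lens <- Biostrings::width(object@sequences)[match(chr, names(object@sequences))]
      if (any(start(g) < 1L) || any(end(g) > lens))
        msg <- c(msg, "gene outside chromosome bounds")
    }
  }
  if (!is.null(object@exons)) {
    ok <- vapply(object@exons, function(e) {
      s <- start(e)
      !is.unsorted(s) && (length(e) < 2L || all(start(e)[-1] > end(e)[-length(e)]))
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "exons must be sorted and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBundle
#'
#' @param sequences DNAStringSet of chromosomes (named).
#' @param genes GRanges of genes (`gene_id`, `subgenome`, `exon_length`).
#' @param tes GRanges of TEs (`te_class`, `subgenome`); may be empty.
#' @param subgenomeOf Named character chromosome -> subgenome.
#' @param parentOf Named character subgenome -> "maternal"/"paternal".
#' @param exons Optional GRangesList of exons per gene.
#' @return A [GenomeBundle-class] object.
#' @export
GenomeBundle <- function(sequences, genes, tes = GRanges(), subgenomeOf,
                         parentOf, exons = NULL) {
  if (is.null(genes$exon_length)) genes$exon_length <- width(genes)
  new("GenomeBundle", sequences = sequences, genes = genes, exons = exons,
      tes = tes, subgenomeOf = subgenomeOf, parentOf = parentOf)
}

#' @describeIn GenomeBundle-class Chromosome sequences.
#' @param x,object A GenomeBundle.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname GenomeBundle-class
#' @export
setMethod("genomeSequences", "GenomeBundle", function(x) x@sequences)

#' @describeIn GenomeBundle-class Gene models.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname GenomeBundle-class
#' @export
setMethod("geneModels", "GenomeBundle", function(x) x@genes)

#' @describeIn GenomeBundle-class TE annotation.
#' @export
setGeneric("teAnnotation", function(x) standardGeneric("teAnnotation"))
#' @rdname GenomeBundle-class
#' @export
setMethod("teAnnotation", "GenomeBundle", function(x) x@tes)

#' @describeIn GenomeBundle-class Chromosome -> subgenome map.
#' @export
setGeneric("subgenomeOf", function(x) standardGeneric("subgenomeOf"))
#' @rdname GenomeBundle-class
#' @export
setMethod("subgenomeOf", "GenomeBundle", function(x) x@subgenomeOf)

#' @describeIn GenomeBundle-class Subgenome -> parent-of-origin map.
#' @export
setGeneric("parentOf", function(x) standardGeneric("parentOf"))
#' @rdname GenomeBundle-class
#' @export
setMethod("parentOf", "GenomeBundle", function(x) x@parentOf)

#' @describeIn GenomeBundle-class The subgenome id of the maternal (resp.
#'   paternal) parent.
#' @export
setGeneric("maternalSubgenome", function(x) standardGeneric("maternalSubgenome"))
#' @rdname GenomeBundle-class
#' @export
setMethod("maternalSubgenome", "GenomeBundle",
          function(x) names(x@parentOf)[x@parentOf == "maternal"])
#' @describeIn GenomeBundle-class Paternal subgenome id.
#' @export
setGeneric("paternalSubgenome", function(x) standardGeneric("paternalSubgenome"))
#' @rdname GenomeBundle-class
#' @export
setMethod("paternalSubgenome", "GenomeBundle",
          function(x) names(x@parentOf)[x@parentOf == "paternal"])

setMethod("show", "GenomeBundle", function(object) {
  sg <- unique(object@subgenomeOf)
  cat("GenomeBundle with", length(object@sequences), "chromosomes in",
      length(sg), "subgenomes (", paste(sg, collapse = ", "), ")\n")
  cat("  total length:", sum(Biostrings::width(object@sequences)), "bp\n")
  cat("  genes:", length(object@genes), " TEs:", length(object@tes), "\n")
})

#' SimConfig: parameters of the synthetic diploid-hybrid generator
#'
#' Holds every tunable of the synthetic data generator as a validated named
#' list. Construct with [SimConfig()]; retrieve single parameters with
#' `simParam(config, name)` or the full list with `simParams(config)`.
#'
#' @slot params Named list of generator parameters.
#' @export
setClass("SimConfig", slots = c(params = "list"))

simConfigDefaults <- function() {
  list(
    seed = 1L,
    ## genome architecture
    n_chromosomes = 2L,              # per subgenome (desk scale, not 19)
    n_gene_pairs = 500L,
    gene_length_meanlog = log(1500), # lognormal body-length model
    gene_length_sdlog = 0.25,
    gene_length_range = c(500L, 4000L),
    promoter_length = 2000L,
    snp_rate = 0.01,                 # per-base divergence between alleles
    relocation_fraction = 0.1,       # pairs moved out of collinear order
    intergenic_range = c(600L, 1400L),
    max_chromosome_length = NA_real_,  # NA: derived from content
    te_density = 0.3,                # fraction of intergenic gaps with a TE
    te_class_mix = c(LTR = 0.35, LINE = 0.25, DNA = 0.25, SINE = 0.15),
    te_length_range = c(200L, 500L),
    subgenomes = c(alba = "maternal", glan = "paternal"),
    ## methylome model
    ctx_frac_meth = c(CG = 0.50, CHG = 0.35, CHH = 0.12),
    ctx_beta_hi = list(CG = c(8, 2), CHG = c(5, 3), CHH = c(2, 5)),
    beta_lo = c(0.3, 30),
    te_frac_factor = c(LTR = 1.7, LINE = 1.6, DNA = 1.5, SINE = 2.0),
    phase_factors = rbind(
      CG  = c(LE = 1, DP1 = 0.833, DP2 = 0.95, IP1 = 0.909, IP2 = 0.95, IP3 = 1.00),
      CHG = c(LE = 1, DP1 = 0.833, DP2 = 0.95, IP1 = 0.909, IP2 = 0.95, IP3 = 1.00),
      CHH = c(LE = 1, DP1 = 0.750, DP2 = 0.85, IP1 = 0.800, IP2 = 0.95, IP3 = 1.10)),
    coverage_mean = 30,
    non_conversion = 0.005,
    replicate_concentration = 200,   # beta-binomial replicate jitter
    n_reps_meth = 3L,
    ## true DMR windows (offset from DP1/IP1 onward)
    n_dmr_windows = 100L,            # per context
    dmr_offset = 0.4,
    dmr_hypo_fraction = 0.7,
    ## allele-specific methylation truth
    asmg_fraction = 0.3,
    asmr_offset = 0.4,
    asmr_n_bins = 5L,                # contiguous 80-scheme bins per ASMG
    ## expression model
    mu_meanlog = log(150),
    mu_sdlog = 1.5,
    silent_fraction = 0.1,  # near-zero expression; populates TPM class I
    dispersion = 0.05,
    aseg_fraction = 0.15,
    aseg_log2fc_range = c(1.5, 3),
    phase_dep_fraction = 0.05,
    n_reps_expr = 3L,
    library_size_range = c(0.8, 1.25),
    ## promoter motif model
    motif_presence_prob = 0.4,
    motif_flip_prob = 0.03,
    aseg_flip_prob = 0.25
  )
}

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- character()
  need <- names(simConfigDefaults())
  miss <- setdiff(need, names(p))
  if (length(miss)) return(paste("missing parameters:", paste(miss, collapse = ", ")))
  probs <- c(p$snp_rate, p$relocation_fraction, p$te_density, p$te_class_mix,
             p$ctx_frac_meth, p$non_conversion, p$aseg_fraction,
             p$phase_dep_fraction, p$asmg_fraction, p$dmr_hypo_fraction,
             p$motif_presence_prob, p$motif_flip_prob, p$aseg_flip_prob)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (p$coverage_mean <= 0) msg <- c(msg, "coverage_mean must be > 0")
  if (p$promoter_length != 2000L) msg <- c(msg, "promoter_length must be 2000")
  if (p$n_reps_meth < 2L || p$n_reps_expr < 2L)
    msg <- c(msg, "at least 2 replicates per phase required")
  if (p$dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (!all(rownames(p$phase_factors) == CONTEXTS) ||
      !all(colnames(p$phase_factors) == METH_PHASES))
    msg <- c(msg, "phase_factors must be a context x methylome-phase matrix")
  if (length(msg)) msg else TRUE
})

#' Build a simulator configuration
#'
#' Returns the default configuration of the synthetic diploid-hybrid
#' generator, with any named arguments overriding defaults. Defaults emulate
#' the study system at desk scale: two subgenomes of 2 chromosomes carrying
#' 500 diverged allele pairs (1% SNP divergence, 10% relocated), ~30x
#' Poisson bisulfite coverage with a 0.005 non-conversion rate, global
#' hypomethylation at the first induction phases, a CHH
#' decrease-then-increase trajectory, TE hypermethylation with SINEs highest,
#' negative-binomial allele counts with configurable phase-dependent bias,
#' and promoter motif content whose divergence is coupled to allelic
#' expression divergence.
#'
#' @param ... Named parameter overrides; see `simParams(SimConfig())` for the
#'   full set.
#' @return A [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- SimConfig(n_gene_pairs = 50L, seed = 7L)
#' simParam(cfg, "coverage_mean")
SimConfig <- function(...) {
  over <- list(...)
  p <- simConfigDefaults()
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown SimConfig parameters: ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  new("SimConfig", params = p)
}

#' @describeIn SimConfig-class All parameters as a named list.
#' @param x A SimConfig.
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
#' @rdname SimConfig-class
#' @export
setMethod("simParams", "SimConfig", function(x) x@params)

#' @describeIn SimConfig-class A single parameter by name.
#' @param name Parameter name.
#' @export
simParam <- function(x, name) {
  p <- simParams(x)
  if (!name %in% names(p)) stop("no such parameter: ", name)
  p[[name]]
}

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$n_gene_pairs, "gene pairs on", p$n_chromosomes,
      "chromosomes/subgenome\n")
  cat("  divergence:", p$snp_rate, " relocation:", p$relocation_fraction, "\n")
  cat("  coverage:", p$coverage_mean, "x  non-conversion:", p$non_conversion, "\n")
  cat("  ASEG fraction:", p$aseg_fraction, " phase-dependent:",
      p$phase_dep_fraction, " ASMG fraction:", p$asmg_fraction, "\n")
})
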