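#' Parameters of the synthetic tetraploid genome
#'
#' An S4 container holding every tunable of the synthetic-genome generator.
#' The defaults describe the standard study conditions: a two-subgenome
#' (AABB) tetraploid scaled down to `nHomeologousPairs` homeologous pairs of
#' `chromosomeLength`-base chromosomes, a repeat-rich composition
#' (`teFraction`), conserved genes with grass orthologs at a mean coding
#' length of 2772 bases, planted miRNA hairpins (a fraction embedded in
#' transposable elements), lncRNAs, coding decoys, SSR loci, and one
#' engineered interchromosomal translocation.
#'
#' @slot nHomeologousPairs number of homeologous chromosome pairs.
#' @slot chromosomeLength length of every chromosome, bases.
#' @slot teFraction target fraction of bases covered by transposable
#'   elements, in `[0,1]`.
#' @slot teFamilyWeights named numeric sampling weights over the internal
#'   repeat-library families.
#' @slot nConservedGenesPerChr conserved genes planted per chromosome.
#' @slot meanCdsLength mean planted coding-sequence length, bases.
#' @slot nMirnaHairpins total miRNA hairpins planted genome-wide.
#' @slot teEmbeddedMirnaFraction fraction of hairpins embedded inside a
#'   transposable-element copy.
#' @slot nLncrna total lncRNA loci planted genome-wide.
#' @slot nCodingDecoys total protein-coding decoy transcripts planted.
#' @slot nSsr total SSR loci planted genome-wide (above detection
#'   thresholds; a few sub-threshold repeats are planted in addition).
#' @slot translocation list with elements `donor`, `acceptor`,
#'   `tailLength` describing the engineered one-way segment move, or an
#'   empty list for none.
#' @slot scaffoldN50Target target N50 for [fragmentIntoScaffolds()], bases.
#' @slot seed integer seed; a fixed seed makes the entire output
#'   byte-identical across runs.
#' @export
setClass("SyntheticGenomeSpec",
  representation(
    nHomeologousPairs = "integer",
    chromosomeLength = "integer",
    teFraction = "numeric",
    teFamilyWeights = "numeric",
    nConservedGenesPerChr = "integer",
    meanCdsLength = "integer",
    nMirnaHairpins = "integer",
    teEmbeddedMirnaFraction = "numeric",
    nLncrna = "integer",
    nCodingDecoys = "integer",
    nSsr = "integer",
    translocation = "list",
    scaffoldN50Target = "integer",
    seed = "integer"))

setValidity("SyntheticGenomeSpec", function(object) {
  msg <- character(0)
  fr <- c(teFraction = object@teFraction,
          teEmbeddedMirnaFraction = object@teEmbeddedMirnaFraction)
  bad <- fr < 0 | fr > 1
  if (any(bad)) msg <- c(msg, paste0(names(fr)[bad], " must lie in [0,1]"))
  for (s in c("nHomeologousPairs", "chromosomeLength", "meanCdsLength",
              "scaffoldN50Target")) {
    if (slot(object, s) <= 0L) msg <- c(msg, paste0(s, " must be > 0"))
  }
  for (s in c("nConservedGenesPerChr", "nMirnaHairpins", "nLncrna",
              "nCodingDecoys", "nSsr")) {
    if (slot(object, s) < 0L) msg <- c(msg, paste0(s, " must be >= 0"))
  }
  if (length(object@translocation) &&
      !all(c("donor", "acceptor", "tailLength") %in%
           names(object@translocation)))
    msg <- c(msg, "translocation needs donor, acceptor, tailLength")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic genome specification
#'
#' @param nHomeologousPairs,chromosomeLength,teFraction,teFamilyWeights
#'   see the class slots.
#' @param nConservedGenesPerChr,meanCdsLength,nMirnaHairpins
#'   see the class slots.
#' @param teEmbeddedMirnaFraction,nLncrna,nCodingDecoys,nSsr,translocation
#'   see the class slots.
#' @param scaffoldN50Target,seed see the class slots.
#' @return a validated [SyntheticGenomeSpec-class] object.
#' @examples
#' spec <- syntheticGenomeSpec(seed = 7)
#' spec
#' @export
syntheticGenomeSpec <- function(nHomeologousPairs = 2L,
                                chromosomeLength = 500000L,
                                teFraction = 0.6,
                                teFamilyWeights = NULL,
                                nConservedGenesPerChr = 25L,
                                meanCdsLength = 2772L,
                                nMirnaHairpins = 16L,
                                teEmbeddedMirnaFraction = 0.25,
                                nLncrna = 12L,
                                nCodingDecoys = 12L,
                                nSsr = 20L,
                                translocation = list(donor = "2A",
                                                     acceptor = "1B",
                                                     tailLength = 50000L),
                                scaffoldN50Target = 5000L,
                                seed = 1L) {
  if (is.null(teFamilyWeights)) teFamilyWeights <- defaultFamilyWeights()
  new("SyntheticGenomeSpec",
      nHomeologousPairs = as.integer(nHomeologousPairs),
      chromosomeLength = as.integer(chromosomeLength),
      teFraction = teFraction,
      teFamilyWeights = teFamilyWeights,
      nConservedGenesPerChr = as.integer(nConservedGenesPerChr),
      meanCdsLength = as.integer(meanCdsLength),
      nMirnaHairpins = as.integer(nMirnaHairpins),
      teEmbeddedMirnaFraction = teEmbeddedMirnaFraction,
      nLncrna = as.integer(nLncrna),
      nCodingDecoys = as.integer(nCodingDecoys),
      nSsr = as.integer(nSsr),
      translocation = translocation,
      scaffoldN50Target = as.integer(scaffoldN50Target),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticGenomeSpec", function(object) {
  chroms <- paste0(rep(seq_len(object@nHomeologousPairs), each = 2L),
                   c("A", "B"))
  cat("SyntheticGenomeSpec:", length(chroms), "chromosomes (",
      paste(chroms, collapse = ", "), ") x",
      object@chromosomeLength, "b\n")
  cat("  teFraction:", object@teFraction,
      " genes/chr:", object@nConservedGenesPerChr,
      " hairpins:", object@nMirnaHairpins,
      " lncRNA:", object@nLncrna, "\n")
  if (length(object@translocation))
    cat("  translocation:", object@translocation$donor, "->",
        object@translocation$acceptor,
        paste0("(", object@translocation$tailLength, " b tail)\n"))
  cat("  seed:", object@seed, "\n")
})

#' Ground truth of a synthetic genome
#'
#' Records every planted feature (coordinates and identities), the per
#' chromosome true repeat fraction, the true conserved-gene count, and the
#' engineered translocation breakpoints. All coordinates are 0-based
#' half-open on the final (post-translocation) chromosomes. The manifest
#' round-trips losslessly through [writeManifest()] / [readManifest()].
#'
#' @slot chromosomeLengths named integer vector of final chromosome lengths.
#' @slot tes data.frame of transposable-element copies (`te_id`, `chrom`,
#'   `start`, `end`, `family`, `superfamily`, `class`, `mutation_rate`).
#' @slot genes data.frame of conserved genes with grass-ortholog identifiers
#'   and homeolog group labels.
#' @slot exons data.frame of exon intervals per gene.
#' @slot mirnas data.frame of planted hairpin loci (`precursor` interval,
#'   mature interval, family, mature RNA sequence, `te_embedded` flag).
#' @slot lncrnas data.frame of planted lncRNA loci (with
#'   `has_mirna_site` / `site_family` for the planted target-mimicry sites).
#' @slot decoys data.frame of planted protein-coding decoys and the cascade
#'   stage expected to remove each (`removal`).
#' @slot ssrs data.frame of planted SSR loci, including sub-threshold
#'   repeats flagged `above_threshold = FALSE`.
#' @slot teJunctions data.frame of assayable transposable-element junctions.
#' @slot translocation list of engineered breakpoints (empty if none).
#' @slot trueRepeatFraction named numeric, per-chromosome repeat fraction.
#' @slot trueConservedGeneCount integer, planted conserved gene count.
#' @slot spec the generating [SyntheticGenomeSpec-class].
#' @export
setClass("TruthManifest",
  representation(
    chromosomeLengths = "integer",
    tes = "data.frame",
    genes = "data.frame",
    exons = "data.frame",
    mirnas = "data.frame",
    lncrnas = "data.frame",
    decoys = "data.frame",
    ssrs = "data.frame",
    teJunctions = "data.frame",
    translocation = "list",
    trueRepeatFraction = "numeric",
    trueConservedGeneCount = "integer",
    spec = "SyntheticGenomeSpec"))

setValidity("TruthManifest", function(object) {
  msg <- character(0)
  lens <- object@chromosomeLengths
  inBounds <- function(df, what) {
    if (!nrow(df)) return(character(0))
    bad <- df$start < 0 | df$end > lens[df$chrom] | df$start >= df$end
    if (any(bad)) paste0(what, ": feature outside its chromosome")
    else character(0)
  }
  msg <- c(msg, inBounds(object@tes, "tes"), inBounds(object@genes, "genes"),
           inBounds(object@lncrnas, "lncrnas"), inBounds(object@ssrs, "ssrs"))
  for (s in c("tes", "genes", "mirnas", "lncrnas", "decoys", "ssrs")) {
    df <- slot(object, s)
    if (ncol(df) && anyDuplicated(df[[1L]]))
      msg <- c(msg, paste0(s, ": duplicate identifiers"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthManifest", function(object) {
  cat("TruthManifest:", length(object@chromosomeLengths), "chromosomes,",
      sum(as.numeric(object@chromosomeLengths)), "b total\n")
  cat("  planted:", nrow(object@tes), "TEs,",
      nrow(object@genes), "genes,", nrow(object@mirnas), "hairpins,",
      nrow(object@lncrnas), "lncRNAs,", nrow(object@decoys), "decoys,",
      nrow(object@ssrs), "SSRs\n")
  cat("  true repeat fraction:",
      round(sum(object@trueRepeatFraction * object@chromosomeLengths) /
            sum(as.numeric(object@chromosomeLengths)), 4), "(genome-wide)\n")
  if (length(object@translocation))
    cat("  translocation:", object@translocation$donor, "->",
        object@translocation$acceptor, "at donor breakpoint",
        object@translocation$donorBreakpoint, "\n")
})

## canonical empty feature tables (column prototypes shared by the
## generator, the manifest reader and the class default)
.manifestProtos <- list(
  tes = data.frame(te_id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   family = character(0), superfamily = character(0),
                   class = character(0), strand = character(0),
                   mutation_rate = numeric(0), stringsAsFactors = FALSE),
  genes = data.frame(gene_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), cds_length = integer(0),
                     homeolog_group = character(0),
                     ortholog_bd = character(0), ortholog_os = character(0),
                     ortholog_sb = character(0), ortholog_hv = character(0),
                     stringsAsFactors = FALSE),
  exons = data.frame(gene_id = character(0), exon_index = integer(0),
                     start = integer(0), end = integer(0),
                     stringsAsFactors = FALSE),
  mirnas = data.frame(mirna_id = character(0), family = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      mature_seq = character(0), te_embedded = logical(0),
                      stringsAsFactors = FALSE),
  lncrnas = data.frame(lnc_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), has_mirna_site = logical(0),
                       site_family = character(0), stringsAsFactors = FALSE),
  decoys = data.frame(decoy_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), removal = character(0),
                      stringsAsFactors = FALSE),
  ssrs = data.frame(ssr_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    motif = character(0), count = integer(0),
                    above_threshold = logical(0), stringsAsFactors = FALSE),
  teJunctions = data.frame(junction_id = character(0), chrom = character(0),
                           pos = integer(0), left = character(0),
                           right = character(0), stringsAsFactors = FALSE))

#' @describeIn TruthManifest-class chromosome lengths accessor
#' @param x a `TruthManifest`.
#' @export
chromosomeLengths <- function(x) x@chromosomeLengths

#' @describeIn TruthManifest-class planted-feature accessor; `what` is one of
#'   `"tes"`, `"genes"`, `"exons"`, `"mirnas"`, `"lncrnas"`, `"decoys"`,
#'   `"ssrs"`, `"teJunctions"`.
#' @param what feature table name.
#' @export
plantedFeatures <- function(x, what) {
  stopifnot(is(x, "TruthManifest"))
  slot(x, match.arg(what, c("tes", "genes", "exons", "mirnas", "lncrnas",
                            "decoys", "ssrs", "teJunctions")))
}

#' @describeIn TruthManifest-class true per-chromosome repeat fraction
#' @export
trueRepeatFraction <- function(x) x@trueRepeatFraction

#' @describeIn TruthManifest-class planted conserved-gene count
#' @export
trueConservedGeneCount <- function(x) x@trueConservedGeneCount

#' @describeIn TruthManifest-class engineered translocation breakpoints
#' @export
translocationTruth <- function(x) x@translocation

#' Reference-guided super-scaffold set
#'
#' Holds the super-scaffold sequences (N-gapped concatenations of member
#' scaffolds in reference orientation) together with the ordered member
#' placements that produced each one.
#'
#' @slot sequences [Biostrings::DNAStringSet] of super-scaffold sequences.
#' @slot members data.frame with one row per member placement: `super_id`,
#'   `query_id`, `chrom`, `start`, `end` (0-based half-open on the
#'   reference), `strand`, `order`.
#' @export
setClass("SuperScaffoldSet",
  representation(sequences = "DNAStringSet", members = "data.frame"))

setValidity("SuperScaffoldSet", function(object) {
  m <- object@members
  if (nrow(m) && !all(m$super_id %in% names(object@sequences)))
    return("members reference unknown super-scaffold ids")
  ok <- vapply(split(m, m$super_id), function(d) {
    !is.unsorted(d$start[order(d$order)])
  }, logical(1L))
  if (!all(ok)) return("members not sorted by reference start")
  TRUE
})

setMethod("show", "SuperScaffoldSet", function(object) {
  nmem <- table(object@members$super_id)
  cat("SuperScaffoldSet:", length(object@sequences), "super-scaffolds from",
      nrow(object@members), "member placements\n")
  cat("  merged (>1 member):", sum(nmem > 1L),
      " total length:", sum(Biostrings::width(object@sequences)), "b\n")
})

#' @describeIn SuperScaffoldSet-class sequences accessor
#' @param x a `SuperScaffoldSet`.
#' @export
superScaffoldSequences <- function(x) x@sequences

#' @describeIn SuperScaffoldSet-class member-placement accessor
#' @export
superScaffoldMembers <- function(x) x@members
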