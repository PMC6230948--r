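## Internal sequence libraries for the synthetic genome. Both are generated
## under a fixed internal seed so they are identical for every user seed;
## the user seed only controls where and how copies are planted.

.teFamilyTable <- data.frame(
  family      = c("Angela", "Fatima", "Karin", "Aladin", "Jorge",
                  "Thalos", "Wanderer"),
  superfamily = c("Copia", "Gypsy", "L1", "SINE", "En-Spm/CACTA",
                  "Tc1/Mariner", "undetermined-LTR"),
  class       = c("I-retroelement", "I-retroelement", "I-retroelement",
                  "I-retroelement", "II-DNA-transposon", "II-DNA-transposon",
                  "undetermined-LTR"),
  length      = c(2000L, 2200L, 1500L, 300L, 1800L, 800L, 1200L),
  stringsAsFactors = FALSE)

#' Built-in transposable-element library
#'
#' Seven repeat families spanning Class I LTR retroelements (Copia/Gypsy),
#' a LINE, a SINE, Class II DNA transposons (a dominant CACTA family named
#' after the Triticeae "Jorge" family, and a Tc1/Mariner analogue) and an
#' "undetermined LTR" class. Headers follow the
#' \code{family#superfamily#class} convention used throughout the package.
#' Sequences are fixed (internal seed) so landscape summaries are
#' reproducible.
#'
#' @return a [Biostrings::DNAStringSet] named \code{family#superfamily#class}.
#' @examples
#' names(repeatLibrary())
#' @export
repeatLibrary <- function() {
  seqs <- withSeed(20180521L, vapply(.teFamilyTable$length, randomDna,
                                     character(1L)))
  Biostrings::DNAStringSet(setNames(seqs, paste(.teFamilyTable$family,
                                                .teFamilyTable$superfamily,
                                                .teFamilyTable$class,
                                                sep = "#")))
}

## default family sampling weights; the CACTA family dominates, emulating
## the prominence of Jorge among Triticeae DNA transposons
defaultFamilyWeights <- function() {
  c(Jorge = 0.28, Angela = 0.20, Fatima = 0.16, Karin = 0.12,
    Wanderer = 0.10, Thalos = 0.09, Aladin = 0.05)
}

## subgenome tilt applied to the undetermined-LTR family so that the A
## subgenome carries visibly more of it than B (A-vs-B landscape contrast)
.wandererTilt <- c(A = 1.8, B = 0.9)

#' Mature miRNA catalogue of the synthetic genome
#'
#' Eight 21-nt mature sequences. The first is the miR437 family mature
#' (AAAGUUAGAGAAGUUUGACUU); the others are fixed synthetic matures.
#'
#' @return named character vector of RNA strings (family -> mature).
#' @export
mirnaFamilies <- function() {
  extra <- withSeed(20180522L, vapply(1:7, function(i) {
    paste(sample(c("A", "C", "G", "U"), 21L, replace = TRUE), collapse = "")
  }, character(1L)))
  c("tdi-miR437" = "AAAGUUAGAGAAGUUUGACUU",
    setNames(extra, sprintf("tdi-miRs%02d", 2:8)))
}

## parse "family#superfamily#class" repeat-library headers
parseLibraryHeaders <- function(nm) {
  parts <- strsplit(nm, "#", fixed = TRUE)
  data.frame(family = vapply(parts, `[`, character(1L), 1L),
             superfamily = vapply(parts, function(p) {
               if (length(p) >= 2L) p[2L] else "unknown"
             }, character(1L)),
             class = vapply(parts, function(p) {
               if (length(p) >= 3L) p[3L] else "other"
             }, character(1L)),
             stringsAsFactors = FALSE)
}

#' Read a repeat library FASTA with \code{family#superfamily#class} headers
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] with the headers preserved.
#' @export
readRepeatLibrary <- function(path) {
  lib <- Biostrings::readDNAStringSet(path)
  parseLibraryHeaders(names(lib))  # validates header structure
  lib
}
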