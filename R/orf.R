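## Six-frame ORF scanning shared by the lncRNA cascade and the synthetic
## generator (which must plant lncRNAs free of long ORFs and decoys that
## carry one).

## peptide lengths (aa, excluding the stop, including the initial Met) of
## every complete ATG..stop ORF in the three forward frames of a DNA string
forwardOrfPeptides <- function(seq) {
  out <- integer(0)
  n <- nchar(seq)
  for (frame in 0:2) {
    len <- n - frame
    if (len < 6L) next
    len <- len - (len %% 3L)
    if (len < 6L) next
    ## no.init.codon: the frame start must not be promoted to M when it is
    ## an alternative initiation codon (CTG/TTG)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, frame + 1L, frame + len)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    m <- gregexpr("M[^*]*\\*", aa)[[1L]]
    if (m[1L] != -1L) out <- c(out, attr(m, "match.length") - 1L)
  }
  out
}

#' Length of the longest complete ORF in six frames
#'
#' Scans the three frames of the sequence and of its reverse complement for
#' complete ATG..stop open reading frames and returns the longest encoded
#' peptide length in amino acids (excluding the stop). ORFs without an
#' in-frame stop codon are not counted.
#'
#' @param seq a DNA string (character).
#' @param frames `6` (default) or `3` (forward frames only).
#' @return integer peptide length; `0` if no complete ORF exists.
#' @export
longestOrfLength <- function(seq, frames = 6L) {
  p <- forwardOrfPeptides(seq)
  if (frames == 6L) p <- c(p, forwardOrfPeptides(revcomp(seq)))
  if (length(p)) max(p) else 0L
}
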