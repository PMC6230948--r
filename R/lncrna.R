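## The lncRNA elimination cascade. Every stage returns the surviving ids
## plus trace rows (one per transcript per stage), so each transcript's
## fate is auditable: removed transcripts have exactly one removing stage,
## and stages always appear in the canonical cascade order
## length -> orf -> homology -> mapping -> splice -> core.

.cascadeStages <- c("length", "orf", "homology", "mapping", "splice", "core")

traceRows <- function(ids, stage, removed, reason) {
  if (!length(ids))
    return(data.frame(transcript_id = character(0), stage = character(0),
                      outcome = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  data.frame(transcript_id = ids, stage = stage,
             outcome = ifelse(removed, "removed", "kept"),
             reason = ifelse(removed, reason, ""),
             stringsAsFactors = FALSE)
}

#' Length filter of the lncRNA cascade
#'
#' Candidates longer than 200 nucleotides are accepted (strictly: a 200-nt
#' transcript is removed).
#'
#' @param transcripts named [Biostrings::DNAStringSet] or named character.
#' @param minLength length threshold (kept iff length > `minLength`).
#' @return list `survivors` (ids), `trace` (data.frame).
#' @export
filterByLength <- function(transcripts, minLength = 200L) {
  ids <- names(transcripts)
  lens <- if (is(transcripts, "XStringSet")) Biostrings::width(transcripts)
          else nchar(transcripts)
  removed <- lens <= minLength
  list(survivors = ids[!removed],
       trace = traceRows(ids, "length", removed,
                         sprintf("length %d <= %d", lens, minLength)))
}

#' ORF filter of the lncRNA cascade
#'
#' Scans all six frames for complete ATG..stop ORFs and removes any
#' transcript encoding a peptide longer than `maxPeptide` amino acids
#' (excluding the stop; a 100-aa ORF is kept under the default). Frames
#' without an in-frame stop codon contribute no ORF.
#'
#' @param transcripts named [Biostrings::DNAStringSet] or named character.
#' @param maxPeptide peptide-length threshold, aa.
#' @param frames 6 (default) or 3.
#' @return list `survivors`, `trace`, `longest_orf` (named integer).
#' @export
filterByOrf <- function(transcripts, maxPeptide = 100L, frames = 6L) {
  ids <- names(transcripts)
  seqs <- as.character(transcripts)
  longest <- vapply(seqs, longestOrfLength, integer(1L), frames = frames)
  removed <- longest > maxPeptide
  list(survivors = ids[!removed],
       trace = traceRows(ids, "orf", removed,
                         sprintf("ORF %d aa > %d", longest, maxPeptide)),
       longest_orf = setNames(longest, ids))
}

#' Default homology screens of the lncRNA cascade
#'
#' blastx against known proteins at (1e-5, length 30, ppos 80); tblastn at
#' (1e-5, 30, pident 80); Unigene/EST at (1e-30, 90, pident 80); organellar
#' genomes and structural ncRNAs at (1e-5, 30, pident 80). Any hit passing
#' its screen discards the transcript.
#'
#' @return named list of screen profiles.
#' @export
lncrnaScreens <- function() {
  list(
    blastx_protein = list(max_evalue = 1e-5, min_length = 30, min_ppos = 80),
    tblastn_protein = list(max_evalue = 1e-5, min_length = 30,
                           min_pident = 80),
    unigene_est = list(max_evalue = 1e-30, min_length = 90, min_pident = 80),
    organellar = list(max_evalue = 1e-5, min_length = 30, min_pident = 80),
    ncrna = list(max_evalue = 1e-5, min_length = 30, min_pident = 80))
}

#' Homology filter of the lncRNA cascade
#'
#' Removes any transcript with at least one hit passing its screen's
#' thresholds ("any homology discards"). Hits are tagged with a `screen`
#' column naming the screen profile that applies; an unknown tag is an
#' error. Externally produced coding-potential labels may be supplied as an
#' additional removal screen.
#'
#' @param ids transcript ids entering the stage.
#' @param hitTables data.frame with `query_id`, `screen` and the BLAST-style
#'   threshold columns (`evalue`, `length`, `ppos`, `pident`).
#' @param screens named list of screen profiles (see [lncrnaScreens()]).
#' @param codingLabels optional character vector of transcript ids labelled
#'   protein-coding by an external classifier (removed).
#' @return list `survivors`, `trace`.
#' @export
filterByHomology <- function(ids, hitTables, screens = lncrnaScreens(),
                             codingLabels = character(0)) {
  if (nrow(hitTables)) {
    unknown <- setdiff(unique(hitTables$screen), names(screens))
    if (length(unknown))
      stop("unknown homology screen tag: ", paste(unknown, collapse = ", "))
    pass <- vapply(seq_len(nrow(hitTables)), function(r) {
      p <- screens[[hitTables$screen[r]]]
      ok <- hitTables$evalue[r] <= p$max_evalue &&
        hitTables$length[r] >= p$min_length
      if (!is.null(p$min_ppos)) ok <- ok && hitTables$ppos[r] >= p$min_ppos
      if (!is.null(p$min_pident))
        ok <- ok && hitTables$pident[r] >= p$min_pident
      ok
    }, logical(1L))
    hitIds <- unique(hitTables$query_id[pass])
  } else hitIds <- character(0)
  removed <- ids %in% hitIds | ids %in% codingLabels
  reason <- ifelse(ids %in% hitIds, "homology hit", "coding label")
  list(survivors = ids[!removed],
       trace = traceRows(ids, "homology", removed, reason))
}

#' Mapping acceptance of lncRNA candidates, per genome
#'
#' A candidate is accepted on a genome iff it maps through its entire
#' length (coverage 1.0, tolerance configurable) with an alignment score of
#' at least `minScore` (a score of exactly 40 is accepted under the
#' default).
#'
#' @param ids transcript ids entering the stage.
#' @param mappingRecords data.frame `transcript_id`, `genome`, `coverage`
#'   (fraction of transcript, in `[0,1]`), `score`, `splice_signals`
#'   (comma-separated donor-acceptor dinucleotides, e.g. `"GT-AG"`; empty
#'   for mono-exonic alignments).
#' @param minScore minimum alignment score.
#' @param coverageTol tolerated coverage shortfall (default 0, i.e. the
#'   entire length).
#' @return list `acceptedPerGenome` (named list of id vectors), `survivors`
#'   (ids accepted on at least one genome), `trace`.
#' @export
acceptByMapping <- function(ids, mappingRecords, minScore = 40,
                            coverageTol = 0) {
  stopifnot(all(mappingRecords$coverage >= 0 & mappingRecords$coverage <= 1))
  rec <- mappingRecords[mappingRecords$transcript_id %in% ids, , drop = FALSE]
  ok <- rec$coverage >= 1 - coverageTol & rec$score >= minScore
  acc <- split(rec$transcript_id[ok], rec$genome[ok])
  acc <- lapply(acc, unique)
  survivors <- ids[ids %in% unlist(acc)]
  removed <- !(ids %in% survivors)
  list(acceptedPerGenome = acc, survivors = survivors,
       trace = traceRows(ids, "mapping", removed,
                         "no full-length mapping with score >= threshold"))
}

#' Splice-site sanity check
#'
#' Transcripts whose mapping contains any non-GT..AG intron are discarded
#' iff the reverse-complement orientation would have all-canonical splice
#' signals (i.e. every intron reads CT..AC) and the reverse complement of
#' the transcript contains an ORF encoding more than `maxPeptide` amino
#' acids — the case of a coding transcript picked up on the wrong strand.
#' All other transcripts are kept.
#'
#' @param ids transcript ids entering the stage.
#' @param mappingRecords as in [acceptByMapping()].
#' @param transcripts named sequence set covering `ids`.
#' @param maxPeptide ORF threshold for the reverse orientation, aa.
#' @return list `survivors`, `trace`.
#' @export
spliceSanityCheck <- function(ids, mappingRecords, transcripts,
                              maxPeptide = 100L) {
  splitSignals <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, ",", fixed = TRUE)[[1L]]
  }
  removed <- vapply(ids, function(id) {
    rec <- mappingRecords[mappingRecords$transcript_id == id, , drop = FALSE]
    sig <- unlist(lapply(rec$splice_signals, splitSignals))
    if (!length(sig) || all(sig == "GT-AG")) return(FALSE)
    if (!all(sig[sig != "GT-AG"] == "CT-AC")) return(FALSE)
    rc <- revcomp(as.character(transcripts[[id]]))
    max(c(0L, forwardOrfPeptides(rc))) > maxPeptide
  }, logical(1L))
  list(survivors = ids[!removed],
       trace = traceRows(ids, "splice", removed,
                         "noncanonical splice; reverse complement codes"))
}

#' Core lncRNA set across genomes
#'
#' Transcripts accepted on every genome; the core is never larger than the
#' smallest per-genome set.
#'
#' @param acceptedPerGenome named list (>= 2 genomes) of accepted id
#'   vectors.
#' @return character vector of core ids (sorted).
#' @export
intersectCoreSet <- function(acceptedPerGenome) {
  if (length(acceptedPerGenome) < 2L) stop("need at least 2 genomes")
  sort(Reduce(intersect, lapply(acceptedPerGenome, unique)))
}

#' Pair core lncRNAs with mature miRNAs
#'
#' Applies the miRNA target scorer ([scoreTarget()]) to every (mature,
#' lncRNA) combination and reports windows under the cutoff —
#' target-mimicry candidates.
#'
#' @param lncrnas named sequence set.
#' @param matures named character (family -> mature RNA).
#' @param cutoff penalty cutoff.
#' @return data.frame `lnc_id`, `family`, `target_start`, `target_end`,
#'   `penalty`.
#' @export
pairWithMirna <- function(lncrnas, matures, cutoff = 3.0) {
  rows <- list()
  for (id in names(lncrnas)) {
    seq <- as.character(lncrnas[[id]])
    for (fam in names(matures)) {
      w <- scoreTarget(matures[[fam]], seq, cutoff = cutoff)
      if (nrow(w))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(lnc_id = id, family = fam, stringsAsFactors = FALSE), w)
    }
  }
  if (!length(rows))
    return(data.frame(lnc_id = character(0), family = character(0),
                      target_start = integer(0), target_end = integer(0),
                      penalty = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Run the full lncRNA elimination cascade
#'
#' Applies, in canonical order: the >200-nt length filter, the six-frame
#' >100-aa ORF filter, the homology screens, per-genome full-length mapping
#' acceptance (score >= 40), the noncanonical-splice reverse-complement
#' check, and the cross-genome core-set intersection. Returns the
#' per-transcript audit trail: every input transcript appears with exactly
#' one removing stage or survives to the end.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param hitTables homology hits (see [filterByHomology()]).
#' @param mappingRecords mapping records (see [acceptByMapping()]).
#' @param minLength,maxPeptide,minScore,coverageTol,screens,codingLabels
#'   stage parameters.
#' @return list with `survivors` (final core ids), `acceptedPerGenome`,
#'   `trace` (all stages), `finalStatus` (data.frame `transcript_id`,
#'   `status`, `removing_stage`).
#' @export
runLncrnaCascade <- function(transcripts, hitTables, mappingRecords,
                             minLength = 200L, maxPeptide = 100L,
                             minScore = 40, coverageTol = 0,
                             screens = lncrnaScreens(),
                             codingLabels = character(0)) {
  ids <- names(transcripts)
  traces <- list()
  s1 <- filterByLength(transcripts, minLength)
  traces$length <- s1$trace
  s2 <- filterByOrf(transcripts[s1$survivors], maxPeptide)
  traces$orf <- s2$trace
  s3 <- filterByHomology(s2$survivors, hitTables, screens, codingLabels)
  traces$homology <- s3$trace
  s4 <- acceptByMapping(s3$survivors, mappingRecords, minScore, coverageTol)
  traces$mapping <- s4$trace
  s5 <- spliceSanityCheck(s4$survivors, mappingRecords, transcripts,
                          maxPeptide)
  traces$splice <- s5$trace
  accepted <- lapply(s4$acceptedPerGenome, intersect, s5$survivors)
  core <- if (length(accepted) >= 2L) intersectCoreSet(accepted)
          else sort(unlist(accepted))
  traces$core <- traceRows(s5$survivors, "core",
                           !(s5$survivors %in% core),
                           "not accepted on every genome")
  trace <- do.call(rbind, traces)
  rownames(trace) <- NULL
  rem <- trace[trace$outcome == "removed", , drop = FALSE]
  finalStatus <- data.frame(
    transcript_id = ids,
    status = ifelse(ids %in% core, "core", "removed"),
    removing_stage = rem$stage[match(ids, rem$transcript_id)],
    stringsAsFactors = FALSE)
  list(survivors = core, acceptedPerGenome = accepted, trace = trace,
       finalStatus = finalStatus)
}
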