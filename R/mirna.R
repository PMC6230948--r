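## Homology-based miRNA annotation: scan assemblies with known mature
## sequences, evaluate hairpin foldback of the candidate precursor,
## classify confidence by transposable-element overlap and genomic context,
## score targets with a psRNATarget-style complementarity penalty, and
## summarise cross-genome family core sets and expression evidence.

#' Read a mature miRNA catalogue
#'
#' miRBase-style FASTA (`>family_member` headers). Sequences are normalised
#' to the RNA alphabet; entries shorter than 19 nt are rejected with a
#' warning, and lengths outside 19--24 or letters outside A/C/G/U are
#' errors.
#'
#' @param path FASTA path.
#' @return named character vector of mature RNA sequences.
#' @export
readMatureCatalogue <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(x)))
  short <- nchar(seqs) < 19L
  if (any(short)) {
    warning("rejected ", sum(short), " mature sequence(s) shorter than 19 nt")
    seqs <- seqs[!short]
  }
  if (any(nchar(seqs) > 24L)) stop("mature sequence longer than 24 nt")
  if (any(grepl("[^ACGU]", seqs))) stop("non-ACGU letter in mature catalogue")
  seqs
}

#' Scan assemblies for mature miRNA homology
#'
#' Reports every window on either strand matching a mature sequence with at
#' most `maxMismatches` substitutions (no indels; DNA/RNA handled by T/U
#' normalisation). Each match defines a candidate precursor locus of the
#' mature window extended by `flank` on both sides, clipped at chromosome
#' ends. Candidate loci of the same family whose precursor windows overlap
#' reciprocally by at least 50\% are deduplicated, keeping the match with
#' the fewest mismatches (then leftmost, plus strand first).
#'
#' @param sequences named [Biostrings::DNAStringSet].
#' @param matures named character vector of mature RNA sequences (family ->
#'   sequence), e.g. from [readMatureCatalogue()] or [mirnaFamilies()].
#' @param maxMismatches maximum substitutions.
#' @param flank precursor flank, nt.
#' @param deduplicate drop reciprocally >=50\%-overlapping same-family loci.
#' @return data.frame: `candidate_id`, `family`, `chrom`, `strand`,
#'   `mature_start`, `mature_end`, `precursor_start`, `precursor_end`
#'   (0-based half-open), `mismatches`.
#' @export
scanHomology <- function(sequences, matures, maxMismatches = 2L,
                         flank = 200L, deduplicate = TRUE) {
  if (!length(matures)) stop("empty mature catalogue")
  short <- nchar(matures) < 19L
  if (any(short)) {
    warning("rejected ", sum(short), " mature sequence(s) shorter than 19 nt")
    matures <- matures[!short]
  }
  rows <- list()
  for (fam in names(matures)) {
    pat <- Biostrings::DNAString(chartr("U", "T", matures[[fam]]))
    for (chrom in names(sequences)) {
      subj <- sequences[[chrom]]
      Lc <- length(subj)
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(p, subj, max.mismatch = maxMismatches)
        if (!length(m)) next
        mm <- Biostrings::neditAt(p, subj, at = BiocGenerics::start(m))
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, chrom = chrom, strand = strand,
          mature_start = BiocGenerics::start(m) - 1L,
          mature_end = BiocGenerics::end(m),
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(candidate_id = character(0), family = character(0),
                      chrom = character(0), strand = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      precursor_start = integer(0), precursor_end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  df$precursor_start <- pmax(0L, df$mature_start - as.integer(flank))
  df$precursor_end <- pmin(lens[df$chrom], df$mature_end + as.integer(flank))
  df <- df[order(df$chrom, df$family, df$mismatches, df$mature_start,
                 df$strand), , drop = FALSE]
  if (deduplicate && nrow(df) > 1L) {
    keep <- logical(nrow(df))
    for (key in unique(paste(df$chrom, df$family))) {
      idx <- which(paste(df$chrom, df$family) == key)
      kept <- integer(0)
      for (i in idx) {
        dup <- FALSE
        for (kp in kept) {
          ov <- min(df$precursor_end[i], df$precursor_end[kp]) -
            max(df$precursor_start[i], df$precursor_start[kp])
          if (ov > 0 &&
              ov >= 0.5 * (df$precursor_end[i] - df$precursor_start[i]) &&
              ov >= 0.5 * (df$precursor_end[kp] - df$precursor_start[kp])) {
            dup <- TRUE; break
          }
        }
        if (!dup) { keep[i] <- TRUE; kept <- c(kept, i) }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$mature_start, df$family, df$strand), ,
           drop = FALSE]
  df <- cbind(candidate_id = sprintf("mirc_%04d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[, c("candidate_id", "family", "chrom", "strand", "mature_start",
         "mature_end", "precursor_start", "precursor_end", "mismatches")]
}

#' Evaluate the hairpin potential of a candidate precursor
#'
#' Computes the maximum self base-pairing of the precursor with a
#' Nussinov-style dynamic program (minimum loop 3, G:U allowed) and derives
#' hairpin metrics from one optimal structure: the fraction of mature bases
#' paired, whether the mature spans the terminal loop (a pair with both
#' ends inside the mature), the size of the helix stack containing the
#' mature (stem-arm pairs) and its loop length. The candidate passes iff at
#' least `minPairedFraction` of the mature bases are paired, the mature
#' does not span the terminal loop, and the stem arm holds at least
#' `minStemPairs` pairs.
#'
#' @param precursor DNA/RNA character string, length >= 50.
#' @param matureOffset 0-based offset of the mature within the precursor.
#' @param matureLength mature length, nt.
#' @param minLoop minimum hairpin loop size.
#' @param minPairedFraction pass threshold on the paired-mature fraction.
#' @param minStemPairs pass threshold on stem-arm pairs.
#' @return list with `pairing_score` (total pairs), `mature_paired_fraction`,
#'   `spans_loop`, `stem_pairs`, `loop_length`, `pass`.
#' @export
evaluateHairpin <- function(precursor, matureOffset, matureLength,
                            minLoop = 3L, minPairedFraction = 0.6,
                            minStemPairs = 18L) {
  if (nchar(precursor) < 50L) stop("precursor shorter than 50 nt")
  if (matureOffset < 0L || matureOffset + matureLength > nchar(precursor))
    stop("mature not inside precursor")
  res <- .nussinov(toupper(precursor), as.integer(minLoop))
  pairs <- res$pairs
  mat <- matureOffset:(matureOffset + matureLength - 1L)  # 0-based
  pairedPos <- unique(as.vector(pairs))
  fracPaired <- mean(mat %in% pairedPos)
  inMat <- matrix(pairs %in% mat, ncol = 2L)
  spansLoop <- nrow(pairs) > 0L && any(inMat[, 1L] & inMat[, 2L])
  involving <- which(xor(inMat[, 1L], inMat[, 2L]))
  stemPairs <- 0L; loopLen <- NA_integer_
  if (length(involving)) {
    m <- involving[which.min(pairs[involving, 1L])]
    mi <- pairs[m, 1L]; mj <- pairs[m, 2L]
    chain <- which((pairs[, 1L] <= mi & pairs[, 2L] >= mj) |
                     (pairs[, 1L] >= mi & pairs[, 2L] <= mj))
    stemPairs <- length(chain)
    inner <- chain[which.max(pairs[chain, 1L])]
    loopLen <- pairs[inner, 2L] - pairs[inner, 1L] - 1L
  }
  list(pairing_score = res$max_pairs,
       mature_paired_fraction = fracPaired,
       spans_loop = spansLoop,
       stem_pairs = stemPairs,
       loop_length = loopLen,
       pass = fracPaired >= minPairedFraction && !spansLoop &&
         stemPairs >= minStemPairs)
}

#' Confidence class from transposable-element overlap
#'
#' Low confidence (LC) iff the precursor's TE overlap strictly exceeds 50\%
#' of its length; an overlap of exactly 0.5 is high confidence (HC).
#'
#' @param teOverlap fraction(s) in `[0,1]` (see [overlapFraction()]).
#' @return character vector of `"HC"` / `"LC"`.
#' @examples
#' classifyConfidence(c(0, 0.5, 0.6))  # HC HC LC
#' @export
classifyConfidence <- function(teOverlap) {
  stopifnot(all(teOverlap >= 0 & teOverlap <= 1))
  ifelse(teOverlap > 0.5, "LC", "HC")
}

#' Genomic context of mature miRNA loci
#'
#' Each mature locus is labelled `exon` if it overlaps any exon, else
#' `intron` if it lies within a gene, else `intergenic`. Percentages over
#' all matures sum to 100.
#'
#' @param matureLoci data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param exons data.frame `gene_id`, `start`, `end`.
#' @return list with `context` (character per locus) and `tally`
#'   (data.frame `context`, `n`, `percent`).
#' @export
classifyGenomicContext <- function(matureLoci, genes, exons) {
  if (nrow(exons)) {
    g <- genes[match(exons$gene_id, genes$gene_id), , drop = FALSE]
    if (any(is.na(g$gene_id)) ||
        any(exons$start < g$start | exons$end > g$end))
      stop("malformed gene model: exon outside its gene")
    byGene <- split(exons, exons$gene_id)
    if (any(vapply(byGene, function(d) {
      d <- d[order(d$start), , drop = FALSE]
      nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])
    }, logical(1L))))
      stop("malformed gene model: overlapping exons")
  }
  overlapsAny <- function(chrom, s, e, tab) {
    sel <- tab$chrom == chrom
    any(sel & tab$start < e & tab$end > s)
  }
  exonTab <- if (nrow(exons))
    cbind(exons, chrom = genes$chrom[match(exons$gene_id, genes$gene_id)])
  else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  ctx <- vapply(seq_len(nrow(matureLoci)), function(i) {
    ch <- matureLoci$chrom[i]; s <- matureLoci$start[i]
    e <- matureLoci$end[i]
    if (overlapsAny(ch, s, e, exonTab)) "exon"
    else if (overlapsAny(ch, s, e, genes)) "intron"
    else "intergenic"
  }, character(1L))
  lev <- c("intergenic", "exon", "intron")
  n <- vapply(lev, function(l) sum(ctx == l), numeric(1L))
  tally <- data.frame(context = lev, n = as.integer(n),
                      percent = if (length(ctx)) 100 * n / length(ctx)
                                else rep(NA_real_, 3L),
                      stringsAsFactors = FALSE)
  list(context = ctx, tally = tally)
}

.pairCost <- local({
  keys <- c("AU", "UA", "GC", "CG")
  wob <- c("GU", "UG")
  cost <- setNames(rep(1, 16L),
                   as.vector(outer(c("A", "C", "G", "U"),
                                   c("A", "C", "G", "U"), paste0)))
  cost[keys] <- 0
  cost[wob] <- 0.5
  cost
})

#' Score miRNA-target complementarity
#'
#' Slides the mature along the transcript (no gaps) and scores each window
#' by reverse-complement pairing: Watson-Crick pairs cost 0, G:U wobbles
#' 0.5, mismatches 1.0, with all costs doubled inside the seed region
#' (positions `seedStart`--`seedEnd` from the mature 5' end). The mature 5'
#' end pairs with the 3' end of the transcript window. Windows with penalty
#' at or below `cutoff` are reported — a documented surrogate for
#' psRNATarget-style expectation scoring.
#'
#' @param mature mature RNA string.
#' @param transcript transcript sequence (DNA or RNA); must be at least as
#'   long as the mature.
#' @param cutoff maximum reported penalty.
#' @param seedStart,seedEnd seed region (1-based mature positions, doubled
#'   costs).
#' @return data.frame `target_start`, `target_end` (0-based half-open on
#'   the transcript), `penalty`, sorted by penalty then position.
#' @examples
#' scoreTarget("AAAGUUAGAGAAGUUUGACUU",
#'             paste0("GGG", "AAGTCAAACTTCTCTAACTTT", "GGG"))
#' @export
scoreTarget <- function(mature, transcript, cutoff = 3.0, seedStart = 2L,
                        seedEnd = 13L) {
  m <- strsplit(chartr("Tt", "UU", toupper(mature)), "")[[1L]]
  tr <- strsplit(chartr("Tt", "UU", toupper(transcript)), "")[[1L]]
  Lm <- length(m); Lt <- length(tr)
  empty <- data.frame(target_start = integer(0), target_end = integer(0),
                      penalty = numeric(0))
  if (Lt < Lm) return(empty)
  posw <- ifelse(seq_len(Lm) >= seedStart & seq_len(Lm) <= seedEnd, 2, 1)
  nWin <- Lt - Lm + 1L
  ## aligned transcript base for mature position p in window o:
  ## tr[o + Lm - p] (mature 5' pairs the window's 3' end)
  idx <- outer(Lm:1, 0:(nWin - 1L), `+`)
  costs <- matrix(.pairCost[paste0(m, tr[idx])], nrow = Lm)
  penalty <- as.vector(posw %*% costs)
  keep <- which(penalty <= cutoff)
  if (!length(keep)) return(empty)
  out <- data.frame(target_start = keep - 1L, target_end = keep - 1L + Lm,
                    penalty = penalty[keep])
  out[order(out$penalty, out$target_start), , drop = FALSE]
}

#' Cross-genome miRNA family core set
#'
#' @param familyLists named list (>= 2 genomes) of per-genome family name
#'   vectors.
#' @return list with `core` (families in all genomes), `union`,
#'   `exclusive` (per-genome families found nowhere else) and `counts`.
#' @export
familyCoreSet <- function(familyLists) {
  if (length(familyLists) < 2L) stop("need at least 2 genomes")
  sets <- lapply(familyLists, unique)
  core <- sort(Reduce(intersect, sets))
  uni <- sort(Reduce(union, sets))
  excl <- lapply(seq_along(sets), function(i)
    sort(setdiff(sets[[i]], Reduce(union, sets[-i]))))
  names(excl) <- names(sets)
  list(core = core, union = uni, exclusive = excl,
       counts = data.frame(genome = names(sets),
                           n_families = lengths(sets),
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' Expression evidence per miRNA family
#'
#' A family is sRNA-supported if any small-RNA read matches its mature
#' exactly (T/U-normalised), and pre-miRNA-supported if any transcript
#' contains one of its precursor sequences at >= `minIdentity` identity
#' over the full precursor length (substitutions only).
#'
#' @param matures named character (family -> mature RNA).
#' @param precursors data.frame `family`, `seq` of candidate precursor
#'   sequences (may be empty).
#' @param reads [Biostrings::DNAStringSet] (or character) of sRNA reads.
#' @param transcripts [Biostrings::DNAStringSet] (or character).
#' @param minIdentity full-length identity threshold for pre-miRNA support.
#' @return data.frame `family`, `srna_supported`, `premirna_supported`,
#'   `supported`.
#' @export
expressionEvidence <- function(matures, precursors, reads, transcripts,
                               minIdentity = 0.95) {
  readSet <- unique(chartr("U", "T", toupper(as.character(reads))))
  txSet <- Biostrings::DNAStringSet(chartr("U", "T",
                                           toupper(as.character(transcripts))))
  rows <- lapply(names(matures), function(fam) {
    matDna <- chartr("U", "T", matures[[fam]])
    srna <- matDna %in% readSet
    pre <- FALSE
    if (length(txSet) && nrow(precursors)) {
      for (ps in precursors$seq[precursors$family == fam]) {
        mm <- floor((1 - minIdentity) * nchar(ps))
        if (any(Biostrings::vcountPattern(ps, txSet,
                                          max.mismatch = mm) > 0L)) {
          pre <- TRUE; break
        }
      }
    }
    data.frame(family = fam, srna_supported = srna,
               premirna_supported = pre, supported = srna || pre,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
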