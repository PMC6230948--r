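## Repeat annotation with a seeded library masker and landscape summaries.
## The masker is an exact-k-mer-seed-and-extend matcher with a mismatch
## tolerance, a desk-scale surrogate for a full repeat masker: every k-mer
## of every library element is matched exactly against the subject, seed
## hits falling on one alignment diagonal are merged into a candidate, and
## the candidate is extended along the diagonal while the aligned mismatch
## fraction stays within tolerance. Externally produced annotations (GFF3 /
## BED) can be ingested instead via readRepeatAnnotations().

.repeatSeedK <- 15L

## all k-mer seed matches of one oriented library element against one
## subject string, as (diagonal, subject-start) pairs
seedHits <- function(pdict, offsets, subject) {
  m <- Biostrings::matchPDict(pdict, subject)
  starts <- BiocGenerics::start(m)
  n <- lengths(starts)
  if (sum(n) == 0L) return(NULL)
  data.frame(off = rep.int(offsets, n), start = unlist(starts) - 1L)
}

## grow [s, e) (1-based closed on the match vector) while the mismatch
## fraction of the window stays within tol; both directions, iterated
expandWindow <- function(match, s, e, tol) {
  mis <- cumsum(!match)
  frac <- function(a, b) (mis[b] - if (a > 1L) mis[a - 1L] else 0L) / (b - a + 1L)
  repeat {
    moved <- FALSE
    if (e < length(match)) {
      cand <- (e + 1L):length(match)
      ok <- cand[frac(s, cand) <= tol]
      if (length(ok)) { e <- max(ok); moved <- TRUE }
    }
    if (s > 1L) {
      cand <- 1L:(s - 1L)
      ok <- cand[vapply(cand, function(a) frac(a, e) <= tol, logical(1L))]
      if (length(ok)) { s <- min(ok); moved <- TRUE }
    }
    if (!moved) break
  }
  while (s < e && !match[s]) s <- s + 1L      # anchor ends on exact matches
  while (e > s && !match[e]) e <- e - 1L
  c(s, e)
}

#' Annotate repeats by comparison against a repeat library
#'
#' @param sequences named [Biostrings::DNAStringSet] (chromosomes/contigs).
#' @param library repeat library with \code{family#superfamily#class}
#'   headers (see [repeatLibrary()], [readRepeatLibrary()]); both
#'   orientations of every element are searched.
#' @param minMatch minimum reported match length, bases.
#' @param maxMismatchFraction mismatch tolerance of the extended alignment.
#' @return data.frame of repeat annotations: `chrom`, `start`, `end`
#'   (0-based half-open), `family`, `superfamily`, `class`, `strand`,
#'   `mismatch_fraction`. Overlapping calls from different families are
#'   resolved to the longer match; same-family overlaps are unioned.
#' @export
maskWithLibrary <- function(sequences, library = repeatLibrary(),
                            minMatch = 50L, maxMismatchFraction = 0.1) {
  if (length(library) == 0L) stop("empty repeat library")
  info <- parseLibraryHeaders(names(library))
  k <- .repeatSeedK
  ## oriented element table: sequence, family info, strand
  elems <- list()
  for (i in seq_along(library)) {
    fwd <- as.character(library[[i]])
    elems[[length(elems) + 1L]] <- c(seq = fwd, strand = "+", i = i)
    elems[[length(elems) + 1L]] <- c(seq = revcomp(fwd), strand = "-", i = i)
  }
  pdicts <- lapply(elems, function(el) {
    n <- nchar(el[["seq"]])
    if (n < k) return(NULL)
    offsets <- 0:(n - k)
    list(pdict = Biostrings::PDict(Biostrings::DNAStringSet(
           substring(el[["seq"]], offsets + 1L, offsets + k))),
         offsets = offsets)
  })

  rows <- list()
  for (chrom in names(sequences)) {
    subject <- sequences[[chrom]]
    subjChar <- NULL
    Lc <- length(subject)
    for (ei in seq_along(elems)) {
      if (is.null(pdicts[[ei]])) next
      el <- elems[[ei]]
      elen <- nchar(el[["seq"]])
      hits <- seedHits(pdicts[[ei]]$pdict, pdicts[[ei]]$offsets, subject)
      if (is.null(hits)) next
      hits$diag <- hits$start - hits$off
      o <- order(hits$diag, hits$start)
      hits <- hits[o, , drop = FALSE]
      grp <- cumsum(c(TRUE, diff(hits$diag) != 0L))
      if (is.null(subjChar)) subjChar <- as.character(subject)
      for (g in split(seq_len(nrow(hits)), grp)) {
        d <- hits$diag[g[1L]]
        seedS <- min(hits$start[g]); seedE <- max(hits$start[g]) + k
        ## aligned projection of the whole element on this diagonal
        aS <- max(0L, d); aE <- min(Lc, d + elen)
        if (aE - aS < minMatch) next
        sub <- substr(subjChar, aS + 1L, aE)
        ref <- substr(el[["seq"]], aS - d + 1L, aE - d)
        match <- strsplit(sub, "")[[1L]] == strsplit(ref, "")[[1L]]
        w <- expandWindow(match, seedS - aS + 1L, seedE - aS, maxMismatchFraction)
        len <- w[2L] - w[1L] + 1L
        if (len < minMatch) next
        mf <- sum(!match[w[1L]:w[2L]]) / len
        if (mf > maxMismatchFraction) next
        fi <- as.integer(el[["i"]])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = aS + w[1L] - 1L, end = aS + w[2L],
          family = info$family[fi], superfamily = info$superfamily[fi],
          class = info$class[fi], strand = el[["strand"]],
          mismatch_fraction = mf, stringsAsFactors = FALSE)
      }
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               family = character(0), superfamily = character(0),
               class = character(0), strand = character(0),
               mismatch_fraction = numeric(0), stringsAsFactors = FALSE)
  resolveRepeatOverlaps(ann)
}

## same-family overlapping calls are unioned; remaining overlaps between
## different families are resolved to the longer match (nested/overlapping
## shorter calls dropped)
resolveRepeatOverlaps <- function(ann) {
  if (!nrow(ann)) return(ann)
  for (col in c("superfamily", "class", "strand"))
    if (is.null(ann[[col]])) ann[[col]] <- "unknown"
  if (is.null(ann$mismatch_fraction)) ann$mismatch_fraction <- NA_real_
  merged <- list()
  for (keyDf in split(ann, paste(ann$chrom, ann$family, ann$strand))) {
    ir <- IRanges::reduce(ir0(keyDf$start, keyDf$end))
    merged[[length(merged) + 1L]] <- data.frame(
      chrom = keyDf$chrom[1L], start = BiocGenerics::start(ir) - 1L,
      end = BiocGenerics::end(ir), family = keyDf$family[1L],
      superfamily = keyDf$superfamily[1L], class = keyDf$class[1L],
      strand = keyDf$strand[1L],
      mismatch_fraction = min(keyDf$mismatch_fraction),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, merged)
  ann <- ann[order(ann$chrom, -(ann$end - ann$start), ann$start), ,
             drop = FALSE]
  keep <- logical(nrow(ann))
  for (chrom in unique(ann$chrom)) {
    idx <- which(ann$chrom == chrom)
    kept <- IRanges::IRanges()
    for (i in idx) {
      cur <- ir0(ann$start[i], ann$end[i])
      if (length(kept) == 0L || sum(IRanges::countOverlaps(kept, cur)) == 0L) {
        keep[i] <- TRUE
        kept <- c(kept, cur)
      }
    }
  }
  ann <- ann[keep, , drop = FALSE]
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Read repeat annotations from GFF3 or BED
#'
#' GFF3 attributes are expected to carry the family in a `Family=` (or
#' `Name=`) tag formatted \code{family#superfamily#class}; BED uses the
#' name column with the same convention. Coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @return repeat-annotation data.frame as from [maskWithLibrary()].
#' @export
readRepeatAnnotations <- function(path) {
  isBed <- grepl("\\.bed$", path, ignore.case = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (isBed) {
    lab <- vapply(parts, `[`, character(1L), 4L)
    df <- data.frame(chrom = vapply(parts, `[`, character(1L), 1L),
                     start = as.integer(vapply(parts, `[`, character(1L), 2L)),
                     end = as.integer(vapply(parts, `[`, character(1L), 3L)),
                     strand = vapply(parts, function(p)
                       if (length(p) >= 6L) p[6L] else "+", character(1L)),
                     stringsAsFactors = FALSE)
  } else {
    attr9 <- vapply(parts, `[`, character(1L), 9L)
    lab <- sub(".*(?:Family|Name)=([^;]+).*", "\\1", attr9)
    df <- data.frame(chrom = vapply(parts, `[`, character(1L), 1L),
                     start = as.integer(vapply(parts, `[`, character(1L),
                                               4L)) - 1L,
                     end = as.integer(vapply(parts, `[`, character(1L), 5L)),
                     strand = vapply(parts, `[`, character(1L), 7L),
                     stringsAsFactors = FALSE)
  }
  cbind(df[, c("chrom", "start", "end")], parseLibraryHeaders(lab),
        strand = df$strand, mismatch_fraction = NA_real_,
        stringsAsFactors = FALSE)
}

#' Summarise the repeat landscape per chromosome and subgenome
#'
#' `masked_fraction` is the width of the interval union of all annotations
#' divided by the scope length; per-family shares are family bases over all
#' masked bases (they sum to 1). Subgenome landscapes aggregate member
#' chromosomes by base counts, not by averaging fractions. Overlapping
#' annotations are resolved (longest-match priority) before counting so the
#' shares partition the masked bases.
#'
#' @param annotations repeat-annotation data.frame.
#' @param chromosomeLengths named vector of chromosome lengths.
#' @param subgenomeMap named character vector chromosome -> subgenome; by
#'   default the trailing A/B of the chromosome name.
#' @return list with data.frames `chromosome` and `subgenome`, each with
#'   columns `scope`, `length`, `masked_bases`, `masked_fraction`, `family`,
#'   `family_bases`, `family_fraction_of_masked` (long format, one row per
#'   scope x family).
#' @export
summarizeLandscape <- function(annotations, chromosomeLengths,
                               subgenomeMap = NULL) {
  unknown <- setdiff(annotations$chrom, names(chromosomeLengths))
  if (length(unknown))
    stop("annotation on unknown chromosome: ", paste(unknown, collapse = ", "))
  if (is.null(subgenomeMap))
    subgenomeMap <- setNames(substr(names(chromosomeLengths),
                                    nchar(names(chromosomeLengths)),
                                    nchar(names(chromosomeLengths))),
                             names(chromosomeLengths))
  ann <- resolveRepeatOverlaps(annotations)
  famBases <- function(d) {
    if (!nrow(d)) return(numeric(0))
    vapply(split(d, d$family), function(x) as.numeric(
      unionWidth(x$start, x$end)), numeric(1L))
  }
  scopeTab <- function(scopes, chromsOf) {
    out <- list()
    for (sc in scopes) {
      chs <- chromsOf(sc)
      d <- ann[ann$chrom %in% chs, , drop = FALSE]
      len <- sum(as.numeric(chromosomeLengths[chs]))
      masked <- sum(vapply(chs, function(ch) {
        sel <- d$chrom == ch
        as.numeric(unionWidth(d$start[sel], d$end[sel]))
      }, numeric(1L)))
      fb <- famBases(d)
      if (!length(fb))
        out[[sc]] <- data.frame(scope = sc, length = len,
                                masked_bases = 0, masked_fraction = 0,
                                family = NA_character_, family_bases = 0,
                                family_fraction_of_masked = NA_real_,
                                stringsAsFactors = FALSE)
      else
        out[[sc]] <- data.frame(scope = sc, length = len,
                                masked_bases = masked,
                                masked_fraction = masked / len,
                                family = names(fb), family_bases = fb,
                                family_fraction_of_masked = fb / sum(fb),
                                stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  }
  list(chromosome = scopeTab(names(chromosomeLengths), function(sc) sc),
       subgenome = scopeTab(sort(unique(subgenomeMap)), function(sc)
         names(subgenomeMap)[subgenomeMap == sc]))
}

#' Fraction of a feature covered by repeat annotations
#'
#' Returns `|union(annotation intersect feature)| / |feature|` for one
#' feature interval.
#'
#' @param chrom,start,end feature interval, 0-based half-open.
#' @param annotations repeat-annotation data.frame.
#' @return fraction in `[0,1]`.
#' @examples
#' ann <- data.frame(chrom = "1A", start = c(0, 50), end = c(30, 80))
#' overlapFraction("1A", 0, 100, ann)  # 0.6
#' @export
overlapFraction <- function(chrom, start, end, annotations) {
  if (end <= start) stop("zero-length feature")
  sel <- annotations$chrom == chrom
  if (!any(sel)) return(0)
  hit <- IRanges::intersect(
    IRanges::reduce(ir0(annotations$start[sel], annotations$end[sel])),
    ir0(start, end))
  sum(IRanges::width(hit)) / (end - start)
}
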