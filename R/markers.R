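## Marker discovery: SSR loci (MISA-style perfect tandem repeats), ISBP
## (insertion-site-based polymorphism) junctions at transposable-element
## boundaries, and variant-record filtering/summarisation.

.misaThresholds <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L,
                     `6` = 5L)

## minimal lexicographic rotation of a motif
canonicalRotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L)), character(1L))
  min(rots)
}

## a motif is primitive if it is not a whole-number repetition of a shorter
## motif (non-primitive runs are reported at the shorter motif length)
isPrimitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k / d) == motif) return(FALSE)
  }
  TRUE
}

#' Find SSR loci (perfect microsatellites)
#'
#' Reports maximal perfect tandem runs of 1--6-nt motifs meeting per-motif
#' -length minimum unit counts (MISA defaults: mono 10, di 6, tri/tetra/
#' penta/hexa 5). Motifs are canonicalised to their lexicographically
#' minimal rotation (no reverse-complement collapsing). Runs whose motif is
#' a repetition of a shorter motif are reported at the shorter length only,
#' and a locus wholly contained in a locus of longer motif is suppressed
#' (longest-motif priority). Two loci closer than `maxInterruption` bases
#' are merged into one compound locus.
#'
#' @param sequence DNA string (character) or `DNAString`.
#' @param contigId id recorded in the output.
#' @param thresholds named integer vector: motif length (`"1"`..`"6"`) ->
#'   minimum unit count.
#' @param maxInterruption maximum gap merged into a compound locus.
#' @return data.frame `contig_id`, `start`, `end` (0-based half-open),
#'   `motif`, `repeat_count`, `type` (`mono`..`hexa` or `compound`,
#'   compound loci list members in `components`).
#' @examples
#' findSsrs(paste0(strrep("G", 20), strrep("AC", 6), strrep("G", 20)))
#' @export
findSsrs <- function(sequence, contigId = "contig",
                     thresholds = .misaThresholds,
                     maxInterruption = 100L) {
  stopifnot(all(thresholds > 0L))
  seq <- toupper(as.character(sequence))
  typeNames <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  cand <- list()
  for (k in seq_along(thresholds)) {
    minCount <- thresholds[[as.character(k)]]
    pat <- sprintf("([ACGTN]{%d})\\1{%d,}", k, minCount - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (h in seq_along(m)) {
      s <- m[h]; len <- attr(m, "match.length")[h]
      count <- len %/% k
      motif <- substr(seq, s, s + k - 1L)
      if (!isPrimitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = s - 1L, end = s - 1L + count * k,
        motif = canonicalRotation(motif), repeat_count = count,
        k = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      repeat_count = integer(0), type = character(0),
                      components = character(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, cand)
  ## longest-motif priority: drop a locus contained in one of longer motif
  keep <- vapply(seq_len(nrow(d)), function(i) {
    !any(d$k > d$k[i] & d$start <= d$start[i] & d$end >= d$end[i])
  }, logical(1L))
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$start, -d$k), , drop = FALSE]
  ## merge loci closer than maxInterruption into compound loci
  grp <- cumsum(c(TRUE, d$start[-1L] - d$end[-nrow(d)] >= maxInterruption))
  rows <- lapply(split(d, grp), function(g) {
    if (nrow(g) == 1L)
      data.frame(contig_id = contigId, start = g$start, end = g$end,
                 motif = g$motif, repeat_count = g$repeat_count,
                 type = typeNames[g$k], components = "",
                 stringsAsFactors = FALSE)
    else
      data.frame(contig_id = contigId, start = min(g$start),
                 end = max(g$end),
                 motif = paste(g$motif, collapse = "/"),
                 repeat_count = NA_integer_, type = "compound",
                 components = paste(sprintf("%s(%d)@%d", g$motif,
                                            g$repeat_count, g$start),
                                    collapse = ";"),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find ISBP junctions at repeat-annotation boundaries
#'
#' A junction is every boundary where the annotation state changes along
#' the contig (TE family to a different family at zero gap, TE to
#' unannotated, unannotated to TE) with at least `minFlank` assayable bases
#' between the junction and either contig end. Overlapping annotations are
#' resolved (longest-match priority) first.
#'
#' @param annotations repeat-annotation data.frame (`chrom`, `start`,
#'   `end`, `family`), coordinates 0-based half-open.
#' @param contigLengths named vector of contig lengths.
#' @param minFlank minimum assayable flank, bases.
#' @return data.frame `contig_id`, `position`, `left`, `right` (family
#'   names or `"unique"`), sorted by contig then position.
#' @export
findIsbpJunctions <- function(annotations, contigLengths, minFlank = 30L) {
  ann <- resolveRepeatOverlaps(annotations)
  rows <- list()
  for (contig in names(contigLengths)) {
    d <- ann[ann$chrom == contig, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$start), , drop = FALSE]
    L <- contigLengths[[contig]]
    for (i in seq_len(nrow(d))) {
      ## left edge of annotation i
      leftState <- if (i > 1L && d$end[i - 1L] == d$start[i])
        d$family[i - 1L] else "unique"
      if (leftState != d$family[i])
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig, position = d$start[i], left = leftState,
          right = d$family[i], stringsAsFactors = FALSE)
      ## right edge (only when not immediately followed by an annotation,
      ## which is handled as that annotation's left edge)
      rightState <- if (i < nrow(d) && d$start[i + 1L] == d$end[i])
        d$family[i + 1L] else "unique"
      if (rightState == "unique" && d$family[i] != rightState)
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig, position = d$end[i], left = d$family[i],
          right = rightState, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), position = integer(0),
                      left = character(0), right = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  L <- contigLengths[out$contig_id]
  out <- out[out$position >= minFlank & (L - out$position) >= minFlank, ,
             drop = FALSE]
  out <- out[order(out$contig_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variant records and summarise SNP/InDel counts
#'
#' Applies a predicate filter (minimum depth, minimum quality, optionally
#' biallelic records only) and partitions the survivors into SNPs (both
#' alleles single-base) and InDels. Counts are conserved:
#' `n_snp + n_indel = n_surviving`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multiallelic records), `qual`, `depth`.
#' @param minDepth,minQual,biallelicOnly filter profile.
#' @return list `survivors` (data.frame with added `variant_type`),
#'   `summary` (data.frame `n_input`, `n_surviving`, `n_snp`, `n_indel`).
#' @export
filterVariants <- function(variants, minDepth = 10, minQual = 30,
                           biallelicOnly = TRUE) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("malformed variant table, missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(variants$pos) | is.na(variants$ref) |
                 !nzchar(variants$ref) | !nzchar(variants$alt))
  if (length(bad))
    stop("malformed variant record at line ", bad[1L])
  keep <- variants$depth >= minDepth & variants$qual >= minQual
  if (biallelicOnly) keep <- keep & !grepl(",", variants$alt, fixed = TRUE)
  surv <- variants[keep, , drop = FALSE]
  isSnp <- nchar(surv$ref) == 1L &
    vapply(strsplit(surv$alt, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L), logical(1L))
  surv$variant_type <- ifelse(isSnp, "SNP", "InDel")
  list(survivors = surv,
       summary = data.frame(n_input = nrow(variants),
                            n_surviving = nrow(surv),
                            n_snp = sum(isSnp), n_indel = sum(!isSnp)))
}

#' Read variant records from a VCF file
#'
#' Minimal reader for the columns [filterVariants()] needs; depth is taken
#' from the INFO `DP` tag (NA when absent).
#'
#' @param path VCF path (uncompressed).
#' @return variant data.frame (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`).
#' @export
readVariants <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), depth = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 8L)
  if (length(short))
    stop("malformed VCF record at line ",
         which(!startsWith(lines, "#"))[short[1L]])
  info <- vapply(parts, `[`, character(1L), 8L)
  dp <- suppressWarnings(as.numeric(sub(".*(?:^|;)DP=([0-9]+).*", "\\1",
                                        info)))
  dp[!grepl("(^|;)DP=", info)] <- NA_real_
  data.frame(chrom = vapply(parts, `[`, character(1L), 1L),
             pos = as.integer(vapply(parts, `[`, character(1L), 2L)),
             ref = vapply(parts, `[`, character(1L), 4L),
             alt = vapply(parts, `[`, character(1L), 5L),
             qual = suppressWarnings(as.numeric(vapply(parts, `[`,
                                                       character(1L), 6L))),
             depth = dp, stringsAsFactors = FALSE)
}
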