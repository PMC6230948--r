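## Link-based synteny: dual placements become links, links are bundled into
## ribbons on windowed interval pairs, and bundled ribbons on unexpected
## chromosome pairs flag translocation-like signals.

## unique best placement per query; queries with tied best scores or no
## placement are dropped ("specific location" rule)
uniqueBestPlacement <- function(placements) {
  o <- order(placements$query_id, -placements$score, placements$chrom,
             placements$start)
  p <- placements[o, , drop = FALSE]
  first <- !duplicated(p$query_id)
  best <- p[first, , drop = FALSE]
  second <- p[!first, , drop = FALSE]
  secondBest <- second[!duplicated(second$query_id), , drop = FALSE]
  tied <- secondBest$query_id[
    secondBest$score == best$score[match(secondBest$query_id,
                                         best$query_id)]]
  best[!(best$query_id %in% tied), , drop = FALSE]
}

#' Build synteny links from dual placements
#'
#' One link per query that has a unique best placement in each genome;
#' queries with tied best placements in either genome are excluded.
#'
#' @param placements1,placements2 placement data.frames (see
#'   [readPlacements()]) on the two genomes, sharing `query_id`s.
#' @return data.frame `query_id`, `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`.
#' @export
buildLinks <- function(placements1, placements2) {
  b1 <- uniqueBestPlacement(placements1)
  b2 <- uniqueBestPlacement(placements2)
  m <- merge(b1[, c("query_id", "chrom", "start", "end")],
             b2[, c("query_id", "chrom", "start", "end")],
             by = "query_id", suffixes = c("1", "2"))
  names(m) <- c("query_id", "chrom1", "start1", "end1", "chrom2", "start2",
                "end2")
  m[order(m$chrom1, m$start1, m$query_id), , drop = FALSE]
}

#' Bundle links into ribbons on windowed interval pairs
#'
#' Each link is assigned to the (chromosome, window) pair containing its
#' midpoints; a ribbon is bundled iff its link count strictly exceeds
#' `minLinks` (the published rule is bundling >200 links along 1-Mb
#' intervals; the threshold scales with problem size). Ribbon counts sum to
#' the link count.
#'
#' @param links data.frame from [buildLinks()].
#' @param window window size, bases (> 0).
#' @param minLinks bundling threshold (strict).
#' @return data.frame `chrom1`, `bin1`, `chrom2`, `bin2` (0-based window
#'   indices), `count`, `bundled`.
#' @export
bundleRibbons <- function(links, window = 1e6, minLinks = 200L) {
  stopifnot(window > 0)
  if (!nrow(links))
    return(data.frame(chrom1 = character(0), bin1 = integer(0),
                      chrom2 = character(0), bin2 = integer(0),
                      count = integer(0), bundled = logical(0),
                      stringsAsFactors = FALSE))
  bin1 <- as.integer(floor((links$start1 + links$end1) / 2 / window))
  bin2 <- as.integer(floor((links$start2 + links$end2) / 2 / window))
  key <- paste(links$chrom1, bin1, links$chrom2, bin2, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom1 = vapply(parts, `[`, character(1L), 1L),
                    bin1 = as.integer(vapply(parts, `[`, character(1L), 2L)),
                    chrom2 = vapply(parts, `[`, character(1L), 3L),
                    bin2 = as.integer(vapply(parts, `[`, character(1L), 4L)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out$bundled <- out$count > minLinks
  out <- out[order(out$chrom1, out$bin1, out$chrom2, out$bin2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-density track
#'
#' Counts gene positions in half-open windows (a position on a window
#' boundary belongs to the right-hand window); counts sum to the number of
#' genes.
#'
#' @param positions data.frame `chrom`, `pos`.
#' @param chromosomeLengths named vector.
#' @param window window size, bases.
#' @return data.frame `chrom`, `start`, `end`, `count` (bedGraph-ready).
#' @export
geneDensity <- function(positions, chromosomeLengths, window = 5e5) {
  stopifnot(window > 0)
  if (nrow(positions) &&
      any(positions$pos < 0 |
            positions$pos >= chromosomeLengths[positions$chrom]))
    stop("gene position outside its chromosome")
  rows <- lapply(names(chromosomeLengths), function(chrom) {
    nBins <- ceiling(chromosomeLengths[[chrom]] / window)
    cnt <- integer(nBins)
    p <- positions$pos[positions$chrom == chrom]
    if (length(p)) {
      b <- floor(p / window) + 1L
      t <- table(b)
      cnt[as.integer(names(t))] <- as.integer(t)
    }
    data.frame(chrom = chrom, start = (seq_len(nBins) - 1L) * window,
               end = pmin(seq_len(nBins) * window,
                          chromosomeLengths[[chrom]]),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag interchromosomal (translocation-like) ribbons
#'
#' Bundled ribbons whose chromosome pair is not among the expected
#' correspondences are flagged, with their window coordinates.
#'
#' @param ribbons data.frame from [bundleRibbons()].
#' @param expectedPairs data.frame `chrom1`, `chrom2` of expected
#'   correspondences (e.g. each assembly chromosome with its reference
#'   counterpart).
#' @return the flagged subset of the bundled ribbons.
#' @export
flagInterchromosomal <- function(ribbons, expectedPairs) {
  b <- ribbons[ribbons$bundled, , drop = FALSE]
  if (!nrow(b)) return(b)
  exp <- paste(expectedPairs$chrom1, expectedPairs$chrom2, sep = "\r")
  flagged <- b[!(paste(b$chrom1, b$chrom2, sep = "\r") %in% exp), ,
               drop = FALSE]
  rownames(flagged) <- NULL
  flagged
}
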