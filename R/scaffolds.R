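## Reference-guided super-scaffolding. Draft scaffolds placed on a reference
## chromosome are chained when the reference gap between consecutive
## placements is smaller than a merge threshold, and joined with exactly
## that many N characters, so the super-scaffold preserves the
## reference-projected length.

#' Remove ultra-short scaffolds
#'
#' Keeps exactly the sequences with length >= `minLength`; the default
#' reproduces the exclusion of ultra-short contigs of <200 bases, so a
#' 200-base scaffold is kept.
#'
#' @param scaffolds a [Biostrings::DNAStringSet].
#' @param minLength minimum retained length, bases (non-negative).
#' @return the filtered `DNAStringSet`.
#' @examples
#' s <- Biostrings::DNAStringSet(c(a = "ACGT", b = strrep("A", 200)))
#' length(filterMinLength(s, 200))
#' @export
filterMinLength <- function(scaffolds, minLength = 200L) {
  stopifnot(minLength >= 0)
  scaffolds[Biostrings::width(scaffolds) >= minLength]
}

#' Read / write placement tables
#'
#' Placements map a query sequence onto a reference chromosome. The on-disk
#' form is tab-separated with six documented columns: `query_id`, `chrom`,
#' `start`, `end` (0-based half-open on the reference), `strand` (`+`/`-`)
#' and `score` (non-negative).
#'
#' @param path file path.
#' @return `readPlacements` returns the placement data.frame.
#' @export
readPlacements <- function(path) {
  df <- readTsv(path)
  need <- c("query_id", "chrom", "start", "end", "strand", "score")
  if (!all(need %in% names(df)))
    stop("placement table must have columns: ", paste(need, collapse = ", "))
  validatePlacements(df)
  df
}

#' @rdname readPlacements
#' @param placements placement data.frame.
#' @export
writePlacements <- function(placements, path) {
  writeTsv(placements[, c("query_id", "chrom", "start", "end", "strand",
                          "score")], path)
}

validatePlacements <- function(placements, referenceLengths = NULL) {
  if (any(placements$start >= placements$end))
    stop("placement with start >= end")
  if (any(placements$score < 0)) stop("negative placement score")
  if (!is.null(referenceLengths) &&
      any(placements$end > referenceLengths[placements$chrom]))
    stop("placement end beyond reference length")
  invisible(placements)
}

## multi-mapping queries: keep the highest-score placement only; ties break
## to the lexicographically smallest chromosome, then leftmost start
bestPlacementPerQuery <- function(placements) {
  o <- order(placements$query_id, -placements$score, placements$chrom,
             placements$start)
  p <- placements[o, , drop = FALSE]
  p[!duplicated(p$query_id), , drop = FALSE]
}

#' Build reference-guided super-scaffolds
#'
#' Per reference chromosome, placements are sorted by start and consecutive
#' placements whose reference gap `g = next_start - prev_end` satisfies
#' `0 <= g < maxGap` are chained into one super-scaffold whose sequence
#' inserts exactly `g` N characters between members (the default 50
#' reproduces the "closer than 50 nucleotides" merge rule, so a gap of
#' exactly 50 starts a new super-scaffold). Members placed on the minus
#' strand are reverse-complemented so every super-scaffold reads in
#' reference orientation. Placements on different chromosomes never merge;
#' scaffolds that end up alone pass through unchanged under their original
#' identifier. Multi-mapping queries are reduced to their best placement
#' first (score, then lexicographically smallest chromosome, then leftmost).
#'
#' @param placements placement data.frame (see [readPlacements()]).
#' @param scaffolds named [Biostrings::DNAStringSet] with every placed query.
#' @param maxGap merge threshold, bases; gaps must be strictly smaller.
#' @param mergeOverlapping policy for overlapping placements (`g < 0`):
#'   `FALSE` (default) starts a new super-scaffold and warns once; `TRUE`
#'   chains them with zero N inserted.
#' @return a [SuperScaffoldSet-class].
#' @examples
#' sc <- Biostrings::DNAStringSet(c(s1 = strrep("A", 500),
#'                                  s2 = strrep("C", 470)))
#' pl <- data.frame(query_id = c("s1", "s2"), chrom = "5A",
#'                  start = c(1000L, 1530L), end = c(1500L, 2000L),
#'                  strand = "+", score = 1)
#' ss <- buildSuperScaffolds(pl, sc, maxGap = 50)
#' Biostrings::width(superScaffoldSequences(ss))  # 1000 = 500 + 30 N + 470
#' @export
buildSuperScaffolds <- function(placements, scaffolds, maxGap = 50L,
                                mergeOverlapping = FALSE) {
  validatePlacements(placements)
  missing <- setdiff(placements$query_id, names(scaffolds))
  if (length(missing))
    stop("placement query without sequence: ",
         paste(head(missing, 5L), collapse = ", "))
  p <- bestPlacementPerQuery(placements)
  p <- p[order(p$chrom, p$start, p$end), , drop = FALSE]

  ## chain id per chromosome: new chain when gap >= maxGap (or overlap
  ## under the default policy)
  warned <- FALSE
  chains <- integer(nrow(p)); chainId <- 0L
  for (i in seq_len(nrow(p))) {
    newChain <- i == 1L || p$chrom[i] != p$chrom[i - 1L]
    if (!newChain) {
      g <- p$start[i] - p$end[i - 1L]
      if (g < 0L && !mergeOverlapping) {
        if (!warned) {
          warning("overlapping placements not merged (policy); ",
                  "set mergeOverlapping = TRUE to chain them")
          warned <- TRUE
        }
        newChain <- TRUE
      } else if (g >= maxGap) newChain <- TRUE
    }
    if (newChain) chainId <- chainId + 1L
    chains[i] <- chainId
  }

  seqs <- character(0); ids <- character(0); members <- list()
  for (cid in unique(chains)) {
    d <- p[chains == cid, , drop = FALSE]
    if (nrow(d) == 1L) {
      id <- d$query_id
      seqs <- c(seqs, as.character(scaffolds[[d$query_id]]))
    } else {
      id <- sprintf("ss_%s_%07d", d$chrom[1L], d$start[1L])
      pieces <- vapply(seq_len(nrow(d)), function(i) {
        s <- scaffolds[[d$query_id[i]]]
        if (d$strand[i] == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      }, character(1L))
      gapN <- pmax(0L, d$start[-1L] - d$end[-nrow(d)])
      seqs <- c(seqs, paste0(paste0(pieces[-length(pieces)],
                                    strrep("N", gapN), collapse = ""),
                             pieces[length(pieces)]))
    }
    ids <- c(ids, id)
    members[[length(members) + 1L]] <-
      data.frame(super_id = id, query_id = d$query_id, chrom = d$chrom,
                 start = d$start, end = d$end, strand = d$strand,
                 order = seq_len(nrow(d)), stringsAsFactors = FALSE)
  }
  new("SuperScaffoldSet",
      sequences = Biostrings::DNAStringSet(setNames(seqs, ids)),
      members = do.call(rbind, members))
}

#' Assembly statistics (length filter, N50, reference representation)
#'
#' `n50` is the largest length L such that sequences of length >= L contain
#' at least half the total bases; it is always a member of the input length
#' multiset. `representation_fraction` is the width of the union of the
#' covered reference intervals divided by the reference chromosome length.
#'
#' @param sequences a `DNAStringSet` or a numeric vector of lengths
#'   (non-empty).
#' @param referenceLength reference chromosome length, bases.
#' @param covered optional data.frame of 0-based half-open covered intervals
#'   (`start`, `end`) on the reference.
#' @param minLengthApplied the length filter that produced `sequences`
#'   (recorded in the output).
#' @return a list with `n_sequences`, `total_length`, `n50`,
#'   `min_length_applied`, `representation_fraction`.
#' @examples
#' computeAssemblyStats(c(5, 4, 3, 2, 1), referenceLength = 1000,
#'                      covered = data.frame(start = c(0, 500),
#'                                           end = c(100, 600)))
#' @export
computeAssemblyStats <- function(sequences, referenceLength = NA_real_,
                                 covered = NULL, minLengthApplied = 0L) {
  lens <- if (is(sequences, "XStringSet")) Biostrings::width(sequences)
          else as.numeric(sequences)
  if (length(lens) == 0L) stop("computeAssemblyStats: empty sequence set")
  rep <- NA_real_
  if (!is.null(covered) && !is.na(referenceLength))
    rep <- unionWidth(covered$start, covered$end) / referenceLength
  list(n_sequences = length(lens),
       total_length = sum(lens),
       n50 = n50(lens),
       min_length_applied = minLengthApplied,
       representation_fraction = rep)
}
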