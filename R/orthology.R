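## Orthology: per-species hit filtering, best reciprocal hits, OrthoMCL-style
## clustering of grass genes, chromosome-occupancy classification and
## conserved gene-content estimation.

#' Default per-species hit-filter profiles
#'
#' Thresholds are the published parameter triplets: Brachypodium, rice and
#' sorghum proteomes at (1e-6, length 30, ppos 75); barley high-confidence
#' proteins at (1e-6, 30, ppos 90); wheat transcripts at (1e-30, 100,
#' pident 99) and wheat predicted proteins at (1e-6, 30, ppos 99).
#'
#' @return named list of profiles, each with `max_evalue`, `min_length` and
#'   one of `min_ppos` / `min_pident`.
#' @export
hitFilterProfiles <- function() {
  list(
    brachypodium = list(max_evalue = 1e-6, min_length = 30, min_ppos = 75),
    rice         = list(max_evalue = 1e-6, min_length = 30, min_ppos = 75),
    sorghum      = list(max_evalue = 1e-6, min_length = 30, min_ppos = 75),
    barley       = list(max_evalue = 1e-6, min_length = 30, min_ppos = 90),
    wheat_transcripts = list(max_evalue = 1e-30, min_length = 100,
                             min_pident = 99),
    wheat_proteins = list(max_evalue = 1e-6, min_length = 30, min_ppos = 99))
}

#' Filter homology hits by per-species threshold profiles
#'
#' Keeps hits with `evalue <= max_evalue` and `length >= min_length` and
#' positives (or identity, whichever the profile specifies) at or above its
#' threshold. Every subject species present in the table must have a
#' profile.
#'
#' @param hits data.frame with BLAST-style columns `query_id`, `subject_id`,
#'   `subject_species`, `pident`, `ppos`, `length`, `evalue`, `bit_score`
#'   (plus any others, preserved).
#' @param profiles named list as from [hitFilterProfiles()].
#' @return the surviving rows of `hits`.
#' @export
filterHits <- function(hits, profiles = hitFilterProfiles()) {
  sp <- unique(hits$subject_species)
  missing <- setdiff(sp, names(profiles))
  if (length(missing))
    stop("no hit-filter profile for species: ",
         paste(missing, collapse = ", "))
  keep <- vapply(seq_len(nrow(hits)), function(r) {
    p <- profiles[[hits$subject_species[r]]]
    ok <- hits$evalue[r] <= p$max_evalue && hits$length[r] >= p$min_length
    if (!is.null(p$min_ppos)) ok <- ok && hits$ppos[r] >= p$min_ppos
    if (!is.null(p$min_pident)) ok <- ok && hits$pident[r] >= p$min_pident
    ok
  }, logical(1L))
  hits[keep, , drop = FALSE]
}

## deterministic top hit per query: bit score desc, then evalue asc, then
## lexicographically smallest subject id
topHitPerQuery <- function(hits) {
  o <- order(hits$query_id, -hits$bit_score, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Best reciprocal hits between two species
#'
#' `(q, s)` is returned iff `s` is `q`'s top hit among subjects of species B
#' and `q` is `s`'s top hit among subjects of species A. Ranking is by bit
#' score, ties broken by smaller e-value and then by lexicographically
#' smallest subject id, which makes the result deterministic and one-to-one
#' per species pair.
#'
#' @param hits hit data.frame with `query_species` and `subject_species`
#'   columns in addition to the BLAST-style columns.
#' @param speciesA,speciesB the two species labels.
#' @return data.frame with columns `id_a`, `id_b`, `bit_score_ab`,
#'   `bit_score_ba`, `evalue_ab`, `evalue_ba` (possibly empty).
#' @export
bestReciprocalHits <- function(hits, speciesA, speciesB) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      bit_score_ab = numeric(0), bit_score_ba = numeric(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0),
                      stringsAsFactors = FALSE)
  ab <- hits[hits$query_species == speciesA &
               hits$subject_species == speciesB, , drop = FALSE]
  ba <- hits[hits$query_species == speciesB &
               hits$subject_species == speciesA, , drop = FALSE]
  if (!nrow(ab) || !nrow(ba)) return(empty)
  topAB <- topHitPerQuery(ab)
  topBA <- topHitPerQuery(ba)
  m <- merge(topAB, topBA, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_ab", "_ba"))
  if (!nrow(m)) return(empty)
  out <- data.frame(id_a = m$query_id, id_b = m$subject_id,
                    bit_score_ab = m$bit_score_ab,
                    bit_score_ba = m$bit_score_ba,
                    evalue_ab = m$evalue_ab, evalue_ba = m$evalue_ba,
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Cluster genes into orthologous groups
#'
#' Builds a weighted homology graph (edge weight `-log10(evalue)` capped at
#' 200) from best-reciprocal-hit pairs and partitions it with Markov
#' clustering ([markovCluster()]), the OrthoMCL-style construction of
#' nonredundant orthologous groups. Every input gene ends up in exactly one
#' group; disconnected graph components never merge.
#'
#' @param brhPairs data.frame with `id_a`, `id_b` and an e-value column
#'   (`evalue`, or `evalue_ab`/`evalue_ba` of which the smaller is used);
#'   alternatively pre-computed `weight`.
#' @param inflation Markov-clustering inflation (default 2.0).
#' @param singletons optional character vector of gene ids with no edges,
#'   returned as singleton groups.
#' @return data.frame `gene_id`, `group_id` (groups labelled
#'   `OG%04d` in order of first member).
#' @export
clusterOrthogroups <- function(brhPairs, inflation = 2.0,
                               singletons = character(0)) {
  if (nrow(brhPairs)) {
    w <- if ("weight" %in% names(brhPairs)) brhPairs$weight
    else {
      ev <- if ("evalue" %in% names(brhPairs)) brhPairs$evalue
            else pmin(brhPairs$evalue_ab, brhPairs$evalue_ba)
      pmin(-log10(pmax(ev, 1e-200)), 200)
    }
    edges <- data.frame(from = brhPairs$id_a, to = brhPairs$id_b, weight = w,
                        stringsAsFactors = FALSE)
    cl <- markovCluster(edges, inflation = inflation)
  } else cl <- setNames(integer(0), character(0))
  singletons <- setdiff(singletons, names(cl))
  if (length(singletons))
    cl <- c(cl, setNames(max(c(0L, cl)) + seq_along(singletons), singletons))
  ids <- sprintf("OG%04d", match(cl, unique(cl)))
  data.frame(gene_id = names(cl), group_id = ids, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classify the chromosome occupancy of ortholog groups
#'
#' Loci found on only one chromosome, on the two homeologous chromosomes of
#' one group, or on all chromosomes are excluded; groups matched on two or
#' more non-homeologous chromosomes are retained as candidate
#' interchromosomal duplication/loss events.
#'
#' @param groupChromosomes named list: group id -> character vector of wheat
#'   chromosomes with evidence for that group. Names must parse as
#'   group-number + subgenome (e.g. `"3A"`).
#' @param allChromosomes character vector of every chromosome in the genome.
#' @return data.frame `group_id`, `n_chromosomes`, `chromosomes`
#'   (comma-separated), `category` (one of `single-chromosome`,
#'   `homeologous-only`, `ubiquitous`, `multi-chromosome`), `excluded`.
#' @export
classifyLoci <- function(groupChromosomes, allChromosomes) {
  parseChromName(allChromosomes)       # validates
  rows <- lapply(names(groupChromosomes), function(gid) {
    chs <- sort(unique(groupChromosomes[[gid]]))
    info <- parseChromName(chs)
    category <-
      if (length(chs) == 1L) "single-chromosome"
      else if (setequal(chs, allChromosomes)) "ubiquitous"
      else if (length(chs) == 2L && length(unique(info$group)) == 1L &&
               setequal(info$subgenome, c("A", "B"))) "homeologous-only"
      else "multi-chromosome"
    data.frame(group_id = gid, n_chromosomes = length(chs),
               chromosomes = paste(chs, collapse = ","),
               category = category,
               excluded = category != "multi-chromosome",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-chromosome conserved-matched bases from hit evidence
#'
#' Given filtered hits whose queries have known genomic intervals, returns
#' the width of the union of the intervals of matched queries, per
#' chromosome — the "conserved fraction" numerator of the gene-content
#' estimator.
#'
#' @param hits filtered hit data.frame (`query_id`).
#' @param queryRanges data.frame `query_id`, `chrom`, `start`, `end`.
#' @return named numeric vector: matched bases per chromosome.
#' @export
conservedBases <- function(hits, queryRanges) {
  q <- queryRanges[queryRanges$query_id %in% unique(hits$query_id), ,
                   drop = FALSE]
  vapply(split(q, q$chrom), function(d) as.numeric(
    unionWidth(d$start, d$end)), numeric(1L))
}

#' Estimate conserved gene content
#'
#' The default coverage estimator divides the conserved-matched bases of
#' each chromosome by the chromosome size to obtain a conserved fraction,
#' and converts summed matched bases to a gene count by assuming a mean
#' coding-sequence length (2772 bases by default):
#' `genes = sum_chr(size * fraction) / meanCdsLength`. An alternative
#' locus-count estimator (`method = "loci"`) instead counts distinct
#' group-by-chromosome loci.
#'
#' @param matchedBases named numeric: conserved-matched bases per chromosome
#'   (see [conservedBases()]).
#' @param chromosomeSizes named numeric of chromosome sizes, bases.
#' @param meanCdsLength mean coding-sequence length, bases (> 0).
#' @param method `"coverage"` (default) or `"loci"`.
#' @param lociCounts for `method = "loci"`: named numeric of distinct locus
#'   counts per chromosome.
#' @return list with `per_chromosome` (data.frame `chrom`, `size`,
#'   `matched_bases`, `conserved_fraction`, `estimated_genes`) and
#'   `estimated_gene_count`.
#' @examples
#' estimateGeneContent(c(chr1 = 1.386e6), c(chr1 = 1e8))  # 500 genes
#' @export
estimateGeneContent <- function(matchedBases, chromosomeSizes,
                                meanCdsLength = 2772,
                                method = c("coverage", "loci"),
                                lociCounts = NULL) {
  method <- match.arg(method)
  if (meanCdsLength <= 0) stop("meanCdsLength must be > 0")
  chroms <- names(chromosomeSizes)
  mb <- setNames(numeric(length(chroms)), chroms)
  mb[names(matchedBases)] <- matchedBases
  if (any(mb > chromosomeSizes))
    stop("matched bases exceed chromosome size")
  frac <- mb / as.numeric(chromosomeSizes)
  perChrom <- data.frame(chrom = chroms, size = as.numeric(chromosomeSizes),
                         matched_bases = as.numeric(mb),
                         conserved_fraction = as.numeric(frac),
                         stringsAsFactors = FALSE)
  if (method == "coverage") {
    perChrom$estimated_genes <- perChrom$size * perChrom$conserved_fraction /
      meanCdsLength
    est <- sum(perChrom$estimated_genes)
  } else {
    if (is.null(lociCounts)) stop("method 'loci' needs lociCounts")
    lc <- setNames(numeric(length(chroms)), chroms)
    lc[names(lociCounts)] <- lociCounts
    perChrom$estimated_genes <- as.numeric(lc)
    est <- sum(lc)
  }
  list(per_chromosome = perChrom, estimated_gene_count = est,
       mean_cds_length = meanCdsLength, method = method)
}

#' Tally putatively wheat-specific contigs
#'
#' Contigs hitting wheat transcripts/proteins but no grass gene are counted
#' separately, with a flag for hits covering at least a fraction (default
#' 70\%) of the target length.
#'
#' @param wheatHits filtered hits of contigs against wheat
#'   transcripts/proteins, with columns `query_id`, `subject_id`, `sstart`,
#'   `send` and subject lengths in `subject_length`.
#' @param grassMatched character vector of query ids with any grass-gene hit.
#' @param coverageFlag coverage fraction threshold.
#' @return data.frame `query_id`, `best_target`, `target_coverage`,
#'   `covers_target` for queries with no grass match.
#' @export
wheatSpecificTally <- function(wheatHits, grassMatched, coverageFlag = 0.7) {
  h <- wheatHits[!(wheatHits$query_id %in% grassMatched), , drop = FALSE]
  if (!nrow(h))
    return(data.frame(query_id = character(0), best_target = character(0),
                      target_coverage = numeric(0), covers_target = logical(0),
                      stringsAsFactors = FALSE))
  h$cov <- abs(h$send - h$sstart + 1) / h$subject_length
  o <- order(h$query_id, -h$cov)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  data.frame(query_id = h$query_id, best_target = h$subject_id,
             target_coverage = h$cov,
             covers_target = h$cov >= coverageFlag,
             stringsAsFactors = FALSE, row.names = NULL)
}
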