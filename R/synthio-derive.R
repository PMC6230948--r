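## Derived synthetic inputs: transcript sets, homology hit tables, mapping
## records and small-RNA reads, all deterministic functions of the genome
## and its manifest (plus a seed where noise is drawn).

extractSeq <- function(chromosomes, chrom, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(chromosomes[[chrom]], start + 1L, end))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Planted transcript set (lncRNAs + coding decoys)
#'
#' Extracts the genomic sequence of every planted lncRNA and decoy; the
#' resulting FASTA-ready set is the input of the lncRNA elimination
#' cascade.
#'
#' @param chromosomes genome [Biostrings::DNAStringSet].
#' @param manifest the [TruthManifest-class].
#' @return named [Biostrings::DNAStringSet].
#' @export
plantedTranscripts <- function(chromosomes, manifest) {
  ln <- plantedFeatures(manifest, "lncrnas")
  de <- plantedFeatures(manifest, "decoys")
  ids <- c(ln$lnc_id, de$decoy_id)
  chs <- c(ln$chrom, de$chrom)
  ss <- c(ln$start, de$start); es <- c(ln$end, de$end)
  seqs <- vapply(seq_along(ids), function(i)
    extractSeq(chromosomes, chs[i], ss[i], es[i]), character(1L))
  Biostrings::DNAStringSet(setNames(seqs, ids))
}

#' Mature catalogue of the planted miRNA families
#'
#' @param manifest the [TruthManifest-class].
#' @return named character vector family -> mature RNA sequence.
#' @export
matureCatalogue <- function(manifest) {
  m <- plantedFeatures(manifest, "mirnas")
  fams <- mirnaFamilies()
  fams[names(fams) %in% m$family]
}

#' Simulated homology hit tables for the orthology stage
#'
#' Emits (i) grass-vs-grass hits in both directions for every planted
#' ortholog set (Brachypodium, rice, sorghum, barley members of each
#' homeolog group) and (ii) wheat-vs-grass hits in both directions linking
#' each planted wheat gene to its grass orthologs. Noiseless by default;
#' `noise` adds that many spurious weak hits (below the filter profiles)
#' per table.
#'
#' @param manifest the [TruthManifest-class].
#' @param noise number of spurious sub-threshold hits to add.
#' @param seed seed for the noise draws.
#' @return data.frame with columns `query_id`, `query_species`,
#'   `subject_id`, `subject_species`, `pident`, `ppos`, `length`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bit_score`.
#' @export
simulateHomologyHits <- function(manifest, noise = 0L, seed = 1L) {
  genes <- plantedFeatures(manifest, "genes")
  speciesCols <- c(brachypodium = "ortholog_bd", rice = "ortholog_os",
                   sorghum = "ortholog_sb", barley = "ortholog_hv")
  rows <- list()
  hit <- function(q, qs, s, ss, len, ev, bs, pid = 88, ppos = 94) {
    data.frame(query_id = q, query_species = qs, subject_id = s,
               subject_species = ss, pident = pid, ppos = ppos,
               length = len, qstart = 1L, qend = len, sstart = 1L,
               send = len, evalue = ev, bit_score = bs,
               stringsAsFactors = FALSE)
  }
  ## one ortholog set per homeolog group
  og <- genes[!duplicated(genes$homeolog_group), , drop = FALSE]
  for (i in seq_len(nrow(og))) {
    len <- og$cds_length[i] %/% 3L
    members <- setNames(unlist(og[i, speciesCols]), names(speciesCols))
    for (a in names(members)) for (b in names(members)) {
      if (a == b) next
      rows[[length(rows) + 1L]] <-
        hit(members[[a]], a, members[[b]], b, len, 1e-180, 1500)
    }
  }
  ## wheat gene loci vs grass orthologs, both directions
  for (i in seq_len(nrow(genes))) {
    len <- genes$cds_length[i] %/% 3L
    for (sp in names(speciesCols)) {
      orth <- genes[[speciesCols[[sp]]]][i]
      rows[[length(rows) + 1L]] <-
        hit(genes$gene_id[i], "wheat", orth, sp, len, 1e-120, 800)
      rows[[length(rows) + 1L]] <-
        hit(orth, sp, genes$gene_id[i], "wheat", len, 1e-120, 800)
    }
  }
  df <- do.call(rbind, rows)
  if (noise > 0L) {
    df <- rbind(df, withSeed(subSeed(seed, 101L), {
      sp <- sample(names(speciesCols), noise, replace = TRUE)
      hit(sprintf("noise_q%04d", seq_len(noise)), "wheat",
          sprintf("noise_s%04d", seq_len(noise)), sp,
          len = sample(10:25, noise, replace = TRUE),
          ev = 10^runif(noise, -4, 0), bs = runif(noise, 20, 40),
          pid = runif(noise, 30, 60), ppos = runif(noise, 40, 70))
    }))
  }
  rownames(df) <- NULL
  df
}

#' Simulated spliced-alignment records for the lncRNA cascade
#'
#' Every planted lncRNA maps full-length (coverage 1.0) with a score in
#' `[60, 95]` and canonical GT..AG splice signals on each of the three
#' genome resources (the chromosome assemblies and two reference genomes);
#' decoys receive partial, low-score mappings.
#'
#' @param manifest the [TruthManifest-class].
#' @param genomes labels of the mapped genome resources.
#' @param seed seed for the score draws.
#' @return data.frame `transcript_id`, `genome`, `coverage`, `score`,
#'   `n_introns`, `splice_signals`, `strand`.
#' @export
simulateMappingRecords <- function(manifest,
                                   genomes = c("assembly", "zavitan",
                                               "chinese_spring"),
                                   seed = 1L) {
  ln <- plantedFeatures(manifest, "lncrnas")
  de <- plantedFeatures(manifest, "decoys")
  withSeed(subSeed(seed, 211L), {
    rows <- list()
    for (g in genomes) {
      if (nrow(ln))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = ln$lnc_id, genome = g, coverage = 1.0,
          score = round(runif(nrow(ln), 60, 95), 1), n_introns = 1L,
          splice_signals = "GT-AG", strand = "+", stringsAsFactors = FALSE)
      if (nrow(de))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = de$decoy_id, genome = g,
          coverage = round(runif(nrow(de), 0.5, 0.95), 2),
          score = round(runif(nrow(de), 10, 35), 1), n_introns = 0L,
          splice_signals = "", strand = "+", stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}

#' Simulated homology hits against known proteins for the decoy screen
#'
#' Decoys designated for removal at the homology stage receive one strong
#' protein hit passing the blastx screen; all other transcripts receive
#' none.
#'
#' @param manifest the [TruthManifest-class].
#' @return data.frame `query_id`, `screen`, `evalue`, `length`, `ppos`,
#'   `pident`.
#' @export
simulateLncrnaHits <- function(manifest) {
  de <- plantedFeatures(manifest, "decoys")
  de <- de[de$removal == "homology", , drop = FALSE]
  if (!nrow(de))
    return(data.frame(query_id = character(0), screen = character(0),
                      evalue = numeric(0), length = numeric(0),
                      ppos = numeric(0), pident = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(query_id = de$decoy_id, screen = "blastx_protein",
             evalue = 1e-40, length = 120, ppos = 92, pident = 85,
             stringsAsFactors = FALSE)
}

#' Simulated small-RNA reads supporting a fraction of planted families
#'
#' Emits exact mature-sequence reads (DNA alphabet) for the first
#' `supportedFraction` of the planted families (in catalogue order) plus
#' random background reads, so the supported fraction recovered by
#' [expressionEvidence()] is known.
#'
#' @param manifest the [TruthManifest-class].
#' @param supportedFraction fraction of planted families given reads.
#' @param nBackground random 21-nt background reads.
#' @param seed seed.
#' @return list `reads` ([Biostrings::DNAStringSet]), `supportedFamilies`.
#' @export
simulateSmallRnaReads <- function(manifest, supportedFraction = 0.5,
                                  nBackground = 20L, seed = 1L) {
  fams <- matureCatalogue(manifest)
  nSup <- round(supportedFraction * length(fams))
  sup <- names(fams)[seq_len(nSup)]
  withSeed(subSeed(seed, 307L), {
    reads <- c(chartr("U", "T", unlist(fams[sup])),
               vapply(seq_len(nBackground), function(i) randomDna(21L),
                      character(1L)))
    names(reads) <- sprintf("read_%03d", seq_along(reads))
    list(reads = Biostrings::DNAStringSet(reads), supportedFamilies = sup)
  })
}

#' Simulated variant records against a reference genotype
#'
#' Draws `n` random single-nucleotide or short insertion/deletion records
#' across the chromosomes with Poisson depths and uniform qualities, for
#' exercising the variant filter/summary stage.
#'
#' @param manifest the [TruthManifest-class].
#' @param n number of records.
#' @param indelFraction fraction of records that are InDels.
#' @param seed seed.
#' @return variant data.frame (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`).
#' @export
simulateVariants <- function(manifest, n = 500L, indelFraction = 0.15,
                             seed = 1L) {
  lens <- chromosomeLengths(manifest)
  withSeed(subSeed(seed, 401L), {
    chrom <- sample(names(lens), n, replace = TRUE)
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1L), integer(1L))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1L))
    isIndel <- runif(n) < indelFraction
    ins <- runif(n) < 0.5
    ref[isIndel & !ins] <- paste0(ref[isIndel & !ins],
                                  vapply(which(isIndel & !ins), function(i)
                                    randomDna(sample(1:3, 1L)),
                                    character(1L)))
    alt[isIndel & !ins] <- substr(ref[isIndel & !ins], 1L, 1L)
    alt[isIndel & ins] <- paste0(ref[isIndel & ins],
                                 vapply(which(isIndel & ins), function(i)
                                   randomDna(sample(1:3, 1L)),
                                   character(1L)))
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               qual = round(runif(n, 5, 60), 1),
               depth = stats::rpois(n, 20), stringsAsFactors = FALSE,
               row.names = NULL)
  })
}

#' Project placements back to the pre-translocation reference arrangement
#'
#' Placements on the acceptor chromosome beyond the translocation junction
#' are mapped back to the donor chromosome's original coordinates, yielding
#' the arrangement of a reference genome that does not carry the
#' translocation. Links between the assembly and this reference then
#' expose the engineered event as an off-diagonal chromosome pair.
#'
#' @param placements placement data.frame on the assembly chromosomes.
#' @param manifest the [TruthManifest-class] (carries the breakpoints).
#' @return placement data.frame in reference coordinates.
#' @export
referencePlacements <- function(placements, manifest) {
  tr <- translocationTruth(manifest)
  if (!length(tr)) return(placements)
  p <- placements
  sel <- p$chrom == tr$acceptor & p$start >= tr$acceptorJunction
  off <- tr$acceptorJunction - tr$donorBreakpoint
  p$chrom[sel] <- tr$donor
  p$start[sel] <- p$start[sel] - off
  p$end[sel] <- p$end[sel] - off
  p
}

#' Write chromosomes, scaffolds or transcripts as FASTA
#'
#' @param seqs [Biostrings::DNAStringSet] (or named character).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Emit the planted features of a manifest as GFF3
#'
#' @param manifest the [TruthManifest-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeManifestGff3 <- function(manifest, path) {
  tabs <- list(
    transposable_element = plantedFeatures(manifest, "tes"),
    gene = plantedFeatures(manifest, "genes"),
    miRNA_primary_transcript = plantedFeatures(manifest, "mirnas"),
    lnc_RNA = plantedFeatures(manifest, "lncrnas"),
    microsatellite = plantedFeatures(manifest, "ssrs"))
  rows <- list()
  for (type in names(tabs)) {
    d <- tabs[[type]]
    if (!nrow(d)) next
    rows[[type]] <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                               type = type,
                               strand = if ("strand" %in% names(d)) d$strand
                                        else "+",
                               id = d[[1L]], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  writeGff3(df, path)
}
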