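## End-to-end pipeline: one structured configuration drives
## simulate -> scaffold -> repeats -> orthology -> mirna -> lncrna ->
## markers -> synteny, writing plot-ready tables and a survey report.
## Every published constant (200-b contig filter, 50-nt merge, 2772-b CDS,
## >50% TE confidence rule, 100-aa ORF, 200-nt lncRNA, mapping score 40,
## >200 links / 1-Mb bundling, 500-kb density windows, the per-species
## BLAST profiles) appears as an explicit named default here, never inline.

#' Default pipeline configuration
#'
#' @return nested named list of every stage parameter.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      nHomeologousPairs = 2L, chromosomeLength = 500000L,
      teFraction = 0.6, nConservedGenesPerChr = 25L,
      meanCdsLength = 2772L, nMirnaHairpins = 16L,
      teEmbeddedMirnaFraction = 0.25, nLncrna = 12L, nCodingDecoys = 12L,
      nSsr = 20L,
      translocation = list(donor = "2A", acceptor = "1B",
                           tailLength = 50000L),
      scaffoldN50Target = 5000L, errorRate = 0),
    scaffold = list(min_length = 200L, max_gap = 50L),
    repeats = list(min_match = 50L, max_mismatch_fraction = 0.1),
    orthology = list(inflation = 2.0, mean_cds_length = 2772,
                     profiles = c(hitFilterProfiles(),
                                  list(wheat = list(max_evalue = 1e-6,
                                                    min_length = 30,
                                                    min_ppos = 75)))),
    mirna = list(max_mismatches = 2L, flank = 200L, target_cutoff = 3.0,
                 min_paired_fraction = 0.6, min_stem_pairs = 18L),
    lncrna = list(min_length = 200L, max_peptide = 100L,
                  min_map_score = 40, coverage_tol = 0),
    markers = list(min_flank = 30L, min_depth = 10, min_qual = 30,
                   biallelic_only = TRUE, n_variants = 500L),
    synteny = list(window = 1e5, min_links = 5L,
                   gene_density_window = 5e5))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the schema of
#' [defaultPipelineConfig()] before any stage runs: unknown keys (at any
#' nesting level except within `orthology$profiles` and
#' `simulate$translocation`) are rejected, and missing keys are filled with
#' their defaults.
#'
#' @param config nested list (possibly partial).
#' @return the merged, validated configuration.
#' @export
validatePipelineConfig <- function(config) {
  def <- defaultPipelineConfig()
  free <- c("profiles", "translocation")   # open sub-schemas
  mergeCheck <- function(cfg, dflt, path) {
    unknown <- setdiff(names(cfg), names(dflt))
    if (length(unknown))
      stop("unknown configuration key: ",
           paste(paste0(path, unknown), collapse = ", "))
    for (k in names(dflt)) {
      if (is.null(cfg[[k]])) cfg[k] <- dflt[k]
      else if (is.list(dflt[[k]]) && !(k %in% free))
        cfg[[k]] <- mergeCheck(cfg[[k]], dflt[[k]], paste0(path, k, "$"))
    }
    cfg[names(dflt)]
  }
  mergeCheck(config, def, "")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

specFromConfig <- function(cfg) {
  s <- cfg$simulate
  syntheticGenomeSpec(
    nHomeologousPairs = s$nHomeologousPairs,
    chromosomeLength = s$chromosomeLength, teFraction = s$teFraction,
    nConservedGenesPerChr = s$nConservedGenesPerChr,
    meanCdsLength = s$meanCdsLength, nMirnaHairpins = s$nMirnaHairpins,
    teEmbeddedMirnaFraction = s$teEmbeddedMirnaFraction,
    nLncrna = s$nLncrna, nCodingDecoys = s$nCodingDecoys, nSsr = s$nSsr,
    translocation = if (is.null(s$translocation)) list() else
      s$translocation,
    scaffoldN50Target = s$scaffoldN50Target, seed = cfg$seed)
}

#' Run the full survey pipeline
#'
#' Executes every stage on the synthetic genome defined by the
#' configuration, writes the result tables and a human-readable summary to
#' `outdir`, and returns the stage outputs invisibly. Output is
#' byte-identical across runs with the same configuration and seed. On a
#' stage error the run aborts naming the failing stage; tables written by
#' completed stages are retained and listed in `stages_completed.txt`.
#'
#' @param config configuration list (see [defaultPipelineConfig()]);
#'   validated before any stage runs.
#' @param outdir output directory (created).
#' @return (invisibly) list with all stage outputs and the report tallies.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir) {
  cfg <- validatePipelineConfig(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  completed <- character(0)
  note <- function(stage) {
    completed <<- c(completed, stage)
    writeLines(completed, file.path(outdir, "stages_completed.txt"))
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logLines <- character(0)
  logp <- function(...) logLines <<- c(logLines, paste0(...))

  ## -- simulate ----------------------------------------------------------
  res <- list(config = cfg)
  run("simulate", {
    spec <- specFromConfig(cfg)
    g <- generateGenome(spec)
    res$chromosomes <- g$chromosomes
    res$manifest <- g$manifest
    writeFasta(g$chromosomes, file.path(outdir, "chromosomes.fasta"))
    writeManifest(g$manifest, file.path(outdir, "truth_manifest.json"))
    writeManifestGff3(g$manifest, file.path(outdir, "planted_features.gff3"))
    logp("simulate: seed=", cfg$seed, " teFraction=",
         cfg$simulate$teFraction)
  })
  note("simulate")
  lens <- setNames(Biostrings::width(res$chromosomes),
                   names(res$chromosomes))

  ## -- scaffold ----------------------------------------------------------
  run("scaffold", {
    fr <- fragmentIntoScaffolds(res$chromosomes,
                                cfg$simulate$scaffoldN50Target,
                                cfg$simulate$errorRate, seed = cfg$seed)
    kept <- filterMinLength(fr$scaffolds, cfg$scaffold$min_length)
    placements <- fr$placements[fr$placements$query_id %in% names(kept), ,
                                drop = FALSE]
    res$scaffolds <- kept
    res$placements <- placements
    res$superScaffolds <- buildSuperScaffolds(placements, kept,
                                              maxGap = cfg$scaffold$max_gap)
    stats <- lapply(names(lens), function(ch) {
      sel <- placements$chrom == ch
      st <- computeAssemblyStats(
        Biostrings::width(kept[placements$query_id[sel]]),
        referenceLength = lens[[ch]],
        covered = placements[sel, c("start", "end")],
        minLengthApplied = cfg$scaffold$min_length)
      data.frame(chrom = ch, n_scaffolds = st$n_sequences,
                 total_length = st$total_length, n50 = st$n50,
                 representation = st$representation_fraction)
    })
    res$assemblyStats <- do.call(rbind, stats)
    writeTsv(res$assemblyStats, file.path(outdir, "assembly_stats.tsv"))
    writePlacements(placements, file.path(outdir, "placements.tsv"))
    logp("scaffold: min_length=", cfg$scaffold$min_length, " max_gap=",
         cfg$scaffold$max_gap)
  })
  note("scaffold")

  ## -- repeats -----------------------------------------------------------
  run("repeats", {
    res$repeatAnnotations <- maskWithLibrary(
      res$chromosomes, repeatLibrary(),
      minMatch = cfg$repeats$min_match,
      maxMismatchFraction = cfg$repeats$max_mismatch_fraction)
    res$landscape <- summarizeLandscape(res$repeatAnnotations, lens)
    writeTsv(res$repeatAnnotations, file.path(outdir,
                                              "repeat_annotations.tsv"))
    writeTsv(res$landscape$chromosome,
             file.path(outdir, "repeat_landscape_chromosome.tsv"))
    writeTsv(res$landscape$subgenome,
             file.path(outdir, "repeat_landscape_subgenome.tsv"))
    logp("repeats: min_match=", cfg$repeats$min_match,
         " max_mismatch_fraction=", cfg$repeats$max_mismatch_fraction)
  })
  note("repeats")

  ## -- orthology ---------------------------------------------------------
  run("orthology", {
    hits <- simulateHomologyHits(res$manifest, seed = cfg$seed)
    filtered <- filterHits(hits, cfg$orthology$profiles)
    grass <- c("brachypodium", "rice", "sorghum", "barley")
    brh <- list()
    for (i in seq_along(grass)) for (j in seq_along(grass)) {
      if (i >= j) next
      brh[[length(brh) + 1L]] <- bestReciprocalHits(filtered, grass[i],
                                                    grass[j])
    }
    brhPairs <- do.call(rbind, brh)
    grassGenes <- unique(filtered$subject_id[
      filtered$subject_species %in% grass])
    res$orthoGroups <- clusterOrthogroups(brhPairs,
                                          inflation = cfg$orthology$inflation,
                                          singletons = grassGenes)
    ## group occupancy from filtered wheat-query hits
    wheatHits <- filtered[filtered$query_species == "wheat" &
                            filtered$subject_species %in% grass, ,
                          drop = FALSE]
    genes <- plantedFeatures(res$manifest, "genes")
    queryChrom <- setNames(genes$chrom, genes$gene_id)
    g2g <- setNames(res$orthoGroups$group_id, res$orthoGroups$gene_id)
    ev <- data.frame(group = g2g[wheatHits$subject_id],
                     chrom = queryChrom[wheatHits$query_id],
                     stringsAsFactors = FALSE)
    ev <- ev[!is.na(ev$group) & !is.na(ev$chrom), , drop = FALSE]
    groupChrom <- lapply(split(ev$chrom, ev$group), unique)
    res$locusCalls <- classifyLoci(groupChrom, names(lens))
    queryRanges <- data.frame(query_id = genes$gene_id, chrom = genes$chrom,
                              start = genes$start, end = genes$end,
                              stringsAsFactors = FALSE)
    mb <- conservedBases(wheatHits, queryRanges)
    res$geneContent <- estimateGeneContent(
      mb, lens, meanCdsLength = cfg$orthology$mean_cds_length)
    writeTsv(res$orthoGroups, file.path(outdir, "ortholog_groups.tsv"))
    writeTsv(res$locusCalls, file.path(outdir, "locus_classification.tsv"))
    writeTsv(res$geneContent$per_chromosome,
             file.path(outdir, "gene_content.tsv"))
    logp("orthology: inflation=", cfg$orthology$inflation,
         " mean_cds_length=", cfg$orthology$mean_cds_length)
  })
  note("orthology")

  ## -- mirna -------------------------------------------------------------
  run("mirna", {
    matures <- matureCatalogue(res$manifest)
    cand <- scanHomology(res$chromosomes, matures,
                         maxMismatches = cfg$mirna$max_mismatches,
                         flank = cfg$mirna$flank)
    if (nrow(cand)) {
      metrics <- lapply(seq_len(nrow(cand)), function(i) {
        pre <- extractSeq(res$chromosomes, cand$chrom[i],
                          cand$precursor_start[i], cand$precursor_end[i],
                          cand$strand[i])
        off <- if (cand$strand[i] == "+")
          cand$mature_start[i] - cand$precursor_start[i]
        else cand$precursor_end[i] - cand$mature_end[i]
        hp <- evaluateHairpin(pre, off, cand$mature_end[i] -
                                cand$mature_start[i],
                              minPairedFraction =
                                cfg$mirna$min_paired_fraction,
                              minStemPairs = cfg$mirna$min_stem_pairs)
        ov <- overlapFraction(cand$chrom[i], cand$precursor_start[i],
                              cand$precursor_end[i], res$repeatAnnotations)
        data.frame(precursor_seq = pre,
                   hairpin_pass = hp$pass,
                   pairing_score = hp$pairing_score,
                   mature_paired_fraction = hp$mature_paired_fraction,
                   te_overlap = ov,
                   confidence = classifyConfidence(ov),
                   stringsAsFactors = FALSE)
      })
      cand <- cbind(cand, do.call(rbind, metrics))
    }
    res$mirnaCandidates <- cand
    genes <- plantedFeatures(res$manifest, "genes")
    exons <- plantedFeatures(res$manifest, "exons")
    ctx <- classifyGenomicContext(
      data.frame(chrom = cand$chrom, start = cand$mature_start,
                 end = cand$mature_end, stringsAsFactors = FALSE),
      genes, exons)
    res$mirnaContext <- ctx$tally
    ## family core set across subgenomes
    sub <- substr(cand$chrom, nchar(cand$chrom), nchar(cand$chrom))
    res$mirnaCore <- familyCoreSet(split(cand$family, sub))
    ## expression evidence
    sr <- simulateSmallRnaReads(res$manifest, seed = cfg$seed)
    res$mirnaExpression <- expressionEvidence(
      matures,
      data.frame(family = cand$family, seq = cand$precursor_seq,
                 stringsAsFactors = FALSE),
      sr$reads, Biostrings::DNAStringSet())
    ## targets among the planted transcript set
    tx <- plantedTranscripts(res$chromosomes, res$manifest)
    res$mirnaTargets <- pairWithMirna(tx, matures,
                                      cutoff = cfg$mirna$target_cutoff)
    writeTsv(cand[, setdiff(names(cand), "precursor_seq")],
             file.path(outdir, "mirna_candidates.tsv"))
    writeTsv(res$mirnaContext, file.path(outdir, "mirna_context.tsv"))
    writeTsv(res$mirnaExpression, file.path(outdir, "mirna_expression.tsv"))
    writeTsv(res$mirnaTargets, file.path(outdir, "mirna_targets.tsv"))
    logp("mirna: max_mismatches=", cfg$mirna$max_mismatches, " flank=",
         cfg$mirna$flank, " target_cutoff=", cfg$mirna$target_cutoff)
  })
  note("mirna")

  ## -- lncrna ------------------------------------------------------------
  run("lncrna", {
    tx <- plantedTranscripts(res$chromosomes, res$manifest)
    casc <- runLncrnaCascade(
      tx, simulateLncrnaHits(res$manifest),
      simulateMappingRecords(res$manifest, seed = cfg$seed),
      minLength = cfg$lncrna$min_length,
      maxPeptide = cfg$lncrna$max_peptide,
      minScore = cfg$lncrna$min_map_score,
      coverageTol = cfg$lncrna$coverage_tol)
    res$lncrnaCascade <- casc
    res$mirnaLncrnaPairs <- pairWithMirna(tx[casc$survivors],
                                          matureCatalogue(res$manifest),
                                          cutoff = cfg$mirna$target_cutoff)
    writeTsv(casc$trace, file.path(outdir, "lncrna_trace.tsv"))
    writeTsv(casc$finalStatus, file.path(outdir, "lncrna_status.tsv"))
    writeTsv(res$mirnaLncrnaPairs,
             file.path(outdir, "mirna_lncrna_pairs.tsv"))
    logp("lncrna: min_length=", cfg$lncrna$min_length, " max_peptide=",
         cfg$lncrna$max_peptide, " min_map_score=",
         cfg$lncrna$min_map_score)
  })
  note("lncrna")

  ## -- markers -----------------------------------------------------------
  run("markers", {
    ssrs <- do.call(rbind, lapply(names(res$chromosomes), function(ch)
      findSsrs(res$chromosomes[[ch]], contigId = ch)))
    res$ssrLoci <- ssrs
    res$isbpJunctions <- findIsbpJunctions(res$repeatAnnotations, lens,
                                           minFlank = cfg$markers$min_flank)
    vars <- simulateVariants(res$manifest, n = cfg$markers$n_variants,
                             seed = cfg$seed)
    res$variantFilter <- filterVariants(vars,
                                        minDepth = cfg$markers$min_depth,
                                        minQual = cfg$markers$min_qual,
                                        biallelicOnly =
                                          cfg$markers$biallelic_only)
    writeTsv(ssrs, file.path(outdir, "ssr_loci.tsv"))
    writeTsv(res$isbpJunctions, file.path(outdir, "isbp_junctions.tsv"))
    writeTsv(res$variantFilter$summary,
             file.path(outdir, "variant_summary.tsv"))
    logp("markers: min_flank=", cfg$markers$min_flank, " min_depth=",
         cfg$markers$min_depth, " min_qual=", cfg$markers$min_qual)
  })
  note("markers")

  ## -- synteny -----------------------------------------------------------
  run("synteny", {
    refPlace <- referencePlacements(res$placements, res$manifest)
    links <- buildLinks(res$placements, refPlace)
    ribbons <- bundleRibbons(links, window = cfg$synteny$window,
                             minLinks = cfg$synteny$min_links)
    expected <- data.frame(chrom1 = names(lens), chrom2 = names(lens),
                           stringsAsFactors = FALSE)
    res$syntenyLinks <- links
    res$syntenyRibbons <- ribbons
    res$translocationFlags <- flagInterchromosomal(ribbons, expected)
    genes <- plantedFeatures(res$manifest, "genes")
    res$geneDensity <- geneDensity(
      data.frame(chrom = genes$chrom, pos = genes$start,
                 stringsAsFactors = FALSE),
      lens, window = cfg$synteny$gene_density_window)
    writeTsv(links, file.path(outdir, "synteny_links.tsv"))
    writeTsv(ribbons, file.path(outdir, "synteny_ribbons.tsv"))
    writeTsv(res$translocationFlags,
             file.path(outdir, "translocation_flags.tsv"))
    writeTsv(res$geneDensity, file.path(outdir, "gene_density.tsv"))
    logp("synteny: window=", cfg$synteny$window, " min_links=",
         cfg$synteny$min_links)
  })
  note("synteny")

  writeLines(logLines, file.path(outdir, "parameters.log"))
  writeSummary(res, file.path(outdir, "summary.txt"))
  invisible(res)
}

## human-readable survey report; content is a pure function of the stage
## outputs, so identical seeds give byte-identical files
writeSummary <- function(res, path) {
  man <- res$manifest
  lens <- chromosomeLengths(man)
  s <- c("emmerSurvey pipeline report",
         "===========================",
         "",
         sprintf("Genome: %d chromosomes, %.0f b total",
                 length(lens), sum(as.numeric(lens))),
         "",
         "Assembly (per chromosome):",
         sprintf("  %-4s n=%5d total=%9.0f N50=%6.0f repr=%.3f",
                 res$assemblyStats$chrom, res$assemblyStats$n_scaffolds,
                 res$assemblyStats$total_length, res$assemblyStats$n50,
                 res$assemblyStats$representation),
         "",
         "Repeat landscape:")
  sg <- res$landscape$subgenome
  for (scope in unique(sg$scope)) {
    d <- sg[sg$scope == scope, , drop = FALSE]
    top <- d$family[which.max(d$family_fraction_of_masked)]
    s <- c(s, sprintf("  subgenome %s: masked %.1f%% (truth %.1f%%), top family %s",
                      scope, 100 * d$masked_fraction[1L],
                      100 * sum(trueRepeatFraction(man)[grepl(
                        paste0(scope, "$"), names(lens))] *
                          lens[grepl(paste0(scope, "$"), names(lens))]) /
                        sum(lens[grepl(paste0(scope, "$"), names(lens))]),
                      top))
  }
  cats <- table(res$locusCalls$category)
  s <- c(s, "",
         sprintf("Orthology: %d groups; locus categories: %s",
                 length(unique(res$orthoGroups$group_id)),
                 paste(sprintf("%s=%d", names(cats), as.integer(cats)),
                       collapse = ", ")),
         sprintf("Gene content estimate: %.1f genes (planted %d)",
                 res$geneContent$estimated_gene_count,
                 trueConservedGeneCount(man)),
         "",
         sprintf("miRNA: %d candidate loci, %d families; HC=%d LC=%d",
                 nrow(res$mirnaCandidates),
                 length(unique(res$mirnaCandidates$family)),
                 sum(res$mirnaCandidates$confidence == "HC"),
                 sum(res$mirnaCandidates$confidence == "LC")),
         sprintf("  context: %s",
                 paste(sprintf("%s=%.2f%%", res$mirnaContext$context,
                               res$mirnaContext$percent), collapse = ", ")),
         sprintf("  expression-supported families: %d of %d",
                 sum(res$mirnaExpression$supported),
                 nrow(res$mirnaExpression)),
         "",
         sprintf("lncRNA cascade: %d in, %d core survivors; removed: %s",
                 nrow(res$lncrnaCascade$finalStatus),
                 length(res$lncrnaCascade$survivors),
                 {
                   rem <- res$lncrnaCascade$finalStatus
                   rem <- rem[rem$status == "removed", , drop = FALSE]
                   t <- table(rem$removing_stage)
                   paste(sprintf("%s=%d", names(t), as.integer(t)),
                         collapse = ", ")
                 }),
         sprintf("miRNA-lncRNA target pairs: %d",
                 nrow(res$mirnaLncrnaPairs)),
         "",
         sprintf("Markers: %d SSR loci, %d ISBP junctions; variants kept %d of %d (SNP %d, InDel %d)",
                 nrow(res$ssrLoci), nrow(res$isbpJunctions),
                 res$variantFilter$summary$n_surviving,
                 res$variantFilter$summary$n_input,
                 res$variantFilter$summary$n_snp,
                 res$variantFilter$summary$n_indel),
         "",
         sprintf("Synteny: %d links, %d ribbons (%d bundled); flagged chromosome pairs: %s",
                 nrow(res$syntenyLinks), nrow(res$syntenyRibbons),
                 sum(res$syntenyRibbons$bundled),
                 if (nrow(res$translocationFlags))
                   paste(unique(paste0(res$translocationFlags$chrom1, "<->",
                                       res$translocationFlags$chrom2)),
                         collapse = ", ")
                 else "none"))
  writeLines(s, path)
  invisible(path)
}
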