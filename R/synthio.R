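## Synthetic tetraploid genome generator. The generator plants every feature
## class the downstream modules annotate (TE copies from the built-in
## library, conserved genes with grass orthologs, miRNA hairpins, lncRNAs,
## coding decoys, SSRs) at known coordinates and records them in a
## TruthManifest, so parameter recovery is measurable without external data.
## All coordinates are 0-based half-open internally.

## -- free-gap bookkeeping -------------------------------------------------
## gaps: data.frame(start, end), disjoint, sorted. A placement consumes its
## margin at placement time, so consecutive features end up separated by at
## least the later feature's margin.
place1 <- function(gaps, len, margin) {
  cap <- gaps$end - gaps$start - len - 2L * margin
  ok <- which(cap >= 0L)
  if (!length(ok)) return(NULL)
  g <- if (length(ok) == 1L) ok else
    ok[sample.int(length(ok), 1L, prob = cap[ok] + 1)]
  s <- gaps$start[g] + margin + sample.int(cap[g] + 1L, 1L) - 1L
  e <- s + len
  pieces <- rbind(gaps[-g, , drop = FALSE],
                  data.frame(start = c(gaps$start[g], e),
                             end = c(s, gaps$end[g])))
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
  list(start = s, gaps = pieces[order(pieces$start), , drop = FALSE])
}

.senseCodons <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))

## CDS of a given length (multiple of 3): ATG + sense codons + TAA
makeCds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", paste(sample(.senseCodons, len / 3L - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

## two-exon gene block: exon1 + canonical GT..AG intron + exon2
.intronLen <- 120L
makeGeneBlock <- function(cds) {
  e1 <- (nchar(cds) %/% 2L)
  intron <- paste0("GT", randomDna(.intronLen - 4L), "AG")
  list(block = paste0(substr(cds, 1L, e1), intron,
                      substr(cds, e1 + 1L, nchar(cds))),
       exon1Len = e1, intronLen = .intronLen)
}

## hairpin block: 50-nt arm (10 + mature + 19) + 8-nt loop + revcomp(arm);
## the mature sits at offset 10 within the block
.hairpinLoop <- "CAACAAAC"
makeHairpin <- function(matureRna) {
  arm <- paste0(randomDna(10L), chartr("U", "T", matureRna), randomDna(19L))
  paste0(arm, .hairpinLoop, revcomp(arm))
}
.matureOffset <- 10L

## lncRNA body: no six-frame ORF > 100 aa; optionally carries the exact
## reverse complement of a mature miRNA (target-mimicry site)
makeLncrna <- function(len, siteMature = NULL) {
  site <- if (is.null(siteMature)) "" else revcomp(chartr("U", "T", siteMature))
  core <- len - nchar(site)
  for (i in 1:50) {
    left <- randomDna(core %/% 2L)
    seq <- paste0(left, site, randomDna(core - nchar(left)))
    if (longestOrfLength(seq) <= 100L) return(seq)
  }
  stop("could not generate an ORF-free lncRNA body")
}

## -- main generator -------------------------------------------------------

#' Generate a synthetic tetraploid genome with ground truth
#'
#' Builds A/B subgenome chromosomes named \code{"1A"}, \code{"1B"}, ... on an
#' i.i.d. uniform A/C/G/T background, plants transposable-element copies
#' (1--5\% point mutations, occasional 5'-anchored truncation) up to the
#' target repeat fraction, conserved two-exon genes at colinear positions on
#' homeologous chromosomes, miRNA hairpins (a fraction embedded inside a
#' low-divergence CACTA copy), lncRNAs, protein-coding decoys and SSR loci,
#' and finally applies the engineered one-way translocation (the donor
#' chromosome's tail is appended to the acceptor). Identical spec and seed
#' give byte-identical output.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @return list with `chromosomes` ([Biostrings::DNAStringSet]) and
#'   `manifest` ([TruthManifest-class]).
#' @examples
#' g <- generateGenome(syntheticGenomeSpec(chromosomeLength = 60000L,
#'   nConservedGenesPerChr = 3L, nMirnaHairpins = 4L, nLncrna = 2L,
#'   nCodingDecoys = 2L, nSsr = 4L,
#'   translocation = list(donor = "2A", acceptor = "1B", tailLength = 8000L),
#'   seed = 1))
#' g$manifest
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  P <- spec@nHomeologousPairs
  L <- spec@chromosomeLength
  chroms <- paste0(rep(seq_len(P), each = 2L), c("A", "B"))
  lib <- repeatLibrary()
  libInfo <- parseLibraryHeaders(names(lib))
  libInfo$len <- Biostrings::width(lib)
  rownames(libInfo) <- libInfo$family
  libSeq <- setNames(as.character(lib), libInfo$family)
  fams <- mirnaFamilies()
  w0 <- spec@teFamilyWeights
  if (!all(names(w0) %in% libInfo$family))
    stop("teFamilyWeights name unknown families")

  withSeed(spec@seed, {
    ## genome-wide feature assignment, round robin over chromosomes
    asgn <- function(n, prefix) {
      if (n == 0L) return(data.frame(id = character(0), chrom = character(0),
                                     stringsAsFactors = FALSE))
      data.frame(id = sprintf("%s_%03d", prefix, seq_len(n)),
                 chrom = chroms[(seq_len(n) - 1L) %% length(chroms) + 1L],
                 stringsAsFactors = FALSE)
    }
    cyc <- function(n, v) v[(seq_len(n) - 1L) %% length(v) + 1L]
    mir <- asgn(spec@nMirnaHairpins, "mir")
    mir$family <- cyc(nrow(mir), names(fams))
    nEmbed <- if (spec@teFraction > 0)
      round(spec@teEmbeddedMirnaFraction * nrow(mir)) else 0L
    mir$te_embedded <- seq_len(nrow(mir)) <= nEmbed
    lnc <- asgn(spec@nLncrna, "lnc")
    lnc$has_site <- seq_len(nrow(lnc)) %% 2L == 1L
    lnc$site_family <- cyc(nrow(lnc), names(fams))
    dec <- asgn(spec@nCodingDecoys, "decoy")
    dec$removal <- cyc(nrow(dec), c("orf", "homology", "length"))
    ssrDefs <- data.frame(motif = c("A", "AG", "AAC", "AGAT", "AACGT",
                                    "AACGTC"),
                          count = c(12L, 8L, 6L, 5L, 5L, 5L),
                          stringsAsFactors = FALSE)
    ssr <- asgn(spec@nSsr, "ssr")
    ssr$motif <- cyc(nrow(ssr), ssrDefs$motif)
    ssr$count <- cyc(nrow(ssr), ssrDefs$count)
    ssr$above <- TRUE
    if (spec@nSsr > 0L) {
      sub <- data.frame(id = c("ssrsub_001", "ssrsub_002"),
                        chrom = chroms[c(1L, 2L)],
                        motif = c("AC", "AAG"), count = c(5L, 4L),
                        above = FALSE, stringsAsFactors = FALSE)
      ssr <- rbind(ssr, sub)
    }

    teBudget <- round(spec@teFraction * L)
    out <- list()                      # per-chromosome results
    for (n in seq_len(P)) {
      ## shared gene layout for the homeologous pair (colinearity)
      nG <- spec@nConservedGenesPerChr
      cds <- integer(0)
      gaps0 <- data.frame(start = 0L, end = L)
      geneStarts <- integer(0)
      if (nG > 0L) {
        cds <- pmax(900L, round(rnorm(nG, spec@meanCdsLength, 250)))
        cds <- as.integer(cds - cds %% 3L)
        for (i in seq_len(nG)) {
          res <- place1(gaps0, cds[i] + .intronLen, 240L)
          if (is.null(res))
            stop("infeasible packing: cannot place genes on chromosome ",
                 n, "A/", n, "B")
          geneStarts[i] <- res$start
          gaps0 <- res$gaps
        }
      }
      baseCds <- vapply(cds, makeCds, character(1L))
      for (sub in c("A", "B")) {
        chrom <- paste0(n, sub)
        out[[chrom]] <- buildChromosome(
          chrom = chrom, L = L, gaps = gaps0,
          geneStarts = geneStarts, cds = cds, baseCds = baseCds,
          pair = n, sub = sub,
          mir = mir[mir$chrom == chrom, , drop = FALSE],
          lnc = lnc[lnc$chrom == chrom, , drop = FALSE],
          dec = dec[dec$chrom == chrom, , drop = FALSE],
          ssr = ssr[ssr$chrom == chrom, , drop = FALSE],
          teBudget = teBudget, weights = w0, libSeq = libSeq,
          libInfo = libInfo, fams = fams)
      }
    }

    ## assemble manifest tables
    bindTab <- function(nm) {
      res <- do.call(rbind, c(lapply(out, `[[`, nm),
                              list(make.row.names = FALSE)))
      if (is.null(res)) .manifestProtos[[nm]] else res
    }
    tes <- bindTab("tes"); genes <- bindTab("genes"); exons <- bindTab("exons")
    mirnas <- bindTab("mirnas"); lncrnas <- bindTab("lncrnas")
    decoys <- bindTab("decoys"); ssrs <- bindTab("ssrs")
    seqs <- lapply(out, `[[`, "seq")
    lens <- setNames(rep(L, length(chroms)), chroms)

    ## engineered translocation: donor tail appended to acceptor
    transloc <- list()
    tl <- spec@translocation
    if (length(tl) && all(c(tl$donor, tl$acceptor) %in% chroms)) {
      cut <- L - as.integer(tl$tailLength)
      shift <- function(df) {          # move cut out of any planted feature
        if (!nrow(df)) return(cut)
        inside <- df$chrom == tl$donor & df$start < cut & df$end > cut
        if (any(inside)) min(df$start[inside]) else cut
      }
      for (tab in list(tes, genes, mirnas, lncrnas, decoys, ssrs))
        cut <- min(cut, shift(tab))
      La <- lens[tl$acceptor]
      move <- function(df) {
        if (!nrow(df)) return(df)
        sel <- df$chrom == tl$donor & df$start >= cut
        off <- La - cut
        for (col in intersect(c("start", "end", "mature_start", "mature_end"),
                              names(df))) {
          df[[col]][sel] <- df[[col]][sel] + off
          df[[col]] <- as.integer(df[[col]])
        }
        df$chrom[sel] <- tl$acceptor
        df
      }
      tes <- move(tes); genes <- move(genes)
      ## exons share gene ids; shift those of moved genes
      if (nrow(exons)) {
        moved <- genes$gene_id[genes$chrom == tl$acceptor &
                                 startsWith(genes$gene_id,
                                            paste0("gene_", tl$donor))]
        sel <- exons$gene_id %in% moved
        exons$start <- as.integer(exons$start + (La - cut) * sel)
        exons$end <- as.integer(exons$end + (La - cut) * sel)
      }
      mirnas <- move(mirnas); lncrnas <- move(lncrnas)
      decoys <- move(decoys); ssrs <- move(ssrs)
      tail <- substr(seqs[[tl$donor]], cut + 1L, L)
      seqs[[tl$donor]] <- substr(seqs[[tl$donor]], 1L, cut)
      seqs[[tl$acceptor]] <- paste0(seqs[[tl$acceptor]], tail)
      lens[tl$donor] <- cut
      lens[tl$acceptor] <- La + (L - cut)
      transloc <- list(donor = tl$donor, acceptor = tl$acceptor,
                       donorBreakpoint = as.integer(cut),
                       acceptorJunction = as.integer(La),
                       tailLength = as.integer(L - cut))
    }

    ## TE junction truth from final TE intervals (both edges, flank >= 30)
    teJunctions <- data.frame(junction_id = character(0), chrom = character(0),
                              pos = integer(0), left = character(0),
                              right = character(0), stringsAsFactors = FALSE)
    if (nrow(tes)) {
      jl <- data.frame(chrom = rep(tes$chrom, 2L),
                       pos = as.integer(c(tes$start, tes$end)),
                       left = c(rep("unique", nrow(tes)), tes$family),
                       right = c(tes$family, rep("unique", nrow(tes))),
                       stringsAsFactors = FALSE)
      keep <- jl$pos >= 30L & (lens[jl$chrom] - jl$pos) >= 30L
      jl <- jl[keep, , drop = FALSE]
      jl <- jl[order(jl$chrom, jl$pos), , drop = FALSE]
      rownames(jl) <- NULL
      jl <- cbind(junction_id = sprintf("isbp_%04d", seq_len(nrow(jl))), jl,
                  stringsAsFactors = FALSE)
      teJunctions <- jl
    }

    trueRep <- vapply(names(lens), function(ch) {
      sel <- tes$chrom == ch
      unionWidth(tes$start[sel], tes$end[sel]) / lens[[ch]]
    }, numeric(1L))

    manifest <- new("TruthManifest",
                    chromosomeLengths = setNames(as.integer(lens),
                                                 names(lens)),
                    tes = tes, genes = genes, exons = exons, mirnas = mirnas,
                    lncrnas = lncrnas, decoys = decoys, ssrs = ssrs,
                    teJunctions = teJunctions, translocation = transloc,
                    trueRepeatFraction = trueRep,
                    trueConservedGeneCount = nrow(genes),
                    spec = spec)
    validObject(manifest)
    list(chromosomes = Biostrings::DNAStringSet(unlist(seqs)),
         manifest = manifest)
  })
}

## build one chromosome: place remaining features, fill TEs, emit sequence
## and manifest rows (coordinates pre-translocation)
buildChromosome <- function(chrom, L, gaps, geneStarts, cds, baseCds,
                            pair, sub, mir, lnc, dec, ssr, teBudget,
                            weights, libSeq, libInfo, fams) {
  parts <- list()                      # start, seq pairs
  addPart <- function(start, seq) parts[[length(parts) + 1L]] <<-
    list(start = start, seq = seq)

  ## genes (shared layout; B copies diverged 2% from the pair's base CDS)
  geneRows <- exonRows <- NULL
  if (length(geneStarts)) {
    geneRows <- lapply(seq_along(geneStarts), function(i) {
      cdsSeq <- if (sub == "A") baseCds[i] else mutateDna(baseCds[i], 0.02)
      gb <- makeGeneBlock(cdsSeq)
      s <- geneStarts[i]
      addPart(s, gb$block)
      gid <- sprintf("gene_%s_%03d", chrom, i)
      list(gene = data.frame(
             gene_id = gid, chrom = chrom, start = s,
             end = s + nchar(gb$block), strand = "+",
             cds_length = cds[i],
             homeolog_group = sprintf("hg_%d_%03d", pair, i),
             ortholog_bd = sprintf("Bradi%dg%03d", pair, i),
             ortholog_os = sprintf("Os%02dg%03d", pair, i),
             ortholog_sb = sprintf("Sb%02dg%03d", pair, i),
             ortholog_hv = sprintf("HORVU%dG%03d", pair, i),
             stringsAsFactors = FALSE),
           exons = data.frame(
             gene_id = gid, exon_index = 1:2,
             start = c(s, s + gb$exon1Len + gb$intronLen),
             end = c(s + gb$exon1Len, s + nchar(gb$block)),
             stringsAsFactors = FALSE))
    })
  }

  ## SSRs with guard bases so the planted run cannot extend into background
  ssrRows <- NULL
  if (nrow(ssr)) {
    ssrRows <- lapply(seq_len(nrow(ssr)), function(i) {
      motif <- ssr$motif[i]; count <- ssr$count[i]
      run <- strrep(motif, count)
      g1 <- setdiff(c("A", "C", "G", "T"),
                    substr(motif, nchar(motif), nchar(motif)))[1L]
      g2 <- setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1L]
      block <- paste0(g1, run, g2)
      res <- place1(gaps, nchar(block), 150L)
      if (is.null(res))
        stop("infeasible packing: cannot place SSRs on chromosome ", chrom)
      gaps <<- res$gaps
      addPart(res$start, block)
      data.frame(ssr_id = ssr$id[i], chrom = chrom,
                 start = res$start + 1L,
                 end = res$start + 1L + nchar(run),
                 motif = motif, count = count,
                 above_threshold = ssr$above[i], stringsAsFactors = FALSE)
    })
  }

  ## free-standing hairpins (margin 220 keeps the +/-200-nt precursor
  ## window clear of neighbouring repeats -> truthfully HC)
  freeMir <- mir[!mir$te_embedded, , drop = FALSE]
  mirRows <- NULL
  if (nrow(freeMir)) {
    mirRows <- lapply(seq_len(nrow(freeMir)), function(i) {
      hp <- makeHairpin(fams[[freeMir$family[i]]])
      res <- place1(gaps, nchar(hp), 220L)
      if (is.null(res))
        stop("infeasible packing: cannot place miRNA hairpins on ", chrom)
      gaps <<- res$gaps
      addPart(res$start, hp)
      data.frame(mirna_id = freeMir$id[i], family = freeMir$family[i],
                 chrom = chrom, start = res$start,
                 end = res$start + nchar(hp), strand = "+",
                 mature_start = res$start + .matureOffset,
                 mature_end = res$start + .matureOffset + 21L,
                 mature_seq = fams[[freeMir$family[i]]],
                 te_embedded = FALSE, stringsAsFactors = FALSE)
    })
  }

  ## lncRNA loci and coding decoys
  lncRows <- NULL
  if (nrow(lnc)) {
    lncRows <- lapply(seq_len(nrow(lnc)), function(i) {
      seq <- makeLncrna(450L, if (lnc$has_site[i])
        fams[[lnc$site_family[i]]] else NULL)
      res <- place1(gaps, nchar(seq), 60L)
      if (is.null(res))
        stop("infeasible packing: cannot place lncRNAs on ", chrom)
      gaps <<- res$gaps
      addPart(res$start, seq)
      data.frame(lnc_id = lnc$id[i], chrom = chrom, start = res$start,
                 end = res$start + nchar(seq), strand = "+",
                 has_mirna_site = lnc$has_site[i],
                 site_family = if (lnc$has_site[i]) lnc$site_family[i]
                               else NA_character_,
                 stringsAsFactors = FALSE)
    })
  }
  decRows <- NULL
  if (nrow(dec)) {
    decRows <- lapply(seq_len(nrow(dec)), function(i) {
      seq <- switch(dec$removal[i],
        orf = paste0(makeCds(3L * 152L), randomDna(60L)),
        homology = makeLncrna(400L),
        length = randomDna(150L))
      res <- place1(gaps, nchar(seq), 60L)
      if (is.null(res))
        stop("infeasible packing: cannot place decoys on ", chrom)
      gaps <<- res$gaps
      addPart(res$start, seq)
      data.frame(decoy_id = dec$id[i], chrom = chrom, start = res$start,
                 end = res$start + nchar(seq), strand = "+",
                 removal = dec$removal[i], stringsAsFactors = FALSE)
    })
  }

  ## transposable elements: dedicated low-divergence CACTA hosts for the
  ## TE-embedded hairpins first, then weighted filling to the budget
  embMir <- mir[mir$te_embedded, , drop = FALSE]
  teRows <- list(); teBases <- 0L; teIdx <- 0L
  subW <- weights
  if ("Wanderer" %in% names(subW))
    subW["Wanderer"] <- subW["Wanderer"] * .wandererTilt[[sub]]
  addTe <- function(fam, seq, start, rate) {
    teIdx <<- teIdx + 1L
    teRows[[length(teRows) + 1L]] <<- data.frame(
      te_id = sprintf("te_%s_%04d", chrom, teIdx), chrom = chrom,
      start = start, end = start + nchar(seq), family = fam,
      superfamily = libInfo[fam, "superfamily"],
      class = libInfo[fam, "class"], strand = "+",
      mutation_rate = rate, stringsAsFactors = FALSE)
    teBases <<- teBases + nchar(seq)
  }
  embRows <- NULL
  if (teBudget > 0L && nrow(embMir)) {
    embRows <- lapply(seq_len(nrow(embMir)), function(i) {
      res <- place1(gaps, libInfo["Jorge", "len"], 20L)
      if (is.null(res))
        stop("infeasible packing: cannot place host repeats on ", chrom)
      gaps <<- res$gaps
      host <- mutateDna(libSeq[["Jorge"]], 0.01)
      hp <- makeHairpin(fams[[embMir$family[i]]])
      substr(host, 301L, 300L + nchar(hp)) <- hp
      addPart(res$start, host)
      addTe("Jorge", host, res$start, 0.01)
      data.frame(mirna_id = embMir$id[i], family = embMir$family[i],
                 chrom = chrom, start = res$start + 300L,
                 end = res$start + 300L + nchar(hp), strand = "+",
                 mature_start = res$start + 300L + .matureOffset,
                 mature_end = res$start + 300L + .matureOffset + 21L,
                 mature_seq = fams[[embMir$family[i]]],
                 te_embedded = TRUE, stringsAsFactors = FALSE)
    })
  }
  while (teBases < teBudget - 200L) {
    fam <- sample(names(subW), 1L, prob = subW)
    elen <- libInfo[fam, "len"]
    len <- if (runif(1) < 0.2)
      max(150L, as.integer(floor(elen * runif(1, 0.4, 1)))) else elen
    ## never overshoot the budget by more than a truncation floor
    len <- min(len, max(150L, teBudget - teBases))
    res <- place1(gaps, len, 20L)
    if (is.null(res)) {               # fall back to the shortest element
      fam <- "Aladin"; len <- min(libInfo["Aladin", "len"],
                                  teBudget - teBases)
      if (len < 60L) break
      res <- place1(gaps, len, 20L)
      if (is.null(res)) break
    }
    gaps <- res$gaps
    rate <- runif(1, 0.01, 0.05)
    seq <- mutateDna(substr(libSeq[[fam]], 1L, len), rate)
    addPart(res$start, seq)
    addTe(fam, seq, res$start, rate)
  }
  if (teBases < teBudget - 0.015 * L)
    stop("infeasible packing: chromosome ", chrom, " cannot reach the ",
         "requested repeat fraction (placed ", teBases, " of ", teBudget,
         " TE bases)")

  ## realise the sequence
  seq <- randomDna(L)
  if (length(parts)) {
    starts <- vapply(parts, `[[`, numeric(1L), "start")
    pieces <- vapply(parts, `[[`, character(1L), "seq")
    x <- Biostrings::replaceAt(Biostrings::DNAString(seq),
                               ir0(starts, starts + nchar(pieces)),
                               Biostrings::DNAStringSet(pieces))
    seq <- as.character(x)
  }

  emptyDf <- function(x) if (is.null(x)) NULL else do.call(rbind, x)
  list(seq = seq,
       tes = if (length(teRows)) do.call(rbind, teRows) else
         data.frame(te_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    family = character(0), superfamily = character(0),
                    class = character(0), strand = character(0),
                    mutation_rate = numeric(0), stringsAsFactors = FALSE),
       genes = emptyDf(lapply(geneRows, `[[`, "gene")),
       exons = emptyDf(lapply(geneRows, `[[`, "exons")),
       mirnas = rbind(emptyDf(mirRows), emptyDf(embRows)),
       lncrnas = emptyDf(lncRows),
       decoys = emptyDf(decRows),
       ssrs = emptyDf(ssrRows))
}

#' Fragment chromosomes into draft scaffolds with known placements
#'
#' Cuts each chromosome into consecutive fragments whose lengths are drawn
#' uniformly from \code{[0.5, 1.5] * n50Target} (so the realised N50 falls
#' within 20\% of the target), optionally applies per-base substitution
#' errors, and returns the exact source intervals as true placements.
#'
#' @param chromosomes [Biostrings::DNAStringSet].
#' @param n50Target target scaffold N50, bases; must be positive and smaller
#'   than every chromosome.
#' @param errorRate per-base substitution probability.
#' @param seed integer seed.
#' @return list with `scaffolds` (DNAStringSet) and `placements`
#'   (data.frame: `query_id`, `chrom`, `start`, `end` 0-based half-open,
#'   `strand`, `score`).
#' @export
fragmentIntoScaffolds <- function(chromosomes, n50Target, errorRate = 0,
                                  seed = 1L) {
  if (n50Target <= 0) stop("n50Target must be > 0")
  if (any(Biostrings::width(chromosomes) <= n50Target))
    stop("n50Target must be smaller than every chromosome length")
  withSeed(subSeed(seed, 7919L), {
    lo <- max(1L, as.integer(round(0.5 * n50Target)))
    hi <- as.integer(round(1.5 * n50Target))
    rows <- list(); seqs <- list(); idx <- 0L
    for (chrom in names(chromosomes)) {
      cs <- as.character(chromosomes[[chrom]])
      Lc <- nchar(cs); pos <- 0L
      while (pos < Lc) {
        len <- min(sample(lo:hi, 1L), Lc - pos)
        idx <- idx + 1L
        frag <- substr(cs, pos + 1L, pos + len)
        if (errorRate > 0) frag <- mutateDna(frag, errorRate)
        seqs[[idx]] <- frag
        rows[[idx]] <- data.frame(query_id = sprintf("scf_%06d", idx),
                                  chrom = chrom, start = pos,
                                  end = pos + len, strand = "+",
                                  score = 100, stringsAsFactors = FALSE)
        pos <- pos + len
      }
    }
    placements <- do.call(rbind, rows)
    scaffolds <- Biostrings::DNAStringSet(setNames(unlist(seqs),
                                                   placements$query_id))
    list(scaffolds = scaffolds, placements = placements)
  })
}
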