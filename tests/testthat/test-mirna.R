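test_that("a planted miR437 mature is recovered on the planted strand", {
  mat <- c(`tdi-miR437` = "AAAGUUAGAGAAGUUUGACUU")
  set.seed(41)
  bg <- rndDna(2000L)
  substr(bg, 501L, 521L) <- chartr("U", "T", mat[[1L]])
  cand <- scanHomology(Biostrings::DNAStringSet(c(`1A` = bg)), mat)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$strand, "+")
  expect_identical(cand$mature_start, 500L)
  expect_identical(cand$mismatches, 0L)
  expect_identical(cand$precursor_start, 300L)
  expect_identical(cand$precursor_end, 721L)
})

test_that("windows beyond the mismatch budget are not reported", {
  mat <- c(fam = "AAAGUUAGAGAAGUUUGACUU")
  m3 <- chartr("U", "T", mat[[1L]])
  substr(m3, 1, 1) <- "C"; substr(m3, 5, 5) <- "C"; substr(m3, 9, 9) <- "C"
  set.seed(42)
  bg <- rndDna(1000L)
  substr(bg, 101L, 121L) <- m3
  cand <- scanHomology(Biostrings::DNAStringSet(c(`1A` = bg)), mat,
                       maxMismatches = 2L)
  expect_false(any(cand$mature_start == 100L))
  cand3 <- scanHomology(Biostrings::DNAStringSet(c(`1A` = bg)), mat,
                        maxMismatches = 3L)
  expect_true(any(cand3$mature_start == 100L))
})

test_that("random plantings on both strands are all recovered at oracle positions", {
  set.seed(43)
  matures <- mirnaFamilies()
  bg <- rndDna(30000L)
  truth <- list()
  pos <- 100L
  for (i in 1:40) {
    fam <- sample(names(matures), 1L)
    strand <- sample(c("+", "-"), 1L)
    seqDna <- chartr("U", "T", matures[[fam]])
    if (strand == "-") seqDna <- emmerSurvey:::revcomp(seqDna)
    nmm <- sample(0:2, 1L)
    if (nmm > 0L) {
      at <- sample(21L, nmm)
      ch <- strsplit(seqDna, "")[[1L]]
      for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
      seqDna <- paste(ch, collapse = "")
    }
    substr(bg, pos + 1L, pos + 21L) <- seqDna
    truth[[i]] <- data.frame(fam = fam, start = pos, strand = strand,
                             stringsAsFactors = FALSE)
    pos <- pos + sample(500:700, 1L)
  }
  truth <- do.call(rbind, truth)
  seqs <- Biostrings::DNAStringSet(c(chr = bg))
  cand <- scanHomology(seqs, matures, deduplicate = FALSE)
  ## 100% recall of the planted matures
  for (i in seq_len(nrow(truth))) {
    hit <- cand$family == truth$fam[i] & cand$mature_start == truth$start[i]
    expect_true(any(hit), info = paste("planting", i))
  }
  ## positions equal the brute-force Hamming oracle per family
  for (fam in names(matures)) {
    want <- oracleHammingScan(chartr("U", "T", matures[[fam]]), bg, 2L)
    got <- cand[cand$family == fam, , drop = FALSE]
    expect_identical(sort(paste(got$mature_start, got$strand)),
                     sort(paste(want$start, want$strand)), info = fam)
  }
})

test_that("a perfect inverted repeat passes hairpin evaluation", {
  set.seed(44)
  arm <- paste0(rndDna(10L), "ATGGCCTAGCTAGGCATTACG", rndDna(19L))
  hp <- paste0(arm, "CAACAA", emmerSurvey:::revcomp(arm))
  ev <- evaluateHairpin(hp, matureOffset = 10L, matureLength = 21L)
  expect_true(ev$pass)
  expect_identical(ev$mature_paired_fraction, 1)
  expect_false(ev$spans_loop)
  expect_gte(ev$stem_pairs, 18L)
})

test_that("a homopolymer precursor has zero pairing and fails", {
  ev <- evaluateHairpin(strrep("A", 80L), 10L, 21L)
  expect_identical(ev$pairing_score, 0L)
  expect_false(ev$pass)
})

test_that("the Nussinov DP equals recursive and exhaustive oracles", {
  set.seed(45)
  ## exhaustive enumeration on very short sequences
  for (i in 1:15) {
    s <- rndDna(sample(8:13, 1L))
    expect_identical(emmerSurvey:::.nussinov(s, 3L)$max_pairs,
                     oracleEnumeratePairing(s), info = s)
  }
  ## memoised recursion up to 40 nt
  for (i in 1:25) {
    s <- rndDna(sample(15:40, 1L))
    expect_identical(emmerSurvey:::.nussinov(s, 3L)$max_pairs,
                     oracleMaxPairing(s), info = s)
  }
  ## traceback pair list is consistent: non-crossing, pairable, count match
  s <- rndDna(40L)
  res <- emmerSurvey:::.nussinov(s, 3L)
  p <- res$pairs
  expect_identical(nrow(p), res$max_pairs)
  expect_true(all(p[, 2L] - p[, 1L] > 3L))
  ch <- strsplit(s, "")[[1L]]
  ok <- paste0(ch[p[, 1L] + 1L], ch[p[, 2L] + 1L]) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG")
  expect_true(all(ok))
  expect_false(anyDuplicated(as.vector(p)) > 0)
})

test_that("TE-overlap confidence uses a strict 50% boundary", {
  expect_identical(classifyConfidence(c(0, 0.5, 0.500001, 0.6, 1)),
                   c("HC", "HC", "LC", "LC", "LC"))
  expect_error(classifyConfidence(1.2))
})

test_that("genomic context labels follow exon > intron > intergenic", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("1A", "1A"),
                      start = c(100L, 1000L), end = c(500L, 1400L),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g1", "g2"),
                      start = c(100L, 400L, 1000L),
                      end = c(200L, 500L, 1400L), stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "1A", start = c(150L, 250L, 700L),
                     end = c(171L, 271L, 721L), stringsAsFactors = FALSE)
  ctx <- classifyGenomicContext(loci, genes, exons)
  expect_identical(ctx$context, c("exon", "intron", "intergenic"))
  expect_equal(sum(ctx$tally$percent), 100)
  expect_error(classifyGenomicContext(
    loci, genes, data.frame(gene_id = "g1", start = 0L, end = 600L)),
    "malformed gene model")
})

test_that("random loci match an interval-containment oracle and sum to 100%", {
  set.seed(46)
  genes <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "1A",
                      start = seq(0L, 4000L, by = 1000L),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 600L
  exons <- do.call(rbind, lapply(seq_len(5), function(i)
    data.frame(gene_id = genes$gene_id[i],
               start = genes$start[i] + c(0L, 400L),
               end = genes$start[i] + c(200L, 600L),
               stringsAsFactors = FALSE)))
  loci <- data.frame(chrom = "1A",
                     start = sample(0L:5000L, 50L, replace = TRUE),
                     stringsAsFactors = FALSE)
  loci$end <- loci$start + 21L
  ctx <- classifyGenomicContext(loci, genes, exons)
  want <- vapply(seq_len(50L), function(i) {
    s <- loci$start[i]; e <- loci$end[i]
    inExon <- any(exons$start < e & exons$end > s)
    inGene <- any(genes$start < e & genes$end > s)
    if (inExon) "exon" else if (inGene) "intron" else "intergenic"
  }, character(1L))
  expect_identical(ctx$context, want)
  expect_equal(sum(ctx$tally$percent), 100)
})

test_that("target scoring reproduces the documented penalty scheme", {
  mat <- "AAAGUUAGAGAAGUUUGACUU"
  rcDna <- emmerSurvey:::revcomp(chartr("U", "T", mat))
  perfect <- paste0("GGG", rcDna, "CCC")
  hit <- scoreTarget(mat, perfect)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$penalty, 0)
  expect_identical(hit$target_start, 3L)

  ## single G:U at mature position 15 -> 0.5 (outside the doubled seed)
  ## mature pos 15 is U; pairs transcript G instead of A
  ch <- strsplit(rcDna, "")[[1L]]
  p <- 21L - 15L + 1L                    # transcript window position
  expect_identical(ch[p], "A")
  ch[p] <- "G"
  t2 <- paste(ch, collapse = "")
  expect_identical(scoreTarget(mat, t2)$penalty, 0.5)

  ## single mismatch at mature position 5 -> 2.0 (seed doubling)
  ch <- strsplit(rcDna, "")[[1L]]
  p5 <- 21L - 5L + 1L
  ch[p5] <- setdiff(c("A", "C"), ch[p5])[1L]
  t3 <- paste(ch, collapse = "")
  s3 <- scoreTarget(mat, t3)
  expect_identical(s3$penalty, 2)
})

test_that("family core sets follow set intersection", {
  expect_identical(familyCoreSet(list(A = c("m1", "m2"), B = "m2"))$core,
                   "m2")
  same <- familyCoreSet(list(A = c("m1", "m2"), B = c("m1", "m2")))
  expect_identical(same$core, c("m1", "m2"))
  set.seed(47)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j)
      sample(sprintf("f%02d", 1:12), sample(3:10, 1L)))
    names(sets) <- c("g1", "g2", "g3")
    got <- familyCoreSet(sets)
    expect_identical(got$core,
                     sort(intersect(intersect(sets$g1, sets$g2), sets$g3)))
    expect_lte(length(got$core), min(lengths(lapply(sets, unique))))
  }
  expect_error(familyCoreSet(list(A = "x")), "at least 2")
})

test_that("expression evidence distinguishes sRNA and pre-miRNA support", {
  mats <- c(famA = "AAAGUUAGAGAAGUUUGACUU", famB = "ACGUACGUACGUACGUACGUA")
  reads <- Biostrings::DNAStringSet(c(r1 = chartr("U", "T", mats[["famA"]]),
                                      r2 = strrep("G", 21L)))
  pre <- data.frame(family = "famB", seq = strrep("ACGT", 30L),
                    stringsAsFactors = FALSE)
  tx <- Biostrings::DNAStringSet(c(t1 = paste0("AAA", strrep("ACGT", 30L),
                                               "TTT")))
  ev <- expressionEvidence(mats, pre, reads, tx)
  expect_identical(ev$srna_supported, c(TRUE, FALSE))
  expect_identical(ev$premirna_supported, c(FALSE, TRUE))
  ## no reads, no transcripts -> nothing supported
  ev0 <- expressionEvidence(mats, pre[0, ], Biostrings::DNAStringSet(),
                            Biostrings::DNAStringSet())
  expect_false(any(ev0$supported))
})

test_that("planted reads for half the families give exactly half support", {
  g <- smallGenome()
  sr <- simulateSmallRnaReads(g$manifest, supportedFraction = 0.5,
                              seed = 13L)
  mats <- matureCatalogue(g$manifest)
  ev <- expressionEvidence(mats, data.frame(family = character(0),
                                            seq = character(0)),
                           sr$reads, Biostrings::DNAStringSet())
  expect_equal(sum(ev$supported), round(0.5 * length(mats)))
  expect_identical(sort(ev$family[ev$supported]),
                   sort(sr$supportedFamilies))
})

test_that("strand symmetry: a reverse-complemented genome mirrors candidates", {
  set.seed(48)
  matures <- mirnaFamilies()[1:3]
  bg <- rndDna(5000L)
  substr(bg, 1001L, 1021L) <- chartr("U", "T", matures[[1L]])
  substr(bg, 3001L, 3021L) <-
    emmerSurvey:::revcomp(chartr("U", "T", matures[[2L]]))
  fwd <- scanHomology(Biostrings::DNAStringSet(c(chr = bg)), matures,
                      deduplicate = FALSE)
  rcg <- emmerSurvey:::revcomp(bg)
  rev <- scanHomology(Biostrings::DNAStringSet(c(chr = rcg)), matures,
                      deduplicate = FALSE)
  L <- nchar(bg)
  mirrored <- data.frame(family = rev$family,
                         mature_start = L - rev$mature_end,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         stringsAsFactors = FALSE)
  expect_identical(
    sort(paste(fwd$family, fwd$mature_start, fwd$strand)),
    sort(paste(mirrored$family, mirrored$mature_start, mirrored$strand)))
})
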