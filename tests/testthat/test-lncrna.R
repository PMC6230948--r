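txSet <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("the 200-nt length filter is strict", {
  set.seed(51)
  tx <- txSet(c(a = rndDna(200L), b = rndDna(201L)))
  r <- filterByLength(tx)
  expect_identical(r$survivors, "b")
  expect_identical(r$trace$outcome, c("removed", "kept"))
  empty <- filterByLength(txSet(character(0)))
  expect_identical(length(empty$survivors), 0L)
  ## predicate oracle on random lengths
  lens <- sample(150:260, 1000L, replace = TRUE)
  tx2 <- txSet(setNames(strrep("A", lens), sprintf("t%04d", seq_len(1000L))))
  expect_identical(filterByLength(tx2)$survivors,
                   sprintf("t%04d", seq_len(1000L))[lens > 200L])
})

test_that("the 100-aa ORF filter is strict and six-frame", {
  orfTx <- function(naa) paste0("CC", "ATG", strrep("GCA", naa - 1L),
                                "TAA", "GG")
  ## ATG at offset 2; peptide = 1 (M) + (naa-1) = naa
  tx <- txSet(c(over = orfTx(101L), atLimit = orfTx(100L)))
  r <- filterByOrf(tx)
  expect_identical(r$survivors, "atLimit")
  expect_identical(unname(r$longest_orf), c(101L, 100L))
  ## ORF on the reverse strand is seen too
  rcTx <- txSet(c(rc = emmerSurvey:::revcomp(orfTx(120L))))
  expect_identical(length(filterByOrf(rcTx)$survivors), 0L)
  ## a stop-free frame contributes no ORF
  noStop <- txSet(c(open = paste0("ATG", strrep("GCT", 150L))))
  expect_identical(filterByOrf(noStop)$survivors, "open")
})

test_that("ORF decisions equal a six-frame brute-force oracle", {
  set.seed(52)
  for (i in 1:60) {
    s <- rndDna(sample(150:450, 1L))
    expect_identical(longestOrfLength(s), oracleLongestOrf(s), info = s)
  }
})

test_that("homology screens remove on any passing hit, independent of order", {
  ids <- c("t1", "t2", "t3", "t4")
  hits <- data.frame(
    query_id = c("t1", "t2", "t3"),
    screen = c("blastx_protein", "blastx_protein", "unigene_est"),
    evalue = c(1e-6, 1e-6, 1e-40),
    length = c(40, 25, 120),
    ppos = c(85, 85, NA),
    pident = c(70, 70, 85), stringsAsFactors = FALSE)
  r <- filterByHomology(ids, hits)
  ## t1 removed (passes blastx screen); t2 kept (length 25 < 30);
  ## t3 removed (unigene screen); t4 kept (no hit)
  expect_identical(r$survivors, c("t2", "t4"))
  ## screen order invariance
  r2 <- filterByHomology(ids, hits[c(3, 1, 2), ])
  expect_identical(sort(r2$survivors), sort(r$survivors))
  expect_error(filterByHomology(ids, transform(hits, screen = "mystery")),
               "unknown homology screen")
  ## external coding labels act as an additional removal screen
  r3 <- filterByHomology(ids, hits[0, ], codingLabels = "t4")
  expect_identical(r3$survivors, c("t1", "t2", "t3"))
})

test_that("homology decisions equal a per-screen predicate oracle", {
  set.seed(53)
  screens <- lncrnaScreens()
  ids <- sprintf("t%03d", 1:200)
  hits <- data.frame(
    query_id = sample(ids, 400L, replace = TRUE),
    screen = sample(names(screens), 400L, replace = TRUE),
    evalue = 10^runif(400L, -45, 0),
    length = sample(10:150, 400L, replace = TRUE),
    ppos = runif(400L, 50, 100), pident = runif(400L, 50, 100),
    stringsAsFactors = FALSE)
  got <- filterByHomology(ids, hits)$survivors
  pass <- vapply(seq_len(400L), function(r) {
    p <- screens[[hits$screen[r]]]
    ok <- hits$evalue[r] <= p$max_evalue & hits$length[r] >= p$min_length
    if (!is.null(p$min_ppos)) ok <- ok && hits$ppos[r] >= p$min_ppos
    if (!is.null(p$min_pident)) ok <- ok && hits$pident[r] >= p$min_pident
    ok
  }, logical(1L))
  expect_identical(got, setdiff(ids, unique(hits$query_id[pass])))
})

test_that("mapping acceptance requires full coverage and score >= 40", {
  rec <- data.frame(
    transcript_id = c("a", "b", "c", "d"), genome = "g1",
    coverage = c(1.0, 0.99, 1.0, 1.0), score = c(40, 90, 39.9, 55),
    splice_signals = "GT-AG", stringsAsFactors = FALSE)
  r <- acceptByMapping(c("a", "b", "c", "d"), rec)
  expect_identical(sort(r$acceptedPerGenome$g1), c("a", "d"))
  ## predicate oracle on random records
  set.seed(54)
  rec2 <- data.frame(
    transcript_id = sprintf("t%03d", 1:300), genome = "g1",
    coverage = sample(c(1, 0.97, 0.99), 300L, replace = TRUE),
    score = runif(300L, 20, 70), splice_signals = "GT-AG",
    stringsAsFactors = FALSE)
  got <- acceptByMapping(rec2$transcript_id, rec2)$acceptedPerGenome$g1
  expect_identical(sort(got),
                   sort(rec2$transcript_id[rec2$coverage == 1 &
                                             rec2$score >= 40]))
})

test_that("the splice sanity check discards antisense coding transcripts only", {
  fwdOrf <- paste0("CC", "ATG", strrep("GCA", 150L), "TAA", "GG")
  coding <- emmerSurvey:::revcomp(fwdOrf)   # codes on the reverse strand
  set.seed(55)
  noOrf <- rndDna(300L)
  while (longestOrfLength(noOrf) > 100L) noOrf <- rndDna(300L)
  tx <- txSet(c(canon = noOrf, anti = coding, antiNoOrf = noOrf))
  rec <- data.frame(
    transcript_id = c("canon", "anti", "antiNoOrf"), genome = "g1",
    coverage = 1, score = 50,
    splice_signals = c("GT-AG", "CT-AC", "CT-AC"),
    stringsAsFactors = FALSE)
  r <- spliceSanityCheck(c("canon", "anti", "antiNoOrf"), rec, tx)
  expect_identical(sort(r$survivors), c("antiNoOrf", "canon"))
  ## mixed signals (not cleanly reverse-canonical) are kept
  recMixed <- transform(rec, splice_signals = c("GT-AG", "CT-AC,GC-AG",
                                                "GT-AG"))
  expect_identical(length(spliceSanityCheck("anti", recMixed,
                                            tx)$survivors), 1L)
})

test_that("core-set intersection equals the set oracle", {
  expect_identical(intersectCoreSet(list(a = c("x", "y"), b = "y",
                                         c = c("y", "z"))), "y")
  expect_identical(intersectCoreSet(list(a = "x", b = "x")), "x")
  set.seed(56)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(5:15, 1L)))
    names(sets) <- c("g1", "g2", "g3")
    core <- intersectCoreSet(sets)
    expect_identical(core,
                     sort(intersect(intersect(sets$g1, sets$g2), sets$g3)))
    expect_lte(length(core), min(lengths(sets)))
  }
  expect_error(intersectCoreSet(list(a = "x")), "at least 2")
})

test_that("the cascade is monotone with a complete, single-removal trace", {
  g <- smallGenome()
  tx <- plantedTranscripts(g$chromosomes, g$manifest)
  casc <- runLncrnaCascade(tx, simulateLncrnaHits(g$manifest),
                           simulateMappingRecords(g$manifest, seed = 2L))
  trace <- casc$trace
  stages <- c("length", "orf", "homology", "mapping", "splice", "core")
  ## survivors shrink monotonically through the canonical stage order
  surv <- vapply(stages, function(st)
    sum(trace$stage == st & trace$outcome == "kept"), integer(1L))
  expect_true(all(diff(surv) <= 0))
  ## every transcript has exactly one removing stage or none
  perTx <- table(trace$transcript_id[trace$outcome == "removed"])
  expect_true(all(perTx == 1L))
  expect_identical(sum(trace$outcome == "removed") +
                     length(casc$survivors), length(tx))
  ## stages appear in canonical order in the trace
  expect_identical(unique(trace$stage), stages)
})

test_that("planted decoys are removed and planted lncRNAs reach the core", {
  g <- smallGenome()
  man <- g$manifest
  tx <- plantedTranscripts(g$chromosomes, man)
  casc <- runLncrnaCascade(tx, simulateLncrnaHits(man),
                           simulateMappingRecords(man, seed = 2L))
  lnc <- plantedFeatures(man, "lncrnas")
  dec <- plantedFeatures(man, "decoys")
  expect_identical(sort(casc$survivors), sort(lnc$lnc_id))
  expect_true(all(!dec$decoy_id %in% casc$survivors))
  ## decoys are removed by the stage they were planted to trigger
  st <- casc$finalStatus
  got <- setNames(st$removing_stage, st$transcript_id)[dec$decoy_id]
  expect_identical(unname(got), dec$removal)
})

test_that("planted miRNA-complementary sites are fully recovered", {
  g <- smallGenome()
  man <- g$manifest
  tx <- plantedTranscripts(g$chromosomes, man)
  lnc <- plantedFeatures(man, "lncrnas")
  pairs <- pairWithMirna(tx[lnc$lnc_id], matureCatalogue(man))
  withSite <- lnc[lnc$has_mirna_site, , drop = FALSE]
  for (i in seq_len(nrow(withSite))) {
    hit <- pairs$lnc_id == withSite$lnc_id[i] &
      pairs$family == withSite$site_family[i] & pairs$penalty == 0
    expect_true(any(hit), info = withSite$lnc_id[i])
  }
  ## a transcript with no complementary window yields no pair
  set.seed(57)
  noSite <- txSet(c(x = strrep("A", 400L)))
  expect_identical(nrow(pairWithMirna(noSite,
                                      c(f = "AAAAAAAAAAAAAAAAAAAAA"),
                                      cutoff = 3)), 0L)
})
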