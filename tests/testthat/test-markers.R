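## SSR-free spacer of length n (rejection-sampled against the oracle)
neutral <- function(n) {
  repeat {
    x <- rndDna(n)
    if (nrow(oracleSsr(x)) == 0L) return(x)
  }
}

## guard bases stop a planted run from extending into the flanks
plantRun <- function(motif, count) {
  g1 <- setdiff(c("A", "C", "G", "T"),
                substr(motif, nchar(motif), nchar(motif)))[1L]
  g2 <- setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1L]
  paste0(g1, strrep(motif, count), g2)
}

test_that("SSR detection applies MISA thresholds with exact boundaries", {
  set.seed(60)
  P1 <- neutral(30L); P2 <- neutral(30L)
  pad <- function(motif, count) paste0(P1, plantRun(motif, count), P2)
  d <- findSsrs(pad("AC", 6L))
  expect_identical(nrow(d), 1L)
  expect_identical(d$motif, "AC")
  expect_identical(d$repeat_count, 6L)
  expect_identical(d$start, 31L)
  expect_identical(d$end, 43L)
  expect_identical(d$type, "di")
  ## AC x 5 is below threshold
  expect_identical(nrow(findSsrs(pad("AC", 5L))), 0L)
  ## mono threshold 10
  expect_identical(findSsrs(pad("A", 10L))$type, "mono")
  expect_identical(nrow(findSsrs(pad("A", 9L))), 0L)
  ## perfect-repeat invariant: count x motif length = interval length
  for (m in c("A", "AG", "AAC", "AGAT", "AACGT", "AACGTC")) {
    d <- findSsrs(pad(m, 12L))
    simple <- d[d$type != "compound", , drop = FALSE]
    expect_true(all(simple$repeat_count * nchar(simple$motif) ==
                      simple$end - simple$start))
  }
})

test_that("motifs are canonical rotations and non-primitive motifs collapse", {
  set.seed(63)
  P1 <- neutral(20L); P2 <- neutral(20L)
  ## run starting mid-unit reports the minimal rotation
  d <- findSsrs(paste0(P1, "C", "GA", strrep("AG", 6L), "C", P2))
  expect_true(all(d$motif == "AG"))
  ## an (ACAC) tetra run is a di run, not tetra
  d2 <- findSsrs(paste0(P1, plantRun("AC", 10L), P2))
  expect_identical(d2$type, "di")
  expect_identical(d2$repeat_count, 10L)
})

test_that("nearby SSRs merge into a compound locus, distant ones stay separate", {
  set.seed(64)
  P1 <- neutral(20L); P2 <- neutral(20L)
  near <- paste0(P1, plantRun("AT", 7L), neutral(50L),
                 plantRun("AAG", 6L), P2)
  d <- findSsrs(near)
  expect_identical(d$type, "compound")
  expect_identical(d$motif, "AT/AAG")
  far <- paste0(P1, plantRun("AT", 7L), neutral(120L),
                plantRun("AAG", 6L), P2)
  d2 <- findSsrs(far)
  expect_identical(d2$type, c("di", "tri"))
})

test_that("SSR calls equal the exhaustive oracle on random sequences", {
  set.seed(61)
  motifs <- c("A", "C", "AC", "AG", "AAC", "AGG", "AGAT", "AACGT", "AACGTC")
  for (rep in 1:25) {
    ## random sequence with a few planted runs to make hits likely
    s <- rndDna(3000L)
    for (p in seq_len(sample(2:5, 1L))) {
      m <- sample(motifs, 1L)
      cnt <- sample(4:12, 1L)
      at <- sample(2500L, 1L)
      substr(s, at, at + nchar(m) * cnt - 1L) <- strrep(m, cnt)
    }
    got <- findSsrs(s)
    want <- oracleSsr(s)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(got$motif, want$motif)
      expect_identical(got$type, want$type)
    }
  }
})

test_that("planted SSRs are recovered exactly and sub-threshold repeats never", {
  g <- smallGenome()
  ssrs <- plantedFeatures(g$manifest, "ssrs")
  for (ch in names(g$chromosomes)) {
    found <- findSsrs(g$chromosomes[[ch]], contigId = ch)
    planted <- ssrs[ssrs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(planted))) {
      if (planted$above_threshold[i]) {
        hit <- found$start == planted$start[i] &
          found$end == planted$end[i] & found$motif == planted$motif[i]
        expect_true(any(hit), info = planted$ssr_id[i])
      } else {
        expect_false(any(found$start == planted$start[i] &
                           found$end == planted$end[i]),
                     info = planted$ssr_id[i])
      }
    }
  }
})

test_that("ISBP junctions sit at annotation state changes with flank control", {
  ann <- data.frame(chrom = "ctg", start = 0L, end = 500L, family = "Jorge",
                    stringsAsFactors = FALSE)
  j <- findIsbpJunctions(ann, c(ctg = 900L))
  expect_identical(nrow(j), 1L)            # start edge at 0 fails the flank
  expect_identical(j$position, 500L)
  expect_identical(j$left, "Jorge")
  expect_identical(j$right, "unique")
  ## fully unannotated contig: none
  expect_identical(nrow(findIsbpJunctions(ann[0, ], c(ctg = 900L))), 0L)
  ## junction 10 b from the contig end is suppressed
  ann2 <- data.frame(chrom = "ctg", start = 100L, end = 890L,
                     family = "Jorge", stringsAsFactors = FALSE)
  j2 <- findIsbpJunctions(ann2, c(ctg = 900L), minFlank = 30L)
  expect_identical(j2$position, 100L)
  ## adjacent different families: one family-family junction
  ann3 <- data.frame(chrom = "ctg", start = c(100L, 300L),
                     end = c(300L, 500L), family = c("Jorge", "Angela"),
                     stringsAsFactors = FALSE)
  j3 <- findIsbpJunctions(ann3, c(ctg = 900L))
  expect_identical(j3$position, c(100L, 300L, 500L))
  expect_identical(j3$left[2L], "Jorge")
  expect_identical(j3$right[2L], "Angela")
})

test_that("planted TE junctions are recovered exactly from truth annotations", {
  g <- smallGenome()
  man <- g$manifest
  tes <- plantedFeatures(man, "tes")
  lens <- chromosomeLengths(man)
  got <- findIsbpJunctions(tes, lens, minFlank = 30L)
  want <- plantedFeatures(man, "teJunctions")
  expect_identical(nrow(got), nrow(want))
  expect_identical(paste(got$contig_id, got$position),
                   paste(want$chrom, want$pos))
  expect_identical(got$left, want$left)
  expect_identical(got$right, want$right)
})

test_that("variant filtering is a predicate with conserved summary counts", {
  v <- data.frame(chrom = "1A", pos = 1:4, ref = c("A", "A", "AT", "G"),
                  alt = c("T", "C,G", "A", "GA"),
                  qual = c(50, 50, 50, 50), depth = c(5, 20, 20, 20),
                  stringsAsFactors = FALSE)
  r <- filterVariants(v, minDepth = 10, minQual = 30)
  expect_identical(nrow(r$survivors), 2L)   # depth 5 out, multiallelic out
  expect_identical(r$survivors$variant_type, c("InDel", "InDel"))
  expect_identical(r$summary$n_snp + r$summary$n_indel,
                   r$summary$n_surviving)
  expect_error(filterVariants(transform(v, ref = c("A", "", "AT", "G"))),
               "line 2")
  ## random records equal a predicate oracle
  set.seed(62)
  n <- 400L
  v2 <- data.frame(chrom = "1A", pos = seq_len(n),
                   ref = sample(c("A", "C", "ATT"), n, replace = TRUE),
                   alt = sample(c("G", "T", "G,T", "GAA"), n,
                                replace = TRUE),
                   qual = runif(n, 0, 60), depth = rpois(n, 12),
                   stringsAsFactors = FALSE)
  r2 <- filterVariants(v2, minDepth = 10, minQual = 30)
  want <- v2$depth >= 10 & v2$qual >= 30 & !grepl(",", v2$alt)
  expect_identical(nrow(r2$survivors), sum(want))
  wantSnp <- want & nchar(v2$ref) == 1L & nchar(v2$alt) == 1L
  expect_identical(r2$summary$n_snp, sum(wantSnp))
})

test_that("VCF records round-trip through the minimal reader", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1A\t101\t.\tA\tT\t45.0\tPASS\tDP=22",
               "1B\t202\t.\tAT\tA\t12.5\tPASS\tNS=3;DP=8",
               "2A\t303\t.\tG\tC\t50\tPASS\tNS=3"), path)
  v <- readVariants(path)
  expect_identical(v$pos, c(101L, 202L, 303L))
  expect_identical(v$depth, c(22, 8, NA))
  r <- filterVariants(v[!is.na(v$depth), ], minDepth = 10, minQual = 30)
  expect_identical(r$summary$n_surviving, 1L)
})
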