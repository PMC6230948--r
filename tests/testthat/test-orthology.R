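mkHit <- function(q, s, sspecies, ev, len, ppos = 80, pident = 70,
                  bs = 100, qspecies = "wheat") {
  data.frame(query_id = q, query_species = qspecies, subject_id = s,
             subject_species = sspecies, pident = pident, ppos = ppos,
             length = len, qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = ev, bit_score = bs, stringsAsFactors = FALSE)
}

test_that("hit filtering applies the published per-species profiles", {
  h <- rbind(mkHit("q1", "s1", "brachypodium", 1e-7, 35, ppos = 80),
             mkHit("q2", "s2", "brachypodium", 1e-5, 35, ppos = 80),
             mkHit("q3", "s3", "brachypodium", 1e-7, 29, ppos = 80),
             mkHit("q4", "s4", "brachypodium", 1e-7, 35, ppos = 74),
             mkHit("q5", "s5", "barley", 1e-7, 35, ppos = 89),
             mkHit("q6", "s6", "barley", 1e-7, 35, ppos = 90),
             mkHit("q7", "s7", "wheat_transcripts", 1e-31, 120,
                   pident = 99),
             mkHit("q8", "s8", "wheat_transcripts", 1e-31, 120,
                   pident = 98))
  kept <- filterHits(h)
  expect_identical(kept$query_id, c("q1", "q6", "q7"))
  expect_error(filterHits(mkHit("q", "s", "unknown_species", 1e-9, 50)),
               "no hit-filter profile")
})

test_that("hit filtering equals a predicate oracle on random hits", {
  set.seed(31)
  n <- 500L
  h <- mkHit(sprintf("q%03d", seq_len(n)), sprintf("s%03d", seq_len(n)),
             sample(c("brachypodium", "rice", "sorghum", "barley"), n,
                    replace = TRUE),
             ev = 10^runif(n, -12, 0), len = sample(10:60, n, TRUE),
             ppos = runif(n, 50, 100))
  prof <- hitFilterProfiles()
  want <- vapply(seq_len(n), function(i) {
    p <- prof[[h$subject_species[i]]]
    h$evalue[i] <= p$max_evalue && h$length[i] >= p$min_length &&
      h$ppos[i] >= p$min_ppos
  }, logical(1L))
  expect_identical(filterHits(h)$query_id, h$query_id[want])
})

test_that("best reciprocal hits follow the reciprocal-argmax definition", {
  ## A -> g1 (100), A -> g2 (90); g1 -> A (100), g1 -> B (80)
  h <- rbind(mkHit("A", "g1", "rice", 1e-50, 50, bs = 100,
                   qspecies = "wheat"),
             mkHit("A", "g2", "rice", 1e-40, 50, bs = 90,
                   qspecies = "wheat"),
             mkHit("g1", "A", "wheat", 1e-50, 50, bs = 100,
                   qspecies = "rice"),
             mkHit("g1", "B", "wheat", 1e-30, 50, bs = 80,
                   qspecies = "rice"))
  brh <- bestReciprocalHits(h, "wheat", "rice")
  expect_identical(brh$id_a, "A")
  expect_identical(brh$id_b, "g1")
  expect_identical(nrow(bestReciprocalHits(h[0, ], "wheat", "rice")), 0L)
})

test_that("BRH equals the brute-force oracle on random score matrices", {
  set.seed(32)
  for (rep in 1:50) {
    nA <- sample(3:12, 1L); nB <- sample(3:12, 1L)
    score <- matrix(0, nA, nB)
    filled <- runif(nA * nB) < 0.4
    score[filled] <- sample(10:60, sum(filled), replace = TRUE)
    rows <- list()
    for (i in seq_len(nA)) for (j in seq_len(nB)) {
      if (score[i, j] <= 0) next
      rows[[length(rows) + 1L]] <-
        rbind(mkHit(sprintf("a%02d", i), sprintf("b%02d", j), "rice",
                    1e-20, 50, bs = score[i, j], qspecies = "wheat"),
              mkHit(sprintf("b%02d", j), sprintf("a%02d", i), "wheat",
                    1e-20, 50, bs = score[i, j], qspecies = "rice"))
    }
    h <- do.call(rbind, rows)
    got <- bestReciprocalHits(h, "wheat", "rice")
    want <- oracleBrh(score)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      wantIds <- sort(sprintf("a%02d:b%02d", want[, 1L], want[, 2L]))
      expect_identical(sort(paste0(got$id_a, ":", got$id_b)), wantIds)
    }
    ## one-to-one per species pair
    expect_false(any(duplicated(got$id_a)) || any(duplicated(got$id_b)))
  }
})

test_that("Markov clustering recovers disconnected components exactly", {
  tri <- function(prefix) {
    v <- paste0(prefix, 1:3)
    data.frame(from = v[c(1, 2, 3)], to = v[c(2, 3, 1)], weight = 50,
               stringsAsFactors = FALSE)
  }
  cl <- markovCluster(rbind(tri("x"), tri("y")))
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[paste0("x", 1:3)])), 1L)
  expect_identical(length(unique(cl[paste0("y", 1:3)])), 1L)
  ## single node via clusterOrthogroups singleton handling
  og <- clusterOrthogroups(data.frame(id_a = character(0),
                                      id_b = character(0),
                                      evalue = numeric(0)),
                           singletons = "lonely")
  expect_identical(og$gene_id, "lonely")
  expect_identical(length(unique(og$group_id)), 1L)
})

test_that("a weakly-bridged barbell splits into two clusters", {
  clique <- function(prefix, w = 50) {
    v <- paste0(prefix, 1:4)
    do.call(rbind, lapply(seq_along(v), function(i)
      do.call(rbind, lapply(seq_len(i - 1L), function(j)
        data.frame(from = v[i], to = v[j], weight = w,
                   stringsAsFactors = FALSE)))))
  }
  edges <- rbind(clique("L"), clique("R"),
                 data.frame(from = "L1", to = "R1", weight = 0.01,
                            stringsAsFactors = FALSE))
  cl <- markovCluster(edges, inflation = 2)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[paste0("L", 1:4)])), 1L)
})

test_that("sparse Markov clustering matches the independent dense reference", {
  set.seed(33)
  for (rep in 1:20) {
    ## random barbell/mixture graphs
    nL <- sample(3:6, 1L); nR <- sample(3:6, 1L)
    nodes <- c(paste0("l", seq_len(nL)), paste0("r", seq_len(nR)))
    rows <- list()
    for (grp in list(seq_len(nL), nL + seq_len(nR))) {
      v <- nodes[grp]
      for (i in seq_along(v)) for (j in seq_len(i - 1L)) {
        if (runif(1) < 0.8)
          rows[[length(rows) + 1L]] <- data.frame(
            from = v[i], to = v[j], weight = runif(1, 20, 80),
            stringsAsFactors = FALSE)
      }
    }
    if (runif(1) < 0.7)
      rows[[length(rows) + 1L]] <- data.frame(
        from = "l1", to = "r1", weight = runif(1, 0.001, 0.1),
        stringsAsFactors = FALSE)
    edges <- do.call(rbind, rows)
    got <- markovCluster(edges, inflation = 2)
    want <- oracleMcl(sort(unique(c(edges$from, edges$to))), edges$from,
                      edges$to, edges$weight, inflation = 2)
    ## same partition (up to label renaming)
    got <- got[names(want)]
    expect_identical(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(x)
      length(unique(x))) == 1L))
  }
})

test_that("locus categories partition all groups with the exclusion rule", {
  gc <- list(g1 = "3A", g2 = c("2A", "2B"), g3 = c("4A", "5B"),
             g4 = c("1A", "1B", "2A", "2B"), g5 = c("1A", "1B"))
  calls <- classifyLoci(gc, c("1A", "1B", "2A", "2B", "3A", "4A", "5B"))
  expect_identical(setNames(calls$category, calls$group_id),
                   c(g1 = "single-chromosome", g2 = "homeologous-only",
                     g3 = "multi-chromosome", g4 = "multi-chromosome",
                     g5 = "homeologous-only"))
  expect_identical(calls$excluded, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(nrow(calls), length(gc))  # categories partition groups
  ## ubiquitous when the set covers every chromosome in the genome
  calls2 <- classifyLoci(list(g = c("1A", "1B", "2A", "2B")),
                         c("1A", "1B", "2A", "2B"))
  expect_identical(calls2$category, "ubiquitous")
  expect_error(classifyLoci(list(g = "chr7"), c("1A")), "unparseable")
})

test_that("the coverage estimator reproduces direct evaluation", {
  est <- estimateGeneContent(c(chr1 = 1.386e6), c(chr1 = 1e8))
  expect_equal(est$estimated_gene_count, 500)
  expect_equal(est$per_chromosome$conserved_fraction, 0.01386)
  zero <- estimateGeneContent(c(chr1 = 0), c(chr1 = 1e8))
  expect_identical(zero$estimated_gene_count, 0)
  expect_error(estimateGeneContent(c(chr1 = 10), c(chr1 = 100),
                                   meanCdsLength = 0), "> 0")
  loci <- estimateGeneContent(c(chr1 = 10), c(chr1 = 100),
                              method = "loci",
                              lociCounts = c(chr1 = 7))
  expect_identical(loci$estimated_gene_count, 7)
})

test_that("noiseless synthetic hits recover planted groups and homeologs exactly", {
  g <- smallGenome()
  man <- g$manifest
  hits <- simulateHomologyHits(man)
  profiles <- c(hitFilterProfiles(),
                list(wheat = list(max_evalue = 1e-6, min_length = 30,
                                  min_ppos = 75)))
  filtered <- filterHits(hits, profiles)
  grass <- c("brachypodium", "rice", "sorghum", "barley")
  brh <- do.call(rbind, lapply(combn(grass, 2, simplify = FALSE),
                               function(p) bestReciprocalHits(filtered,
                                                              p[1], p[2])))
  og <- clusterOrthogroups(brh)
  genes <- plantedFeatures(man, "genes")
  ## one group per planted homeolog group, containing its four orthologs
  expect_identical(length(unique(og$group_id)),
                   length(unique(genes$homeolog_group)))
  g2g <- setNames(og$group_id, og$gene_id)
  for (i in seq_len(nrow(genes))) {
    ids <- unlist(genes[i, c("ortholog_bd", "ortholog_os", "ortholog_sb",
                             "ortholog_hv")])
    expect_identical(length(unique(g2g[ids])), 1L)
  }
  ## homeolog classification: every non-translocated group is {nA, nB}
  wheatHits <- filtered[filtered$query_species == "wheat", ]
  ev <- data.frame(group = g2g[wheatHits$subject_id],
                   chrom = setNames(genes$chrom,
                                    genes$gene_id)[wheatHits$query_id])
  calls <- classifyLoci(lapply(split(ev$chrom, ev$group), unique),
                        names(chromosomeLengths(man)))
  tr <- translocationTruth(man)
  movedGenes <- genes$gene_id[genes$chrom == tr$acceptor &
                                startsWith(genes$gene_id,
                                           paste0("gene_", tr$donor))]
  movedGroups <- unique(g2g[genes$ortholog_bd[genes$gene_id %in%
                                                movedGenes]])
  expect_true(all(calls$category[!(calls$group_id %in% movedGroups)] ==
                    "homeologous-only"))
  if (length(movedGroups))
    expect_true(all(calls$category[calls$group_id %in% movedGroups] ==
                      "multi-chromosome"))
  ## gene-content estimate within 15% of planted truth
  qr <- data.frame(query_id = genes$gene_id, chrom = genes$chrom,
                   start = genes$start, end = genes$end,
                   stringsAsFactors = FALSE)
  est <- estimateGeneContent(conservedBases(wheatHits, qr),
                             chromosomeLengths(man))
  expect_lt(abs(est$estimated_gene_count - trueConservedGeneCount(man)) /
              trueConservedGeneCount(man), 0.15)
})

test_that("wheat-specific contigs are tallied with the 70% coverage flag", {
  wh <- rbind(mkHit("c1", "t1", "wheat_transcripts", 1e-40, 300),
              mkHit("c2", "t2", "wheat_transcripts", 1e-40, 100))
  wh$subject_length <- c(350, 500)
  wh$send <- c(300, 100)
  tall <- wheatSpecificTally(wh, grassMatched = "c2")
  expect_identical(tall$query_id, "c1")
  expect_true(tall$covers_target)        # 300/350 > 0.7
})
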