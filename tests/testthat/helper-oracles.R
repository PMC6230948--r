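## Independent brute-force oracles. Each one re-derives an expected result
## by the most literal method available (exhaustive loops, union-find,
## recursion), sharing no code path with the package implementation.

## N50: walk the descending lengths accumulating until half the total
oracleN50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= sum(lengths) / 2) return(x)
  }
}

## O(n^2) transitive chaining of placements via union-find: any two
## placements on the same chromosome with reference gap in [0, maxGap)
## belong to the same super-scaffold
oracleChain <- function(placements, maxGap) {
  n <- nrow(placements)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || placements$chrom[i] != placements$chrom[j]) next
    g <- placements$start[j] - placements$end[i]
    if (g >= 0 && g < maxGap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  split(placements$query_id, comp)
}

## brute-force best reciprocal hits from a dense score matrix
## (rows = species A genes, cols = species B genes; 0 = no hit)
oracleBrh <- function(score) {
  pairs <- list()
  for (i in seq_len(nrow(score))) {
    for (j in seq_len(ncol(score))) {
      if (score[i, j] <= 0) next
      ## j must be i's unique argmax and i must be j's unique argmax,
      ## with ties broken to the lexicographically smallest subject id
      topJ <- which(score[i, ] == max(score[i, ]))
      topI <- which(score[, j] == max(score[, j]))
      if (min(topJ) == j && min(topI) == i)
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  do.call(rbind, pairs)
}

## independent dense-matrix Markov clustering, mirroring the published
## scheme (expansion 2, inflation, pruning, self-loops = max incident
## weight, clusters = components of the converged non-zero structure)
oracleMcl <- function(nodes, edgeFrom, edgeTo, edgeWeight, inflation = 2,
                      pruning = 1e-6, maxIter = 100, tol = 1e-9) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_along(edgeFrom)) {
    M[edgeFrom[e], edgeTo[e]] <- max(M[edgeFrom[e], edgeTo[e]],
                                     edgeWeight[e])
    M[edgeTo[e], edgeFrom[e]] <- max(M[edgeTo[e], edgeFrom[e]],
                                     edgeWeight[e])
  }
  for (v in seq_len(n)) {
    mx <- max(M[, v])
    M[v, v] <- if (mx > 0) mx else 1
  }
  norm <- function(X) sweep(X, 2, pmax(colSums(X), .Machine$double.xmin),
                            "/")
  M <- norm(M)
  for (it in seq_len(maxIter)) {
    prev <- M
    M <- M %*% M
    M <- M^inflation
    M[M < pruning] <- 0
    M <- norm(M)
    if (max(abs(M - prev)) < tol) break
  }
  A <- (M + t(M)) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    q <- v
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      q <- c(q, which(A[u, ] & is.na(comp)))
    }
  }
  setNames(comp, nodes)
}

## sliding-window Hamming scan for a mature pattern, both strands
oracleHammingScan <- function(patternDna, subject, maxMismatch) {
  revc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
  sub <- strsplit(subject, "")[[1L]]
  hits <- list()
  for (strand in c("+", "-")) {
    p <- strsplit(if (strand == "+") patternDna else revc(patternDna),
                  "")[[1L]]
    k <- length(p)
    for (s in seq_len(length(sub) - k + 1L)) {
      mm <- sum(sub[s:(s + k - 1L)] != p)
      if (mm <= maxMismatch)
        hits[[length(hits) + 1L]] <- data.frame(
          start = s - 1L, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0),
                                       strand = character(0),
                                       mismatches = integer(0)))
  do.call(rbind, hits)
}

## memoised recursion for the maximum non-crossing pairing (min loop,
## Watson-Crick + G:U), independent of the iterative DP
oracleMaxPairing <- function(seq, minLoop = 3) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1L]]
  pairOk <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i <= minLoop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + minLoop + 1L):j) {
      if (pairOk(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) 0L else rec(1L, n)
}

## truly exhaustive enumeration of all non-crossing structures (tiny n):
## the available positions are kept as disjoint segments and pairs may only
## form within one segment, which a chosen pair splits in two
oracleEnumeratePairing <- function(seq, minLoop = 3) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1L]]
  pairOk <- function(a, b)
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  best <- 0L
  go <- function(segs, count) {
    best <<- max(best, count)
    segs <- segs[lengths(segs) > 0L]
    if (!length(segs)) return()
    seg <- segs[[1L]]
    rest <- segs[-1L]
    i <- seg[1L]
    go(c(list(seg[-1L]), rest), count)          # i unpaired
    for (k in seg[-1L]) {
      if (k - i > minLoop && pairOk(ch[i], ch[k])) {
        go(c(list(seg[seg > i & seg < k]), list(seg[seg > k]), rest),
           count + 1L)
      }
    }
  }
  go(list(seq_along(ch)), 0L)
  best
}

## brute-force six-frame longest complete ORF (aa, excluding stop)
oracleLongestOrf <- function(seq) {
  codonTable <- c(TAA = "*", TAG = "*", TGA = "*")
  revc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, "")[[1L]]),
                                   collapse = ""))
  best <- 0L
  for (s in c(seq, revc(seq))) {
    ch <- strsplit(s, "")[[1L]]
    n <- length(ch)
    for (frame in 0:2) {
      starts <- seq(frame + 1L, n - 2L, by = 3L)
      codons <- vapply(starts, function(p)
        paste(ch[p:(p + 2L)], collapse = ""), character(1L))
      i <- 1L
      while (i <= length(codons)) {
        if (codons[i] == "ATG") {
          stops <- which(codons %in% names(codonTable))
          stp <- stops[stops > i]
          if (length(stp)) {
            best <- max(best, stp[1L] - i)
            i <- i + 1L
          } else i <- i + 1L
        } else i <- i + 1L
      }
    }
  }
  best
}

## exhaustive SSR enumeration with the package's documented semantics:
## per motif length, leftmost maximal whole-unit runs meeting the unit
## threshold, primitive motifs only, containment suppression by longer
## motif, compound merge of loci closer than the interruption distance
oracleSsr <- function(seq, thresholds = c(`1` = 10, `2` = 6, `3` = 5,
                                          `4` = 5, `5` = 5, `6` = 5),
                      maxInterruption = 100) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  prim <- function(m) {
    k <- nchar(m)
    for (d in seq_len(k - 1L))
      if (k %% d == 0L &&
          paste(rep(substr(m, 1L, d), k / d), collapse = "") == m)
        return(FALSE)
    TRUE
  }
  minrot <- function(m) {
    k <- nchar(m)
    min(vapply(seq_len(k), function(i)
      paste0(substr(m, i, k), substr(m, 1L, i - 1L)), character(1L)))
  }
  cand <- list()
  for (k in 1:6) {
    thr <- thresholds[[as.character(k)]]
    i <- 1L
    while (i + k * thr - 1L <= n) {
      motif <- paste(ch[i:(i + k - 1L)], collapse = "")
      ## count whole-unit repeats starting at i
      u <- 1L
      while (i + (u + 1L) * k - 1L <= n &&
             paste(ch[(i + u * k):(i + (u + 1L) * k - 1L)],
                   collapse = "") == motif) u <- u + 1L
      if (u >= thr && prim(motif)) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + u * k, motif = minrot(motif),
          count = u, k = k, stringsAsFactors = FALSE)
        i <- i + u * k
      } else i <- i + 1L
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), count = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(d)), function(i)
    !any(d$k > d$k[i] & d$start <= d$start[i] & d$end >= d$end[i]),
    logical(1L))
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$start, -d$k), , drop = FALSE]
  typeNames <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  out <- list()
  i <- 1L
  while (i <= nrow(d)) {
    j <- i
    while (j < nrow(d) && d$start[j + 1L] - d$end[j] < maxInterruption)
      j <- j + 1L
    if (j == i)
      out[[length(out) + 1L]] <- data.frame(
        start = d$start[i], end = d$end[i], motif = d$motif[i],
        count = d$count[i], type = typeNames[d$k[i]],
        stringsAsFactors = FALSE)
    else
      out[[length(out) + 1L]] <- data.frame(
        start = d$start[i], end = d$end[j],
        motif = paste(d$motif[i:j], collapse = "/"),
        count = NA_integer_, type = "compound", stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

## random DNA string from the current RNG stream
rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
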