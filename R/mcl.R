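## Markov clustering on a weighted undirected graph (sparse matrices).

#' Markov clustering of a weighted graph
#'
#' Runs the expansion/inflation Markov-cluster process on the
#' column-normalised weighted adjacency matrix with self-loops. Expansion
#' power is 2; entries below the pruning threshold are dropped after every
#' inflation; iteration stops at convergence (`max |M - M_prev| < tol`) or
#' after `maxIter` rounds. Clusters are the connected components of the
#' non-zero structure of the converged matrix, so nodes in disconnected
#' components can never merge.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (non-negative;
#'   an asymmetric list is symmetrised by the maximum weight, with a
#'   message).
#' @param inflation inflation exponent.
#' @param pruning entries below this are zeroed after inflation.
#' @param maxIter iteration cap.
#' @param tol convergence threshold on `max |delta|`.
#' @param selfLoops self-loop weight scheme: each node receives a loop equal
#'   to its maximum incident edge weight (1 for isolated nodes).
#' @return named integer vector: cluster id per node.
#' @export
markovCluster <- function(edges, inflation = 2.0, pruning = 1e-6,
                          maxIter = 100L, tol = 1e-9, selfLoops = TRUE) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  if (n == 0L) return(setNames(integer(0), character(0)))
  i <- match(edges$from, nodes); j <- match(edges$to, nodes)
  w <- as.numeric(edges$weight)
  ## symmetrise by max weight over both directions
  ii <- c(i, j); jj <- c(j, i); ww <- c(w, w)
  key <- paste(ii, jj)
  mxw <- tapply(ww, key, max)
  if (any(mxw != tapply(ww, key, min)))
    message("markovCluster: asymmetric edge list symmetrised by max weight")
  ks <- strsplit(names(mxw), " ", fixed = TRUE)
  m <- Matrix::sparseMatrix(
    i = as.integer(vapply(ks, `[`, character(1L), 1L)),
    j = as.integer(vapply(ks, `[`, character(1L), 2L)),
    x = as.numeric(mxw), dims = c(n, n))
  m <- as(m, "CsparseMatrix")
  if (selfLoops) {
    loop <- apply(as.matrix(m), 2L, max)
    loop[loop == 0] <- 1
    Matrix::diag(m) <- loop
  }
  normalise <- function(x) {
    cs <- Matrix::colSums(x)
    cs[cs == 0] <- 1
    x %*% Matrix::Diagonal(n, 1 / cs)
  }
  m <- normalise(m)
  for (iter in seq_len(maxIter)) {
    prev <- m
    m <- m %*% m                       # expansion
    m@x <- m@x^inflation               # inflation
    m <- Matrix::drop0(m)
    m@x[m@x < pruning] <- 0
    m <- Matrix::drop0(m)
    m <- normalise(m)
    if (max(abs(m - prev)) < tol) break
  }
  ## clusters = connected components of the non-zero structure
  adj <- (m + Matrix::t(m)) > 0
  comp <- rep(NA_integer_, n); cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      nb <- which(adj[, u] | adj[u, ])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  setNames(comp, nodes)
}
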