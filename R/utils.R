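#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
#' @useDynLib emmerSurvey, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package route through this helper so that
#' a given seed yields byte-identical output without clobbering the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a stage-specific sub-seed; kept well below .Machine$integer.max
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset) %% 2147480000)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together contain at
#' least half of the total bases (equivalently, the smallest length whose
#' descending cumulative sum reaches 50% of the total). The returned value is
#' always a member of the input length multiset.
#'
#' @param lengths numeric vector of sequence lengths.
#' @return a single length (bases).
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50: empty length set")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

## width of the union of 0-based half-open intervals given as two vectors
unionWidth <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

## IRanges from 0-based half-open coordinates
ir0 <- function(start, end) IRanges::IRanges(as.integer(start) + 1L, as.integer(end))

## reverse complement of a plain character DNA string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## random DNA of length n from the current RNG stream
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## apply per-base substitutions at a given rate (current RNG stream)
mutateDna <- function(x, rate) {
  if (rate <= 0) return(x)
  n <- nchar(x)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(x)
  pos <- sample.int(n, k)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  ch[pos] <- vapply(ch[pos], function(b) sample(alt[[b]], 1L), character(1L))
  paste(ch, collapse = "")
}

## deterministic TSV writer (fixed eol, no quoting surprises)
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write genomic feature annotations as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 emission converts to
#' 1-based closed.
#'
#' @param features data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `type`, optionally `strand`, `id`, `attributes`.
#' @param path output path.
#' @param source source tag for column 2.
#' @return the path, invisibly.
#' @export
writeGff3 <- function(features, path, source = "emmerSurvey") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    strand <- if ("strand" %in% names(features)) features$strand else "+"
    attr <- if ("attributes" %in% names(features)) features$attributes
            else if ("id" %in% names(features)) paste0("ID=", features$id)
            else "."
    lines <- paste(features$chrom, source, features$type,
                   features$start + 1L, features$end, ".", strand, ".",
                   attr, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

## parse chromosome names like "3A" -> list(group=3, subgenome="A")
parseChromName <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)([AB])$", x))
  bad <- vapply(m, length, integer(1L)) == 0L
  if (any(bad)) stop("unparseable chromosome name(s): ",
                     paste(x[bad], collapse = ", "))
  data.frame(chrom = x,
             group = as.integer(vapply(m, `[`, character(1L), 2L)),
             subgenome = vapply(m, `[`, character(1L), 3L),
             stringsAsFactors = FALSE)
}
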