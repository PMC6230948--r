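## Shared fixtures. The small genome keeps per-test cost low; the default
## genome (study conditions) is built once for the acceptance tests.

smallSpec <- function(seed = 11L, ...) {
  args <- list(chromosomeLength = 60000L, nConservedGenesPerChr = 4L,
               nMirnaHairpins = 6L, nLncrna = 4L, nCodingDecoys = 4L,
               nSsr = 6L,
               translocation = list(donor = "2A", acceptor = "1B",
                                    tailLength = 9000L),
               scaffoldN50Target = 2000L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticGenomeSpec, args)
}

smallGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateGenome(smallSpec())
    cache
  }
})

defaultGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateGenome(syntheticGenomeSpec(seed = 20180524L))
    cache
  }
})
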