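## TruthManifest serialisation. The on-disk form is a single JSON document
## with a fixed top-level key order; data frames are stored column-wise so
## the round trip is lossless including column types.

.manifestTables <- c("tes", "genes", "exons", "mirnas", "lncrnas", "decoys",
                     "ssrs", "teJunctions")

#' Write a truth manifest to disk
#'
#' Serialises the manifest (planted features, translocation breakpoints,
#' per-chromosome repeat fractions, generator parameters) as one structured
#' JSON text file with stable key order. [readManifest()] restores an
#' identical object.
#'
#' @param manifest a [TruthManifest-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "TruthManifest"))
  spec <- manifest@spec
  specList <- list(
    nHomeologousPairs = spec@nHomeologousPairs,
    chromosomeLength = spec@chromosomeLength,
    teFraction = spec@teFraction,
    teFamilyWeights = as.list(spec@teFamilyWeights),
    nConservedGenesPerChr = spec@nConservedGenesPerChr,
    meanCdsLength = spec@meanCdsLength,
    nMirnaHairpins = spec@nMirnaHairpins,
    teEmbeddedMirnaFraction = spec@teEmbeddedMirnaFraction,
    nLncrna = spec@nLncrna,
    nCodingDecoys = spec@nCodingDecoys,
    nSsr = spec@nSsr,
    translocation = spec@translocation,
    scaffoldN50Target = spec@scaffoldN50Target,
    seed = spec@seed)
  obj <- c(list(format = "emmerSurvey-truth-manifest/1",
                chromosomeLengths = as.list(manifest@chromosomeLengths)),
           setNames(lapply(.manifestTables, function(t) slot(manifest, t)),
                    .manifestTables),
           list(translocationEvent = manifest@translocation,
                trueRepeatFraction = as.list(manifest@trueRepeatFraction),
                trueConservedGeneCount = manifest@trueConservedGeneCount,
                spec = specList))
  json <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a truth manifest written by [writeManifest()]
#'
#' @param path path to the JSON manifest.
#' @return a [TruthManifest-class].
#' @export
readManifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emmerSurvey-truth-manifest/1"))
    stop("not an emmerSurvey truth manifest: ", path)
  sp <- obj$spec
  spec <- syntheticGenomeSpec(
    nHomeologousPairs = sp$nHomeologousPairs,
    chromosomeLength = sp$chromosomeLength,
    teFraction = sp$teFraction,
    teFamilyWeights = unlist(sp$teFamilyWeights),
    nConservedGenesPerChr = sp$nConservedGenesPerChr,
    meanCdsLength = sp$meanCdsLength,
    nMirnaHairpins = sp$nMirnaHairpins,
    teEmbeddedMirnaFraction = sp$teEmbeddedMirnaFraction,
    nLncrna = sp$nLncrna,
    nCodingDecoys = sp$nCodingDecoys,
    nSsr = sp$nSsr,
    translocation = sp$translocation,
    scaffoldN50Target = sp$scaffoldN50Target,
    seed = sp$seed)
  asTab <- function(nm) {
    d <- obj[[nm]]
    if (is.null(d) || (is.list(d) && !length(d)))
      return(.manifestProtos[[nm]])
    df <- as.data.frame(d, stringsAsFactors = FALSE)
    for (col in c("start", "end", "mature_start", "mature_end", "count",
                  "pos", "exon_index", "cds_length"))
      if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
    df
  }
  tabs <- setNames(lapply(.manifestTables, asTab), .manifestTables)
  new("TruthManifest",
      chromosomeLengths = setNames(as.integer(unlist(obj$chromosomeLengths)),
                                   names(obj$chromosomeLengths)),
      tes = tabs$tes, genes = tabs$genes, exons = tabs$exons,
      mirnas = tabs$mirnas, lncrnas = tabs$lncrnas, decoys = tabs$decoys,
      ssrs = tabs$ssrs, teJunctions = tabs$teJunctions,
      translocation = if (length(obj$translocationEvent))
        obj$translocationEvent else list(),
      trueRepeatFraction = setNames(as.numeric(unlist(obj$trueRepeatFraction)),
                                    names(obj$trueRepeatFraction)),
      trueConservedGeneCount = as.integer(obj$trueConservedGeneCount),
      spec = spec)
}
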