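## Constructors, accessors and show() methods.

.loadNNTable <- function(set) {
  path <- system.file("extdata", paste0("nn_", set, ".tsv"),
                      package = "mpxdesign", mustWork = FALSE)
  if (!nzchar(path))
    stop("unknown nearest-neighbor parameter set: ", set)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$pair
  stacks <- tab[nchar(tab$pair) == 2L, ]
  list(
    stackDH = structure(stacks$dH, names = stacks$pair),
    stackDS = structure(stacks$dS, names = stacks$pair),
    initDH = c(GC = tab["initGC", "dH"], AT = tab["initAT", "dH"]),
    initDS = c(GC = tab["initGC", "dS"], AT = tab["initAT", "dS"]),
    symDS = tab["sym", "dS"]
  )
}

#' Create a thermodynamic configuration
#'
#' @param nnParameterSet name of the nearest-neighbor table shipped under
#'   `extdata/` (default `"santalucia1998"`, the unified DNA/DNA set).
#' @param monovalentmM monovalent cation concentration, mM.
#' @param divalentmM divalent cation concentration, mM.
#' @param dntpmM total dNTP concentration, mM (binds divalent cations).
#' @param oligoConcentrationNM total oligo concentration, nM.
#' @param temperatureC temperature (degrees C) for free-energy evaluation.
#' @param hairpinLoopPenalty fixed hairpin loop closure penalty, kcal/mol.
#'
#' @return a [ThermoConfig-class] object.
#' @examples
#' cfg <- thermoConfig()
#' meltingTemperature("AGCGTAGCTAGCTAGCTAGCTAG", cfg)
#' @export
thermoConfig <- function(nnParameterSet = "santalucia1998",
                         monovalentmM = 50,
                         divalentmM = 1.5,
                         dntpmM = 0.6,
                         oligoConcentrationNM = 50,
                         temperatureC = 37,
                         hairpinLoopPenalty = 3.5) {
  nn <- .loadNNTable(nnParameterSet)
  new("ThermoConfig",
      nnParameterSet = nnParameterSet,
      stackDH = nn$stackDH, stackDS = nn$stackDS,
      initDH = nn$initDH, initDS = nn$initDS, symDS = nn$symDS,
      monovalentmM = monovalentmM, divalentmM = divalentmM,
      dntpmM = dntpmM, oligoConcentrationNM = oligoConcentrationNM,
      temperatureC = temperatureC,
      hairpinLoopPenalty = hairpinLoopPenalty)
}

#' Create a design configuration
#'
#' @param mTubes number of test tubes (>= 2).
#' @param optimumTmC optimum primer melting temperature, degrees C.
#' @param flankLen boundary window length in bases (the window holding the
#'   first forward and, mirrored, the last reverse primer).
#' @param ampliconMin,ampliconMax PCR product length bounds, bases.
#' @param tmPairToleranceC Tm tolerance (degrees C) around the optimum and
#'   between the primers of a pair.
#' @param dgThreshold secondary-structure free-energy floor, kcal/mol.
#' @param timeLimitS wall-clock search budget, seconds.
#' @param ordering candidate traversal strategy (see
#'   [orderCandidates()]).
#' @param primerLenMin,primerLenMax oligo length bounds, nt.
#' @param gcMin,gcMax inclusive GC-fraction bounds.
#' @param maxHomopolymer longest allowed single-base run.
#' @param thermo a [ThermoConfig-class]; built with defaults when omitted.
#'
#' @return a [DesignConfig-class] object.
#' @examples
#' cfg <- designConfig(mTubes = 3, flankLen = 120, timeLimitS = 10)
#' @export
designConfig <- function(mTubes = 2L,
                         optimumTmC = 60,
                         flankLen = 240L,
                         ampliconMin = 300L,
                         ampliconMax = 500L,
                         tmPairToleranceC = 0.5,
                         dgThreshold = -3.0,
                         timeLimitS = 240,
                         ordering = "bothNormal",
                         primerLenMin = 23L,
                         primerLenMax = 30L,
                         gcMin = 0.30,
                         gcMax = 0.70,
                         maxHomopolymer = 3L,
                         thermo = thermoConfig()) {
  new("DesignConfig",
      mTubes = as.integer(mTubes), optimumTmC = optimumTmC,
      flankLen = as.integer(flankLen),
      ampliconMin = as.integer(ampliconMin),
      ampliconMax = as.integer(ampliconMax),
      tmPairToleranceC = tmPairToleranceC, dgThreshold = dgThreshold,
      timeLimitS = timeLimitS, ordering = ordering,
      primerLenMin = as.integer(primerLenMin),
      primerLenMax = as.integer(primerLenMax),
      gcMin = gcMin, gcMax = gcMax,
      maxHomopolymer = as.integer(maxHomopolymer),
      thermo = thermo)
}

#' Construct a target region from an in-memory sequence
#'
#' @param name sequence identifier.
#' @param sequence DNA string (uppercased on ingest; only A/C/G/T allowed).
#' @param flankLen boundary window length, bases.
#' @param variantPositions integer vector of 0-based known-variant positions.
#' @param metadata optional provenance list.
#'
#' @return a validated [TargetRegion-class].
#' @examples
#' reg <- targetRegion("toy", strrep("ACGT", 600), flankLen = 240)
#' regionLength(reg)
#' @export
targetRegion <- function(name, sequence, flankLen,
                         variantPositions = integer(0), metadata = list()) {
  new("TargetRegion",
      name = as.character(name),
      sequence = toupper(as.character(sequence)),
      flankLen = as.integer(flankLen),
      variantPositions = as.integer(sort(unique(variantPositions))),
      metadata = metadata)
}

#' Specify a synthetic fixture
#'
#' @param length region length, bases.
#' @param gcTarget background GC fraction.
#' @param seed integer seed for reproducibility.
#' @param nProducts planted amplicon count (`NA` = fit as many as possible).
#' @param variantDensity planted variants per kb.
#' @param poisonMode make the planted oligos the only candidates (unique
#'   feasible tiling).
#'
#' @return a [FixtureSpec-class].
#' @seealso [generateRegion()]
#' @export
fixtureSpec <- function(length = 2050L, gcTarget = 0.5, seed = 1L,
                        nProducts = NA_integer_, variantDensity = 0,
                        poisonMode = FALSE) {
  new("FixtureSpec",
      length = as.integer(length), gcTarget = gcTarget,
      seed = as.integer(seed), nProducts = as.integer(nProducts),
      variantDensity = variantDensity, poisonMode = poisonMode)
}

#' @rdname SpecificityBackend-class
#' @param reference DNA string searched for exact oligo occurrences.
#' @return `exactMatchBackend()` an `ExactMatchBackend`; `blastBackend()` a
#'   `BlastBackend`.
#' @examples
#' be <- exactMatchBackend(strrep("ACGT", 100))
#' querySpecificity(be, "ACGTACGTACGTACGTACGTACG")
#' @export
exactMatchBackend <- function(reference) {
  new("ExactMatchBackend", reference = toupper(as.character(reference)))
}

#' @rdname SpecificityBackend-class
#' @param dbPath BLAST database prefix (as produced by `makeblastdb`).
#' @param evalueMax E-value cutoff for counting a hit.
#' @export
blastBackend <- function(dbPath, evalueMax = 0.01) {
  new("BlastBackend", dbPath = dbPath, evalueMax = evalueMax)
}

## ---- accessors --------------------------------------------------------

#' Accessors for TargetRegion and TilingSolution
#'
#' @param x a [TargetRegion-class] or [TilingSolution-class].
#' @return `regionName()` and `regionSequence()` character scalars;
#'   `regionLength()`, `flankLen()` and `variantPositions()` integers;
#'   `solutionPairs()` the pairs data.frame; `solutionStatus()` a character
#'   scalar; `elapsedSeconds()` a numeric scalar; `tubes()` a list of
#'   data.frames, one per tube.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))
#' @rdname accessors
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))
#' @rdname accessors
#' @export
setGeneric("regionLength", function(x) standardGeneric("regionLength"))
#' @rdname accessors
#' @export
setGeneric("flankLen", function(x) standardGeneric("flankLen"))
#' @rdname accessors
#' @export
setGeneric("variantPositions", function(x) standardGeneric("variantPositions"))
#' @rdname accessors
#' @export
setGeneric("solutionPairs", function(x) standardGeneric("solutionPairs"))
#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))
#' @rdname accessors
#' @export
setGeneric("elapsedSeconds", function(x) standardGeneric("elapsedSeconds"))
#' @rdname accessors
#' @export
setGeneric("tubes", function(x) standardGeneric("tubes"))

#' @rdname accessors
setMethod("regionName", "TargetRegion", function(x) x@name)
#' @rdname accessors
setMethod("regionSequence", "TargetRegion", function(x) x@sequence)
#' @rdname accessors
setMethod("regionLength", "TargetRegion", function(x) nchar(x@sequence))
#' @rdname accessors
setMethod("flankLen", "TargetRegion", function(x) x@flankLen)
#' @rdname accessors
setMethod("variantPositions", "TargetRegion", function(x) x@variantPositions)
#' @rdname accessors
setMethod("regionName", "TilingSolution", function(x) x@regionName)
#' @rdname accessors
setMethod("solutionPairs", "TilingSolution", function(x) x@pairs)
#' @rdname accessors
setMethod("solutionStatus", "TilingSolution", function(x) x@status)
#' @rdname accessors
setMethod("elapsedSeconds", "TilingSolution", function(x) x@elapsedS)
#' @rdname accessors
setMethod("tubes", "TilingSolution", function(x) {
  if (nrow(x@pairs) == 0L) return(list())
  split(x@pairs, x@pairs$tube)
})

## ---- show -------------------------------------------------------------

setMethod("show", "TargetRegion", function(object) {
  cat(sprintf("TargetRegion '%s': %d bases, flank %d, %d known variant position(s)\n",
              object@name, nchar(object@sequence), object@flankLen,
              length(object@variantPositions)))
})

setMethod("show", "DesignConfig", function(object) {
  cat(sprintf(paste0(
    "DesignConfig: %d tubes, Tm %.1f +/- %.1f C, flank %d, amplicon %d-%d,\n",
    "  primer %d-%d nt, GC [%.2f, %.2f], homopolymer <= %d, dG floor %.1f kcal/mol,\n",
    "  ordering %s, time limit %.0f s\n"),
    object@mTubes, object@optimumTmC, object@tmPairToleranceC,
    object@flankLen, object@ampliconMin, object@ampliconMax,
    object@primerLenMin, object@primerLenMax, object@gcMin, object@gcMax,
    object@maxHomopolymer, object@dgThreshold, object@ordering,
    object@timeLimitS))
})

setMethod("show", "TilingSolution", function(object) {
  cat(sprintf("TilingSolution for '%s': %s (%.2f s)\n",
              object@regionName, object@status, object@elapsedS))
  if (object@status == "solved") {
    cat(sprintf("  %d pairs across %d tubes; amplicons [%d, %d)\n",
                nrow(object@pairs), object@mTubes,
                object@pairs$ampliconStart[1L],
                object@pairs$ampliconEnd[nrow(object@pairs)]))
  } else if (nzchar(object@diagnostic)) {
    cat("  ", object@diagnostic, "\n", sep = "")
  }
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: %d bases, GC %.2f, seed %d, products %s, %.2f variants/kb%s\n",
              object@length, object@gcTarget, object@seed,
              ifelse(is.na(object@nProducts), "auto", object@nProducts),
              object@variantDensity,
              if (object@poisonMode) ", poison mode" else ""))
})
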