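## Central S4 classes. All genomic coordinates are 0-based, half-open
## [start, end) on the plus strand of the target region; the only place a
## 1-based inclusive convention appears is the human-readable TSV report.

#' Nearest-neighbor thermodynamic configuration
#'
#' Holds the nearest-neighbor (NN) stacking parameter table and the solution
#' conditions used by [meltingTemperature()], [duplexDG()] and [hairpinDG()].
#' The default parameter set is the unified DNA/DNA table of SantaLucia
#' (1998), shipped as a plain-text file under `extdata/` so that independent
#' oracles can read the very same numbers.
#'
#' @slot nnParameterSet identifier of the NN table (file
#'   `extdata/nn_<set>.tsv`).
#' @slot stackDH,stackDS named numeric vectors (16 dinucleotides) of stacking
#'   enthalpy (kcal/mol) and entropy (cal/(mol*K)).
#' @slot initDH,initDS duplex initiation terms, named `GC` and `AT` by the
#'   identity of the terminal base pair.
#' @slot symDS entropy correction for self-complementary duplexes.
#' @slot monovalentmM,divalentmM,dntpmM monovalent cation, divalent cation
#'   and dNTP concentrations (mM) entering the salt correction.
#' @slot oligoConcentrationNM total oligo concentration (nM) for the melting
#'   temperature.
#' @slot temperatureC temperature (degrees C) at which free energies are
#'   evaluated.
#' @slot hairpinLoopPenalty fixed free-energy penalty (kcal/mol) charged for
#'   closing a hairpin loop.
#'
#' @seealso [thermoConfig()]
#' @exportClass ThermoConfig
setClass("ThermoConfig",
  representation(
    nnParameterSet = "character",
    stackDH = "numeric",
    stackDS = "numeric",
    initDH = "numeric",
    initDS = "numeric",
    symDS = "numeric",
    monovalentmM = "numeric",
    divalentmM = "numeric",
    dntpmM = "numeric",
    oligoConcentrationNM = "numeric",
    temperatureC = "numeric",
    hairpinLoopPenalty = "numeric"
  )
)

setValidity("ThermoConfig", function(object) {
  msg <- character(0)
  if (length(object@stackDH) != 16L || length(object@stackDS) != 16L)
    msg <- c(msg, "NN table must contain exactly 16 dinucleotide stacks")
  conc <- c(object@monovalentmM, object@divalentmM, object@dntpmM)
  if (any(conc < 0))
    msg <- c(msg, "salt and dNTP concentrations must be >= 0")
  if (object@oligoConcentrationNM <= 0)
    msg <- c(msg, "oligoConcentrationNM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Design configuration for multiplex tiling
#'
#' Every threshold and search parameter of the design procedure in one
#' object. Defaults encode the screening rules used throughout the package:
#' primer length 23-30 nt, GC content within \[0.30, 0.70\], no homopolymer of
#' 4+ bases, primer Tm within 0.5 degrees C of `optimumTmC`, hairpin /
#' homodimer / heterodimer free energies no more negative than `dgThreshold`
#' (-3 kcal/mol), amplicons of 300-500 bases, and at least two test tubes.
#'
#' @slot mTubes number of test tubes the amplicons are split across
#'   (round-robin); must be >= 2 so that every internal primer site is
#'   covered by a neighboring product from another tube (allele-dropout
#'   protection).
#' @slot optimumTmC target melting temperature (degrees C); each primer must
#'   lie within `tmPairToleranceC` of it.
#' @slot flankLen length (bases) of the boundary windows: the first forward
#'   primer must start in the first `flankLen` bases and the last reverse
#'   primer must end in the last `flankLen` bases.
#' @slot ampliconMin,ampliconMax allowed PCR product length range (bases).
#' @slot tmPairToleranceC maximum Tm spread (degrees C), both around the
#'   optimum and between the two primers of a pair.
#' @slot dgThreshold free-energy floor (kcal/mol): any hairpin, homodimer or
#'   heterodimer with dG below this value disqualifies the primer or pair.
#' @slot timeLimitS wall-clock budget (seconds) for the depth-first search.
#' @slot ordering candidate traversal strategy, one of `"bothNormal"`,
#'   `"fwdReverse"`, `"revReverse"`, `"bothReverse"`.
#' @slot primerLenMin,primerLenMax allowed oligo length range (nt).
#' @slot gcMin,gcMax allowed GC fraction range (inclusive).
#' @slot maxHomopolymer longest allowed single-base run in a primer.
#' @slot thermo a [ThermoConfig-class] object.
#'
#' @seealso [designConfig()], [designMultiplex()]
#' @exportClass DesignConfig
setClass("DesignConfig",
  representation(
    mTubes = "integer",
    optimumTmC = "numeric",
    flankLen = "integer",
    ampliconMin = "integer",
    ampliconMax = "integer",
    tmPairToleranceC = "numeric",
    dgThreshold = "numeric",
    timeLimitS = "numeric",
    ordering = "character",
    primerLenMin = "integer",
    primerLenMax = "integer",
    gcMin = "numeric",
    gcMax = "numeric",
    maxHomopolymer = "integer",
    thermo = "ThermoConfig"
  )
)

orderingStrategies <- function() {
  c("bothNormal", "fwdReverse", "revReverse", "bothReverse")
}

setValidity("DesignConfig", function(object) {
  msg <- character(0)
  if (object@mTubes < 2L)
    msg <- c(msg, "mTubes must be >= 2: amplicons are split into at least two test tubes")
  if (object@ampliconMin > object@ampliconMax)
    msg <- c(msg, "ampliconMin must be <= ampliconMax")
  if (!object@ordering %in% orderingStrategies())
    msg <- c(msg, paste0("ordering must be one of: ",
                         paste(orderingStrategies(), collapse = ", ")))
  if (object@primerLenMin < 8L || object@primerLenMin > object@primerLenMax)
    msg <- c(msg, "primer length range invalid (need 8 <= min <= max)")
  if (object@gcMin < 0 || object@gcMax > 1 || object@gcMin > object@gcMax)
    msg <- c(msg, "GC bounds must satisfy 0 <= gcMin <= gcMax <= 1")
  if (object@flankLen < 1L)
    msg <- c(msg, "flankLen must be positive")
  if (object@timeLimitS < 0)
    msg <- c(msg, "timeLimitS must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A continuous target region with flanks and known variant positions
#'
#' The single input sequence every other module operates on: a continuous
#' stretch of DNA (the region of interest plus upstream/downstream flanking
#' sequence) and the set of known variant positions within it. Positions are
#' 0-based. The flank length defines the boundary windows in which the first
#' forward and the last reverse primer must lie.
#'
#' @slot name sequence identifier (FASTA header word).
#' @slot sequence uppercase DNA string over A/C/G/T.
#' @slot flankLen boundary window length (bases); both windows must fit
#'   without overlapping, i.e. `2 * flankLen < length`.
#' @slot variantPositions sorted integer vector of 0-based positions of known
#'   variants; primers whose 3'-terminal three template bases cover any of
#'   these are rejected.
#' @slot metadata free-form list (fixture provenance, generator geometry).
#'
#' @seealso [targetRegion()], [readTargetRegion()]
#' @exportClass TargetRegion
setClass("TargetRegion",
  representation(
    name = "character",
    sequence = "character",
    flankLen = "integer",
    variantPositions = "integer",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("TargetRegion", function(object) {
  msg <- character(0)
  len <- nchar(object@sequence)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  bad <- gregexpr("[^ACGT]", object@sequence)[[1]]
  if (bad[1] != -1L)
    msg <- c(msg, sprintf("sequence contains non-ACGT character '%s' at position %d (0-based)",
                          substr(object@sequence, bad[1], bad[1]), bad[1] - 1L))
  if (2L * object@flankLen >= len)
    msg <- c(msg, sprintf(
      "flankLen %d too large: need 2*flankLen < length (%d), so both boundary windows fit without overlapping",
      object@flankLen, len))
  vp <- object@variantPositions
  if (length(vp) && (any(vp < 0L) || any(vp >= len)))
    msg <- c(msg, "every variant position p must satisfy 0 <= p < length")
  if (is.unsorted(vp))
    msg <- c(msg, "variantPositions must be sorted")
  if (length(msg)) msg else TRUE
})

#' A tiling of the target region by multiplexed primer pairs
#'
#' The result of [designMultiplex()] (and the element type of
#' [bruteForceTilings()]): an ordered set of primer pairs whose amplicons
#' overlap consecutively, assigned round-robin to `mTubes` test tubes.
#' `pairs` is a data.frame with one row per PCR product, in left-to-right
#' `productIndex` order, carrying 0-based half-open coordinates and cached
#' thermodynamic metrics for both primers.
#'
#' @slot pairs data.frame of primer pairs (possibly 0-row for non-solved
#'   outcomes); see [designMultiplex()] for the column contract.
#' @slot status one of `"solved"`, `"timeout"`, `"infeasible"`.
#' @slot elapsedS wall-clock seconds spent searching.
#' @slot mTubes tube count used for the round-robin assignment.
#' @slot regionName name of the designed region.
#' @slot diagnostic for non-solved outcomes, a short reason (e.g. no
#'   candidate in the first boundary window vs. no compatible tiling).
#'
#' @seealso [designMultiplex()], [verifySolution()], [tubes()]
#' @exportClass TilingSolution
setClass("TilingSolution",
  representation(
    pairs = "data.frame",
    status = "character",
    elapsedS = "numeric",
    mTubes = "integer",
    regionName = "character",
    diagnostic = "character"
  ),
  prototype(diagnostic = "")
)

setValidity("TilingSolution", function(object) {
  msg <- character(0)
  if (!object@status %in% c("solved", "timeout", "infeasible"))
    msg <- c(msg, "status must be solved, timeout or infeasible")
  if (object@status == "solved" && nrow(object@pairs) == 0L)
    msg <- c(msg, "a solved solution must contain at least one pair")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic test region
#'
#' Parameters for [generateRegion()]: a seeded, reproducible target region
#' with primer-friendly windows planted so that at least one tiling is
#' feasible by construction.
#'
#' @slot length region length in bases (flanks included).
#' @slot gcTarget background GC fraction.
#' @slot seed integer seed; two calls with the same spec are bit-identical.
#' @slot nProducts number of planted amplicons (`NA` = as many as fit).
#' @slot variantDensity planted known variants per kilobase (placed outside
#'   planted primer footprints).
#' @slot poisonMode when `TRUE`, everything outside the planted primer
#'   windows is filled with homopolymer blocks so the planted oligos are the
#'   only primer candidates and exactly one tiling is feasible.
#'
#' @seealso [fixtureSpec()], [generateRegion()]
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    length = "integer",
    gcTarget = "numeric",
    seed = "integer",
    nProducts = "integer",
    variantDensity = "numeric",
    poisonMode = "logical"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character(0)
  if (object@length < 400L)
    msg <- c(msg, "fixture length must be at least 400 bases")
  if (object@gcTarget <= 0 || object@gcTarget >= 1)
    msg <- c(msg, "gcTarget must be in (0, 1)")
  if (object@variantDensity < 0)
    msg <- c(msg, "variantDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specificity backends
#'
#' A `SpecificityBackend` answers, for a primer sequence, how many places in
#' a reference it could bind. A candidate is kept only when the answer is at
#' most one (its own locus). `ExactMatchBackend` counts exact occurrences of
#' the oligo and its reverse complement in a reference sequence held in
#' memory -- the offline analogue of a BLAST screen, suitable for tests.
#' `BlastBackend` shells out to `blastn -task blastn-short` against a
#' pre-built BLAST database and counts alignments with E-value below 0.01.
#'
#' @slot reference (`ExactMatchBackend`) the reference DNA string searched
#'   for exact matches.
#' @slot dbPath (`BlastBackend`) path to a BLAST nucleotide database prefix.
#' @slot evalueMax (`BlastBackend`) E-value cutoff defining a hit.
#'
#' @aliases ExactMatchBackend-class BlastBackend-class
#' @seealso [exactMatchBackend()], [blastBackend()], [querySpecificity()]
#' @exportClass SpecificityBackend
setClass("SpecificityBackend", representation("VIRTUAL"))

#' @exportClass ExactMatchBackend
#' @rdname SpecificityBackend-class
setClass("ExactMatchBackend",
  contains = "SpecificityBackend",
  representation(reference = "character")
)

#' @exportClass BlastBackend
#' @rdname SpecificityBackend-class
setClass("BlastBackend",
  contains = "SpecificityBackend",
  representation(dbPath = "character", evalueMax = "numeric")
)
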