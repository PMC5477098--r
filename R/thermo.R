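## Nearest-neighbor thermodynamics: melting temperature, duplex and hairpin
## free energies. The duplex model is an ungapped complementary alignment
## (no bulges or internal loops) and the hairpin model a single stem with a
## single loop, so both admit an exact brute-force oracle over all
## alignments / stem-loop placements.

R_GAS <- 1.9872          # cal / (mol K)
KELVIN0 <- 273.15

.checkDNA <- function(seq, minLen = 1L, what = "sequence") {
  if (length(seq) == 0L)
    stop(what, " must be non-empty")
  if (any(!nzchar(seq)))
    stop(what, " must be a non-empty DNA string")
  if (any(grepl("[^ACGT]", seq)))
    stop(what, " must contain only A/C/G/T")
  if (any(nchar(seq) < minLen))
    stop(what, " must be at least ", minLen, " bases long")
  invisible(seq)
}

.revComp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#'
#' @param seq character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGGT")
#' @export
revComp <- function(seq) {
  .checkDNA(seq)
  as.character(reverseComplement(DNAStringSet(seq)))
}

#' GC fraction of an oligonucleotide
#'
#' The number of G and C bases divided by the total length.
#'
#' @param seq character vector of DNA strings.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' gcFraction(c("AAAA", "GCGC", "ATGC"))
#' @export
gcFraction <- function(seq) {
  .checkDNA(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

#' Longest homopolymer run
#'
#' @param seq character vector of DNA strings.
#' @return integer vector: length of the longest run of one repeated base
#'   (>= 1).
#' @examples
#' maxHomopolymerRun(c("ACGT", "AAAT", "CGGGGA"))
#' @export
maxHomopolymerRun <- function(seq) {
  .checkDNA(seq)
  vapply(strsplit(seq, ""), function(ch) max(rle(ch)$lengths),
         integer(1L))
}

## Effective monovalent cation concentration (molar), folding divalent
## cations not sequestered by dNTPs into the monovalent pool
## (von Ahsen et al. 2001).
.effectiveNa <- function(cfg) {
  freeDiv <- max(cfg@divalentmM - cfg@dntpmM, 0)
  (cfg@monovalentmM + 120 * sqrt(freeDiv)) / 1000
}

.isSelfComplementary <- function(seq) {
  n <- nchar(seq)
  n %% 2L == 0L && seq == .revComp(seq)
}

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model: `Tm = dH / (dS + R ln(CT/x)) - 273.15`,
#' with duplex initiation terms for the two terminal base pairs, a
#' salt-corrected entropy (`dS + 0.368 (N-1) ln[Na+]`, effective monovalent
#' molarity) and `x = 4` for a primer annealing to its (distinct) template
#' strand (`x = 1` plus a symmetry entropy correction for self-complementary
#' oligos).
#'
#' @param seq character vector of DNA strings, each at least 8 nt (the
#'   two-state model is unreliable for shorter oligos).
#' @param cfg a [ThermoConfig-class].
#' @return numeric vector of melting temperatures, degrees C.
#' @examples
#' meltingTemperature("AGCGTAGCTAGCTAGCTAGCTAG")
#' @export
meltingTemperature <- function(seq, cfg = thermoConfig()) {
  .checkDNA(seq, minLen = 8L, what = "primer sequence")
  n <- nchar(seq)
  dn <- dinucleotideFrequency(DNAStringSet(seq))
  dH <- as.numeric(dn %*% cfg@stackDH[colnames(dn)])
  dS <- as.numeric(dn %*% cfg@stackDS[colnames(dn)])
  termType <- function(base) ifelse(base %in% c("G", "C"), "GC", "AT")
  t1 <- termType(substr(seq, 1L, 1L))
  t2 <- termType(substr(seq, n, n))
  dH <- dH + cfg@initDH[t1] + cfg@initDH[t2]
  dS <- dS + cfg@initDS[t1] + cfg@initDS[t2]
  selfc <- vapply(seq, .isSelfComplementary, logical(1L), USE.NAMES = FALSE)
  dS <- dS + ifelse(selfc, cfg@symDS, 0)
  dS <- dS + 0.368 * (n - 1L) * log(.effectiveNa(cfg))
  ct <- cfg@oligoConcentrationNM * 1e-9
  x <- ifelse(selfc, 1, 4)
  tmK <- dH * 1000 / (dS + R_GAS * log(ct / x))
  unname(tmK - KELVIN0)
}

## Per-stack and initiation free energies (kcal/mol) at cfg@temperatureC.
.stackDG <- function(cfg) {
  tK <- cfg@temperatureC + KELVIN0
  cfg@stackDH - tK * cfg@stackDS / 1000
}

.initDG <- function(cfg) {
  tK <- cfg@temperatureC + KELVIN0
  cfg@initDH - tK * cfg@initDS / 1000
}

## Score one contiguous complementary run given as the top-strand character
## vector; stacks plus both terminal initiation terms.
.runDG <- function(chars, stackDG, initDG) {
  k <- length(chars)
  din <- paste0(chars[-k], chars[-1L])
  term <- ifelse(chars[c(1L, k)] %in% c("G", "C"), "GC", "AT")
  sum(stackDG[din]) + sum(initDG[term])
}

#' Free energy of the most stable primer-primer duplex
#'
#' Scans every ungapped antiparallel alignment of `seqA` against `seqB` and
#' scores each maximal stretch of consecutive Watson-Crick pairs with the
#' nearest-neighbor table (stacks plus the two terminal initiation terms) at
#' `cfg@temperatureC`. Returns the most negative score, or 0 when no
#' alignment contains at least 4 consecutive complementary pairs. Symmetric
#' in its two arguments; the homodimer case is `seqA == seqB`.
#'
#' @param seqA,seqB DNA strings of length >= 8 (5'->3').
#' @param cfg a [ThermoConfig-class].
#' @return free energy in kcal/mol (<= 0).
#' @examples
#' p <- "AGCGTAGCTAGCTAGCTAGCTAG"
#' duplexDG(p, revComp(p))   # perfect duplex, strongly negative
#' duplexDG(p, p)            # homodimer
#' @export
duplexDG <- function(seqA, seqB, cfg = thermoConfig()) {
  .checkDNA(c(seqA, seqB), minLen = 8L, what = "oligo")
  a <- strsplit(seqA, "")[[1L]]
  b <- strsplit(.revComp(seqB), "")[[1L]]   # match == complementary pair
  nA <- length(a); nB <- length(b)
  ## quick rejection: positions starting 4 consecutive complementary pairs
  M <- outer(a, b, "==")
  M4 <- M[1:(nA - 3L), 1:(nB - 3L), drop = FALSE] &
        M[2:(nA - 2L), 2:(nB - 2L), drop = FALSE] &
        M[3:(nA - 1L), 3:(nB - 1L), drop = FALSE] &
        M[4:nA, 4:nB, drop = FALSE]
  hit <- which(M4, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(0)
  stackDG <- .stackDG(cfg); initDG <- .initDG(cfg)
  best <- 0
  for (off in unique(hit[, 1L] - hit[, 2L])) {
    i0 <- max(1L, off + 1L); i1 <- min(nA, nB + off)
    idx <- i0:i1
    hits <- a[idx] == b[idx - off]
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 4L)) {
      run <- idx[starts[j]:ends[j]]
      dg <- .runDG(a[run], stackDG, initDG)
      if (dg < best) best <- dg
    }
  }
  best
}

#' Free energy of the most stable hairpin
#'
#' Considers every single-stem, single-loop structure with a stem of at
#' least 3 Watson-Crick pairs and a loop of at least 3 unpaired bases. The
#' stem is scored with nearest-neighbor stacks at `cfg@temperatureC` plus a
#' fixed loop penalty (`cfg@hairpinLoopPenalty`). Returns the most negative
#' structure score, or 0 when no qualifying structure exists (or none is
#' favorable).
#'
#' @param seq DNA string of length >= 8.
#' @param cfg a [ThermoConfig-class].
#' @return free energy in kcal/mol (<= 0).
#' @examples
#' hairpinDG("GGGGAAAACCCC")   # 4-bp stem, 4-base loop
#' hairpinDG("ATATATAT")       # no 3-bp stem closes a loop
#' @export
hairpinDG <- function(seq, cfg = thermoConfig()) {
  .checkDNA(seq, minLen = 8L, what = "oligo")
  ch <- strsplit(seq, "")[[1L]]
  comp <- chartr("ACGT", "TGCA", seq)
  cc <- strsplit(comp, "")[[1L]]
  n <- length(ch)
  stackDG <- .stackDG(cfg)
  pen <- cfg@hairpinLoopPenalty
  best <- 0
  if (n < 9L) return(best)
  for (i in seq_len(n - 8L)) {
    for (j in (i + 8L):n) {
      # pairs (i+t, j-t), t = 0..s-1; loop after s pairs has
      # j - i - 2s + 1 bases, so s <= (j - i - 2) / 2 keeps loop >= 3
      kmax <- (j - i - 2L) %/% 2L
      k <- 0L
      while (k < kmax && ch[i + k] == cc[j - k]) k <- k + 1L
      if (k < 3L) next
      # best stem prefix of length >= 3 ending anywhere up to k
      stem <- ch[i:(i + k - 1L)]
      dgStack <- cumsum(stackDG[paste0(stem[-k], stem[-1L])])
      dg <- min(dgStack[2L:(k - 1L)]) + pen
      if (dg < best) best <- dg
    }
  }
  best
}
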