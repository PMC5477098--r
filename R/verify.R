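## Standalone solution verifier. Shares the thermodynamic primitives and
## parameter table with the rest of the package but none of the search
## logic: every rule is re-derived from the region sequence and the pair
## coordinates, so a bug in the search cannot hide itself here.

#' Verify a tiling solution against every design rule
#'
#' Re-checks, from scratch, everything a solved [TilingSolution-class] must
#' satisfy: primer sequences match the template, per-primer screening rules
#' (length, GC, homopolymer, Tm band, hairpin/homodimer free energy,
#' 3'-variant exclusion), the seven positional rules (first/last boundary
#' windows, consecutive overlap, two-apart disjointness, strictly
#' increasing reverse ends, round-robin tube assignment with no within-tube
#' overlap), amplicon length bounds, the within-pair Tm tolerance and
#' heterodimer threshold, the per-tube pairwise compatibility clique, and
#' gap-free coverage of the inner target.
#'
#' @param solution a [TilingSolution-class].
#' @param region the [TargetRegion-class] it was designed for.
#' @param cfg the [DesignConfig-class] used.
#'
#' @return `TRUE` when every rule holds, otherwise `FALSE` with a character
#'   vector of failure descriptions in `attr(, "failures")`.
#' @examples
#' cfg <- designConfig(flankLen = 120L, timeLimitS = 30)
#' reg <- generateRegion(fixtureSpec(length = 1300, seed = 11), cfg)
#' sol <- designMultiplex(reg, cfg)
#' verifySolution(sol, reg, cfg)
#' @export
verifySolution <- function(solution, region, cfg) {
  fails <- character(0)
  note <- function(fmt, ...) fails <<- c(fails, sprintf(fmt, ...))
  p <- solution@pairs
  len <- regionLength(region)
  flank <- cfg@flankLen
  thermo <- cfg@thermo
  vp <- variantPositions(region)

  if (solution@status != "solved") {
    note("status is '%s', not 'solved'", solution@status)
  } else if (nrow(p) == 0L) {
    note("solved solution has no pairs")
  } else {
    if (solution@mTubes != cfg@mTubes)
      note("solution tube count %d != config %d", solution@mTubes, cfg@mTubes)

    checkPrimer <- function(start, end, oligo, strand, label) {
      L <- end - start
      tmpl <- substr(region@sequence, start + 1L, end)
      expect <- if (strand == "reverse") .revComp(tmpl) else tmpl
      if (!identical(oligo, expect))
        note("%s: oligo does not match template at [%d,%d)", label, start, end)
      if (L < cfg@primerLenMin || L > cfg@primerLenMax)
        note("%s: length %d outside [%d,%d]", label, L,
             cfg@primerLenMin, cfg@primerLenMax)
      gc <- gcFraction(oligo)
      if (gc < cfg@gcMin - 1e-9 || gc > cfg@gcMax + 1e-9)
        note("%s: GC %.3f outside [%.2f,%.2f]", label, gc, cfg@gcMin, cfg@gcMax)
      if (maxHomopolymerRun(oligo) > cfg@maxHomopolymer)
        note("%s: homopolymer run > %d", label, cfg@maxHomopolymer)
      tm <- meltingTemperature(oligo, thermo)
      if (abs(tm - cfg@optimumTmC) > cfg@tmPairToleranceC + 1e-9)
        note("%s: Tm %.2f outside optimum band", label, tm)
      if (hairpinDG(oligo, thermo) < cfg@dgThreshold)
        note("%s: hairpin dG below threshold", label)
      if (duplexDG(oligo, oligo, thermo) < cfg@dgThreshold)
        note("%s: homodimer dG below threshold", label)
      zone <- if (strand == "forward") (end - 3L):(end - 1L) else start:(start + 2L)
      if (length(vp) && any(vp %in% zone))
        note("%s: known variant under the 3'-terminal three bases", label)
      tm
    }

    n <- nrow(p)
    for (i in seq_len(n)) {
      fTm <- checkPrimer(p$fwdStart[i], p$fwdEnd[i], p$fwdSeq[i], "forward",
                         sprintf("pair %d forward", i - 1L))
      rTm <- checkPrimer(p$revStart[i], p$revEnd[i], p$revSeq[i], "reverse",
                         sprintf("pair %d reverse", i - 1L))
      ampLen <- p$ampliconEnd[i] - p$ampliconStart[i]
      if (p$ampliconStart[i] != p$fwdStart[i] || p$ampliconEnd[i] != p$revEnd[i])
        note("pair %d: amplicon interval does not match its primers", i - 1L)
      if (ampLen < cfg@ampliconMin || ampLen > cfg@ampliconMax)
        note("pair %d: amplicon length %d outside [%d,%d]", i - 1L, ampLen,
             cfg@ampliconMin, cfg@ampliconMax)
      if (abs(fTm - rTm) > cfg@tmPairToleranceC + 1e-9)
        note("pair %d: primer Tm difference exceeds tolerance", i - 1L)
      if (duplexDG(p$fwdSeq[i], p$revSeq[i], thermo) < cfg@dgThreshold)
        note("pair %d: forward-reverse heterodimer below threshold", i - 1L)
      if (p$productIndex[i] != i - 1L)
        note("pair %d: productIndex out of order", i - 1L)
      if (p$tube[i] != (i - 1L) %% cfg@mTubes)
        note("pair %d: tube is not productIndex mod m", i - 1L)
    }

    if (p$fwdStart[1L] >= flank)
      note("first forward primer does not start within the first %d bases", flank)
    if (p$revEnd[n] <= len - flank || p$revEnd[n] > len)
      note("last reverse primer does not end within the final %d bases", flank)
    if (n > 1L) {
      if (any(diff(p$revEnd) <= 0L))
        note("reverse ends are not strictly increasing")
      if (any(diff(p$ampliconStart) <= 0L))
        note("amplicon starts are not strictly increasing (left-to-right order)")
      if (any(p$ampliconStart[-1L] >= p$ampliconEnd[-n]))
        note("consecutive amplicons do not overlap")
    }
    if (n > 2L) {
      for (i in 3L:n) {
        if (p$ampliconStart[i] <= p$ampliconEnd[i - 2L])
          note("amplicons %d and %d (two apart) are not disjoint", i - 3L, i - 1L)
      }
    }
    for (t in unique(p$tube)) {
      rows <- p[p$tube == t, , drop = FALSE]
      if (nrow(rows) > 1L) {
        for (i in 2L:nrow(rows)) {
          if (rows$fwdStart[i] <= rows$revEnd[i - 1L])
            note("tube %d: consecutive products overlap within the tube", t)
        }
      }
      primers <- c(rows$fwdSeq, rows$revSeq)
      if (length(primers) > 1L) {
        for (i in 1L:(length(primers) - 1L)) {
          for (j in (i + 1L):length(primers)) {
            if (duplexDG(primers[i], primers[j], thermo) < cfg@dgThreshold)
              note("tube %d: primers %d and %d form a heterodimer below threshold",
                   t, i, j)
          }
        }
      }
    }
    ## coverage of the inner target with no gaps
    cov <- rep(FALSE, len)
    for (i in seq_len(n))
      cov[(p$ampliconStart[i] + 1L):p$ampliconEnd[i]] <- TRUE
    inner <- (flank + 1L):(len - flank)
    if (!all(cov[inner]))
      note("amplicons do not cover the inner target [%d, %d)", flank, len - flank)
    span <- (p$ampliconStart[1L] + 1L):p$ampliconEnd[n]
    if (!all(cov[span]))
      note("amplicon union has an internal gap")
  }

  ok <- length(fails) == 0L
  attr(ok, "failures") <- fails
  ok
}
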