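## Time-limited depth-first tiling search. Product index n is global and
## 0-based; tube = n mod m; positions compare a forward primer by its start
## (first template base) and a reverse primer by its (half-open) end.
## Positional rules enforced at every extension:
##   - first forward starts within the first flankLen bases;
##   - new forward start < previous reverse end  (adjacent products overlap);
##   - new forward start > reverse end two products back (disjoint);
##   - new forward start > reverse end of the previous product in its own
##     tube (no within-tube overlap);
##   - reverse ends strictly increase;
##   - search succeeds at the first state whose last reverse ends within the
##     final flankLen bases.

#' Order candidates for depth-first traversal
#'
#' The four traversal strategies permute the canonical (ascending start,
#' ascending length) candidate order: `bothNormal` keeps both roles in
#' normal order by base location, `fwdReverse` reverses only the forward
#' role, `revReverse` only the reverse role, and `bothReverse` reverses
#' both. Reversal is of the full canonical order, so the permutation is
#' stable and deterministic.
#'
#' @param candidates candidate data.frame in canonical order (from
#'   [enumerateCandidates()]).
#' @param role `"forward"` or `"reverse"`: which role these candidates play.
#' @param strategy one of `"bothNormal"`, `"fwdReverse"`, `"revReverse"`,
#'   `"bothReverse"`.
#'
#' @return the reordered data.frame.
#' @examples
#' df <- data.frame(start = c(10, 40, 70), end = c(33, 63, 93))
#' orderCandidates(df, "forward", "fwdReverse")$start
#' @export
orderCandidates <- function(candidates, role = c("forward", "reverse"),
                            strategy) {
  role <- match.arg(role)
  if (!strategy %in% orderingStrategies())
    stop("unknown ordering strategy '", strategy, "'; valid: ",
         paste(orderingStrategies(), collapse = ", "))
  descend <- switch(strategy,
    bothNormal = FALSE,
    fwdReverse = role == "forward",
    revReverse = role == "reverse",
    bothReverse = TRUE)
  if (descend && nrow(candidates) > 1L)
    candidates <- candidates[rev(seq_len(nrow(candidates))), , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

#' Validate a forward/reverse pair as one amplicon
#'
#' True exactly when the product length lies within
#' `[cfg@ampliconMin, cfg@ampliconMax]`, the two melting temperatures differ
#' by at most `cfg@tmPairToleranceC`, and the forward-reverse heterodimer
#' free energy is not below `cfg@dgThreshold`.
#'
#' @param fwd,rev single candidate rows (forward / reverse strand).
#' @param cfg a [DesignConfig-class].
#' @return logical scalar.
#' @export
pairIsValid <- function(fwd, rev, cfg) {
  ampLen <- rev$end - fwd$start
  if (ampLen < cfg@ampliconMin || ampLen > cfg@ampliconMax) return(FALSE)
  if (abs(fwd$tmC - rev$tmC) > cfg@tmPairToleranceC) return(FALSE)
  duplexDG(fwd$sequence, rev$sequence, cfg@thermo) >= cfg@dgThreshold
}

#' Check a primer against all current members of a tube
#'
#' Incremental maintenance of the per-tube clique condition: the candidate
#' may join a tube only if its heterodimer free energy with every primer
#' already in that tube is not below `cfg@dgThreshold`. An empty tube is
#' vacuously compatible.
#'
#' @param candidate a single candidate row (or its sequence).
#' @param tubeMembers character vector of primer sequences already assigned
#'   to the tube.
#' @param cfg a [DesignConfig-class].
#' @return logical scalar, independent of member order.
#' @export
tubeCompatible <- function(candidate, tubeMembers, cfg) {
  seqC <- if (is.character(candidate)) candidate else candidate$sequence
  for (s in tubeMembers) {
    if (duplexDG(seqC, s, cfg@thermo) < cfg@dgThreshold) return(FALSE)
  }
  TRUE
}

.pairRow <- function(n, mTubes, fwd, rev, pairDG) {
  data.frame(
    productIndex = n, tube = n %% mTubes,
    fwdStart = fwd$start, fwdEnd = fwd$end, fwdSeq = fwd$sequence,
    fwdTm = fwd$tmC, fwdGC = fwd$gc, fwdHairpinDG = fwd$hairpinDG,
    fwdHomodimerDG = fwd$homodimerDG,
    revStart = rev$start, revEnd = rev$end, revSeq = rev$sequence,
    revTm = rev$tmC, revGC = rev$gc, revHairpinDG = rev$hairpinDG,
    revHomodimerDG = rev$homodimerDG,
    ampliconStart = fwd$start, ampliconEnd = rev$end,
    ampliconLength = rev$end - fwd$start,
    pairDuplexDG = pairDG,
    stringsAsFactors = FALSE)
}

.emptyPairs <- function() .pairRow(0L, 2L,
  data.frame(start = 0L, end = 0L, sequence = "", tmC = 0, gc = 0,
             hairpinDG = 0, homodimerDG = 0),
  data.frame(start = 0L, end = 0L, sequence = "", tmC = 0, gc = 0,
             hairpinDG = 0, homodimerDG = 0), 0)[0L, ]

## memoized heterodimer dG, keyed on the (sorted) sequence pair and the
## thermodynamic conditions; shared across searches
.dimerStore <- new.env(parent = emptyenv())
.dimerStore$.n <- 0L

.dimerCache <- function(thermo) {
  prefix <- paste(thermo@nnParameterSet, thermo@temperatureC, sep = "|")
  function(a, b) {
    key <- if (a <= b) paste(prefix, a, b) else paste(prefix, b, a)
    val <- .dimerStore[[key]]
    if (is.null(val)) {
      val <- duplexDG(a, b, thermo)
      if (.dimerStore$.n > 300000L) {
        rm(list = ls(.dimerStore), envir = .dimerStore)
        .dimerStore$.n <- 0L
      }
      .dimerStore[[key]] <- val
      .dimerStore$.n <- .dimerStore$.n + 1L
    }
    val
  }
}

## full-region candidate enumeration, cached across calls so a benchmark
## sweep over orderings/tube counts does not recompute thermodynamics
.candidateStore <- new.env(parent = emptyenv())

.allCandidates <- function(region, cfg) {
  len <- regionLength(region)
  key <- paste(region@sequence,
               paste(region@variantPositions, collapse = ","),
               cfg@optimumTmC, cfg@tmPairToleranceC, cfg@gcMin, cfg@gcMax,
               cfg@maxHomopolymer, cfg@primerLenMin, cfg@primerLenMax,
               cfg@dgThreshold, cfg@ampliconMin,
               cfg@thermo@nnParameterSet, cfg@thermo@temperatureC,
               cfg@thermo@monovalentmM, cfg@thermo@oligoConcentrationNM,
               sep = "|")
  val <- .candidateStore[[key]]
  if (is.null(val)) {
    val <- list(
      fwd = enumerateCandidates(region, 0L, len - cfg@ampliconMin + 1L,
                                "forward", cfg),
      rev = enumerateCandidates(region, cfg@ampliconMin - 1L, len,
                                "reverse", cfg))
    if (length(ls(.candidateStore)) > 30L)
      rm(list = ls(.candidateStore), envir = .candidateStore)
    .candidateStore[[key]] <- val
  }
  val
}

#' Design a multiplex tiling by time-limited depth-first search
#'
#' Enumerates primer candidates over the whole region, then searches
#' depth-first for the first sequence of primer pairs whose amplicons tile
#' the region: the first forward primer starts in the first `flankLen`
#' bases, consecutive products overlap while products two apart are
#' disjoint, forward starts and reverse ends strictly increase (products
#' are numbered left to right), products are assigned
#' round-robin to `mTubes` tubes with no within-tube overlap, and every
#' primer joining a tube must be pairwise compatible (heterodimer dG not
#' below the threshold) with all primers already there. The search succeeds
#' at the first state whose last reverse primer ends within the final
#' `flankLen` bases; it backtracks on dead ends, and aborts with status
#' `"timeout"` once the wall clock exceeds `cfg@timeLimitS` (checked at
#' every node expansion). The search is deterministic: the only sources of
#' traversal order are the candidate enumeration and `cfg@ordering`.
#'
#' @param region a [TargetRegion-class].
#' @param cfg a [DesignConfig-class]; `cfg@flankLen` is the boundary window
#'   used for the search.
#' @param backend optional [SpecificityBackend-class] applied to all
#'   candidates before the search.
#'
#' @return a [TilingSolution-class] with status `"solved"` (first feasible
#'   tiling found), `"timeout"` (budget exhausted) or `"infeasible"` (search
#'   space exhausted; the diagnostic distinguishes an empty first window
#'   from the absence of a compatible tiling).
#' @examples
#' cfg <- designConfig(flankLen = 120L, timeLimitS = 30)
#' reg <- generateRegion(fixtureSpec(length = 1300, seed = 11), cfg)
#' sol <- designMultiplex(reg, cfg)
#' solutionStatus(sol)
#' @export
designMultiplex <- function(region, cfg, backend = NULL) {
  validObject(region); validObject(cfg)
  len <- regionLength(region)
  flank <- cfg@flankLen
  if (2L * flank >= len)
    stop("flankLen too large for this region: need 2*flankLen < length")
  t0 <- proc.time()[["elapsed"]]
  deadline <- t0 + cfg@timeLimitS
  mkSolution <- function(pairs, status, diagnostic = "") {
    new("TilingSolution", pairs = pairs, status = status,
        elapsedS = proc.time()[["elapsed"]] - t0, mTubes = cfg@mTubes,
        regionName = regionName(region), diagnostic = diagnostic)
  }
  if (proc.time()[["elapsed"]] >= deadline)
    return(mkSolution(.emptyPairs(), "timeout"))

  cands <- .allCandidates(region, cfg)
  fwdAll <- cands$fwd
  revAll <- cands$rev
  if (!is.null(backend)) {
    fwdAll <- applySpecificityFilter(fwdAll, backend)
    revAll <- applySpecificityFilter(revAll, backend)
  }
  fwdOrd <- orderCandidates(fwdAll, "forward", cfg@ordering)
  revOrd <- orderCandidates(revAll, "reverse", cfg@ordering)
  if (!any(fwdAll$start < flank))
    return(mkSolution(.emptyPairs(), "infeasible",
                      "no primer candidates in the first boundary window"))

  dimer <- .dimerCache(cfg@thermo)
  m <- cfg@mTubes
  fS <- fwdOrd$start; fSeq <- fwdOrd$sequence; fTm <- fwdOrd$tmC
  rE <- revOrd$end; rSeq <- revOrd$sequence; rTm <- revOrd$tmC
  compatAll <- function(seqC, members) {
    for (s in members) if (dimer(seqC, s) < cfg@dgThreshold) return(FALSE)
    TRUE
  }
  st <- new.env(parent = emptyenv())
  st$timedOut <- FALSE
  st$solution <- NULL

  ## chosen[[n+1]] = list(fi, ri, dg): indices into fwdOrd / revOrd
  extend <- function(n, chosen, tubeSeqs, tubeLastEnd, prevE1, prevE2, prevS1) {
    if (proc.time()[["elapsed"]] >= deadline) {
      st$timedOut <- TRUE
      return(FALSE)
    }
    tube <- n %% m
    ## product index is global left-to-right order: forward starts increase
    loStart <- if (n == 0L) 0L
               else max(prevE2, tubeLastEnd[tube + 1L], prevS1) + 1L
    hiStart <- if (n == 0L) flank - 1L else prevE1 - 1L
    for (fi in which(fS >= loStart & fS <= hiStart)) {
      if (!compatAll(fSeq[fi], tubeSeqs[[tube + 1L]])) next
      eLo <- max(fS[fi] + cfg@ampliconMin,
                 if (n >= 1L) prevE1 + 1L else 0L)
      eHi <- min(fS[fi] + cfg@ampliconMax, len)
      rsel <- rE >= eLo & rE <= eHi &
        abs(fTm[fi] - rTm) <= cfg@tmPairToleranceC
      for (ri in which(rsel)) {
        if (proc.time()[["elapsed"]] >= deadline) {
          st$timedOut <- TRUE
          return(FALSE)
        }
        dg <- dimer(fSeq[fi], rSeq[ri])
        if (dg < cfg@dgThreshold) next
        if (!compatAll(rSeq[ri], c(tubeSeqs[[tube + 1L]], fSeq[fi]))) next
        chosen[[n + 1L]] <- list(fi = fi, ri = ri, dg = dg)
        if (rE[ri] > len - flank) {
          st$solution <- chosen
          return(TRUE)
        }
        ts2 <- tubeSeqs
        ts2[[tube + 1L]] <- c(ts2[[tube + 1L]], fSeq[fi], rSeq[ri])
        tle2 <- tubeLastEnd
        tle2[tube + 1L] <- rE[ri]
        if (extend(n + 1L, chosen, ts2, tle2, rE[ri],
                   if (is.na(prevE1)) -1L else prevE1, fS[fi])) return(TRUE)
        if (st$timedOut) return(FALSE)
      }
    }
    FALSE
  }

  found <- extend(0L, list(), rep(list(character(0)), m), rep(-1L, m),
                  NA_integer_, -1L, -1L)
  if (found) {
    rows <- lapply(seq_along(st$solution), function(i) {
      p <- st$solution[[i]]
      .pairRow(i - 1L, m, fwdOrd[p$fi, ], revOrd[p$ri, ], p$dg)
    })
    pairs <- do.call(rbind, rows)
    rownames(pairs) <- NULL
    return(mkSolution(pairs, "solved"))
  }
  if (st$timedOut) return(mkSolution(.emptyPairs(), "timeout"))
  mkSolution(.emptyPairs(), "infeasible",
             "no compatible tiling within the candidate set")
}
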