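## Primer candidate enumeration and the per-primer screening rules:
## length 23-30 nt, GC within [0.30, 0.70] (inclusive), no homopolymer of
## 4+ bases, Tm within 0.5 C of the optimum, hairpin and homodimer dG no
## more negative than -3 kcal/mol, and no known variant under the oligo's
## 3'-terminal three template bases.

## cumulative variant counts; .variantCount(lo, hi) = variants in [lo, hi)
.variantCounter <- function(region) {
  len <- regionLength(region)
  cnt <- integer(len + 1L)
  if (length(region@variantPositions))
    cnt <- c(0L, cumsum(tabulate(region@variantPositions + 1L, nbins = len)))
  else
    cnt <- integer(len + 1L)
  function(lo, hi) cnt[hi + 1L] - cnt[lo + 1L]
}

#' Enumerate primer candidates in a window
#'
#' Generates every (start, length) combination with length between
#' `cfg@primerLenMin` and `cfg@primerLenMax` whose anchor coordinate lies in
#' the 0-based half-open window `[windowStart, windowEnd)`, and keeps those
#' passing all per-primer screening rules. Forward candidates are anchored
#' by their 5' start; reverse candidates by their 3'-most template
#' coordinate, i.e. the last base of their template footprint. Output rows
#' are ordered by ascending start, ties by ascending length -- the canonical
#' order that the traversal strategies of [orderCandidates()] permute.
#'
#' @param region a [TargetRegion-class].
#' @param windowStart,windowEnd 0-based half-open anchor window; an empty
#'   window yields an empty result.
#' @param strand `"forward"` or `"reverse"`.
#' @param cfg a [DesignConfig-class].
#'
#' @return a data.frame with columns `start`, `end` (0-based half-open
#'   template footprint), `strand`, `sequence` (the oligo 5'->3', reverse
#'   complemented for the reverse strand), `tmC`, `gc`, `hairpinDG`,
#'   `homodimerDG`, `specificityChecked` (FALSE until
#'   [applySpecificityFilter()] runs).
#' @examples
#' reg <- generateRegion(fixtureSpec(length = 1300, seed = 3),
#'                       designConfig(flankLen = 120L))
#' head(enumerateCandidates(reg, 0, 120, "forward", designConfig(flankLen = 120L)))
#' @export
enumerateCandidates <- function(region, windowStart, windowEnd,
                                strand = c("forward", "reverse"), cfg) {
  strand <- match.arg(strand)
  len <- regionLength(region)
  windowStart <- max(0L, as.integer(windowStart))
  windowEnd <- min(len, as.integer(windowEnd))
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      tmC = numeric(0), gc = numeric(0),
                      hairpinDG = numeric(0), homodimerDG = numeric(0),
                      specificityChecked = logical(0),
                      stringsAsFactors = FALSE)
  if (windowStart >= windowEnd) return(empty)

  starts <- integer(0); lens <- integer(0)
  for (L in cfg@primerLenMin:cfg@primerLenMax) {
    if (strand == "forward") {
      s <- windowStart:(windowEnd - 1L)
      s <- s[s + L <= len]
    } else {
      # anchor = last template base = end - 1 in [windowStart, windowEnd)
      e <- (windowStart + 1L):windowEnd
      s <- e - L
      s <- s[s >= 0L]
    }
    starts <- c(starts, s)
    lens <- c(lens, rep.int(L, length(s)))
  }
  if (!length(starts)) return(empty)
  ord <- order(starts, lens)
  starts <- starts[ord]; lens <- lens[ord]
  ends <- starts + lens

  tmpl <- substring(region@sequence, starts + 1L, ends)
  oligo <- if (strand == "reverse") {
    as.character(reverseComplement(DNAStringSet(tmpl)))
  } else tmpl

  # integer-exact GC bounds, then homopolymer, then the 3'-variant rule
  gcCount <- nchar(gsub("[AT]", "", oligo))
  keep <- gcCount >= cfg@gcMin * lens - 1e-9 & gcCount <= cfg@gcMax * lens + 1e-9
  hp <- sprintf("([ACGT])\\1{%d,}", cfg@maxHomopolymer)
  keep <- keep & !grepl(hp, oligo)
  varCount <- .variantCounter(region)
  zoneLo <- if (strand == "forward") ends - 3L else starts
  keep[keep] <- vapply(which(keep), function(i)
    varCount(zoneLo[i], zoneLo[i] + 3L) == 0L, logical(1L))

  starts <- starts[keep]; ends <- ends[keep]; lens <- lens[keep]
  oligo <- oligo[keep]
  if (!length(starts)) return(empty)

  tm <- meltingTemperature(oligo, cfg@thermo)
  keep <- abs(tm - cfg@optimumTmC) <= cfg@tmPairToleranceC
  starts <- starts[keep]; ends <- ends[keep]; oligo <- oligo[keep]
  tm <- tm[keep]
  if (!length(starts)) return(empty)

  hairpin <- vapply(oligo, hairpinDG, numeric(1L), cfg = cfg@thermo,
                    USE.NAMES = FALSE)
  homod <- vapply(oligo, function(o) duplexDG(o, o, cfg@thermo), numeric(1L),
                  USE.NAMES = FALSE)
  keep <- hairpin >= cfg@dgThreshold & homod >= cfg@dgThreshold
  if (!any(keep)) return(empty)

  data.frame(start = starts[keep], end = ends[keep], strand = strand,
             sequence = oligo[keep], tmC = tm[keep],
             gc = gcFraction(oligo[keep]),
             hairpinDG = hairpin[keep], homodimerDG = homod[keep],
             specificityChecked = FALSE, stringsAsFactors = FALSE)
}

#' Count potential binding sites of an oligo in a reference
#'
#' @param backend a [SpecificityBackend-class] implementation.
#' @param sequence the oligo (5'->3').
#' @return integer: number of hits (for BLAST, alignments with E-value below
#'   the cutoff; for exact matching, occurrences of the oligo or its reverse
#'   complement).
#' @export
setGeneric("querySpecificity",
           function(backend, sequence) standardGeneric("querySpecificity"))

#' @rdname querySpecificity
setMethod("querySpecificity", "ExactMatchBackend", function(backend, sequence) {
  ref <- DNAString(backend@reference)
  countPattern(DNAString(sequence), ref) +
    countPattern(reverseComplement(DNAString(sequence)), ref)
})

#' @rdname querySpecificity
setMethod("querySpecificity", "BlastBackend", function(backend, sequence) {
  if (Sys.which("blastn") == "")
    stop("blastn not found on PATH")
  qf <- tempfile(fileext = ".fa")
  on.exit(unlink(qf), add = TRUE)
  writeLines(c(">query", sequence), qf)
  out <- system2("blastn",
                 c("-task", "blastn-short", "-db", backend@dbPath,
                   "-query", qf, "-outfmt", "6", "-evalue", "10"),
                 stdout = TRUE)
  if (!length(out)) return(0L)
  ev <- as.numeric(vapply(strsplit(out, "\t"), `[`, character(1L), 11L))
  sum(ev < backend@evalueMax)
})

#' Discard candidates with more than one potential binding site
#'
#' A candidate is retained exactly when the backend reports at most one hit:
#' the hit at its own locus is expected, any second hit means possible
#' off-target amplification. Order is preserved; retained rows are marked
#' `specificityChecked = TRUE`.
#'
#' @param candidates a candidate data.frame from [enumerateCandidates()].
#' @param backend a [SpecificityBackend-class].
#' @param onUnavailable `"fail"` (default) to propagate backend errors, or
#'   `"pass"` to keep all candidates unchecked with a warning.
#'
#' @return the filtered candidate data.frame.
#' @export
applySpecificityFilter <- function(candidates, backend,
                                   onUnavailable = c("fail", "pass")) {
  onUnavailable <- match.arg(onUnavailable)
  if (nrow(candidates) == 0L) return(candidates)
  hits <- tryCatch(
    vapply(candidates$sequence, function(s) querySpecificity(backend, s),
           integer(1L), USE.NAMES = FALSE),
    error = function(e) {
      if (onUnavailable == "fail") stop(e)
      warning("specificity backend unavailable (", conditionMessage(e),
              "); candidates pass through unchecked")
      NULL
    })
  if (is.null(hits)) return(candidates)
  out <- candidates[hits <= 1L, , drop = FALSE]
  out$specificityChecked <- TRUE
  rownames(out) <- NULL
  out
}
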