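## Seeded synthetic regions. The generator plants primer-friendly windows
## (oligos rejection-sampled against the full per-primer screen) at
## positions laid out so that the planted amplicons tile the region with
## the required overlaps, then fills everything else with either random
## background or, in poison mode, homopolymer blocks that exclude all other
## candidates so exactly one tiling is feasible.

## scoped RNG: run fn under a fixed seed, restoring global state after
.withSeed <- function(seed, fn) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## Amplicon layout: forward starts s_i = s0 + i*step, amplicon length
## step + 70, giving consecutive overlaps of 70 bases and two-apart gaps of
## step - 70. In the flexible layout the last amplicon is stretched so the
## tiling ends 40 bases before the region end. The exact layout (poison
## mode) keeps every amplicon at step + 70 with step confined to
## [263, 276]: then any pair anchored at a planted-site mirror (the
## reverse-complement reading of a planted footprint, which passes every
## per-primer screen whenever the plant does) yields a product of at most
## step + 23 <= 299 or at least 2*step - 24 >= 502 bases -- outside
## [300, 500] -- so the planted tiling is the only feasible one.
.fixtureGeometry <- function(len, flank, nProducts, exact = FALSE) {
  s0 <- flank - 60L
  if (s0 < 0L) stop("flankLen must be at least 60 for fixture generation")
  if (exact) {
    ks <- if (is.na(nProducts)) 2:20 else nProducts
    for (k in ks) {
      for (step in 263:276) {
        eLast <- s0 + k * step + 70L
        if (eLast > len - flank && eLast <= len - 30L) {
          s <- s0 + (seq_len(k) - 1L) * step
          return(list(k = k, fwdStart = s, revEnd = s + step + 70L))
        }
      }
    }
    stop(sprintf(
      "no exact fixture geometry for length %d, flank %d (try length near flank - 60 + k*270 + 110)",
      len, flank))
  }
  eLast <- len - 40L
  span <- eLast - s0 - 70L
  k <- if (is.na(nProducts)) max(2L, as.integer(round(span / 330))) else nProducts
  if (k < 2L) stop("fixture too short for two products")
  step <- span %/% k
  if (step < 240L || step > 425L)
    stop(sprintf(
      "no feasible fixture geometry for length %d, flank %d, %d products (step %d)",
      len, flank, k, step))
  s <- s0 + (seq_len(k) - 1L) * step
  e <- s + step + 70L
  e[k] <- eLast
  a <- e - s
  if (any(a < 300L | a > 500L))
    stop("fixture geometry produced an amplicon outside [300, 500]")
  list(k = k, fwdStart = s, revEnd = e)
}

## Rejection-sample one planted oligo passing the full per-primer screen
## with Tm within +/- tmHalfBand of the optimum, and pairwise-compatible
## (heterodimer dG above threshold) with every previously accepted oligo.
## In trap mode the oligo is forced to start and end with a run of exactly
## three identical bases; together with a single guard base of the same
## identity placed just outside the footprint, any candidate shifted or
## extended across the footprint boundary acquires a 4-base homopolymer and
## fails the screen, so the planted oligo is the only candidate at its site.
.samplePlant <- function(cfg, accepted, tmHalfBand = 0.25, batch = 400L,
                         maxBatches = 60L, trap = FALSE) {
  L <- cfg@primerLenMin
  gc <- 0.5
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(probs)
  for (b in seq_len(maxBatches)) {
    if (trap) {
      coreLen <- L - 6L
      lead <- sample(bases, batch, replace = TRUE)
      tailb <- sample(bases, batch, replace = TRUE)
      core <- matrix(sample(bases, batch * coreLen, replace = TRUE, prob = probs),
                     nrow = batch)
      fix1 <- core[, 1L] == lead
      core[fix1, 1L] <- vapply(lead[fix1],
                               function(x) sample(setdiff(bases, x), 1L), "")
      fixN <- core[, coreLen] == tailb
      core[fixN, coreLen] <- vapply(tailb[fixN],
                                    function(x) sample(setdiff(bases, x), 1L), "")
      oligos <- paste0(strrep(lead, 3L), apply(core, 1L, paste, collapse = ""),
                       strrep(tailb, 3L))
    } else {
      mat <- matrix(sample(bases, batch * L, replace = TRUE, prob = probs),
                    nrow = batch)
      oligos <- apply(mat, 1L, paste, collapse = "")
    }
    gcc <- nchar(gsub("[AT]", "", oligos))
    keep <- gcc >= cfg@gcMin * L & gcc <= cfg@gcMax * L
    keep <- keep & !grepl(sprintf("([ACGT])\\1{%d,}", cfg@maxHomopolymer), oligos)
    oligos <- oligos[keep]
    if (!length(oligos)) next
    tm <- meltingTemperature(oligos, cfg@thermo)
    oligos <- oligos[abs(tm - cfg@optimumTmC) <= tmHalfBand]
    for (o in oligos) {
      if (hairpinDG(o, cfg@thermo) < cfg@dgThreshold) next
      if (duplexDG(o, o, cfg@thermo) < cfg@dgThreshold) next
      ok <- TRUE
      for (a in accepted) {
        if (duplexDG(o, a, cfg@thermo) < cfg@dgThreshold) { ok <- FALSE; break }
      }
      if (ok) return(o)
    }
  }
  stop("could not sample a planted oligo compatible with the accepted set")
}

.poisonBackground <- function(len) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  total <- 0L
  while (total < len) {
    b <- sample(bases, 1L)
    w <- sample(4:6, 1L)
    out <- c(out, strrep(b, w))
    total <- total + w
  }
  substr(paste(out, collapse = ""), 1L, len)
}

.randomBackground <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a seeded synthetic target region
#'
#' Builds a reproducible region in which a tiling is feasible by
#' construction: planted forward/reverse primer sites are rejection-sampled
#' against the full per-primer screen (with Tm held within 0.25 degrees C of
#' the optimum so any planted pair also meets the pair tolerance) and
#' checked for mutual heterodimer compatibility, then spliced into the
#' background at positions giving amplicons of 300-500 bases with ~70-base
#' overlaps. In poison mode the background consists of homopolymer blocks,
#' so no candidate outside the planted windows survives the screen and
#' exactly one tiling is feasible; the generator re-draws (still under the
#' spec seed) until full-region enumeration confirms the planted oligos are
#' the only candidates. In either mode each planted window is verified to
#' yield its candidate via [enumerateCandidates()] before returning.
#' Planted variants are placed outside all primer footprints.
#'
#' @param spec a [FixtureSpec-class].
#' @param cfg a [DesignConfig-class]; its `flankLen`, thresholds and optimum
#'   Tm define what "primer-friendly" means.
#' @param maxAttempts re-draw budget for poison-mode uniqueness.
#'
#' @return a [TargetRegion-class] whose `metadata` records the spec and the
#'   planted geometry (`fwdStart`, `revEnd`, planted oligo sequences).
#' @examples
#' reg <- generateRegion(fixtureSpec(length = 1300, seed = 7),
#'                       designConfig(flankLen = 120L))
#' regionLength(reg)
#' @export
generateRegion <- function(spec, cfg = designConfig(), maxAttempts = 40L) {
  validObject(spec); validObject(cfg)
  len <- spec@length
  flank <- cfg@flankLen
  if (2L * flank >= len)
    stop("fixture length must exceed twice the flank length")
  geo <- .fixtureGeometry(len, flank, spec@nProducts, exact = spec@poisonMode)
  k <- geo$k
  .withSeed(spec@seed, function() {
    for (attempt in seq_len(maxAttempts)) {
      plants <- character(0)
      for (i in seq_len(2L * k))
        plants <- c(plants, .samplePlant(cfg, plants, trap = spec@poisonMode))
      fwdOligo <- plants[seq_len(k)]
      revOligo <- plants[k + seq_len(k)]
      bg <- if (spec@poisonMode) .poisonBackground(len)
            else .randomBackground(len, spec@gcTarget)
      ch <- strsplit(bg, "")[[1L]]
      pl <- cfg@primerLenMin
      footprints <- integer(0)
      for (i in seq_len(k)) {
        fs <- geo$fwdStart[i]
        substrRange <- fs + seq_len(pl)
        ch[substrRange] <- strsplit(fwdOligo[i], "")[[1L]]
        re <- geo$revEnd[i]
        tmplRev <- strsplit(.revComp(revOligo[i]), "")[[1L]]
        ch[(re - pl + 1L):re] <- tmplRev
        if (spec@poisonMode) {
          # guard bases: boundary-crossing candidates gain a 4-homopolymer
          if (fs >= 1L) ch[fs] <- substr(fwdOligo[i], 1L, 1L)
          if (fs + pl + 1L <= len) ch[fs + pl + 1L] <- substr(fwdOligo[i], pl, pl)
          if (re - pl >= 1L) ch[re - pl] <- tmplRev[1L]
          if (re + 1L <= len) ch[re + 1L] <- tmplRev[pl]
        }
        footprints <- c(footprints, substrRange - 1L,
                        (re - pl):(re - 1L))
      }
      seq <- paste(ch, collapse = "")
      variants <- integer(0)
      nVar <- round(spec@variantDensity * len / 1000)
      if (nVar > 0L) {
        allowed <- setdiff(0:(len - 1L), footprints)
        variants <- sort(sample(allowed, min(nVar, length(allowed))))
      }
      region <- targetRegion(
        paste0("fixture_s", spec@seed), seq, flank, variants,
        metadata = list(spec = spec, fwdStart = geo$fwdStart,
                        revEnd = geo$revEnd, fwdOligo = fwdOligo,
                        revOligo = revOligo,
                        poisonMode = spec@poisonMode))
      ## every planted window must yield its candidate
      plantOK <- TRUE
      for (i in seq_len(k)) {
        fw <- enumerateCandidates(region, geo$fwdStart[i],
                                  geo$fwdStart[i] + 1L, "forward", cfg)
        rv <- enumerateCandidates(region, geo$revEnd[i] - 1L,
                                  geo$revEnd[i], "reverse", cfg)
        if (!any(fw$sequence == fwdOligo[i]) || !any(rv$sequence == revOligo[i])) {
          plantOK <- FALSE
          break
        }
      }
      if (!plantOK) next
      if (spec@poisonMode) {
        ## the only candidates must be the planted oligos and the
        ## reverse-complement mirror readings of their footprints (which
        ## pass the same screens by symmetry but, under the exact layout,
        ## can never anchor a 300-500 base product)
        fwdAll <- enumerateCandidates(region, 0L, len, "forward", cfg)
        revAll <- enumerateCandidates(region, 0L, len, "reverse", cfg)
        allowedFwd <- c(geo$fwdStart, geo$revEnd - pl)
        allowedRev <- c(geo$fwdStart + pl, geo$revEnd)
        if (!all(fwdAll$start %in% allowedFwd) ||
            !all(revAll$end %in% allowedRev)) next
        if (length(bruteForceTilings(region, cfg)) != 1L) next
      }
      return(region)
    }
    stop("failed to generate a fixture satisfying all checks in ",
         maxAttempts, " attempts (seed ", spec@seed, ")")
  })
}

#' Exhaustively enumerate all feasible tilings (small fixtures only)
#'
#' The search-independent oracle: plain recursion over every admissible pair
#' sequence under the same positional, pair and per-tube compatibility
#' rules, collecting every feasible tiling rather than stopping at the
#' first. Each returned solution is re-checked by [verifySolution()].
#' Refuses to run when the candidate set is large, since the enumeration is
#' exponential.
#'
#' @param region a [TargetRegion-class].
#' @param cfg a [DesignConfig-class].
#' @param backend optional [SpecificityBackend-class].
#' @param maxCandidates guard on total candidate count (default 200).
#'
#' @return a list of [TilingSolution-class] objects (possibly empty), in
#'   canonical enumeration order.
#' @export
bruteForceTilings <- function(region, cfg, backend = NULL,
                              maxCandidates = 200L) {
  validObject(region); validObject(cfg)
  len <- regionLength(region)
  flank <- cfg@flankLen
  fwdAll <- enumerateCandidates(region, 0L, len - cfg@ampliconMin + 1L,
                                "forward", cfg)
  revAll <- enumerateCandidates(region, cfg@ampliconMin - 1L, len,
                                "reverse", cfg)
  if (!is.null(backend)) {
    fwdAll <- applySpecificityFilter(fwdAll, backend)
    revAll <- applySpecificityFilter(revAll, backend)
  }
  if (nrow(fwdAll) + nrow(revAll) > maxCandidates)
    stop("candidate set too large for exhaustive enumeration (",
         nrow(fwdAll) + nrow(revAll), " > ", maxCandidates,
         "); shrink the fixture")
  m <- cfg@mTubes
  solutions <- list()

  recurse <- function(n, chosen, tubeSeqs, tubeLastEnd) {
    tube <- n %% m
    prevE1 <- if (n >= 1L) chosen[[n]]$rev$end else NA_integer_
    prevE2 <- if (n >= 2L) chosen[[n - 1L]]$rev$end else -1L
    prevS1 <- if (n >= 1L) chosen[[n]]$fwd$start else -1L
    loStart <- if (n == 0L) 0L
               else max(prevE2, tubeLastEnd[tube + 1L], prevS1) + 1L
    hiStart <- if (n == 0L) flank - 1L else prevE1 - 1L
    for (fi in which(fwdAll$start >= loStart & fwdAll$start <= hiStart)) {
      fwd <- fwdAll[fi, ]
      if (!tubeCompatible(fwd$sequence, tubeSeqs[[tube + 1L]], cfg)) next
      eLo <- max(fwd$start + cfg@ampliconMin,
                 if (n >= 1L) prevE1 + 1L else 0L)
      eHi <- min(fwd$start + cfg@ampliconMax, len)
      for (ri in which(revAll$end >= eLo & revAll$end <= eHi)) {
        rev <- revAll[ri, ]
        if (abs(fwd$tmC - rev$tmC) > cfg@tmPairToleranceC) next
        dg <- duplexDG(fwd$sequence, rev$sequence, cfg@thermo)
        if (dg < cfg@dgThreshold) next
        if (!tubeCompatible(rev$sequence,
                            c(tubeSeqs[[tube + 1L]], fwd$sequence), cfg)) next
        chosen[[n + 1L]] <- list(fwd = fwd, rev = rev, dg = dg)
        if (rev$end > len - flank) {
          rows <- lapply(seq_along(chosen), function(i) {
            p <- chosen[[i]]
            .pairRow(i - 1L, m, p$fwd, p$rev, p$dg)
          })
          pairs <- do.call(rbind, rows)
          rownames(pairs) <- NULL
          solutions[[length(solutions) + 1L]] <<- new(
            "TilingSolution", pairs = pairs, status = "solved",
            elapsedS = 0, mTubes = m, regionName = regionName(region))
        } else {
          ts2 <- tubeSeqs
          ts2[[tube + 1L]] <- c(ts2[[tube + 1L]], fwd$sequence, rev$sequence)
          tle2 <- tubeLastEnd
          tle2[tube + 1L] <- rev$end
          recurse(n + 1L, chosen, ts2, tle2)
        }
      }
    }
  }

  recurse(0L, list(), rep(list(character(0)), m), rep(-1L, m))
  for (s in solutions) {
    ok <- verifySolution(s, region, cfg)
    if (!ok)
      stop("internal error: enumerated tiling fails verification: ",
           paste(attr(ok, "failures"), collapse = "; "))
  }
  solutions
}
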