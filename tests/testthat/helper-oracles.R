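# Independent oracles, written before the tested code paths and kept free
# of package internals: they read the same published parameter table but do
# their own parsing, their own alignment enumeration and their own
# arithmetic, so agreement is evidence rather than tautology.

oracleNN <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      path <- system.file("extdata", "nn_santalucia1998.tsv",
                          package = "mpxdesign")
      raw <- read.table(path, header = TRUE, sep = "\t",
                        comment.char = "#", stringsAsFactors = FALSE)
      tab <<- raw
    }
    tab
  }
})

oracleComp <- c(A = "T", C = "G", G = "C", T = "A")

oracleRevComp <- function(s) {
  paste(rev(oracleComp[strsplit(s, "")[[1]]]), collapse = "")
}

# plain-loop nearest-neighbor Tm (salt-corrected entropy, CT/4, symmetry
# handling for self-complementary oligos)
oracleTm <- function(seq, mono = 50, div = 1.5, dntp = 0.6, oligoNM = 50) {
  nn <- oracleNN()
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    row <- nn[nn$pair == paste0(ch[i], ch[i + 1]), ]
    dH <- dH + row$dH; dS <- dS + row$dS
  }
  for (b in ch[c(1, n)]) {
    key <- if (b %in% c("G", "C")) "initGC" else "initAT"
    dH <- dH + nn[nn$pair == key, "dH"]
    dS <- dS + nn[nn$pair == key, "dS"]
  }
  selfc <- n %% 2 == 0 && seq == oracleRevComp(seq)
  if (selfc) dS <- dS + nn[nn$pair == "sym", "dS"]
  naEq <- (mono + 120 * sqrt(max(div - dntp, 0))) / 1000
  dS <- dS + 0.368 * (n - 1) * log(naEq)
  ct <- oligoNM * 1e-9
  x <- if (selfc) 1 else 4
  dH * 1000 / (dS + 1.9872 * log(ct / x)) - 273.15
}

oracleStackDG <- function(tempC = 37) {
  nn <- oracleNN()
  st <- nn[nchar(nn$pair) == 2, ]
  structure(st$dH - (tempC + 273.15) * st$dS / 1000, names = st$pair)
}

oracleInitDG <- function(tempC = 37) {
  nn <- oracleNN()
  g <- nn[nn$pair == "initGC", ]
  a <- nn[nn$pair == "initAT", ]
  c(GC = g$dH - (tempC + 273.15) * g$dS / 1000,
    AT = a$dH - (tempC + 273.15) * a$dS / 1000)
}

# exhaustive duplex: every offset of a against the reverse complement of b,
# every contiguous window of >= 4 complementary pairs (not only maximal
# runs), scored as stacks plus both terminal initiation terms
oracleDuplexDG <- function(a, b, tempC = 37) {
  sg <- oracleStackDG(tempC); ig <- oracleInitDG(tempC)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(oracleRevComp(b), "")[[1]]
  nA <- length(av); nB <- length(bv)
  best <- 0
  for (off in (-(nB - 1)):(nA - 1)) {
    for (i in 1:nA) {
      j <- i - off
      if (j < 1 || j > nB) next
      wMax <- min(nA - i + 1, nB - j + 1)
      if (wMax < 4) next
      for (w in 4:wMax) {
        ia <- i:(i + w - 1); jb <- ia - off
        if (!all(av[ia] == bv[jb])) break
        run <- av[ia]
        dg <- sum(sg[paste0(run[-w], run[-1])])
        for (t in run[c(1, w)])
          dg <- dg + ig[[if (t %in% c("G", "C")) "GC" else "AT"]]
        if (dg < best) best <- dg
      }
    }
  }
  best
}

# exhaustive hairpin: every 5' stem start, 3' stem end and stem length with
# all pairs complementary and >= 3 loop bases; stem stacks + loop penalty
oracleHairpinDG <- function(seq, tempC = 37, loopPenalty = 3.5) {
  sg <- oracleStackDG(tempC)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0
  if (n < 9) return(best)
  for (i in 1:n) {
    for (j in i:n) {
      for (k in 3:n) {
        if (j - i - 2 * k + 1 < 3) break          # loop too small
        if (i + k - 1 > n || j - k + 1 < 1) break
        pairsOK <- all(ch[i:(i + k - 1)] ==
                         oracleComp[ch[j:(j - k + 1)]])
        if (!pairsOK) next
        stem <- ch[i:(i + k - 1)]
        dg <- sum(sg[paste0(stem[-k], stem[-1])]) + loopPenalty
        if (dg < best) best <- dg
      }
    }
  }
  best
}

# independently coded per-primer screening predicate (candidate filters)
oraclePrimerOK <- function(oligo, start, end, strand, regionSeq,
                           variantPositions, optimumTm, lenMin = 23,
                           lenMax = 30, gcMin = 0.30, gcMax = 0.70,
                           maxRun = 3, tmBand = 0.5, dgFloor = -3) {
  L <- nchar(oligo)
  if (L < lenMin || L > lenMax) return(FALSE)
  ch <- strsplit(oligo, "")[[1]]
  gc <- sum(ch %in% c("G", "C")) / L
  if (gc < gcMin || gc > gcMax) return(FALSE)
  run <- 1; maxr <- 1
  for (i in 2:L) {
    run <- if (ch[i] == ch[i - 1]) run + 1 else 1
    if (run > maxr) maxr <- run
  }
  if (maxr > maxRun) return(FALSE)
  if (abs(oracleTm(oligo) - optimumTm) > tmBand) return(FALSE)
  if (oracleHairpinDG(oligo) < dgFloor) return(FALSE)
  if (oracleDuplexDG(oligo, oligo) < dgFloor) return(FALSE)
  zone <- if (strand == "forward") (end - 3):(end - 1) else start:(start + 2)
  if (any(variantPositions %in% zone)) return(FALSE)
  TRUE
}

randomOligo <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
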