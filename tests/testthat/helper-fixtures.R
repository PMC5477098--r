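# Session-level fixture cache: generating a region involves rejection
# sampling and a verification search, so each distinct fixture is built once
# per test run and shared.

.fixtureStore <- new.env(parent = emptyenv())

cachedFixture <- function(seed, length = 1300, flank = 120, poison = FALSE,
                          variantDensity = 0, gcTarget = 0.5) {
  key <- paste(seed, length, flank, poison, variantDensity, gcTarget)
  reg <- .fixtureStore[[key]]
  if (is.null(reg)) {
    cfg <- designConfig(flankLen = as.integer(flank))
    reg <- generateRegion(
      fixtureSpec(length = length, gcTarget = gcTarget, seed = seed,
                  variantDensity = variantDensity, poisonMode = poison),
      cfg)
    .fixtureStore[[key]] <- reg
  }
  reg
}

quickConfig <- function(flank = 120, ...) {
  designConfig(flankLen = as.integer(flank), timeLimitS = 60, ...)
}

# A fixture solvable only with the wide (240-base) boundary window: its
# first planted forward site sits at base 180, and the first 126 bases are
# overwritten with alternating homopolymer quads so that no candidate can
# start before base 120 (any such oligo spans 4 identical consecutive
# bases).
longOnlyFixture <- function(seed) {
  key <- paste("longOnly", seed)
  reg <- .fixtureStore[[key]]
  if (is.null(reg)) {
    base <- cachedFixture(seed, length = 1300, flank = 240)
    seqStr <- regionSequence(base)
    strip <- substr(strrep("AAAACCCC", 16L), 1L, 126L)
    substr(seqStr, 1L, 126L) <- strip
    reg <- targetRegion(paste0(regionName(base), "_longOnly"), seqStr, 240L,
                        metadata = base@metadata)
    .fixtureStore[[key]] <- reg
  }
  reg
}
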