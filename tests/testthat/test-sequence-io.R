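# Target region ingest, validation and round-trips.

writeFasta <- function(seq, name = "seq") {
  path <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), path)
  path
}

test_that("a single-record FASTA with flanks becomes a valid region", {
  fa <- writeFasta(strrep("ACGT", 525), "exon1")  # 2100 bases
  reg <- readTargetRegion(fa, flankLen = 240)
  expect_s4_class(reg, "TargetRegion")
  expect_identical(regionName(reg), "exon1")
  expect_identical(regionLength(reg), 2100L)
  expect_identical(flankLen(reg), 240L)
  expect_identical(variantPositions(reg), integer(0))
})

test_that("lowercase input is uppercased on ingest", {
  fa <- writeFasta(tolower(strrep("acgt", 300)))
  reg <- readTargetRegion(fa, flankLen = 120)
  expect_identical(regionSequence(reg), strrep("ACGT", 300))
})

test_that("multi-record FASTA and ambiguity codes are rejected with detail", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("ACGT", 200), ">b", strrep("ACGT", 200)), path)
  expect_error(readTargetRegion(path, 120), "one FASTA record.*2")
  fa <- writeFasta(paste0("ACGTACG", "N", strrep("ACGT", 300)))
  expect_error(readTargetRegion(fa, 120), "'N' at position 7")
})

test_that("oversized flanks violate the window invariant", {
  fa <- writeFasta(strrep("ACGT", 100))  # 400 bases
  expect_error(readTargetRegion(fa, 200), "2\\*flankLen < length")
})

test_that("BED intervals contribute one variant position per covered base", {
  fa <- writeFasta(strrep("ACGT", 600))  # 2400 bases
  bed <- tempfile(fileext = ".bed")
  writeLines(c("seq\t10\t11", "seq\t100\t104"), bed)
  reg <- readTargetRegion(fa, 240, bed)
  expect_identical(variantPositions(reg), c(10L, 100L, 101L, 102L, 103L))
  # total positions == sum of interval widths
  expect_identical(length(variantPositions(reg)), 1L + 4L)
})

test_that("out-of-range variant intervals are rejected", {
  fa <- writeFasta(strrep("ACGT", 300))  # 1200 bases
  bed <- tempfile(fileext = ".bed")
  writeLines("seq\t1190\t1210", bed)
  expect_error(readTargetRegion(fa, 120, bed), "outside the sequence")
})

test_that("write/read round-trip reproduces the region exactly", {
  reg <- targetRegion("roundtrip", strrep("ACGTTGCA", 200), 240,
                      variantPositions = c(5L, 99L, 1200L))
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  writeTargetRegion(reg, fa, bed)
  back <- readTargetRegion(fa, 240, bed)
  expect_identical(regionName(back), regionName(reg))
  expect_identical(regionSequence(back), regionSequence(reg))
  expect_identical(variantPositions(back), variantPositions(reg))
})

test_that("variant positions inside the region are validated at construction", {
  expect_error(targetRegion("x", strrep("ACGT", 200), 120,
                            variantPositions = 900L),
               "0 <= p < length")
})
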