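## Reading and writing target regions. FASTA handling goes through
## Biostrings, BED through rtracklayer; both accept plain or gzipped files.

#' Read a target region from FASTA (and optionally variants from BED)
#'
#' The FASTA file must contain exactly one record: the continuous target
#' sequence with its upstream/downstream flanking sequence already included.
#' Lowercase bases are uppercased; IUPAC ambiguity codes are rejected
#' because every downstream thermodynamic computation assumes unambiguous
#' bases. Variant intervals are read as 0-based half-open BED; an interval
#' of width w contributes w point positions (variant alleles/types are
#' ignored -- the screening rule is purely positional).
#'
#' @param fastaPath path to a single-record FASTA (optionally gzipped).
#' @param flankLen boundary window length, bases; must satisfy
#'   `2 * flankLen < length`.
#' @param variantBedPath optional path to a BED file of known variants;
#'   intervals must lie within the sequence.
#'
#' @return a validated [TargetRegion-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", strrep("ACGT", 600)), fa)
#' reg <- readTargetRegion(fa, flankLen = 240)
#' @export
readTargetRegion <- function(fastaPath, flankLen, variantBedPath = NULL) {
  dss <- readDNAStringSet(fastaPath)
  if (length(dss) != 1L)
    stop("expected exactly one FASTA record, found ", length(dss))
  name <- strsplit(names(dss)[1L], "\\s+")[[1L]][1L]
  seq <- toupper(as.character(dss[[1L]]))
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L)
    stop(sprintf("non-ACGT character '%s' at position %d (0-based)",
                 substr(seq, bad, bad), bad - 1L))
  variants <- integer(0)
  if (!is.null(variantBedPath)) {
    gr <- rtracklayer::import(variantBedPath, format = "BED")
    if (length(gr)) {
      s <- GenomicRanges::start(gr) - 1L   # back to 0-based
      e <- GenomicRanges::end(gr)          # half-open end
      if (any(s < 0L) || any(e > nchar(seq)))
        stop("variant interval outside the sequence [0, ", nchar(seq), ")")
      variants <- unlist(mapply(function(a, b) seq.int(a, b - 1L), s, e,
                                SIMPLIFY = FALSE))
    }
  }
  targetRegion(name, seq, flankLen, variants)
}

#' Write a target region back to FASTA (and its variants to BED)
#'
#' The written pair round-trips: re-reading with [readTargetRegion()] at the
#' same `flankLen` reconstructs an identical region.
#'
#' @param region a [TargetRegion-class].
#' @param fastaPath output FASTA path.
#' @param bedPath optional output BED path for the variant positions (one
#'   0-based half-open single-base interval per position).
#'
#' @return invisibly, `fastaPath`.
#' @export
writeTargetRegion <- function(region, fastaPath, bedPath = NULL) {
  dss <- DNAStringSet(structure(region@sequence, names = region@name))
  writeXStringSet(dss, fastaPath)
  if (!is.null(bedPath)) {
    vp <- region@variantPositions
    lines <- if (length(vp)) {
      paste(region@name, vp, vp + 1L, sep = "\t")
    } else character(0)
    writeLines(lines, bedPath)
  }
  invisible(fastaPath)
}
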