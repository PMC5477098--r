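## Serialization of solved designs: BED6 amplicon tracks (0-based
## half-open; the score column carries the tube index, a documented
## convention since BED has no tube concept) and a human-readable TSV with
## 1-based inclusive coordinates -- the single place the package leaves its
## internal 0-based half-open convention.

#' Per-primer report table for a solved design
#'
#' @param solution a solved [TilingSolution-class].
#' @param region the designed [TargetRegion-class].
#' @param cfg the [DesignConfig-class] used.
#'
#' @return a data.frame with two rows per pair (forward then reverse):
#'   `tube`, `productIndex`, `role`, `start`, `end` (1-based inclusive),
#'   `length`, `sequence`, `tmC`, `gc`, `hairpinDG`, `homodimerDG`.
#' @export
designReport <- function(solution, region, cfg) {
  if (solution@status != "solved")
    stop("cannot report a solution with status '", solution@status, "'")
  p <- solution@pairs
  one <- function(i, role) {
    pre <- if (role == "forward") "fwd" else "rev"
    g <- function(col) p[[paste0(pre, col)]][i]
    data.frame(tube = p$tube[i], productIndex = p$productIndex[i],
               role = role,
               start = g("Start") + 1L, end = g("End"),
               length = g("End") - g("Start"),
               sequence = g("Seq"), tmC = g("Tm"), gc = g("GC"),
               hairpinDG = g("HairpinDG"), homodimerDG = g("HomodimerDG"),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(p)), function(i)
    rbind(one(i, "forward"), one(i, "reverse"))))
  rownames(rows) <- NULL
  rows
}

#' Write amplicons of a solved design as BED6
#'
#' One line per amplicon, 0-based half-open, name `p<productIndex>`, the
#' score column carrying the (0-based) tube index, strand `+`.
#'
#' @param solution a solved [TilingSolution-class].
#' @param regionName chromosome/sequence name for column 1.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeAmpliconBed <- function(solution, regionName, path) {
  if (solution@status != "solved")
    stop("cannot write BED for a solution with status '", solution@status, "'")
  p <- solution@pairs
  lines <- sprintf("%s\t%d\t%d\tp%d\t%d\t+", regionName,
                   p$ampliconStart, p$ampliconEnd, p$productIndex, p$tube)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write the per-primer TSV report
#'
#' Fixed column order, 1-based inclusive coordinates, floats to two
#' decimals, UTF-8 with LF line endings; byte-identical for a fixed report.
#'
#' @param report a data.frame from [designReport()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePrimerTsv <- function(report, path) {
  header <- paste(c("tube", "product_index", "role", "start", "end",
                    "length", "sequence", "tm_C", "gc", "hairpin_dG",
                    "homodimer_dG"), collapse = "\t")
  lines <- sprintf("%d\t%d\t%s\t%d\t%d\t%d\t%s\t%.2f\t%.2f\t%.2f\t%.2f",
                   report$tube, report$productIndex, report$role,
                   report$start, report$end, report$length, report$sequence,
                   report$tmC, report$gc, report$hairpinDG,
                   report$homodimerDG)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}
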