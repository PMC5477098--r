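## Benchmark harness: success rates, time-to-first-solution and pair counts
## over a factorial grid of (flank length x time limit) batches, candidate
## orderings, and tube counts, with Fisher's exact comparisons of success
## between groups.

#' Build a benchmark cell grid
#'
#' The default grid reproduces the 48-cell evaluation layout: three
#' setting batches (short flank with the base time limit, short flank with
#' twice the base limit, long flank with the base limit) crossed with the
#' four candidate orderings and tube counts 2-5. Time limits are parameters
#' rather than constants because wall-clock behavior is hardware-dependent.
#'
#' @param shortFlank,longFlank boundary window lengths, bases.
#' @param baseTimeLimitS base search budget, seconds.
#' @param orderings candidate traversal strategies to include.
#' @param tubeCounts tube counts to include.
#'
#' @return a data.frame of cells with columns `cell`, `batch`, `flankLen`,
#'   `timeLimitS`, `ordering`, `mTubes`.
#' @examples
#' nrow(benchmarkGrid())   # 48
#' @export
benchmarkGrid <- function(shortFlank = 120L, longFlank = 240L,
                          baseTimeLimitS = 240,
                          orderings = orderingStrategies(),
                          tubeCounts = 2:5) {
  batches <- data.frame(
    batch = c("Short240", "Short480", "Long240"),
    flankLen = c(shortFlank, shortFlank, longFlank),
    timeLimitS = c(baseTimeLimitS, 2 * baseTimeLimitS, baseTimeLimitS),
    stringsAsFactors = FALSE)
  grid <- expand.grid(batch = batches$batch, ordering = orderings,
                      mTubes = tubeCounts, stringsAsFactors = FALSE)
  grid <- merge(grid, batches, by = "batch", sort = FALSE)
  grid <- grid[order(match(grid$batch, batches$batch),
                     match(grid$ordering, orderings), grid$mTubes), ]
  grid$cell <- sprintf("%s_%s_%dt", grid$batch, grid$ordering, grid$mTubes)
  rownames(grid) <- NULL
  grid[, c("cell", "batch", "flankLen", "timeLimitS", "ordering", "mTubes")]
}

#' Run the benchmark over regions and cells
#'
#' Runs [designMultiplex()] for every (region, cell) combination, deriving
#' each cell's configuration from `cfgBase` by overriding flank length, time
#' limit, ordering and tube count.
#'
#' @param regions a list of [TargetRegion-class] objects; names (or
#'   sequential ids) label the rows.
#' @param cells a cell grid from [benchmarkGrid()] (or any data.frame with
#'   its columns).
#' @param cfgBase the base [DesignConfig-class] supplying every other
#'   parameter.
#' @param backend optional [SpecificityBackend-class] passed through.
#'
#' @return a data.frame with one row per region x cell: the cell columns
#'   plus `regionId`, `status`, `elapsedS`, `nPairs`.
#' @export
runBenchmark <- function(regions, cells, cfgBase = designConfig(),
                         backend = NULL) {
  if (!length(regions)) stop("regions must be non-empty")
  ids <- names(regions)
  if (is.null(ids)) ids <- sprintf("region%02d", seq_along(regions))
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cfg <- cfgBase
    cfg@flankLen <- as.integer(cell$flankLen)
    cfg@timeLimitS <- as.numeric(cell$timeLimitS)
    cfg@ordering <- as.character(cell$ordering)
    cfg@mTubes <- as.integer(cell$mTubes)
    validObject(cfg)
    for (ri in seq_along(regions)) {
      sol <- designMultiplex(regions[[ri]], cfg, backend)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell$cell, batch = cell$batch, flankLen = cell$flankLen,
        timeLimitS = cell$timeLimitS, ordering = cell$ordering,
        mTubes = cell$mTubes, regionId = ids[ri],
        status = solutionStatus(sol), elapsedS = elapsedSeconds(sol),
        nPairs = nrow(solutionPairs(sol)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate benchmark rows per cell
#'
#' @param rows a data.frame from [runBenchmark()].
#' @return one row per cell with `successRate` (solved / total),
#'   `medianElapsedS` and `medianPairs` over the solved runs (NA when none
#'   solved).
#' @export
aggregateBenchmark <- function(rows) {
  agg <- lapply(split(rows, rows$cell), function(d) {
    solved <- d[d$status == "solved", , drop = FALSE]
    data.frame(cell = d$cell[1L], batch = d$batch[1L],
               flankLen = d$flankLen[1L], timeLimitS = d$timeLimitS[1L],
               ordering = d$ordering[1L], mTubes = d$mTubes[1L],
               nRegions = nrow(d),
               successRate = nrow(solved) / nrow(d),
               medianElapsedS = if (nrow(solved)) median(solved$elapsedS) else NA_real_,
               medianPairs = if (nrow(solved)) median(solved$nPairs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Fisher's exact comparison of success between two groups
#'
#' Two-sided Fisher's exact test on the 2x2 solved/unsolved table of two
#' groups of benchmark rows.
#'
#' @param groupA,groupB data.frames of benchmark rows (with a `status`
#'   column).
#' @return the two-sided p-value.
#' @examples
#' a <- data.frame(status = rep(c("solved", "timeout"), c(5, 5)))
#' b <- data.frame(status = rep(c("solved", "timeout"), c(5, 5)))
#' compareSuccess(a, b)   # identical groups -> p = 1
#' @export
compareSuccess <- function(groupA, groupB) {
  if (!nrow(groupA) || !nrow(groupB))
    stop("both groups must be non-empty")
  tab <- rbind(
    c(sum(groupA$status == "solved"), sum(groupA$status != "solved")),
    c(sum(groupB$status == "solved"), sum(groupB$status != "solved")))
  fisher.test(tab, alternative = "two.sided")$p.value
}
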