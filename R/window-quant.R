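## Core quantification: per-window read counts, depth normalization and
## the IP/input log2 ratio that serves as the enrichment signal.

#' Count reads into grid windows
#'
#' Assigns each mapped read to exactly one window: the window containing
#' the midpoint of its aligned span (\code{start + alignedLength %/% 2} on
#' the 0-based scale).  With overlapping (sliding) windows the window with
#' the largest start not exceeding the midpoint is used, so the assignment
#' is always unique and total counts are conserved.  Reads on chromosomes
#' absent from the grid are tallied as skipped, not an error.
#'
#' @param reads Read table ([readAlignments()]); only mapped reads are
#'   counted.  Apply [filterByLength()] beforehand.
#' @param grid Target [WindowGrid-class].
#' @param sampleId Sample label for the track.
#' @return A [WindowTrack-class] with units \code{"raw_count"} and
#'   \code{librarySize} equal to the number of assigned reads;
#'   \code{attr(track, "skipped")} counts reads on unknown chromosomes.
#' @export
countReads <- function(reads, grid, sampleId = "sample") {
  stopifnot(is(grid, "WindowGrid"))
  reads <- reads[reads$mapped, , drop = FALSE]
  cs <- grid@chromSizes
  known <- reads$chrom %in% names(cs)
  skipped <- sum(!known)
  reads <- reads[known, , drop = FALSE]
  nwin <- windowCount(grid)
  values <- numeric(nwin)
  if (nrow(reads)) {
    offsets <- .chromOffsets(grid)
    nByChrom <- vapply(cs, .nWindowsChrom, numeric(1),
                       windowSize = grid@windowSize, step = grid@step)
    mid0 <- (reads$start - 1L) + reads$alignedLength %/% 2L
    mid0 <- pmin(pmax(mid0, 0), cs[reads$chrom] - 1)
    local <- pmin(mid0 %/% grid@step, nByChrom[reads$chrom] - 1)
    idx <- offsets[reads$chrom] + local + 1
    tab <- tabulate(idx, nbins = nwin)
    values <- as.numeric(tab)
  }
  track <- WindowTrack(grid, values, units = "raw_count",
                       sampleId = sampleId, librarySize = sum(values))
  attr(track, "skipped") <- skipped
  track
}

#' Depth-normalize a count track to counts per million
#'
#' @param track A [WindowTrack-class] with units \code{"raw_count"}.
#' @return The same track scaled to \code{value * 1e6 / librarySize} with
#'   units \code{"cpm"}.
#' @export
toCPM <- function(track) {
  stopifnot(is(track, "WindowTrack"))
  if (track@units != "raw_count")
    stop(sprintf("toCPM expects raw_count input, got '%s'", track@units))
  if (is.na(track@librarySize) || track@librarySize == 0)
    stop("empty library: cannot normalize a track with library size 0")
  WindowTrack(track@grid, track@values * 1e6 / track@librarySize,
              units = "cpm", sampleId = track@sampleId,
              librarySize = track@librarySize)
}

#' Log2 IP/input ratio track
#'
#' Computes \code{log2((ip + pseudocount) / (input + pseudocount))} per
#' window on depth-normalized tracks.  Sequencing the matched input
#' alongside the IP provides an internal reference, so the ratio cancels
#' shared background and makes karyotypically different samples
#' comparable; windows empty in both samples get a ratio of exactly 0.
#'
#' @param ip,input [WindowTrack-class] objects with units \code{"cpm"} on
#'   an identical grid.
#' @param pseudocount Added to both numerator and denominator (CPM scale,
#'   default 0.5) so sparse windows stay finite.
#' @return A [WindowTrack-class] with units \code{"log2_ratio"}.
#' @export
log2Ratio <- function(ip, input, pseudocount = 0.5) {
  stopifnot(is(ip, "WindowTrack"), is(input, "WindowTrack"),
            pseudocount > 0)
  if (ip@units != "cpm" || input@units != "cpm")
    stop("log2Ratio expects cpm tracks; apply toCPM first")
  .checkSameGrid(ip, input)
  vals <- log2((ip@values + pseudocount) / (input@values + pseudocount))
  WindowTrack(ip@grid, vals, units = "log2_ratio",
              sampleId = sprintf("%s_vs_%s", ip@sampleId, input@sampleId))
}
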