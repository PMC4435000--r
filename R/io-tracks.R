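## bedGraph and peak (BED6+2) serialization.  On-disk coordinates are
## 0-based half-open; the in-memory GRanges representation is 1-based.

#' Write a window track as bedGraph
#'
#' One line per window in grid order, values rendered with six decimal
#' places.  A write/read round trip through [readBedGraph()] restores the
#' values within 1e-6 on tiling grids.
#'
#' @param track A [WindowTrack-class] with finite values.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "WindowTrack"))
  if (any(!is.finite(track@values)))
    stop("track values must be finite for bedGraph output")
  gr <- gridWindows(track@grid)
  lines <- sprintf("%s\t%d\t%d\t%.6f", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr), track@values)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a bedGraph onto a window grid
#'
#' Source intervals aligned to the grid are taken as-is; others are
#' resampled as the length-weighted mean of the source values overlapping
#' each window.  Windows with no source coverage get value 0 and are
#' flagged in the \code{covered} attribute.
#'
#' @param path bedGraph file.
#' @param grid Target [WindowGrid-class].
#' @param units Units tag to attach (source files carry no units; default
#'   \code{"cpm"}).
#' @param sampleId Sample label for the track.
#' @return A [WindowTrack-class]; \code{attr(track, "covered")} is a logical
#'   vector marking windows with source coverage.
#' @export
readBedGraph <- function(path, grid, units = "cpm",
                         sampleId = basename(path)) {
  src <- rtracklayer::import(path, format = "bedGraph")
  cs <- grid@chromSizes
  chr <- as.character(seqnames(src))
  bad <- !(chr %in% names(cs)) | end(src) > cs[chr] | start(src) < 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("bedGraph interval %s:%d-%d lies outside the grid genome",
                 chr[i], start(src)[i] - 1L, end(src)[i]))
  }
  win <- gridWindows(grid)
  hits <- findOverlaps(src, win)
  ovl <- width(pintersect(src[queryHits(hits)], win[subjectHits(hits)]))
  num <- rowsum(mcols(src)$score[queryHits(hits)] * ovl,
                group = subjectHits(hits))
  den <- rowsum(ovl, group = subjectHits(hits))
  values <- numeric(length(win))
  covered <- logical(length(win))
  idx <- as.integer(rownames(num))
  values[idx] <- num[, 1] / den[, 1]
  covered[idx] <- TRUE
  track <- WindowTrack(grid, values, units = units, sampleId = sampleId)
  attr(track, "covered") <- covered
  track
}

#' Write called peaks as BED6+2
#'
#' Columns: chrom, start, end, name (\code{peak_N}), score, strand
#' (\code{"."}), log2 enrichment, q-value.  The display score rescales the
#' log2 enrichment as \code{round(min(1000, 250 * log2_enrichment))},
#' clamped below at 0.
#'
#' @param peaks A [GRanges] from [callPeaks()], sorted by (chrom, start).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(peaks) == 0L) return(invisible(path))
  chr <- as.character(seqnames(peaks))
  ord <- order(match(chr, unique(chr)), start(peaks))
  if (!identical(ord, seq_along(peaks)))
    stop("peaks must be sorted by (chrom, start) before writing")
  score <- pmax(0, round(pmin(1000, 250 * peaks$log2Enrichment)))
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.\t%.4f\t%.3g",
                   chr, start(peaks) - 1L, end(peaks),
                   seq_along(peaks), score,
                   peaks$log2Enrichment, peaks$qValue)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
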