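## Window-level enrichment peak calling.  Each window is tested with a
## one-sided Poisson test of the IP count against a depth-scaled input
## expectation; p-values are corrected by Benjamini-Hochberg across all
## windows and runs of adjacent significant windows are merged into peaks
## ("the most strongly modified regions" as a binary output).

## Centered running mean with window +/- k, computed per chromosome
## segment; edges use the available span.
.runningMean <- function(x, k) {
  if (k <= 0L || length(x) <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Upper Poisson tail P(X >= obs | lambda).
.poissonTail <- function(obs, lambda)
  ppois(obs - 1, lambda, lower.tail = FALSE)

#' Call enrichment peaks from IP and input count tracks
#'
#' Per window, the IP count is tested against the expectation
#' \code{scale * max(input_i, local mean input)} where
#' \code{scale = librarySize(ip) / librarySize(input)} and the local mean
#' is taken over \code{smoothWindows} windows on either side (smoothing the
#' sparse input stabilises the per-window expectation, in the spirit of the
#' local-lambda background of ChIP-seq callers).  The expectation is floored
#' at \code{floorFraction} times the genome-mean IP rate so empty windows
#' cannot produce unbounded significance.  One-sided Poisson p-values are
#' Benjamini-Hochberg adjusted across all windows; windows with
#' \code{q <= alpha} and a log2 CPM ratio of at least \code{minLog2} are
#' significant, and runs of adjacent significant windows merge into peaks.
#'
#' @param ip,input [WindowTrack-class] objects with units
#'   \code{"raw_count"} on an identical grid and positive library sizes.
#' @param minLog2 Minimum log2 CPM enrichment of a significant window
#'   (default 1, i.e. two-fold).
#' @param alpha FDR threshold (default 0.05).
#' @param floorFraction Floor on the expectation, as a fraction of the
#'   genome-mean IP rate per window (default 0.1).
#' @param pseudocount Pseudocount for the log2 CPM ratio (default 0.5).
#' @param smoothWindows Half-width, in windows, of the input smoothing
#'   span (default 25, i.e. 5 kb at 200 bp windows; 0 disables smoothing).
#' @return A [GRanges] of peaks sorted by (chrom, start) with metadata
#'   columns \code{nWindows}, \code{log2Enrichment} (maximum window log2
#'   ratio) and \code{qValue} (minimum window q).
#' @export
callPeaks <- function(ip, input, minLog2 = 1, alpha = 0.05,
                      floorFraction = 0.1, pseudocount = 0.5,
                      smoothWindows = 25L) {
  stopifnot(is(ip, "WindowTrack"), is(input, "WindowTrack"))
  if (ip@units != "raw_count" || input@units != "raw_count")
    stop("callPeaks expects raw_count tracks")
  .checkSameGrid(ip, input)
  if (is.na(input@librarySize) || input@librarySize == 0)
    stop("empty library: input track has library size 0")
  if (is.na(ip@librarySize) || ip@librarySize == 0)
    stop("empty library: IP track has library size 0")
  grid <- ip@grid
  nwin <- windowCount(grid)
  scale <- ip@librarySize / input@librarySize

  nByChrom <- vapply(grid@chromSizes, .nWindowsChrom, numeric(1),
                     windowSize = grid@windowSize, step = grid@step)
  chromOfWindow <- rep(seq_along(nByChrom), nByChrom)
  smoothed <- unlist(lapply(split(input@values, chromOfWindow),
                            .runningMean, k = as.integer(smoothWindows)),
                     use.names = FALSE)
  floor <- floorFraction * ip@librarySize / nwin
  expected <- pmax(scale * pmax(input@values, smoothed), floor)
  p <- .poissonTail(ip@values, expected)
  q <- p.adjust(p, method = "BH")
  lr <- log2Ratio(toCPM(ip), toCPM(input), pseudocount = pseudocount)@values
  sig <- q <= alpha & lr >= minLog2

  win <- gridWindows(grid)
  runs <- S4Vectors::Rle(sig & TRUE)
  starts <- cumsum(c(1L, S4Vectors::runLength(runs)))
  peaks <- GRanges()
  out <- list()
  k <- 0L
  for (j in seq_along(S4Vectors::runLength(runs))) {
    if (!S4Vectors::runValue(runs)[j]) next
    i0 <- starts[j]; i1 <- i0 + S4Vectors::runLength(runs)[j] - 1L
    ## a run can straddle a chromosome boundary; split it there
    for (piece in split(i0:i1, chromOfWindow[i0:i1])) {
      k <- k + 1L
      out[[k]] <- list(
        chrom = names(grid@chromSizes)[chromOfWindow[piece[1]]],
        start = start(win)[piece[1]], end = max(end(win)[piece]),
        nWindows = length(piece),
        log2Enrichment = max(lr[piece]),
        qValue = min(q[piece]))
    }
  }
  if (k == 0L) {
    peaks <- GRanges()
    mcols(peaks) <- DataFrame(nWindows = integer(0),
                              log2Enrichment = numeric(0),
                              qValue = numeric(0))
    return(peaks)
  }
  peaks <- GRanges(vapply(out, `[[`, character(1), "chrom"),
                   IRanges(vapply(out, `[[`, numeric(1), "start"),
                           vapply(out, `[[`, numeric(1), "end")))
  mcols(peaks)$nWindows <- vapply(out, `[[`, numeric(1), "nWindows")
  mcols(peaks)$log2Enrichment <- vapply(out, `[[`, numeric(1),
                                        "log2Enrichment")
  mcols(peaks)$qValue <- vapply(out, `[[`, numeric(1), "qValue")
  ord <- order(match(as.character(seqnames(peaks)),
                     names(grid@chromSizes)), start(peaks))
  peaks[ord]
}

#' Per-window enrichment test results
#'
#' The window-level statistics behind [callPeaks()], exposed for
#' calibration checks: the Poisson expectation, raw p-value, BH q-value
#' and log2 CPM ratio of every window.
#'
#' @inheritParams callPeaks
#' @return A [S4Vectors::DataFrame] with one row per window.
#' @export
windowTests <- function(ip, input, floorFraction = 0.1, pseudocount = 0.5,
                        smoothWindows = 25L) {
  stopifnot(is(ip, "WindowTrack"), is(input, "WindowTrack"))
  .checkSameGrid(ip, input)
  grid <- ip@grid
  nwin <- windowCount(grid)
  scale <- ip@librarySize / input@librarySize
  nByChrom <- vapply(grid@chromSizes, .nWindowsChrom, numeric(1),
                     windowSize = grid@windowSize, step = grid@step)
  chromOfWindow <- rep(seq_along(nByChrom), nByChrom)
  smoothed <- unlist(lapply(split(input@values, chromOfWindow),
                            .runningMean, k = as.integer(smoothWindows)),
                     use.names = FALSE)
  expected <- pmax(scale * pmax(input@values, smoothed),
                   floorFraction * ip@librarySize / nwin)
  p <- .poissonTail(ip@values, expected)
  DataFrame(ipCount = ip@values, expected = expected, p = p,
            q = p.adjust(p, method = "BH"),
            log2CPM = log2Ratio(toCPM(ip), toCPM(input),
                                pseudocount = pseudocount)@values)
}
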