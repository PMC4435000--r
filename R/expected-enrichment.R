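## Closed-form expectation of the capture stage: for each window, the
## probability that a fragment whose midpoint falls in the window is
## retained by the antibody, averaged over the post-selection fragment
## length distribution and the midpoint position.  This is computed by
## numeric integration, independently of the Monte-Carlo path of
## simulateRun, and serves as the oracle the empirical enrichment must
## converge to.

## Discretized post-selection fragment length distribution: integer
## lengths aggregated into bins with representative lengths and weights.
.selectedLengthDist <- function(config, nBins = 12L) {
  lo <- max(config@fragmentMin, config@sizeSelectMin)
  hi <- min(config@fragmentMax, config@sizeSelectMax)
  lens <- lo:hi
  w <- pnorm(lens + 0.5, config@fragmentMean, config@fragmentSd) -
    pnorm(lens - 0.5, config@fragmentMean, config@fragmentSd)
  ## rounding clips everything below fragmentMin up to fragmentMin (and
  ## symmetrically at the top), so the boundary lengths absorb the tails
  if (lens[1] == config@fragmentMin)
    w[1] <- pnorm(lens[1] + 0.5, config@fragmentMean, config@fragmentSd)
  if (lens[length(lens)] == config@fragmentMax)
    w[length(w)] <- 1 - pnorm(lens[length(lens)] - 0.5,
                              config@fragmentMean, config@fragmentSd)
  w <- w / sum(w)
  bins <- cut(lens, breaks = nBins, labels = FALSE)
  rep <- vapply(split(seq_along(lens), bins), function(i)
    sum(lens[i] * w[i]) / sum(w[i]), numeric(1))
  wt <- vapply(split(w, bins), sum, numeric(1))
  list(length = rep, weight = wt / sum(wt))
}

#' Closed-form expected window enrichment of a simulated truth
#'
#' Evaluates, per window, the expected antibody capture probability of a
#' fragment with midpoint in that window under the configured capture
#' model, integrating numerically over the post-selection fragment length
#' distribution and over midpoint positions within the window.  Values are
#' normalized to a genome-wide mean of 1, so they are directly comparable
#' to the empirical IP/input CPM ratio (the input is uniform in
#' expectation).
#'
#' @param truth A [SimTruth-class] from [simulateRun()].
#' @param grid Target [WindowGrid-class]; its genome must match the
#'   simulated one.
#' @param nLengthBins Number of fragment-length integration nodes
#'   (default 12).
#' @param midpointsPerWindow Number of midpoint integration nodes per
#'   window (default 10).
#' @return A [WindowTrack-class] with units \code{"enrichment"};
#'   \code{attr(track, "floor")} gives the normalized nonspecific floor.
#' @export
expectedWindowEnrichment <- function(truth, grid, nLengthBins = 12L,
                                     midpointsPerWindow = 10L) {
  stopifnot(is(truth, "SimTruth"), is(grid, "WindowGrid"))
  config <- truth@config
  ld <- .selectedLengthDist(config, nLengthBins)
  values <- numeric(0)
  for (ch in names(grid@chromSizes)) {
    win <- makeWindows(grid, ch)
    sites <- truth@markedSites[[ch]]
    nw <- length(win)
    offs <- (seq_len(midpointsPerWindow) - 0.5) / midpointsPerWindow
    ## midpoint grid: windows x midpoints
    mids <- rep(start(win) - 1, each = midpointsPerWindow) +
      rep(offs, nw) * rep(width(win), each = midpointsPerWindow)
    ecap <- numeric(length(mids))
    for (j in seq_along(ld$length)) {
      L <- ld$length[j]
      lo <- mids - L / 2
      hi <- mids + L / 2
      k <- if (is.null(sites) || length(sites) == 0L) {
        numeric(length(mids))
      } else {
        findInterval(hi, sites) - findInterval(lo, sites)
      }
      p <- 1 - (1 - config@captureEfficiency)^k
      p[k == 0] <- config@nonspecificRate
      ecap <- ecap + ld$weight[j] * p
    }
    values <- c(values, colMeans(matrix(ecap, nrow = midpointsPerWindow)))
  }
  norm <- mean(values)
  track <- WindowTrack(grid, values / norm, units = "enrichment",
                       sampleId = "expected_enrichment")
  attr(track, "floor") <- config@nonspecificRate / norm
  track
}

#' Recovery of planted enrichment by a peak set
#'
#' Compares called peaks with the simulation ground truth.  A window is
#' truth-positive when its closed-form expected enrichment is at least
#' \code{fold} times the genome median (the median sits at the nonspecific
#' background, so this captures both the planted regions and the
#' neighbourhoods of isolated modified sites).  Precision is the fraction
#' of peaks overlapping a truth-positive window; recall is the fraction of
#' planted regions hit by at least one peak.
#'
#' @param peaks A [GRanges] from [callPeaks()].
#' @param truth A [SimTruth-class].
#' @param grid The [WindowGrid-class] used for calling.
#' @param expected Optional precomputed [expectedWindowEnrichment()] track.
#' @param fold Truth-positive threshold relative to the genome median
#'   (default 2).
#' @return A list with \code{precision}, \code{recall}, \code{nPeaks} and
#'   \code{nTruthWindows}.
#' @export
peakRecovery <- function(peaks, truth, grid, expected = NULL, fold = 2) {
  if (is.null(expected))
    expected <- expectedWindowEnrichment(truth, grid)
  vals <- trackValues(expected)
  positive <- vals >= fold * median(vals)
  win <- gridWindows(grid)[positive]
  precision <- if (length(peaks))
    mean(countOverlaps(peaks, win) > 0) else NA_real_
  recall <- if (length(truth@regions))
    mean(countOverlaps(truth@regions, peaks) > 0) else NA_real_
  list(precision = precision, recall = recall, nPeaks = length(peaks),
       nTruthWindows = sum(positive))
}
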