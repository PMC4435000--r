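## Concordance analyses: random-window sampling, pairwise Pearson
## correlation and R^2, clustered correlation matrices, and descriptive
## condition-difference tracks.

#' Sample random windows from a grid
#'
#' Draws \code{n} distinct window indices uniformly without replacement,
#' deterministically for a given seed.  Subsampling windows (the reference
#' analysis uses 500,000 random 200 bp windows) makes genome-scale
#' correlation estimates cheap without biasing them.
#'
#' @param grid A [WindowGrid-class].
#' @param n Number of windows to draw.
#' @param seed Integer seed.
#' @return Integer vector of \code{n} distinct window indices (grid order).
#' @export
sampleRandomWindows <- function(grid, n = 500000L, seed = 1L) {
  total <- windowCount(grid)
  if (n > total)
    stop(sprintf("cannot sample %d windows from a grid of %d (maximum %d)",
                 n, total, total))
  .withSeed(seed, sample.int(total, n, replace = FALSE))
}

#' Pearson concordance of two tracks over sampled windows
#'
#' @param a,b [WindowTrack-class] objects on an identical grid.
#' @param indices Window indices (e.g. from [sampleRandomWindows()]);
#'   defaults to all windows.
#' @return A list with \code{pearsonR} (sample Pearson correlation) and
#'   \code{rSquared} (its square).  R^2 is defined as the square of the
#'   Pearson coefficient, which is symmetric in the two tracks and avoids
#'   choosing a regression direction.
#' @export
pairwiseConcordance <- function(a, b, indices = seq_len(windowCount(trackGrid(a)))) {
  stopifnot(is(a, "WindowTrack"), is(b, "WindowTrack"))
  .checkSameGrid(a, b)
  if (length(indices) < 3L)
    stop("need at least 3 windows for a correlation")
  x <- a@values[indices]
  y <- b@values[indices]
  if (sd(x) == 0 || sd(y) == 0)
    stop(sprintf("degenerate track: '%s' has zero variance over the selection",
                 if (sd(x) == 0) a@sampleId else b@sampleId))
  r <- cor(x, y)
  list(pearsonR = r, rSquared = r^2)
}

#' Clustered correlation matrix of several tracks
#'
#' All pairwise Pearson correlations over a shared window selection, with
#' average-linkage hierarchical clustering on distance 1 - r; the leaf
#' order of the dendrogram groups concordant samples together.
#'
#' @param tracks List of at least two [WindowTrack-class] objects on an
#'   identical grid.
#' @param indices Window indices over which to correlate; defaults to all.
#' @return A [CorrelationMatrix-class].
#' @export
correlationMatrix <- function(tracks,
                              indices = seq_len(windowCount(trackGrid(tracks[[1]])))) {
  stopifnot(length(tracks) >= 2L)
  for (t in tracks[-1]) .checkSameGrid(tracks[[1]], t)
  ids <- vapply(tracks, sampleId, character(1))
  if (anyDuplicated(ids))
    ids <- make.unique(ids)
  m <- vapply(tracks, function(t) t@values[indices],
              numeric(length(indices)))
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop(sprintf("degenerate track: '%s' has zero variance over the selection",
                 ids[which(sds == 0)[1]]))
  r <- cor(m)
  dimnames(r) <- list(ids, ids)
  hc <- hclust(as.dist(1 - r), method = "average")
  new("CorrelationMatrix", sampleIds = ids, r = r,
      linkageOrder = as.integer(hc$order))
}

#' @export
setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d samples (leaf order: %s)\n",
              length(object@sampleIds),
              paste(object@sampleIds[object@linkageOrder],
                    collapse = ", ")))
  print(round(object@r, 3))
})

#' Difference of two ratio tracks
#'
#' Elementwise \code{a - b} on matching log2 ratio tracks: a descriptive
#' per-window condition difference (e.g. treated minus control), without a
#' significance model.
#'
#' @param a,b [WindowTrack-class] objects with identical grid and units.
#' @return A [WindowTrack-class] with the same units and sample id
#'   \code{"<a>_minus_<b>"}.
#' @export
differenceTrack <- function(a, b) {
  stopifnot(is(a, "WindowTrack"), is(b, "WindowTrack"))
  .checkSameGrid(a, b)
  if (a@units != b@units)
    stop(sprintf("units mismatch: '%s' vs '%s'", a@units, b@units))
  if (a@units != "log2_ratio")
    stop("differenceTrack is defined for log2_ratio tracks")
  WindowTrack(a@grid, a@values - b@values, units = a@units,
              sampleId = sprintf("%s_minus_%s", a@sampleId, b@sampleId))
}
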