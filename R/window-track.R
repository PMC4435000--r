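#' Construct a window track
#'
#' @param grid A [WindowGrid-class].
#' @param values One numeric value per window, in grid order.
#' @param units \code{"raw_count"}, \code{"cpm"}, \code{"log2_ratio"} or
#'   \code{"enrichment"}.
#' @param sampleId Sample label.
#' @param librarySize Total counted reads (ignored for ratio units).
#' @return A [WindowTrack-class].
#' @export
WindowTrack <- function(grid, values, units = "raw_count",
                        sampleId = "sample", librarySize = NA_real_) {
  new("WindowTrack", grid = grid, values = as.numeric(values),
      units = units, sampleId = sampleId,
      librarySize = as.numeric(librarySize))
}

#' @describeIn WindowTrack Numeric vector of per-window values.
#' @param track A [WindowTrack-class].
#' @export
trackValues <- function(track) track@values

#' @describeIn WindowTrack Units tag of the track.
#' @export
trackUnits <- function(track) track@units

#' @describeIn WindowTrack Grid the track lives on.
#' @export
trackGrid <- function(track) track@grid

#' @describeIn WindowTrack Sample label.
#' @export
sampleId <- function(track) track@sampleId

#' @describeIn WindowTrack Total counted reads (NA for ratio units).
#' @export
librarySize <- function(track) track@librarySize

#' Convert a track to GRanges
#'
#' @param track A [WindowTrack-class].
#' @return A [GRanges] of the grid windows with a \code{score} column.
#' @export
asGRanges <- function(track) {
  gr <- gridWindows(track@grid)
  mcols(gr)$score <- track@values
  gr
}

#' @export
setMethod("show", "WindowTrack", function(object) {
  v <- object@values
  cat(sprintf("WindowTrack '%s' [%s]: %d windows", object@sampleId,
              object@units, length(v)))
  if (!is.na(object@librarySize))
    cat(sprintf(", library size %d", as.integer(object@librarySize)))
  if (length(v))
    cat(sprintf("; value range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
})

## Stop unless two tracks share an identical grid; names the first
## differing component for the error message.
.checkSameGrid <- function(a, b) {
  ga <- a@grid; gb <- b@grid
  if (!identical(names(ga@chromSizes), names(gb@chromSizes)) ||
      !identical(unname(ga@chromSizes), unname(gb@chromSizes)))
    stop("tracks are on different grids: chromosome sets differ")
  if (ga@windowSize != gb@windowSize || ga@step != gb@step)
    stop(sprintf(
      "tracks are on different grids: window/step %d/%d vs %d/%d",
      ga@windowSize, ga@step, gb@windowSize, gb@step))
  invisible(TRUE)
}
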