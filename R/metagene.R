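## Metagene profiling: average signal over genes rescaled to a common
## length, with flanks of 25% of each gene's length to show the
## surrounding environment (the canonical view for gene-body marks, which
## are typically depleted right at the TSS and elevated across the body).

## Piecewise-constant integral of a tiling track on one chromosome:
## returns F such that F(x) = integral of the window step function over
## [0, x) for 0-based x.
.trackIntegralFun <- function(starts0, widths, values) {
  cumBefore <- c(0, cumsum(values * widths))
  ends0 <- starts0 + widths
  maxX <- ends0[length(ends0)]
  function(x) {
    x <- pmin(pmax(x, 0), maxX)
    i <- findInterval(x, starts0)
    i <- pmax(i, 1L)
    cumBefore[i] + (x - starts0[i]) * values[i]
  }
}

#' Metagene profile of a track over gene bodies
#'
#' Each gene body is divided into \code{nBodyBins} equal-length bins, and
#' flanks of 25% of the gene length on either side into \code{nBodyBins/4}
#' bins each, so that bins have uniform genomic width within a gene.  The
#' value of a bin is the length-weighted mean of the window signal it
#' covers; minus-strand genes are reversed so that bin 0 is always the 5'
#' flank.  The profile is the unweighted mean over genes; bins falling off
#' a chromosome end are dropped for that gene (per-bin gene counts are
#' reported).
#'
#' @param track A [WindowTrack-class] on a tiling grid
#'   (\code{step == windowSize}).
#' @param genes Gene bodies from [loadGenes()]; must be non-empty.
#' @param nBodyBins Number of body bins (default 100; flanks get 25 each).
#' @return A [MetageneProfile-class].
#' @export
metagene <- function(track, genes, nBodyBins = 100L) {
  stopifnot(is(track, "WindowTrack"))
  if (length(genes) == 0L)
    stop("empty gene set")
  grid <- track@grid
  if (grid@step != grid@windowSize)
    stop("metagene requires a tiling grid (step == windowSize)")
  nBodyBins <- as.integer(nBodyBins)
  nFlankBins <- max(1L, nBodyBins %/% 4L)
  m <- 2L * nFlankBins + nBodyBins

  integrals <- list()
  for (ch in names(grid@chromSizes)) {
    w <- makeWindows(grid, ch)
    integrals[[ch]] <- .trackIntegralFun(start(w) - 1, width(w),
                                         track@values[.chromOffsets(grid)[[ch]] +
                                                        seq_along(w)])
  }
  sums <- numeric(m)
  counts <- numeric(m)
  chr <- as.character(seqnames(genes))
  strands <- as.character(strand(genes))
  for (g in seq_along(genes)) {
    ch <- chr[g]
    if (!ch %in% names(integrals)) next
    len <- grid@chromSizes[[ch]]
    s0 <- start(genes)[g] - 1
    e0 <- end(genes)[g]
    L <- e0 - s0
    FL <- 0.25 * L
    edges <- c(s0 - FL + (0:(nFlankBins - 1)) * FL / nFlankBins,
               s0 + (0:(nBodyBins - 1)) * L / nBodyBins,
               e0 + (0:nFlankBins) * FL / nFlankBins)
    a <- pmax(edges[-length(edges)], 0)
    b <- pmin(edges[-1], len)
    Fn <- integrals[[ch]]
    vals <- ifelse(b > a, (Fn(b) - Fn(a)) / (b - a), NA_real_)
    if (strands[g] == "-") vals <- rev(vals)
    ok <- !is.na(vals)
    sums[ok] <- sums[ok] + vals[ok]
    counts[ok] <- counts[ok] + 1
  }
  values <- ifelse(counts > 0, sums / counts, 0)
  new("MetageneProfile", nBodyBins = nBodyBins, nFlankBins = nFlankBins,
      values = values, binCounts = counts, nGenes = length(genes))
}

#' @export
setMethod("show", "MetageneProfile", function(object) {
  cat(sprintf(
    "MetageneProfile: %d genes, %d+%d+%d bins; body mean %.4g, flank mean %.4g\n",
    object@nGenes, object@nFlankBins, object@nBodyBins, object@nFlankBins,
    mean(object@values[(object@nFlankBins + 1):(object@nFlankBins +
                                                  object@nBodyBins)]),
    mean(object@values[c(seq_len(object@nFlankBins),
                         (object@nFlankBins + object@nBodyBins +
                            1):length(object@values))])))
})

#' Write a metagene profile as TSV
#'
#' @param profile A [MetageneProfile-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMetagene <- function(profile, path) {
  zone <- c(rep("flank5", profile@nFlankBins),
            rep("body", profile@nBodyBins),
            rep("flank3", profile@nFlankBins))
  tab <- data.frame(bin = seq_along(profile@values) - 1L, zone = zone,
                    value = profile@values, n_genes = profile@binCounts)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
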