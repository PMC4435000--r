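## Window grids and gene models.
##
## Coordinates follow the Bioconductor convention internally: GRanges are
## 1-based with closed ends.  All on-disk BED/bedGraph output is 0-based
## half-open; the conversion happens only at the I/O boundary.

#' Construct a window grid
#'
#' @param chromSizes Named numeric vector of chromosome lengths in bp, or a
#'   path to a two-column TSV (chromosome, length) in the UCSC
#'   \code{chrom.sizes} dialect.
#' @param windowSize Window width in bp (default 200).
#' @param step Distance between window starts in bp; defaults to
#'   \code{windowSize} (non-overlapping tiling).
#'
#' @return A [WindowGrid-class] object.
#' @examples
#' grid <- WindowGrid(c(chr1 = 1000), windowSize = 200)
#' makeWindows(grid, "chr1")
#' @export
WindowGrid <- function(chromSizes, windowSize = 200L, step = windowSize) {
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  new("WindowGrid", chromSizes = chromSizes,
      windowSize = as.integer(windowSize), step = as.integer(step))
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric"))
  if (ncol(tab) < 2L)
    stop("chrom.sizes file must have two tab-separated columns")
  setNames(tab[[2]], tab[[1]])
}

## 0-based window starts for one chromosome; the trailing window is
## truncated at the chromosome end rather than dropped.
.windowStarts0 <- function(len, windowSize, step) {
  len <- as.numeric(len)
  if (len <= windowSize) return(0)
  lastFull <- ((len - windowSize) %/% step) * step
  starts <- seq(0, lastFull, by = step)
  if (lastFull + windowSize < len) starts <- c(starts, lastFull + step)
  starts
}

.nWindowsChrom <- function(len, windowSize, step)
  length(.windowStarts0(len, windowSize, step))

#' @describeIn WindowGrid-class Total number of windows in the grid.
#' @param grid A [WindowGrid-class].
#' @export
windowCount <- function(grid) {
  sum(vapply(grid@chromSizes, .nWindowsChrom, numeric(1),
             windowSize = grid@windowSize, step = grid@step))
}

## Cumulative window-index offset of each chromosome (0-based).
.chromOffsets <- function(grid) {
  n <- vapply(grid@chromSizes, .nWindowsChrom, numeric(1),
              windowSize = grid@windowSize, step = grid@step)
  setNames(cumsum(c(0, n[-length(n)])), names(grid@chromSizes))
}

#' Windows of one chromosome
#'
#' Emits the window intervals of a grid for one chromosome, ordered by
#' ascending start.  Window starts advance by \code{step}; the final window
#' is truncated at the chromosome end when the length is not a multiple of
#' the step, so every base is covered by at least one window.
#'
#' @param grid A [WindowGrid-class].
#' @param chrom Chromosome name; must be present in the grid.
#' @return A [GRanges] of windows (1-based, closed ends).
#' @export
makeWindows <- function(grid, chrom) {
  stopifnot(is(grid, "WindowGrid"))
  if (!chrom %in% names(grid@chromSizes))
    stop(sprintf("chromosome '%s' is not in the grid", chrom))
  len <- grid@chromSizes[[chrom]]
  starts0 <- .windowStarts0(len, grid@windowSize, grid@step)
  GRanges(chrom,
          IRanges(start = starts0 + 1,
                  end = pmin(starts0 + grid@windowSize, len)))
}

#' All windows of a grid, in grid order
#'
#' @param grid A [WindowGrid-class].
#' @return A [GRanges] with chromosomes in grid order, then ascending start.
#' @export
gridWindows <- function(grid) {
  grl <- lapply(names(grid@chromSizes), function(ch) makeWindows(grid, ch))
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlevels(gr) <- names(grid@chromSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(grid@chromSizes)
  gr
}

#' @export
setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d chromosome(s), window %d bp, step %d bp, %d windows\n",
              length(object@chromSizes), object@windowSize, object@step,
              windowCount(object)))
})

#' Load gene models from GTF or BED
#'
#' Parses a gene annotation and reduces it to one model per gene: all
#' transcripts sharing a \code{gene_id} (GTF) or name (BED) are unioned into
#' a single body span.  The transcription start site is the 5' end of the
#' body: the leftmost base on the plus strand, the rightmost on the minus
#' strand.
#'
#' @param path Path to a GTF file (records must carry a \code{gene_id}
#'   attribute) or a BED file (name column = gene id).
#' @param format \code{"auto"} (by extension), \code{"gtf"} or \code{"bed"}.
#' @return A [GRanges] with one range per gene (the unioned body),
#'   \code{gene_id} metadata column and explicit strand.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tgeneA\t0\t+", bed)
#' loadGenes(bed)
#' @export
loadGenes <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop(sprintf("failed to parse %s annotation '%s': %s",
                                     format, path, conditionMessage(e))))
  ids <- if (format == "gtf") mcols(gr)$gene_id else mcols(gr)$name
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("%s record without a gene identifier (line %s)",
                 format,
                 paste(which(is.na(ids) | !nzchar(ids)), collapse = ",")))
  keep <- as.character(strand(gr)) %in% c("+", "-")
  if (!all(keep))
    stop(sprintf("gene(s) without strand: %s",
                 paste(unique(ids[!keep]), collapse = ", ")))
  bychrom <- split(as.character(seqnames(gr)), ids)
  multi <- names(bychrom)[vapply(bychrom, function(x)
    length(unique(x)), integer(1)) > 1L]
  if (length(multi))
    stop(sprintf("gene id(s) on conflicting chromosomes: %s",
                 paste(multi, collapse = ", ")))
  bystrand <- split(as.character(strand(gr)), ids)
  multi <- names(bystrand)[vapply(bystrand, function(x)
    length(unique(x)), integer(1)) > 1L]
  if (length(multi))
    stop(sprintf("gene id(s) on conflicting strands: %s",
                 paste(multi, collapse = ", ")))
  bodies <- unlist(range(split(gr, factor(ids, levels = unique(ids)))))
  out <- GRanges(seqnames(bodies), ranges(bodies),
                 strand = vapply(split(as.character(strand(gr)),
                                       factor(ids, levels = unique(ids))),
                                 `[`, character(1), 1L))
  mcols(out)$gene_id <- names(bodies)
  names(out) <- NULL
  out
}

#' Transcription start sites of gene models
#'
#' @param genes A [GRanges] of gene bodies with strand, as from
#'   [loadGenes()].
#' @return A [GRanges] of single-base TSS positions (5' end of each body).
#' @export
tssPositions <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  out <- GRanges(seqnames(genes), IRanges(pos, pos), strand = strand(genes))
  mcols(out) <- mcols(genes)
  out
}
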