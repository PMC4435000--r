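## Five-compartment genomic annotation of peaks relative to gene models:
## promoter core, promoter proximal, promoter distal, intragenic,
## intergenic, with strict precedence in that order.

.COMPARTMENTS <- c("promoter_core", "promoter_proximal", "promoter_distal",
                   "intragenic", "intergenic")

#' Construct a compartment scheme
#'
#' @param core,proximal,distal Radii around the TSS in bp; must be
#'   strictly increasing (defaults 500, 2000, 10000).
#' @return A [CompartmentScheme-class].
#' @export
compartmentScheme <- function(core = 500, proximal = 2000, distal = 10000) {
  new("CompartmentScheme", coreRadius = core, proximalRadius = proximal,
      distalRadius = distal)
}

#' @export
setMethod("show", "CompartmentScheme", function(object) {
  cat(sprintf("CompartmentScheme: core %d bp, proximal %d bp, distal %d bp\n",
              as.integer(object@coreRadius),
              as.integer(object@proximalRadius),
              as.integer(object@distalRadius)))
})

#' Assign peaks to genomic compartments
#'
#' Classifies each peak by its midpoint with strict precedence
#' promoter_core > promoter_proximal > promoter_distal > intragenic >
#' intergenic.  Promoter zones are symmetric around every TSS: the core is
#' TSS +/- \code{coreRadius}, the proximal zone extends to
#' \code{proximalRadius} excluding the core, the distal zone to
#' \code{distalRadius} excluding both.  Midpoints outside all promoter
#' zones are intragenic when inside any gene body, intergenic otherwise.
#' Every peak receives exactly one label; with an empty gene set all peaks
#' are intergenic.
#'
#' @param peaks A [GRanges] of peaks (any ranges work; only midpoints are
#'   used).
#' @param genes Gene bodies from [loadGenes()].
#' @param scheme A [CompartmentScheme-class].
#' @return A factor with levels \code{promoter_core, promoter_proximal,
#'   promoter_distal, intragenic, intergenic}, one per peak.
#' @export
assignCompartment <- function(peaks, genes, scheme = compartmentScheme()) {
  stopifnot(is(scheme, "CompartmentScheme"))
  n <- length(peaks)
  out <- rep("intergenic", n)
  if (n == 0L)
    return(factor(out[0], levels = .COMPARTMENTS))
  mid <- (start(peaks) + end(peaks)) %/% 2L
  if (length(genes)) {
    tss <- tssPositions(genes)
    tssByChrom <- split(start(tss), as.character(seqnames(tss)))
    tssByChrom <- lapply(tssByChrom, sort)
    chr <- as.character(seqnames(peaks))
    dist <- rep(Inf, n)
    for (ch in unique(chr)) {
      pos <- tssByChrom[[ch]]
      if (is.null(pos) || length(pos) == 0L) next
      sel <- which(chr == ch)
      i <- findInterval(mid[sel], pos)
      dLeft <- ifelse(i >= 1L, mid[sel] - pos[pmax(i, 1L)], Inf)
      dRight <- ifelse(i < length(pos), pos[pmin(i + 1L, length(pos))] -
                         mid[sel], Inf)
      dist[sel] <- pmin(dLeft, dRight)
    }
    midGR <- GRanges(chr, IRanges(mid, mid))
    inGene <- countOverlaps(midGR, genes, ignore.strand = TRUE) > 0L
    out[inGene] <- "intragenic"
    out[dist <= scheme@distalRadius] <- "promoter_distal"
    out[dist <= scheme@proximalRadius] <- "promoter_proximal"
    out[dist <= scheme@coreRadius] <- "promoter_core"
  }
  factor(out, levels = .COMPARTMENTS)
}

#' Compartment distribution of a peak set
#'
#' @param peaks A non-empty [GRanges] of peaks.
#' @param genes Gene bodies from [loadGenes()].
#' @param scheme A [CompartmentScheme-class].
#' @return Named numeric vector: percentage of peaks in each of the five
#'   compartments (sums to 100).
#' @export
compartmentDistribution <- function(peaks, genes,
                                    scheme = compartmentScheme()) {
  if (length(peaks) == 0L)
    stop("no peaks to classify")
  comp <- assignCompartment(peaks, genes, scheme)
  tab <- table(comp)
  setNames(as.numeric(100 * tab / length(peaks)), names(tab))
}
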