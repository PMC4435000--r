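#' @import methods
#' @importFrom stats rnorm runif rexp setNames hclust as.dist
#'   p.adjust ppois dpois pnorm
#' @importFrom utils write.table read.table
NULL

.TRACK_UNITS <- c("raw_count", "cpm", "log2_ratio", "enrichment")

#' Genome-wide window grid
#'
#' A \code{WindowGrid} describes a deterministic tiling (or sliding) partition
#' of a genome into fixed-width windows: the chromosome sizes, the window
#' width and the step between successive window starts.  When
#' \code{step == windowSize} the windows tile the genome; when
#' \code{step < windowSize} they overlap.  The final window on each
#' chromosome is truncated at the chromosome end so that every base is
#' covered by at least one window.
#'
#' @slot chromSizes Named numeric vector of chromosome lengths in bp, in the
#'   order windows are emitted.
#' @slot windowSize Window width in bp (default 200, the resolution used for
#'   smoothing DIP-seq coverage).
#' @slot step Distance between successive window starts in bp;
#'   \code{0 < step <= windowSize}.
#'
#' @seealso [WindowGrid()], [makeWindows()], [gridWindows()]
#' @export
setClass("WindowGrid",
  representation(chromSizes = "numeric", windowSize = "integer",
                 step = "integer"),
  validity = function(object) {
    msg <- NULL
    cs <- object@chromSizes
    if (length(cs) == 0L || is.null(names(cs)) || any(!nzchar(names(cs))))
      msg <- c(msg, "chromSizes must be a non-empty named vector")
    if (anyDuplicated(names(cs)))
      msg <- c(msg, "duplicate chromosome names in chromSizes")
    if (any(!is.finite(cs)) || any(cs < 1))
      msg <- c(msg, "chromosome sizes must be positive")
    if (length(object@windowSize) != 1L || object@windowSize < 1L)
      msg <- c(msg, "windowSize must be a positive scalar")
    if (length(object@step) != 1L || object@step < 1L ||
        object@step > object@windowSize)
      msg <- c(msg, "step must satisfy 0 < step <= windowSize")
    if (is.null(msg)) TRUE else msg
  })

#' Per-window signal track
#'
#' A \code{WindowTrack} pairs a [WindowGrid] with one numeric value per
#' window, in grid order, together with a units tag that enforces the
#' normalization discipline of the pipeline: \code{"raw_count"} (integer read
#' counts), \code{"cpm"} (counts per million), \code{"log2_ratio"}
#' (IP over input) or \code{"enrichment"} (model-expected IP/input ratio,
#' relative to the genome mean).
#'
#' @slot grid The [WindowGrid] the values live on.
#' @slot values Numeric vector, one value per window in grid order.
#' @slot units One of \code{"raw_count"}, \code{"cpm"}, \code{"log2_ratio"},
#'   \code{"enrichment"}.
#' @slot sampleId Free-text sample label.
#' @slot librarySize Total number of reads counted into the track
#'   (\code{NA} for ratio/enrichment units).
#'
#' @seealso [countReads()], [toCPM()], [log2Ratio()], [trackValues()]
#' @export
setClass("WindowTrack",
  representation(grid = "WindowGrid", values = "numeric", units = "character",
                 sampleId = "character", librarySize = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- windowCount(object@grid)
    if (length(object@values) != n)
      msg <- c(msg, sprintf("values length (%d) != window count (%d)",
                            length(object@values), n))
    if (length(object@units) != 1L || !object@units %in% .TRACK_UNITS)
      msg <- c(msg, sprintf("units must be one of %s",
                            paste(.TRACK_UNITS, collapse = ", ")))
    if (object@units == "raw_count" && length(object@values) &&
        (any(object@values < 0) ||
         any(object@values != floor(object@values))))
      msg <- c(msg, "raw_count values must be non-negative integers")
    if (object@units == "cpm" && length(object@values) &&
        any(object@values < 0))
      msg <- c(msg, "cpm values must be non-negative")
    if (object@units == "log2_ratio" && length(object@values) &&
        any(!is.finite(object@values)))
      msg <- c(msg, "log2_ratio values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Promoter-centred genomic compartment scheme
#'
#' Radii (bp) around each transcription start site defining the three nested
#' promoter zones used when classifying enriched regions: the core zone
#' (TSS +/- \code{coreRadius}), the proximal zone (out to
#' \code{proximalRadius}, excluding the core) and the distal zone (out to
#' \code{distalRadius}, excluding both).  Peaks outside all promoter zones
#' are intragenic if they fall inside a gene body, intergenic otherwise.
#'
#' @slot coreRadius,proximalRadius,distalRadius Strictly increasing radii
#'   in bp (defaults 500, 2000, 10000).
#'
#' @seealso [compartmentScheme()], [assignCompartment()]
#' @export
setClass("CompartmentScheme",
  representation(coreRadius = "numeric", proximalRadius = "numeric",
                 distalRadius = "numeric"),
  validity = function(object) {
    ok <- object@coreRadius > 0 &&
      object@coreRadius < object@proximalRadius &&
      object@proximalRadius < object@distalRadius
    if (ok) TRUE else "radii must satisfy 0 < core < proximal < distal"
  })

#' Read-length and mapping-quality QC report
#'
#' Summary of the read-length distribution of a library and of mapping rate
#' as a function of read length.  On semiconductor sequencers, degraded
#' fragments and residual amplification adapters accumulate below 50 bp and
#' map poorly, so the report tracks the fraction of reads under that cutoff.
#'
#' @slot histogram Named numeric vector: read count per length bin (bins
#'   labelled by their lower bound; empty bins omitted).
#' @slot meanLength Mean read length in bp (\code{NA} for an empty stream).
#' @slot fractionBelowCutoff Proportion of reads shorter than \code{cutoff}.
#' @slot mappingRateByBin Named numeric vector: fraction mapped per bin.
#' @slot overallMappingRate Fraction of all reads mapped.
#' @slot totalReads Number of reads seen.
#' @slot binWidth,cutoff The bin width and short-read cutoff used (bp).
#'
#' @seealso [qcReport()], [filterByLength()]
#' @export
setClass("LengthQCReport",
  representation(histogram = "numeric", meanLength = "numeric",
                 fractionBelowCutoff = "numeric", mappingRateByBin = "numeric",
                 overallMappingRate = "numeric", totalReads = "numeric",
                 binWidth = "numeric", cutoff = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@histogram) && sum(object@histogram) != object@totalReads)
      msg <- c(msg, "histogram counts must sum to totalReads")
    rates <- c(object@mappingRateByBin, object@overallMappingRate,
               object@fractionBelowCutoff)
    rates <- rates[!is.na(rates)]
    if (length(rates) && (any(rates < 0) || any(rates > 1)))
      msg <- c(msg, "rates must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Average signal profile over scaled gene bodies
#'
#' Mean signal across genes after rescaling each gene body to a common
#' number of bins, with flanks of 25% of the gene length on either side.
#' Bin 0 is always the 5' end (minus-strand genes are reversed).
#'
#' @slot nBodyBins,nFlankBins Bin counts for the body and for each flank.
#' @slot values Mean signal per bin (length \code{2*nFlankBins + nBodyBins}).
#' @slot binCounts Number of genes contributing a defined value to each bin
#'   (flanks running off a chromosome end are dropped per gene).
#' @slot nGenes Number of genes averaged.
#'
#' @seealso [metagene()]
#' @export
setClass("MetageneProfile",
  representation(nBodyBins = "integer", nFlankBins = "integer",
                 values = "numeric", binCounts = "numeric",
                 nGenes = "integer"),
  validity = function(object) {
    msg <- NULL
    nb <- 2L * object@nFlankBins + object@nBodyBins
    if (length(object@values) != nb)
      msg <- c(msg, "values length must equal 2*nFlankBins + nBodyBins")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "profile values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Pairwise Pearson correlation matrix with clustering order
#'
#' All pairwise Pearson correlations between a set of window tracks,
#' evaluated over a common set of sampled windows, together with the leaf
#' order of an average-linkage hierarchical clustering on distance 1 - r.
#'
#' @slot sampleIds Sample labels, in input order.
#' @slot r Symmetric correlation matrix with unit diagonal.
#' @slot linkageOrder Integer permutation: dendrogram leaf order.
#'
#' @seealso [correlationMatrix()], [pairwiseConcordance()]
#' @export
setClass("CorrelationMatrix",
  representation(sampleIds = "character", r = "matrix",
                 linkageOrder = "integer"),
  validity = function(object) {
    msg <- NULL
    r <- object@r
    k <- length(object@sampleIds)
    if (!is.numeric(r) || nrow(r) != k || ncol(r) != k)
      msg <- c(msg, "r must be a square numeric matrix matching sampleIds")
    else {
      if (max(abs(diag(r) - 1)) > 1e-12)
        msg <- c(msg, "diagonal of r must be exactly 1")
      if (max(abs(r - t(r))) > 1e-12)
        msg <- c(msg, "r must be symmetric")
      if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    }
    if (!identical(sort(object@linkageOrder), seq_len(k)))
      msg <- c(msg, "linkageOrder must be a permutation of the samples")
    if (is.null(msg)) TRUE else msg
  })

#' Configuration of the DIP-seq protocol simulator
#'
#' Parameters of the generative model behind [simulateRun()].  The model
#' follows the immunoprecipitation protocol stage by stage: CpG sites are
#' placed along a synthetic genome as a Poisson process; a fraction of them
#' carry the modification (optionally boosted inside enriched regions);
#' fragments are drawn with a truncated-normal length distribution; a 10%
#' aliquot is reserved as input; antibody capture retains a fragment with
#' probability \code{1 - (1 - captureEfficiency)^k} for \code{k} modified
#' sites, or \code{nonspecificRate} when unmodified; retained fragments are
#' amplified, size selected and sequenced to the requested depth.
#'
#' @slot seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @slot genome Named numeric vector of synthetic chromosome lengths (bp).
#' @slot cpgSpacing Mean distance between CpG sites (bp).
#' @slot hmcFraction Baseline probability that a CpG carries the
#'   modification (the tissue-level range is roughly 0.001-0.07).
#' @slot regions [GRanges] of enriched regions with a numeric
#'   \code{multiplier} metadata column; inside a region the marking
#'   probability is \code{min(1, hmcFraction * multiplier)}.
#' @slot captureEfficiency Per-site probability that a modified site on a
#'   fragment triggers antibody capture.
#' @slot nonspecificRate Probability that an unmodified fragment is captured.
#' @slot nFragments Number of fragments sheared from the genome.
#' @slot fragmentMean,fragmentSd,fragmentMin,fragmentMax Fragment length
#'   model: normal(mean, sd) clipped to [min, max] (defaults 300, 75,
#'   100, 500 bp).
#' @slot sizeSelectMin,sizeSelectMax Library size-selection range
#'   (defaults 100-250 bp).
#' @slot wgaCycles Whole-genome amplification cycles (default 10); each
#'   fragment is amplified to an expected \code{2^wgaCycles} copies.
#' @slot wgaBiasSd Log-normal sd of per-fragment amplification efficiency
#'   (0 = unbiased amplification).
#' @slot readMean,readSd Read length model: normal(mean, sd) truncated below
#'   at 20 bp; the emitted read length is the minimum of this draw and the
#'   fragment length (defaults 137, 15 bp).
#' @slot inputFraction Fraction of fragments reserved as input (default 0.1).
#' @slot depth Number of reads sequenced per sample.
#' @slot adapterFraction Fraction of reads replaced by short (20-49 bp)
#'   adapter/degradation artefacts, for QC testing (default 0).
#' @slot degradeShortReads If \code{TRUE}, reads under 50 bp are assigned
#'   low mapping quality and fail to map 60% of the time, reproducing the
#'   poor mapping accuracy of short semiconductor reads.
#'
#' @seealso [simConfig()], [simulateRun()], [expectedWindowEnrichment()]
#' @export
setClass("SimConfig",
  representation(seed = "integer", genome = "numeric", cpgSpacing = "numeric",
                 hmcFraction = "numeric", regions = "GRanges",
                 captureEfficiency = "numeric", nonspecificRate = "numeric",
                 nFragments = "integer", fragmentMean = "numeric",
                 fragmentSd = "numeric", fragmentMin = "numeric",
                 fragmentMax = "numeric", sizeSelectMin = "numeric",
                 sizeSelectMax = "numeric", wgaCycles = "integer",
                 wgaBiasSd = "numeric", readMean = "numeric",
                 readSd = "numeric", inputFraction = "numeric",
                 depth = "integer", adapterFraction = "numeric",
                 degradeShortReads = "logical"),
  validity = function(object) {
    msg <- NULL
    g <- object@genome
    if (length(g) == 0L || is.null(names(g)) || any(g < 1))
      msg <- c(msg, "genome must be a named vector of positive lengths")
    probs <- c(hmcFraction = object@hmcFraction,
               captureEfficiency = object@captureEfficiency,
               nonspecificRate = object@nonspecificRate,
               inputFraction = object@inputFraction,
               adapterFraction = object@adapterFraction)
    bad <- names(probs)[probs < 0 | probs > 1]
    if (length(bad))
      msg <- c(msg, sprintf("probabilities outside [0, 1]: %s",
                            paste(bad, collapse = ", ")))
    if (!(object@fragmentMin < object@fragmentMean &&
          object@fragmentMean < object@fragmentMax))
      msg <- c(msg, "need fragmentMin < fragmentMean < fragmentMax")
    if (object@sizeSelectMin >= object@sizeSelectMax)
      msg <- c(msg, "need sizeSelectMin < sizeSelectMax")
    if (object@sizeSelectMin > object@fragmentMax ||
        object@sizeSelectMax < object@fragmentMin)
      msg <- c(msg, "size-selection range is disjoint from fragment lengths")
    if (object@nFragments < 1L) msg <- c(msg, "nFragments must be positive")
    if (object@depth < 1L) msg <- c(msg, "depth must be positive")
    if (object@cpgSpacing <= 0) msg <- c(msg, "cpgSpacing must be positive")
    if (length(object@regions)) {
      if (is.null(object@regions$multiplier))
        msg <- c(msg, "regions must carry a 'multiplier' metadata column")
      if (!all(as.character(GenomicRanges::seqnames(object@regions)) %in%
               names(g)))
        msg <- c(msg, "regions lie on chromosomes absent from the genome")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Ground truth of a simulated experiment
#'
#' The latent state of a [simulateRun()] draw: the modified CpG positions,
#' the enriched regions with their marking multipliers, and the
#' configuration needed to evaluate the closed-form expected enrichment.
#'
#' @slot markedSites Named list, one sorted integer vector of 1-based
#'   modified CpG positions per chromosome.
#' @slot regions [GRanges] of enriched regions with multipliers (copied from
#'   the configuration).
#' @slot config The [SimConfig] that generated the truth.
#'
#' @seealso [simulateRun()], [expectedWindowEnrichment()], [peakRecovery()]
#' @export
setClass("SimTruth",
  representation(markedSites = "list", regions = "GRanges",
                 config = "SimConfig"),
  validity = function(object) {
    msg <- NULL
    g <- object@config@genome
    for (chrom in names(object@markedSites)) {
      pos <- object@markedSites[[chrom]]
      if (is.unsorted(pos, strictly = TRUE))
        msg <- c(msg, sprintf("marked sites on %s not strictly increasing",
                              chrom))
      if (length(pos) && (pos[1] < 1 || pos[length(pos)] > g[[chrom]]))
        msg <- c(msg, sprintf("marked sites on %s outside the chromosome",
                              chrom))
    }
    if (is.null(msg)) TRUE else msg
  })
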