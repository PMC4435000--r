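## Generative model of the DIP-seq wet-lab protocol, stage by stage:
## CpG placement, stochastic marking (boosted inside enriched regions),
## fragmentation, reservation of an input aliquot, antibody capture,
## whole-genome amplification, size selection and sequencing.  Identical
## configuration and seed give byte-identical output, and the capture
## stage has a closed-form expectation (expectedWindowEnrichment) that the
## Monte-Carlo output can be validated against.

#' Construct a simulator configuration
#'
#' Defaults follow the protocol: fragments of 100-500 bp centred on
#' 300 bp, a 10% input aliquot, 10 amplification cycles, size selection to
#' 100-250 bp and read lengths around 137 bp.  The antibody model retains
#' a fragment carrying \code{k} modified sites with probability
#' \code{1 - (1 - captureEfficiency)^k} (independent per-site capture,
#' chosen for analytic tractability) and an unmodified fragment with
#' probability \code{nonspecificRate}.
#'
#' @param seed Integer seed.
#' @param genome Named vector of chromosome lengths (default two 1 Mb
#'   synthetic chromosomes).
#' @param cpgSpacing Mean CpG spacing in bp (default 100).
#' @param hmcFraction Baseline marking probability per CpG (default 0.01).
#' @param regions [GRanges] with a \code{multiplier} column; marking
#'   probability inside is \code{min(1, hmcFraction * multiplier)}.
#' @param captureEfficiency Per-site capture probability (default 0.9,
#'   reflecting a high-specificity antibody).
#' @param nonspecificRate Capture probability of unmodified fragments
#'   (default 0.1).
#' @param nFragments Fragments sheared from the genome (default 5e5).
#' @param fragmentMean,fragmentSd,fragmentMin,fragmentMax Fragment length
#'   model in bp (defaults 300, 75, 100, 500).
#' @param sizeSelectMin,sizeSelectMax Size selection range (100-250 bp).
#' @param wgaCycles Amplification cycles (default 10).
#' @param wgaBiasSd Log-normal sd of per-fragment amplification
#'   efficiency; 0 = unbiased.
#' @param readMean,readSd Read length model in bp (defaults 137, 15).
#' @param inputFraction Input aliquot fraction (default 0.1).
#' @param depth Reads sequenced per sample (default 2e5).
#' @param adapterFraction Fraction of reads replaced by 20-49 bp
#'   artefacts (default 0).
#' @param degradeShortReads Degrade mapping of sub-50 bp reads
#'   (default FALSE).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      genome = c(chr1 = 1e6, chr2 = 1e6),
                      cpgSpacing = 100,
                      hmcFraction = 0.01,
                      regions = GRanges(),
                      captureEfficiency = 0.9,
                      nonspecificRate = 0.1,
                      nFragments = 500000L,
                      fragmentMean = 300, fragmentSd = 75,
                      fragmentMin = 100, fragmentMax = 500,
                      sizeSelectMin = 100, sizeSelectMax = 250,
                      wgaCycles = 10L, wgaBiasSd = 0,
                      readMean = 137, readSd = 15,
                      inputFraction = 0.1,
                      depth = 200000L,
                      adapterFraction = 0,
                      degradeShortReads = FALSE) {
  new("SimConfig", seed = as.integer(seed), genome = genome,
      cpgSpacing = cpgSpacing, hmcFraction = hmcFraction,
      regions = regions, captureEfficiency = captureEfficiency,
      nonspecificRate = nonspecificRate,
      nFragments = as.integer(nFragments), fragmentMean = fragmentMean,
      fragmentSd = fragmentSd, fragmentMin = fragmentMin,
      fragmentMax = fragmentMax, sizeSelectMin = sizeSelectMin,
      sizeSelectMax = sizeSelectMax, wgaCycles = as.integer(wgaCycles),
      wgaBiasSd = wgaBiasSd, readMean = readMean, readSd = readSd,
      inputFraction = inputFraction, depth = as.integer(depth),
      adapterFraction = adapterFraction,
      degradeShortReads = degradeShortReads)
}

#' Bundled example configuration with planted enriched regions
#'
#' Two 1 Mb synthetic chromosomes with ten planted 2 kb enriched regions
#' (five per chromosome, marking multiplier 50 over a 1% baseline, i.e.
#' half the CpGs inside a region are modified).  Used throughout the test
#' suite as the reference recovery fixture.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simConfig()].
#' @return A [SimConfig-class].
#' @export
simConfigExample <- function(seed = 1L, ...) {
  starts <- c(150001, 300001, 450001, 600001, 750001)
  regions <- GRanges(rep(c("chr1", "chr2"), each = 5),
                     IRanges(rep(starts, 2), width = 2000))
  mcols(regions)$multiplier <- rep(50, 10)
  simConfig(seed = seed, regions = regions, ...)
}

#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d chromosome(s) (%.2g Mb), %d fragments, depth %d, seed %d\n",
    length(object@genome), sum(object@genome) / 1e6, object@nFragments,
    object@depth, object@seed))
  cat(sprintf(
    "  marking %.3g/CpG (spacing %g bp), %d enriched region(s); capture %.2g, nonspecific %.2g\n",
    object@hmcFraction, object@cpgSpacing, length(object@regions),
    object@captureEfficiency, object@nonspecificRate))
})

## CpG positions for one chromosome: Poisson process with the configured
## mean spacing, returned as strictly increasing 1-based integers.
.placeCpGs <- function(len, spacing) {
  expected <- len / spacing
  pos <- numeric(0)
  last <- 0
  while (last < len) {
    k <- max(100, ceiling((len - last) / spacing * 1.2) + 50)
    gaps <- rexp(k, rate = 1 / spacing)
    pos <- c(pos, last + cumsum(gaps))
    last <- pos[length(pos)]
  }
  unique(pmax(1, floor(pos[pos <= len])))
}

## Number of marked sites on each fragment, per chromosome.
.countMarked <- function(chrom, start1, end1, markedSites) {
  k <- integer(length(chrom))
  for (ch in unique(chrom)) {
    sites <- markedSites[[ch]]
    sel <- chrom == ch
    if (is.null(sites) || length(sites) == 0L) next
    k[sel] <- findInterval(end1[sel], sites) -
      findInterval(start1[sel] - 1, sites)
  }
  k
}

#' Simulate a full IP/input sequencing run
#'
#' Executes the protocol stages in order (see [SimConfig-class]) and
#' returns the sequenced reads of the IP and input samples together with
#' the ground truth.  All randomness comes from a single generator seeded
#' with \code{config@seed}, so identical configurations reproduce
#' byte-identical output; the caller's RNG state is left untouched.
#'
#' Reads sequenced from the same original fragment beyond the first are
#' flagged as duplicates (amplification makes such repeats common when the
#' captured pool is smaller than the sequencing depth); downstream
#' counting drops them by default, which collapses each fragment to a
#' single observation.
#'
#' @param config A [SimConfig-class].
#' @param keepFragments If \code{TRUE}, also return the pre-sequencing
#'   fragment pools (useful for checking amplification neutrality).
#' @param truth Optional [SimTruth-class] from a previous run: reuse its
#'   marked sites instead of drawing new ones, so that biological
#'   replicates (independent fragmentation, capture and sequencing of the
#'   same underlying modification state) can be simulated.
#' @return A list with elements \code{ip} and \code{input} (read tables as
#'   documented in [readAlignments()]), \code{truth} (a
#'   [SimTruth-class]), and optionally \code{ipPool}/\code{inputPool}.
#' @export
simulateRun <- function(config, keepFragments = FALSE, truth = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!is.null(truth)) {
    stopifnot(is(truth, "SimTruth"))
    if (!identical(truth@config@genome, config@genome))
      stop("supplied truth was generated on a different genome")
  }
  .withSeed(config@seed, {
    genome <- config@genome
    chroms <- names(genome)

    ## (1) CpG placement and (2) marking (skipped when truth is supplied)
    if (is.null(truth)) {
      markedSites <- list()
      for (ch in chroms) {
        pos <- .placeCpGs(genome[[ch]], config@cpgSpacing)
        p <- rep(config@hmcFraction, length(pos))
        if (length(config@regions)) {
          reg <- config@regions[seqnames(config@regions) == ch]
          if (length(reg)) {
            hits <- findOverlaps(IRanges(pos, pos), ranges(reg))
            p[queryHits(hits)] <- pmin(
              1, config@hmcFraction * reg$multiplier[subjectHits(hits)])
          }
        }
        markedSites[[ch]] <- pos[runif(length(pos)) < p]
      }
      truth <- new("SimTruth", markedSites = markedSites,
                   regions = config@regions, config = config)
    } else {
      markedSites <- truth@markedSites
    }

    ## (3) fragmentation
    n <- config@nFragments
    chromIdx <- sample.int(length(genome), n, replace = TRUE,
                           prob = genome / sum(genome))
    fragChrom <- chroms[chromIdx]
    fragLen <- pmin(pmax(round(rnorm(n, config@fragmentMean,
                                     config@fragmentSd)),
                         config@fragmentMin), config@fragmentMax)
    fragStart1 <- floor(runif(n) * (genome[chromIdx] - fragLen + 1)) + 1
    fragEnd1 <- fragStart1 + fragLen - 1

    ## (4) input aliquot
    isInput <- runif(n) < config@inputFraction

    ## (5) antibody capture of the IP pool
    ipCand <- which(!isInput)
    k <- .countMarked(fragChrom[ipCand], fragStart1[ipCand],
                      fragEnd1[ipCand], markedSites)
    pCap <- 1 - (1 - config@captureEfficiency)^k
    pCap[k == 0] <- config@nonspecificRate
    captured <- ipCand[runif(length(ipCand)) < pCap]

    ## (6) amplification weights and (7) size selection
    pool <- function(idx) {
      wt <- rep(2^config@wgaCycles, length(idx))
      if (config@wgaBiasSd > 0)
        wt <- wt * exp(rnorm(length(idx), 0, config@wgaBiasSd))
      sel <- fragLen[idx] >= config@sizeSelectMin &
        fragLen[idx] <= config@sizeSelectMax
      list(idx = idx[sel], weight = wt[sel])
    }
    ipPool <- pool(captured)
    inputPool <- pool(which(isInput))
    if (length(ipPool$idx) == 0L)
      stop("no IP fragments survived capture and size selection")
    if (length(inputPool$idx) == 0L)
      stop("no input fragments survived size selection")

    ## (8) sequencing
    sequence <- function(p) {
      draw <- sample.int(length(p$idx), config@depth, replace = TRUE,
                         prob = p$weight)
      idx <- p$idx[draw]
      readLen <- pmin(fragLen[idx],
                      pmax(20, round(rnorm(config@depth, config@readMean,
                                           config@readSd))))
      if (config@adapterFraction > 0) {
        art <- runif(config@depth) < config@adapterFraction
        readLen[art] <- sample(20:49, sum(art), replace = TRUE)
      }
      mapped <- rep(TRUE, config@depth)
      mapq <- rep(60L, config@depth)
      if (config@degradeShortReads) {
        short <- readLen < 50
        mapq[short] <- 10L
        mapped[short] <- runif(sum(short)) >= 0.6
      }
      reads <- DataFrame(
        chrom = ifelse(mapped, fragChrom[idx], NA_character_),
        start = ifelse(mapped, as.integer(fragStart1[idx]), NA_integer_),
        alignedLength = ifelse(mapped, as.integer(readLen), NA_integer_),
        mapped = mapped,
        mapq = mapq,
        readLength = as.integer(readLen),
        duplicate = duplicated(draw))
      ord <- order(match(reads$chrom, chroms), reads$start,
                   reads$readLength, na.last = TRUE)
      reads[ord, , drop = FALSE]
    }
    ip <- sequence(ipPool)
    input <- sequence(inputPool)

    out <- list(ip = ip, input = input, truth = truth)
    if (keepFragments) {
      out$ipPool <- DataFrame(chrom = fragChrom[ipPool$idx],
                              start = as.integer(fragStart1[ipPool$idx]),
                              length = as.integer(fragLen[ipPool$idx]),
                              weight = ipPool$weight)
      out$inputPool <- DataFrame(chrom = fragChrom[inputPool$idx],
                                 start = as.integer(fragStart1[inputPool$idx]),
                                 length = as.integer(fragLen[inputPool$idx]),
                                 weight = inputPool$weight)
    }
    out
  })
}

#' Write a simulated run to disk
#'
#' Emits coordinate-sorted SAM files for the IP and input samples, a BED
#' file of the planted enriched regions and (optionally) a bedGraph of the
#' closed-form expected enrichment.
#'
#' @param sim Result of [simulateRun()].
#' @param dir Output directory (created if needed).
#' @param expected Optional [WindowTrack-class] from
#'   [expectedWindowEnrichment()] to serialize alongside.
#' @return Named character vector of the files written.
#' @export
writeSimulation <- function(sim, dir, expected = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- sim$truth@config@genome
  files <- c(ip = file.path(dir, "ip.sam"),
             input = file.path(dir, "input.sam"),
             regions = file.path(dir, "truth_regions.bed"))
  writeSam(sim$ip, genome, files[["ip"]])
  writeSam(sim$input, genome, files[["input"]])
  reg <- sim$truth@regions
  regLines <- if (length(reg))
    sprintf("%s\t%d\t%d\tregion_%d\t%g\t.",
            as.character(seqnames(reg)), start(reg) - 1L, end(reg),
            seq_along(reg), reg$multiplier)
  else character(0)
  con <- file(files[["regions"]], open = "wb")
  if (length(regLines)) writeLines(regLines, con, sep = "\n")
  close(con)
  if (!is.null(expected)) {
    files[["expected"]] <- file.path(dir, "expected_enrichment.bedgraph")
    writeBedGraph(expected, files[["expected"]])
  }
  files
}
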