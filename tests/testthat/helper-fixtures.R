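# Fixture builders shared across the suite.  All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(withr)
})

# Read table with per-column defaults, in the layout readAlignments emits.
makeReads <- function(chrom, start, alignedLength = 100L,
                      mapped = TRUE, mapq = 60L,
                      readLength = alignedLength, duplicate = FALSE) {
  n <- max(length(chrom), length(start))
  S4Vectors::DataFrame(
    chrom = rep_len(chrom, n), start = rep_len(as.integer(start), n),
    alignedLength = rep_len(as.integer(alignedLength), n),
    mapped = rep_len(mapped, n), mapq = rep_len(as.integer(mapq), n),
    readLength = rep_len(as.integer(readLength), n),
    duplicate = rep_len(duplicate, n))
}

# Uniform random mapped reads on a grid's genome.
randomReads <- function(n, chromSizes, seed,
                        lengths = 100L) {
  withr::with_seed(seed, {
    chrom <- sample(names(chromSizes), n, replace = TRUE)
    len <- rep_len(as.integer(lengths), n)
    start <- floor(runif(n) * (chromSizes[chrom] - len)) + 1L
    makeReads(chrom, start, alignedLength = len, readLength = len)
  })
}

# Brute-force midpoint binning: the independent oracle for countReads.
bruteForceCounts <- function(reads, grid) {
  win <- gridWindows(grid)
  counts <- numeric(length(win))
  winChrom <- as.character(GenomicRanges::seqnames(win))
  winStart0 <- GenomicRanges::start(win) - 1L
  winEnd0 <- GenomicRanges::end(win)
  reads <- reads[reads$mapped & reads$chrom %in% names(grid@chromSizes), ,
                 drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    mid0 <- (reads$start[i] - 1L) + reads$alignedLength[i] %/% 2L
    mid0 <- min(max(mid0, 0), grid@chromSizes[[reads$chrom[i]]] - 1)
    inWin <- which(winChrom == reads$chrom[i] & winStart0 <= mid0 &
                     mid0 < winEnd0)
    counts[max(inWin)] <- counts[max(inWin)] + 1  # latest-start window
  }
  counts
}

# Exact upper Poisson tail by direct term summation (independent of ppois).
exactPoissonTail <- function(obs, lambda) {
  if (obs <= 0) return(1)
  # sum P(X = x) for x = obs .. obs + K, K chosen so the remainder is
  # negligible at the tolerances tested
  x <- obs:(obs + max(200, ceiling(10 * lambda + 50)))
  sum(exp(x * log(lambda) - lambda - lgamma(x + 1)))
}

# Small deterministic gene annotation written as BED, returned as a path.
writeGeneBed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# A small simulated experiment reused by several files (cached per session).
.smallSimCache <- new.env(parent = emptyenv())
smallSim <- function() {
  if (is.null(.smallSimCache$sim)) {
    reg <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                  IRanges::IRanges(c(40001, 90001),
                                                   width = 2000))
    reg$multiplier <- c(50, 50)
    cfg <- simConfig(seed = 303, genome = c(chr1 = 2e5, chr2 = 2e5),
                     regions = reg, nFragments = 100000L, depth = 50000L)
    .smallSimCache$sim <- simulateRun(cfg)
    .smallSimCache$grid <- WindowGrid(cfg@genome, 200)
  }
  list(sim = .smallSimCache$sim, grid = .smallSimCache$grid)
}

dedup <- function(reads) reads[!reads$duplicate, , drop = FALSE]
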