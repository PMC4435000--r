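test_that("window Poisson tail agrees with exact summation", {
  for (lambda in c(0.5, 5, 20, 100)) {
    obs <- unique(pmax(1L, floor(seq(0, 5 * lambda, length.out = 12))))
    for (o in obs) {
      expect_equal(dipscan:::.poissonTail(o, lambda),
                   exactPoissonTail(o, lambda),
                   tolerance = 1e-10,
                   info = sprintf("lambda=%g obs=%d", lambda, o))
    }
  }
})

test_that("identical IP and input yield zero peaks", {
  grid <- WindowGrid(c(chr1 = 10000), windowSize = 200)
  vals <- withr::with_seed(3, rpois(50, 20))
  ip <- WindowTrack(grid, vals, units = "raw_count", librarySize = sum(vals))
  expect_length(callPeaks(ip, ip), 0L)
})

test_that("a single strongly enriched window gives the exact Poisson p", {
  grid <- WindowGrid(c(chr1 = 20000), windowSize = 200)  # 100 windows
  inputVals <- rep(20, 100)
  ipVals <- rep(20, 100); ipVals[40] <- 200
  ip <- WindowTrack(grid, ipVals, units = "raw_count",
                    librarySize = sum(ipVals))
  inp <- WindowTrack(grid, inputVals, units = "raw_count",
                     librarySize = sum(inputVals))
  peaks <- callPeaks(ip, inp)
  expect_length(peaks, 1L)
  expect_equal(peaks$nWindows, 1)
  # expectation is input * libIP/libInput; smoothing leaves a flat input
  # untouched, so the unadjusted p is the plain upper tail
  lambda <- 20 * sum(ipVals) / sum(inputVals)
  tests <- windowTests(ip, inp)
  expect_equal(tests$p[40], exactPoissonTail(200, lambda),
               tolerance = 1e-10)
})

test_that("adjacent significant windows merge; gaps split peaks", {
  grid <- WindowGrid(c(chr1 = 4000), windowSize = 200)  # 20 windows
  inputVals <- rep(10, 20)
  ipVals <- rep(10, 20)
  ipVals[5:7] <- 120
  ipVals[10] <- 120
  ip <- WindowTrack(grid, ipVals, units = "raw_count",
                    librarySize = sum(ipVals))
  inp <- WindowTrack(grid, inputVals, units = "raw_count",
                     librarySize = sum(inputVals))
  peaks <- callPeaks(ip, inp)
  expect_length(peaks, 2L)
  expect_equal(peaks$nWindows, c(3, 1))
  expect_equal(start(peaks) - 1L, c(800L, 1800L))
  expect_equal(end(peaks), c(1400L, 2000L))
  # peak score is the max window log2 ratio, q the min window q
  wt <- windowTests(ip, inp)
  expect_equal(peaks$log2Enrichment[1], max(wt$log2CPM[5:7]))
  expect_equal(peaks$qValue[1], min(wt$q[5:7]))
})

test_that("peaks never straddle chromosome boundaries", {
  grid <- WindowGrid(c(chr1 = 1000, chr2 = 1000), windowSize = 200)
  ipVals <- rep(10, 10); ipVals[4:7] <- 150  # windows 4-5 on chr1, 6-7 on chr2
  inputVals <- rep(10, 10)
  ip <- WindowTrack(grid, ipVals, units = "raw_count",
                    librarySize = sum(ipVals))
  inp <- WindowTrack(grid, inputVals, units = "raw_count",
                     librarySize = sum(inputVals))
  peaks <- callPeaks(ip, inp)
  expect_length(peaks, 2L)
  expect_equal(as.character(seqnames(peaks)), c("chr1", "chr2"))
})

test_that("thresholds act monotonically on the significant-window set", {
  s <- smallSim()
  ip <- countReads(dedup(s$sim$ip), s$grid, "ip")
  inp <- countReads(dedup(s$sim$input), s$grid, "input")
  nSig <- function(alpha, minLog2) {
    wt <- windowTests(ip, inp)
    sum(wt$q <= alpha & wt$log2CPM >= minLog2)
  }
  expect_gte(nSig(0.05, 1), nSig(0.01, 1))
  expect_gte(nSig(0.05, 1), nSig(0.05, 2))
  expect_gte(length(callPeaks(ip, inp, alpha = 0.05)),
             length(callPeaks(ip, inp, alpha = 0.001)))
  expect_gte(length(callPeaks(ip, inp, minLog2 = 1)),
             length(callPeaks(ip, inp, minLog2 = 3)))
})

test_that("degenerate libraries are rejected", {
  grid <- WindowGrid(c(chr1 = 1000), windowSize = 200)
  zero <- WindowTrack(grid, rep(0, 5), units = "raw_count", librarySize = 0)
  some <- WindowTrack(grid, rep(2, 5), units = "raw_count", librarySize = 10)
  expect_error(callPeaks(some, zero), "empty library")
  other <- WindowGrid(c(chr1 = 1200), windowSize = 200)
  expect_error(
    callPeaks(some, WindowTrack(other, rep(2, 6), units = "raw_count",
                                librarySize = 12)), "grids")
})

test_that("compartment precedence is promoter-first", {
  # one + strand gene [10000, 30000) with TSS at 10000 (0-based)
  bed <- writeGeneBed("chr1\t10000\t30000\tgeneA\t0\t+")
  genes <- loadGenes(bed)
  scheme <- compartmentScheme()
  peakAt <- function(mid0) {
    g <- GRanges("chr1", IRanges(mid0 + 1, mid0 + 1))
    g
  }
  expect_equal(as.character(assignCompartment(peakAt(10000), genes, scheme)),
               "promoter_core")
  # 1500 bp downstream of the TSS, inside the body: proximal beats intragenic
  expect_equal(as.character(assignCompartment(peakAt(11500), genes, scheme)),
               "promoter_proximal")
  expect_equal(as.character(assignCompartment(peakAt(15000), genes, scheme)),
               "promoter_distal")
  expect_equal(as.character(assignCompartment(peakAt(25000), genes, scheme)),
               "intragenic")
  expect_equal(as.character(assignCompartment(peakAt(999000), genes, scheme)),
               "intergenic")
  # boundary: exactly coreRadius away is still core
  expect_equal(as.character(assignCompartment(peakAt(10500), genes, scheme)),
               "promoter_core")
})

test_that("every peak gets exactly one label, even with no genes", {
  withr::with_seed(11, {
    peaks <- GRanges("chr1", IRanges(sort(sample(1:900000, 50)), width = 400))
    labels <- assignCompartment(peaks, GRanges())
    expect_length(labels, 50L)
    expect_false(any(is.na(labels)))
    expect_true(all(labels == "intergenic"))
    bed <- writeGeneBed(c("chr1\t100000\t150000\tg1\t0\t+",
                          "chr1\t400000\t420000\tg2\t0\t-"))
    labs2 <- assignCompartment(peaks, loadGenes(bed))
    expect_false(any(is.na(labs2)))
  })
})

test_that("compartment distribution sums to 100 and is order-invariant", {
  bed <- writeGeneBed("chr1\t100000\t130000\tgeneA\t0\t+")
  genes <- loadGenes(bed)
  mids0 <- c(100000, 101500, 120000, 125000)  # core, proximal, 2x intragenic
  peaks <- GRanges("chr1", IRanges(mids0 + 1, mids0 + 1))
  dist <- compartmentDistribution(peaks, genes)
  expect_equal(sum(dist), 100, tolerance = 1e-9)
  expect_equal(unname(dist[c("promoter_core", "promoter_proximal",
                             "promoter_distal", "intragenic",
                             "intergenic")]),
               c(25, 25, 0, 50, 0))
  perm <- compartmentDistribution(peaks[c(3, 1, 4, 2)], genes)
  expect_equal(dist, perm)
  expect_error(compartmentDistribution(peaks[0], genes), "no peaks")
})
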