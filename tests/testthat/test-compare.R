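test_that("random window sampling is deterministic, distinct and exhaustive", {
  grid <- WindowGrid(c(chr1 = 10000, chr2 = 6000), windowSize = 200)
  total <- windowCount(grid)  # 80
  full <- sampleRandomWindows(grid, total, seed = 1)
  expect_setequal(full, seq_len(total))
  a <- sampleRandomWindows(grid, 30, seed = 99)
  b <- sampleRandomWindows(grid, 30, seed = 99)
  expect_identical(a, b)
  expect_false(anyDuplicated(a) > 0)
  expect_error(sampleRandomWindows(grid, total + 1, seed = 1),
               as.character(total))
})

test_that("inclusion frequency is uniform across windows", {
  grid <- WindowGrid(c(chr1 = 8000), windowSize = 200)  # 40 windows
  n <- 10L
  trials <- 400
  hits <- numeric(windowCount(grid))
  for (s in seq_len(trials)) {
    idx <- sampleRandomWindows(grid, n, seed = s)
    hits[idx] <- hits[idx] + 1
  }
  p <- n / windowCount(grid)
  se <- sqrt(p * (1 - p) / trials)
  expect_true(all(abs(hits / trials - p) <= 3 * se + 1e-9))
})

test_that("pairwise concordance matches the textbook formula", {
  grid <- WindowGrid(c(chr1 = 800), windowSize = 200)
  a <- WindowTrack(grid, c(1, 2, 3, 4), units = "cpm", sampleId = "a")
  b <- WindowTrack(grid, c(2, 4, 5, 4), units = "cpm", sampleId = "b")
  # independent evaluation of sum-form Pearson formula
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4); n <- 4
  rOracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  cc <- pairwiseConcordance(a, b)
  expect_equal(cc$pearsonR, rOracle, tolerance = 1e-12)
  expect_equal(cc$rSquared, rOracle^2, tolerance = 1e-12)
  # symmetry, self- and anti-correlation
  expect_equal(pairwiseConcordance(b, a)$pearsonR, cc$pearsonR)
  expect_equal(pairwiseConcordance(a, a)$pearsonR, 1)
  neg <- WindowTrack(grid, -x, units = "log2_ratio", sampleId = "neg")
  expect_equal(pairwiseConcordance(a, neg)$pearsonR, -1)
  expect_equal(pairwiseConcordance(a, neg)$rSquared, 1)
  flat <- WindowTrack(grid, rep(2, 4), units = "cpm", sampleId = "flat")
  expect_error(pairwiseConcordance(a, flat), "degenerate track")
  expect_error(pairwiseConcordance(a, b, indices = 1:2), "at least 3")
})

test_that("correlation matrix clusters concordant samples together", {
  grid <- WindowGrid(c(chr1 = 40000), windowSize = 200)
  withr::with_seed(31, {
    base <- rnorm(200)
    t1 <- WindowTrack(grid, base + rnorm(200, sd = 0.1),
                      units = "log2_ratio", sampleId = "rep1")
    t2 <- WindowTrack(grid, base + rnorm(200, sd = 0.1),
                      units = "log2_ratio", sampleId = "rep2")
    t3 <- WindowTrack(grid, rnorm(200), units = "log2_ratio",
                      sampleId = "noise")
    cm <- correlationMatrix(list(t1, t3, t2))
    expect_equal(diag(cm@r), c(rep1 = 1, noise = 1, rep2 = 1))
    expect_equal(cm@r, t(cm@r))
    ord <- cm@sampleIds[cm@linkageOrder]
    pos <- match(c("rep1", "rep2"), ord)
    expect_equal(abs(diff(pos)), 1L)  # replicates adjacent in leaf order
    # permutation equivariance: same r values by sample id
    cm2 <- correlationMatrix(list(t3, t1, t2))
    expect_equal(cm2@r[cm@sampleIds, cm@sampleIds], cm@r)
  })
})

test_that("difference tracks subtract elementwise and antisymmetrize", {
  grid <- WindowGrid(c(chr1 = 1000), windowSize = 200)
  a <- WindowTrack(grid, c(1, -1, 0, 2, 0.5), units = "log2_ratio",
                   sampleId = "pb")
  b <- WindowTrack(grid, c(0, 1, 0, -2, 0.5), units = "log2_ratio",
                   sampleId = "ctrl")
  d <- differenceTrack(a, b)
  expect_equal(trackValues(d), c(1, -2, 0, 4, 0))
  expect_equal(sampleId(d), "pb_minus_ctrl")
  expect_equal(trackValues(differenceTrack(b, a)), -trackValues(d))
  expect_equal(trackValues(differenceTrack(a, a)), rep(0, 5))
  cpm <- WindowTrack(grid, 1:5, units = "cpm")
  expect_error(differenceTrack(a, cpm), "units")
})

test_that("a condition-specific region dominates the difference track", {
  # treated and control share the same background modification state; the
  # treated sample additionally gains dense marking over one gene region
  reg <- GRanges("chr1", IRanges(40001, width = 2000))
  reg$multiplier <- 80
  cfgT <- simConfig(seed = 61, genome = c(chr1 = 2e5), regions = reg,
                    nFragments = 400000L, depth = 100000L)
  simT <- simulateRun(cfgT)
  cfgC <- simConfig(seed = 62, genome = c(chr1 = 2e5),
                    nFragments = 400000L, depth = 100000L)
  sitesC <- lapply(simT$truth@markedSites, function(pos)
    pos[pos < 40001 | pos > 42000])
  truthC <- new("SimTruth", markedSites = sitesC, regions = GRanges(),
                config = cfgC)
  simC <- simulateRun(cfgC, truth = truthC)
  grid <- WindowGrid(cfgT@genome, 200)
  lr <- function(sim)
    log2Ratio(toCPM(countReads(dedup(sim$ip), grid)),
              toCPM(countReads(dedup(sim$input), grid)))
  d <- trackValues(differenceTrack(lr(simT), lr(simC)))
  inRegion <- which(start(gridWindows(grid)) >= 40001 &
                      end(gridWindows(grid)) <= 42000)
  # rank test: the gained region dominates the positive tail
  w <- wilcox.test(d[inRegion], d[-inRegion], alternative = "greater")
  expect_lt(w$p.value, 1e-6)
  expect_true(all(d[inRegion] > 1))
  expect_gte(mean(inRegion %in% order(d, decreasing = TRUE)[1:25]), 0.9)
})

test_that("metagene of a constant track is flat at the constant", {
  grid <- WindowGrid(c(chr1 = 100000), windowSize = 200)
  track <- WindowTrack(grid, rep(3.5, windowCount(grid)), units = "cpm")
  bed <- writeGeneBed(c("chr1\t20000\t40000\tg1\t0\t+",
                        "chr1\t50000\t58000\tg2\t0\t-"))
  prof <- metagene(track, loadGenes(bed), nBodyBins = 100)
  expect_length(prof@values, 150L)
  expect_equal(prof@values, rep(3.5, 150), tolerance = 1e-9)
  expect_equal(prof@nGenes, 2L)
  expect_error(metagene(track, GRanges()), "empty gene set")
})

test_that("metagene resolves a body-only signal as a step function", {
  grid <- WindowGrid(c(chr1 = 100000), windowSize = 200)
  vals <- numeric(windowCount(grid))
  # gene [20000, 40000): signal 5 inside the body, 0 outside
  bodyWin <- which(start(gridWindows(grid)) - 1 >= 20000 &
                     end(gridWindows(grid)) <= 40000)
  vals[bodyWin] <- 5
  track <- WindowTrack(grid, vals, units = "cpm")
  genes <- loadGenes(writeGeneBed("chr1\t20000\t40000\tg1\t0\t+"))
  prof <- metagene(track, genes, nBodyBins = 100)
  expect_equal(prof@values[26:125], rep(5, 100), tolerance = 1e-9)
  expect_equal(prof@values[c(1:25, 126:150)], rep(0, 50), tolerance = 1e-9)
})

test_that("minus-strand genes mirror the plus-strand profile", {
  grid <- WindowGrid(c(chr1 = 100000), windowSize = 200)
  vals <- seq_len(windowCount(grid))  # ascending genomic gradient
  track <- WindowTrack(grid, vals, units = "cpm")
  plus <- loadGenes(writeGeneBed("chr1\t20000\t40000\tg\t0\t+"))
  minus <- loadGenes(writeGeneBed("chr1\t20000\t40000\tg\t0\t-"))
  pPlus <- metagene(track, plus)
  pMinus <- metagene(track, minus)
  expect_equal(pMinus@values, rev(pPlus@values), tolerance = 1e-9)
})

test_that("metagene is linear in the track", {
  grid <- WindowGrid(c(chr1 = 50000), windowSize = 200)
  withr::with_seed(77, {
    a <- WindowTrack(grid, rnorm(windowCount(grid)), units = "log2_ratio")
    b <- WindowTrack(grid, rnorm(windowCount(grid)), units = "log2_ratio")
  })
  ab <- WindowTrack(grid, trackValues(a) + trackValues(b),
                    units = "log2_ratio")
  genes <- loadGenes(writeGeneBed(c("chr1\t9000\t21000\tg1\t0\t+",
                                    "chr1\t30000\t42000\tg2\t0\t-")))
  pa <- metagene(a, genes)@values
  pb <- metagene(b, genes)@values
  pab <- metagene(ab, genes)@values
  expect_equal(pab, pa + pb, tolerance = 1e-9)
})

test_that("flanks beyond chromosome ends are dropped per gene", {
  grid <- WindowGrid(c(chr1 = 10000), windowSize = 200)
  track <- WindowTrack(grid, rep(1, windowCount(grid)), units = "cpm")
  # 5' flank of this gene would start at -500
  genes <- loadGenes(writeGeneBed("chr1\t1000\t7000\tg1\t0\t+"))
  prof <- metagene(track, genes)
  expect_true(all(prof@binCounts[1:3] == 0))  # fully off-chromosome bins
  expect_true(all(prof@values[prof@binCounts > 0] == 1))
})
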