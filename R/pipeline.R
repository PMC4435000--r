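## End-to-end driver: QC -> length filter -> window counts -> CPM ->
## log2 ratio -> peaks -> annotation -> metagene, with a validate-then-run
## contract (no output is written unless the whole configuration
## validates) and a deterministic manifest of everything written.

#' Construct and validate a pipeline configuration
#'
#' @param ip,input Paths to the IP and input SAM/BAM files.
#' @param chromSizes Named vector of chromosome lengths, or a chrom.sizes
#'   TSV path.
#' @param outDir Output directory.
#' @param genes Optional gene annotation path (GTF/BED) enabling peak
#'   annotation and the metagene profile.
#' @param windowSize,step Window grid parameters in bp (defaults 200/200).
#' @param minReadLength Short-read cutoff in bp (default 50).
#' @param pseudocount Pseudocount for log2 ratios (default 0.5).
#' @param alpha,minLog2 Peak-calling thresholds (defaults 0.05, 1).
#' @param scheme [CompartmentScheme-class] for annotation.
#' @param seed Integer seed for seeded stages.
#' @return A validated configuration (classed list).
#' @export
pipelineConfig <- function(ip, input, chromSizes, outDir, genes = NULL,
                           windowSize = 200L, step = windowSize,
                           minReadLength = 50, pseudocount = 0.5,
                           alpha = 0.05, minLog2 = 1,
                           scheme = compartmentScheme(), seed = 1L) {
  for (f in c(ip, input, genes))
    if (!file.exists(f)) stop(sprintf("input file does not exist: %s", f))
  if (is.character(chromSizes) && length(chromSizes) == 1L) {
    if (!file.exists(chromSizes))
      stop(sprintf("input file does not exist: %s", chromSizes))
    chromSizes <- readChromSizes(chromSizes)
  }
  if (step > windowSize || step < 1L)
    stop("need 0 < step <= windowSize")
  if (minReadLength < 0) stop("minReadLength must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  stopifnot(is(scheme, "CompartmentScheme"))
  ## constructing the grid validates chromSizes
  grid <- WindowGrid(chromSizes, windowSize, step)
  structure(list(ip = ip, input = input, chromSizes = chromSizes,
                 outDir = outDir, genes = genes, windowSize = windowSize,
                 step = step, minReadLength = minReadLength,
                 pseudocount = pseudocount, alpha = alpha,
                 minLog2 = minLog2, scheme = scheme,
                 seed = as.integer(seed), grid = grid),
            class = "PipelineConfig")
}

## Hash of the semantic configuration fields.  The output directory is
## excluded (it does not change what is computed); input paths are kept.
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fields <- config[setdiff(names(config), c("grid", "outDir"))]
  fields$scheme <- c(config$scheme@coreRadius, config$scheme@proximalRadius,
                     config$scheme@distalRadius)
  writeLines(paste(names(fields),
                   vapply(fields, function(x) paste(deparse(x), collapse = ""),
                          character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full enrichment pipeline
#'
#' Executes, in order: read QC on both samples, short-read filtering,
#' window counting, CPM normalization, the IP/input log2 ratio track,
#' peak calling, and (when an annotation is supplied) compartment
#' annotation of peaks and the metagene profile of the log2 track.  Any
#' stage failure aborts with an error naming the stage; nothing is
#' written unless the configuration validated.
#'
#' @param config A configuration from [pipelineConfig()].
#' @return Invisibly, the manifest data frame: one row per output file
#'   with its row count, plus the configuration hash and seed.  The same
#'   table is written to \code{manifest.tsv} in the output directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  grid <- config$grid
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  path <- function(f) file.path(config$outDir, f)

  reads <- list()
  tracks <- list()
  for (s in c("ip", "input")) {
    r <- stage("read", readAlignments(config[[s]]))
    stage("qc", writeQCReport(qcReport(r), path(sprintf("qc_%s.tsv", s))))
    outputs <- c(outputs, sprintf("qc_%s.tsv", s))
    r <- stage("filter", filterByLength(r, config$minReadLength)$reads)
    reads[[s]] <- r
    cnt <- stage("count", countReads(r, grid, sampleId = s))
    tracks[[s]] <- cnt
    cpm <- stage("normalize", toCPM(cnt))
    stage("write", writeBedGraph(cpm, path(sprintf("%s.bedgraph", s))))
    outputs <- c(outputs, sprintf("%s.bedgraph", s))
  }
  lr <- stage("ratio", log2Ratio(toCPM(tracks$ip), toCPM(tracks$input),
                                 pseudocount = config$pseudocount))
  stage("write", writeBedGraph(lr, path("log2.bedgraph")))
  outputs <- c(outputs, "log2.bedgraph")

  peaks <- stage("callpeaks",
                 callPeaks(tracks$ip, tracks$input,
                           minLog2 = config$minLog2, alpha = config$alpha,
                           pseudocount = config$pseudocount))
  stage("write", writePeaks(peaks, path("peaks.bed")))
  outputs <- c(outputs, "peaks.bed")

  if (!is.null(config$genes)) {
    genes <- stage("annotate", loadGenes(config$genes))
    if (length(peaks)) {
      comp <- stage("annotate",
                    assignCompartment(peaks, genes, config$scheme))
      tab <- data.frame(chrom = as.character(seqnames(peaks)),
                        start = start(peaks) - 1L, end = end(peaks),
                        n_windows = peaks$nWindows,
                        log2_enrichment = peaks$log2Enrichment,
                        q_value = peaks$qValue, compartment = comp)
      write.table(tab, path("annotated.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs <- c(outputs, "annotated.tsv")
    }
    prof <- stage("metagene", metagene(lr, genes))
    stage("write", writeMetagene(prof, path("metagene.tsv")))
    outputs <- c(outputs, "metagene.tsv")
  }

  rows <- vapply(outputs, function(f)
    length(readLines(path(f), warn = FALSE)), integer(1))
  manifest <- data.frame(file = outputs, rows = rows,
                         config_hash = .configHash(config),
                         seed = config$seed, stringsAsFactors = FALSE)
  write.table(manifest, path("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
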