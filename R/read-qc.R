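## Read-length diagnostics.  Semiconductor runs that retain adapter
## fragments or degraded DNA show a second mode of reads under 50 bp; those
## reads map poorly and are excluded before quantification.

#' Read-length and mapping-rate QC report
#'
#' Bins reads by query length and reports the length histogram, the mean
#' length, the fraction of reads under the short-read cutoff and the
#' mapping rate per length bin.  A healthy library has most reads over
#' 100 bp with a mean around 125-150 bp.  Rates are computed on the
#' unfiltered stream; [filterByLength()] is applied downstream.
#'
#' @param reads Read table from [readAlignments()] or [simulateRun()].
#' @param binWidth Histogram bin width in bp (default 10, which resolves
#'   both the 50 bp cutoff and the expected 125-150 bp mode).
#' @param cutoff Short-read cutoff in bp (default 50).
#' @return A [LengthQCReport-class].
#' @export
qcReport <- function(reads, binWidth = 10, cutoff = 50) {
  stopifnot(binWidth > 0)
  len <- reads$readLength
  n <- length(len)
  if (n == 0L)
    return(new("LengthQCReport", histogram = setNames(numeric(0), character(0)),
               meanLength = NA_real_, fractionBelowCutoff = NA_real_,
               mappingRateByBin = setNames(numeric(0), character(0)),
               overallMappingRate = NA_real_, totalReads = 0,
               binWidth = binWidth, cutoff = cutoff))
  bin <- (len %/% binWidth) * binWidth
  histogram <- vapply(split(bin, bin), length, numeric(1))
  rate <- vapply(split(reads$mapped, bin), mean, numeric(1))
  new("LengthQCReport",
      histogram = histogram,
      meanLength = mean(len),
      fractionBelowCutoff = mean(len < cutoff),
      mappingRateByBin = rate,
      overallMappingRate = mean(reads$mapped),
      totalReads = n, binWidth = binWidth, cutoff = cutoff)
}

#' @export
setMethod("show", "LengthQCReport", function(object) {
  cat(sprintf("LengthQCReport: %d reads", as.integer(object@totalReads)))
  if (object@totalReads > 0)
    cat(sprintf(", mean length %.1f bp, %.1f%% < %d bp, %.1f%% mapped",
                object@meanLength, 100 * object@fractionBelowCutoff,
                as.integer(object@cutoff),
                100 * object@overallMappingRate))
  cat("\n")
})

#' Write a QC report as TSV
#'
#' One row per length bin (lower bound, read count, mapping rate) followed
#' by a commented summary stanza.
#'
#' @param report A [LengthQCReport-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeQCReport <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("bin_bp\tn_reads\tmapping_rate", con)
  if (length(report@histogram))
    writeLines(sprintf("%s\t%d\t%.6f", names(report@histogram),
                       as.integer(report@histogram),
                       report@mappingRateByBin), con)
  writeLines(c(
    sprintf("# total_reads\t%d", as.integer(report@totalReads)),
    sprintf("# mean_length\t%.3f", report@meanLength),
    sprintf("# fraction_below_%dbp\t%.6f", as.integer(report@cutoff),
            report@fractionBelowCutoff),
    sprintf("# overall_mapping_rate\t%.6f", report@overallMappingRate)),
    con)
  invisible(path)
}

#' Exclude short reads
#'
#' Drops reads whose query length is under \code{minLength} (strictly:
#' a read of exactly \code{minLength} bp passes).  Short semiconductor
#' reads carry residual adapter or degraded sequence and map with poor
#' accuracy, so the default removes everything under 50 bp.  Input order is
#' preserved and the operation is idempotent.
#'
#' @param reads Read table from [readAlignments()] or [simulateRun()].
#' @param minLength Minimum query length in bp (default 50).
#' @return A list with \code{reads} (the passing table) and \code{nRemoved}.
#' @export
filterByLength <- function(reads, minLength = 50) {
  stopifnot(minLength >= 0)
  keep <- reads$readLength >= minLength
  list(reads = reads[keep, , drop = FALSE], nRemoved = sum(!keep))
}
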