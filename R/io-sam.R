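## Reading aligned reads (SAM/BAM) and writing simulated alignments.
##
## Reads are carried through the pipeline as a DataFrame with one row per
## primary alignment record: chrom (NA when unmapped), start (1-based
## leftmost position), alignedLength (reference span of the alignment),
## mapped, mapq, readLength (query length) and duplicate (PCR/optical
## duplicate flag).  Secondary (flag 256) and supplementary (flag 2048)
## records are always skipped; duplicates (flag 1024) are dropped by
## default because low-cycle whole-genome amplification inflates them.

.FLAG_UNMAPPED <- 4L
.FLAG_SECONDARY <- 256L
.FLAG_DUPLICATE <- 1024L
.FLAG_SUPPLEMENTARY <- 2048L

#' Read primary alignments from a SAM or BAM file
#'
#' Yields one record per primary alignment.  Secondary and supplementary
#' alignments are skipped; unmapped records are retained with
#' \code{mapped = FALSE} so that mapping rates can be computed.  Duplicate
#' records (flag 1024) are excluded unless \code{keepDuplicates = TRUE}.
#'
#' @param path SAM or BAM file.  SAM input is converted with
#'   [Rsamtools::asBam()] on the fly.
#' @param region Optional [GRanges] of length 1; restricts the scan to
#'   mapped reads overlapping the region (requires indexable input).
#' @param keepDuplicates Retain records flagged as duplicates.
#' @return A [S4Vectors::DataFrame] with columns \code{chrom},
#'   \code{start}, \code{alignedLength}, \code{mapped}, \code{mapq},
#'   \code{readLength}, \code{duplicate}.
#' @export
readAlignments <- function(path, region = NULL, keepDuplicates = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!is.null(region) &&
             !file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(hdr) || length(hdr) == 0L)
    stop(sprintf("'%s' has no sequence dictionary in its header", path))
  what <- c("flag", "rname", "pos", "mapq", "cigar", "seq")
  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    chrom <- as.character(seqnames(region))
    if (!chrom %in% names(hdr))
      stop(sprintf("region chromosome '%s' absent from the header", chrom))
    param <- Rsamtools::ScanBamParam(what = what, which = region)
  } else {
    param <- Rsamtools::ScanBamParam(what = what)
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  keep <- bitwAnd(flag, .FLAG_SECONDARY + .FLAG_SUPPLEMENTARY) == 0L
  if (!keepDuplicates)
    keep <- keep & bitwAnd(flag, .FLAG_DUPLICATE) == 0L
  mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  cigar <- res$cigar
  readLength <- ifelse(!is.na(cigar),
                       GenomicAlignments::cigarWidthAlongQuerySpace(
                         ifelse(is.na(cigar), "1M", cigar)),
                       BiocGenerics::width(res$seq))
  alignedLength <- rep(NA_integer_, length(flag))
  okc <- !is.na(cigar)
  alignedLength[okc] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    cigar[okc])
  out <- DataFrame(
    chrom = ifelse(mapped, as.character(res$rname), NA_character_),
    start = ifelse(mapped, res$pos, NA_integer_),
    alignedLength = ifelse(mapped, alignedLength, NA_integer_),
    mapped = mapped,
    mapq = res$mapq,
    readLength = as.integer(readLength),
    duplicate = bitwAnd(flag, .FLAG_DUPLICATE) != 0L)
  out <- out[keep, , drop = FALSE]
  bad <- out$mapped & (is.na(out$chrom) | is.na(out$alignedLength) |
                         out$alignedLength <= 0L)
  if (any(bad))
    stop(sprintf("%d mapped record(s) without usable coordinates", sum(bad)))
  out
}

#' Write aligned reads as a SAM file
#'
#' Serializes a read table (as produced by [simulateRun()]) to a
#' coordinate-sorted SAM file.  Alignments are written as full-length
#' matches; sequences are emitted as N runs of the correct length so that
#' query lengths survive the round trip.  Output is byte-deterministic for
#' identical input.
#'
#' @param reads A [S4Vectors::DataFrame] with the columns documented in
#'   [readAlignments()].
#' @param chromSizes Named vector of chromosome lengths for the header.
#' @param path Output SAM path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(reads, chromSizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromSizes),
                   as.integer(chromSizes)))
  ord <- order(match(reads$chrom, names(chromSizes)), reads$start,
               na.last = TRUE)
  reads <- reads[ord, , drop = FALSE]
  flag <- ifelse(reads$mapped, 0L, .FLAG_UNMAPPED) +
    ifelse(reads$duplicate, .FLAG_DUPLICATE, 0L)
  body <- sprintf("read%d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  seq_len(nrow(reads)),
                  flag,
                  ifelse(reads$mapped, reads$chrom, "*"),
                  ifelse(reads$mapped, reads$start, 0L),
                  ifelse(reads$mapped, reads$mapq, 0L),
                  ifelse(reads$mapped,
                         sprintf("%dM", reads$readLength), "*"),
                  strrep("N", reads$readLength))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
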