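#' Read junction-split alignments from SAM/BAM or a blocks table
#'
#' `blocks_tsv` is a 6-column BED-like table (`chrom`, `start`, `end`,
#' `read_id`, `group`, `strand`; multiple rows per junction-split read,
#' 0-based half-open) for alignment-free testing.  `sam`/`bam` uses
#' htslib via Rsamtools; junction gaps come from the alignment's `N`
#' CIGAR skips and the group label from the `CB` tag (missing tags give
#' group `"NA"`).
#'
#' @param path input file.
#' @param format `"blocks_tsv"`, `"sam"` or `"bam"`.
#' @return a [read_alignments()] object.
#' @export
read_alignments_file <- function(path, format = c("blocks_tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) er_stop("missing file: %s", path)
  if (format == "blocks_tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    reads <- unique(dt[, c("read_id", "chrom", "strand", "group")])
    read_alignments(reads, dt[, c("read_id", "start", "end")])
  } else {
    bam <- if (format == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    gal <- GenomicAlignments::readGAlignments(
      bam, use.names = TRUE,
      param = Rsamtools::ScanBamParam(tag = "CB"))
    grl <- GenomicAlignments::grglist(gal)
    bl <- unlist(grl, use.names = FALSE)
    group <- S4Vectors::mcols(gal)$CB
    if (is.null(group)) group <- rep(NA_character_, length(gal))
    reads <- data.frame(
      read_id = names(gal),
      chrom = as.character(GenomicAlignments::seqnames(gal)),
      strand = as.character(GenomicAlignments::strand(gal)),
      group = as.character(group))
    blocks <- data.frame(
      read_id = rep(names(gal), lengths(grl)),
      start = GenomicRanges::start(bl) - 1L,
      end = GenomicRanges::end(bl))
    read_alignments(reads, blocks)
  }
}

#' Write alignments as SAM or a blocks table
#'
#' The SAM writer emits an unmapped-sequence (`SEQ=*`) single-end record
#' per read with `M`/`N` CIGAR from its blocks and the group label in the
#' `CB` tag; `@SQ` lengths cover the largest block end.
#'
#' @param alns a `ReadAlignments`.
#' @param path output file.
#' @param format `"blocks_tsv"` or `"sam"`.
#' @export
write_alignments_file <- function(alns, path, format = c("blocks_tsv", "sam")) {
  format <- match.arg(format)
  if (format == "blocks_tsv") {
    dt <- merge(alns$blocks, alns$reads, by = "read_id")
    dt <- dt[, c("chrom", "start", "end", "read_id", "group", "strand")]
    data.table::setorder(dt, read_id, start)
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    sp <- read_spans(alns)
    lens <- tapply(sp$span_end, sp$chrom, max) + 1000L
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
    bl <- alns$blocks
    cig <- bl[, list(cigar = {
      w <- end - start
      g <- start[-1] - end[-.N]
      parts <- character(2L * .N - 1L)
      parts[seq(1L, 2L * .N - 1L, by = 2L)] <- paste0(w, "M")
      if (.N > 1L) parts[seq(2L, 2L * .N - 2L, by = 2L)] <- paste0(g, "N")
      paste(parts, collapse = "")
    }, pos = min(start) + 1L), by = "read_id"]
    m <- merge(alns$reads, cig, by = "read_id")
    lines <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tCB:Z:%s",
                     m$read_id, m$chrom, m$pos, m$cigar, m$group)
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}

#' Genomic read intervals with a library size
#'
#' The substrate for RPKM and TSS metaprofiles: plain intervals (0-based
#' half-open) plus a declared library size, which defaults to the number
#' of intervals but may be overridden (e.g. when windows are counted
#' against a down-sampled library whose true depth is known).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param library_size total mapped reads; default `nrow(intervals)`.
#' @return an object of class `ReadSet`.
#' @export
read_set <- function(intervals, library_size = NULL) {
  dt <- data.table::as.data.table(intervals)[, c("chrom", "start", "end")]
  if (any(dt$start >= dt$end)) er_stop("read interval with start >= end")
  if (is.null(library_size)) library_size <- nrow(dt)
  if (library_size <= 0) er_stop("library_size must be positive")
  structure(list(intervals = dt, library_size = as.numeric(library_size)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d intervals, library_size %g\n",
              nrow(x$intervals), x$library_size))
  invisible(x)
}

#' Peak intervals (BED6 / narrowPeak)
#'
#' Intervals with optional narrowPeak score/signal/summit columns
#' preserved.
#'
#' @param df data.frame with `chrom`, `start`, `end` and any extra
#'   narrowPeak columns (`name`, `score`, `strand`, `signalValue`,
#'   `pValue`, `qValue`, `peak`).
#' @return an object of class `PeakSet`.
#' @export
peak_set <- function(df) {
  dt <- data.table::as.data.table(df)
  if (any(dt$start >= dt$end)) er_stop("peak with start >= end")
  structure(list(peaks = dt), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks on %d chromosome(s)\n",
              nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Read intervals from BED / narrowPeak
#'
#' @param path BED3+/narrowPeak file (0-based half-open, as BED).
#' @param what `"reads"` (returns a `ReadSet`) or `"peaks"` (`PeakSet`).
#' @param library_size optional external total for `what = "reads"`.
#' @export
read_intervals_bed <- function(path, what = c("reads", "peaks"),
                               library_size = NULL) {
  what <- match.arg(what)
  if (!file.exists(path)) er_stop("missing file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  np_names <- c("chrom", "start", "end", "name", "score", "strand",
                "signalValue", "pValue", "qValue", "peak")
  data.table::setnames(dt, np_names[seq_len(min(ncol(dt), 10))])
  if (what == "reads") read_set(dt, library_size) else peak_set(dt)
}

#' Write a ReadSet / PeakSet as BED or narrowPeak
#'
#' @param x a `ReadSet` or `PeakSet`.
#' @param path output file.
#' @export
write_intervals_bed <- function(x, path) {
  dt <- if (inherits(x, "ReadSet")) x$intervals else x$peaks
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# GRanges view (1-based) of 0-based half-open interval tables
intervals_granges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
}
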