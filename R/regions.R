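#' Target regions
#'
#' A normalized set of genomic intervals (0-based, half-open) describing
#' the targeted panel. Intervals are sorted and overlapping or adjacent
#' intervals on the same chromosome are merged.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based interval starts.
#' @param end Integer vector of interval ends (exclusive); \code{start < end}.
#' @return A \code{region_set}: data.frame with columns chrom, start, end.
#' @export
region_set <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 0) stop("empty region set")
  if (any(start < 0) || any(start >= end))
    stop("regions must satisfy 0 <= start < end")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end)))
  gr <- GenomicRanges::sort(gr)
  structure(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Read a BED file of target regions
#'
#' BED coordinates are 0-based, half-open, matching the internal
#' convention.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A \code{region_set}.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = list(V1 = "character"))
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  region_set(df[[1]], df[[2]], df[[3]])
}

# every single-base site in a region set, as a sorted (chrom, pos0) frame
region_sites <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
    data.frame(chrom = regions$chrom[r],
               pos = seq.int(regions$start[r], regions$end[r] - 1L),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$pos), , drop = FALSE]
}
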