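#' Tally strand-specific allele counts from alignment files
#'
#' Builds the cohort \code{\link{count_tensor}} by piling up one indexed
#' BAM file per sample over the target regions. Counts are kept separately
#' for forward and reverse read orientations; a read base contributes to
#' exactly one allele slot (A/C/G/T, or DEL when a deletion in the read
#' spans the site). Bases below \code{min_base_quality}, reads below
#' \code{min_mapping_quality} and query \code{N} bases contribute to
#' neither counts nor coverage, so the per-strand coverage equals the sum
#' of allele counts by construction. Reads whose CIGAR skips the site
#' (\code{N} operations) contribute nothing.
#'
#' @param alignments Character vector of BAM paths, named by sample id
#'   (unnamed: basenames without extension are used).
#' @param regions A \code{\link{region_set}} (or BED path).
#' @param min_base_quality Minimum phred base quality; default 25.
#' @param min_mapping_quality Minimum read mapping quality; default 30.
#' @param reference Optional FASTA path or named character vector of
#'   sequences used to fill per-site reference alleles.
#' @return A \code{count_tensor} covering every base of \code{regions},
#'   including zero-coverage sites.
#' @export
pileup_counts <- function(alignments, regions, min_base_quality = 25L,
                          min_mapping_quality = 30L, reference = NULL) {
  if (is.character(regions) && length(regions) == 1 && file.exists(regions))
    regions <- read_bed(regions)
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) == 0) stop("empty region set")
  if (length(alignments) == 0) stop("no alignment files given")
  ids <- names(alignments)
  if (is.null(ids) || any(ids == ""))
    ids <- tools::file_path_sans_ext(basename(alignments))
  for (bam in alignments) {
    if (!file.exists(bam)) stop("alignment file not found: ", bam)
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("missing BAM index (.bai) for: ", bam)
  }

  sites <- region_sites(regions)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  ns <- length(ids); nj <- nrow(sites)
  counts <- array(0L, c(ns, nj, 5L, 2L))
  sitekey <- paste(sites$chrom, sites$pos)

  pparam <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapping_quality),
    min_nucleotide_depth = 1L,
    distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = TRUE,
    include_insertions = FALSE)

  for (i in seq_len(ns)) {
    bf <- Rsamtools::BamFile(alignments[[i]])
    hdr_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
    missing_chr <- setdiff(unique(regions$chrom), hdr_chroms)
    if (length(missing_chr))
      stop("region chromosome(s) absent from ", alignments[[i]], ": ",
           paste(missing_chr, collapse = ", "))
    pu <- Rsamtools::pileup(bf,
                            scanBamParam = Rsamtools::ScanBamParam(which = gr),
                            pileupParam = pparam)
    if (nrow(pu) == 0) next
    pu$nucleotide <- as.character(pu$nucleotide)
    pu$nucleotide[pu$nucleotide == "-"] <- "DEL"
    pu <- pu[pu$nucleotide %in% ALLELES, , drop = FALSE]
    if (nrow(pu) == 0) next
    j <- match(paste(as.character(pu$seqnames), pu$pos - 1L), sitekey)
    k <- match(pu$nucleotide, ALLELES)
    s <- ifelse(as.character(pu$strand) == "+", 1L, 2L)
    keep <- !is.na(j)
    idx <- cbind(i, j[keep], k[keep], s[keep])
    # duplicate (j,k,s) cells cannot occur within one pileup call, but
    # regions may touch the same site twice only after reduce(), so plain
    # assignment is safe
    counts[idx] <- counts[idx] + pu$count[keep]
  }
  coverage <- apply(counts, c(1, 2, 4), sum)
  tensor <- count_tensor(ids, sites, counts, coverage)
  if (!is.null(reference)) tensor <- set_reference(tensor, reference)
  tensor
}
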