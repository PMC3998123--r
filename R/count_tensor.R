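# Fixed allele alphabet: the four nucleotides plus a single-base deletion
# spanning the site. Insertions are not modelled.
ALLELES <- c("A", "C", "G", "T", "DEL")
STRANDS <- c("fwd", "rev")

#' Cohort count tensor
#'
#' The central data structure of the package: per-sample, per-site,
#' per-allele, per-strand nucleotide counts \eqn{X_{ijk}} together with the
#' per-strand coverages \eqn{n_{ij}}, for a cohort of samples over a
#' targeted panel. Sites are stored 0-based internally; all file
#' interfaces (count tables, VCF) are 1-based.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sites \code{data.frame} with columns \code{chrom} and \code{pos}
#'   (0-based position). Rows must be strictly ordered by (chrom, pos).
#' @param counts Integer array \code{[sample, site, allele, strand]} with
#'   alleles A, C, G, T, DEL and strands fwd, rev.
#' @param coverage Integer array \code{[sample, site, strand]}; per-strand
#'   coverage, i.e. the number of quality-passing read bases at the site.
#' @param ref_allele Character vector of per-site reference bases
#'   (\code{"N"} when unknown).
#' @return An object of class \code{count_tensor}.
#' @export
count_tensor <- function(sample_ids, sites, counts, coverage,
                         ref_allele = rep("N", nrow(sites))) {
  sample_ids <- as.character(sample_ids)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  ns <- length(sample_ids)
  nj <- nrow(sites)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (nj > 0) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nj)))
      stop("sites must be sorted by (chrom, pos)")
    if (anyDuplicated(sites[c("chrom", "pos")]))
      stop("duplicate sites")
  }
  counts <- array(as.integer(counts), dim = c(ns, nj, 5L, 2L),
                  dimnames = list(sample_ids, NULL, ALLELES, STRANDS))
  coverage <- array(as.integer(coverage), dim = c(ns, nj, 2L),
                    dimnames = list(sample_ids, NULL, STRANDS))
  if (any(counts < 0) || any(coverage < 0))
    stop("negative counts or coverage")
  tot <- apply(counts, c(1, 2, 4), sum)
  if (any(tot > coverage))
    stop("allele counts exceed coverage for some (sample, site, strand)")
  structure(
    list(sample_ids = sample_ids,
         sites = data.frame(chrom = as.character(sites$chrom),
                            pos = as.integer(sites$pos),
                            stringsAsFactors = FALSE),
         counts = counts,
         coverage = coverage,
         ref_allele = as.character(ref_allele)),
    class = "count_tensor")
}

#' @export
print.count_tensor <- function(x, ...) {
  cat(sprintf("count_tensor: %d samples x %d sites (alleles %s)\n",
              length(x$sample_ids), nrow(x$sites),
              paste(ALLELES, collapse = "/")))
  cat(sprintf("  total coverage: %.0f (fwd %.0f / rev %.0f)\n",
              sum(as.numeric(x$coverage)),
              sum(as.numeric(x$coverage[, , 1])),
              sum(as.numeric(x$coverage[, , 2]))))
  invisible(x)
}

#' Assign per-site reference alleles from a reference sequence
#'
#' @param tensor A \code{count_tensor}.
#' @param reference Either a FASTA file path or a named character vector of
#'   chromosome sequences.
#' @return The tensor with \code{ref_allele} filled in.
#' @export
set_reference <- function(tensor, reference) {
  stopifnot(inherits(tensor, "count_tensor"))
  tensor$ref_allele <- vapply(seq_len(nrow(tensor$sites)), function(j) {
    ref_base(reference, tensor$sites$chrom[j], tensor$sites$pos[j])
  }, character(1))
  tensor
}

# reference base at a 0-based position; `reference` is a FASTA path or a
# named character vector of sequences
ref_base <- function(reference, chrom, pos0, len = 1L) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    fa <- Rsamtools::FaFile(reference)
    if (!file.exists(paste0(reference, ".fai")))
      Rsamtools::indexFa(reference)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(pos0 + 1L, pos0 + len))
    toupper(as.character(Rsamtools::scanFa(fa, gr)[[1]]))
  } else {
    if (is.null(names(reference)) || !chrom %in% names(reference))
      stop("chromosome ", chrom, " not found in reference")
    toupper(substr(reference[[chrom]], pos0 + 1L, pos0 + len))
  }
}

#' Read a cohort count table
#'
#' Reads a tab-separated table with header columns \code{sample, chrom,
#' pos, strand, A, C, G, T, DEL, coverage} into a \code{count_tensor}.
#' \code{pos} is 1-based in the file and stored 0-based. Missing
#' (sample, site, strand) rows are zero-filled.
#'
#' @param path Path to the TSV file.
#' @return A \code{count_tensor}.
#' @export
read_count_table <- function(path) {
  req <- c("sample", "chrom", "pos", "strand", "A", "C", "G", "T", "DEL",
           "coverage")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(sample = "character",
                                         chrom = "character"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(req %in% names(df)))
    stop("count table must have columns: ", paste(req, collapse = ", "))
  if (nrow(df) > 0) {
    bad <- which(!df$strand %in% STRANDS | !is.finite(df$pos) | df$pos < 1 |
                   df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0 | df$DEL < 0 |
                   df$coverage < 0)
    if (length(bad))
      stop("malformed count-table row at line ", bad[1] + 1L)
    tot <- df$A + df$C + df$G + df$T + df$DEL
    bad <- which(df$coverage < tot)
    if (length(bad))
      stop("coverage < sum of allele counts at line ", bad[1] + 1L)
    key <- paste(df$sample, df$chrom, df$pos, df$strand)
    if (anyDuplicated(key))
      stop("duplicate (sample, site, strand) row at line ",
           which(duplicated(key))[1] + 1L)
  }
  sample_ids <- sort(unique(df$sample))
  sites <- unique(df[c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites0 <- data.frame(chrom = sites$chrom, pos = as.integer(sites$pos) - 1L)
  ns <- length(sample_ids); nj <- nrow(sites0)
  counts <- array(0L, c(ns, nj, 5L, 2L))
  coverage <- array(0L, c(ns, nj, 2L))
  if (nrow(df) > 0) {
    i <- match(df$sample, sample_ids)
    j <- match(paste(df$chrom, df$pos), paste(sites$chrom, sites$pos))
    s <- match(df$strand, STRANDS)
    for (k in seq_along(ALLELES))
      counts[cbind(i, j, k, s)] <- as.integer(df[[ALLELES[k]]])
    coverage[cbind(i, j, s)] <- as.integer(df$coverage)
  }
  count_tensor(sample_ids, sites0, counts, coverage)
}

#' Write a cohort count table
#'
#' Inverse of \code{\link{read_count_table}}: writes one row per
#' (sample, site, strand) with 1-based positions. All-zero rows are kept so
#' that the round trip is exact.
#'
#' @param tensor A \code{count_tensor}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_count_table <- function(tensor, path) {
  stopifnot(inherits(tensor, "count_tensor"))
  ns <- length(tensor$sample_ids); nj <- nrow(tensor$sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", "chrom", "pos", "strand", ALLELES,
                     "coverage"), collapse = "\t"), con)
  if (ns * nj > 0) {
    g <- expand.grid(s = 1:2, j = seq_len(nj), i = seq_len(ns))
    rows <- data.frame(
      sample = tensor$sample_ids[g$i],
      chrom = tensor$sites$chrom[g$j],
      pos = tensor$sites$pos[g$j] + 1L,
      strand = STRANDS[g$s],
      stringsAsFactors = FALSE)
    for (k in seq_along(ALLELES))
      rows[[ALLELES[k]]] <- tensor$counts[cbind(g$i, g$j, k, g$s)]
    rows$coverage <- tensor$coverage[cbind(g$i, g$j, g$s)]
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
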