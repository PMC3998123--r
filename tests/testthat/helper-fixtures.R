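# Independent quadrature oracle for the beta-binomial pmf: expectation of
# the binomial pmf over the Beta mixing density, integrated through the
# Beta quantile transform so the integrand stays bounded for any shapes.
bb_quadrature <- function(x, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  # piecewise over equal-probability segments of the mixing Beta, so the
  # (bounded, possibly spiky) integrand is tame on every subinterval
  breaks <- seq(0, 1, length.out = 41)
  sum(vapply(seq_len(40), function(s) {
    stats::integrate(function(u) stats::dbinom(x, n, stats::qbeta(u, a, b)),
                     breaks[s], breaks[s + 1], rel.tol = 1e-11,
                     abs.tol = 1e-13, subdivisions = 200L,
                     stop.on.error = FALSE)$value
  }, numeric(1)))
}

# Small deterministic tensor: ns samples x nj sites, background counts of
# allele C given explicitly, remainder of the coverage on the reference A.
make_tensor <- function(ns, nj, cov_fwd, cov_rev, c_fwd = NULL,
                        c_rev = NULL, ref = rep("A", nj)) {
  counts <- array(0L, c(ns, nj, 5L, 2L))
  coverage <- array(0L, c(ns, nj, 2L))
  coverage[, , 1] <- cov_fwd
  coverage[, , 2] <- cov_rev
  if (!is.null(c_fwd)) counts[, , 2, 1] <- c_fwd
  if (!is.null(c_rev)) counts[, , 2, 2] <- c_rev
  counts[, , 1, 1] <- coverage[, , 1] - counts[, , 2, 1]
  counts[, , 1, 2] <- coverage[, , 2] - counts[, , 2, 2]
  count_tensor(sprintf("S%03d", seq_len(ns)),
               data.frame(chrom = "chr1", pos = seq_len(nj) - 1L),
               counts, coverage, ref_allele = ref)
}

# Reference sequence used by the SAM fixtures: 60 T's on chr1, so A/C/G
# read bases are always non-reference.
fixture_reference <- function() c(chr1 = strrep("T", 60))

# Build a coordinate-sorted, indexed BAM from read descriptions.
# reads: data.frame(pos1, strand ("+"/"-"), base, bq (phred int),
#        mapq, cigar (NA = simple 10M match))
write_fixture_bam <- function(reads, dir, name = "s1") {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:60")
  reads <- reads[order(reads$pos1), , drop = FALSE]
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    cigar <- if (is.na(r$cigar)) "10M" else r$cigar
    nref <- sum(as.integer(regmatches(
      cigar, gregexpr("[0-9]+(?=[MD])", cigar, perl = TRUE))[[1]]))
    ndel <- sum(as.integer(c(0, regmatches(
      cigar, gregexpr("[0-9]+(?=D)", cigar, perl = TRUE))[[1]])))
    seqlen <- nref - ndel
    # the interrogated site sits at 1-based reference position 30
    off <- 30 - r$pos1 + 1
    seq <- rep("T", seqlen)
    qual <- rep(40L, seqlen)
    if (off >= 1 && off <= seqlen && !grepl("D", cigar)) {
      seq[off] <- r$base
      qual[off] <- r$bq
    }
    paste(sprintf("r%03d", i), if (r$strand == "+") 0L else 16L, "chr1",
          r$pos1, r$mapq, cigar, "*", 0, 0, paste(seq, collapse = ""),
          rawToChar(as.raw(qual + 33L)), sep = "\t")
  }, character(1))
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(c(hdr, lines), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

simple_reads <- function(n, strand, base, pos1 = 26, bq = 40, mapq = 60,
                         cigar = NA_character_) {
  if (n == 0)
    return(data.frame(pos1 = integer(0), strand = character(0),
                      base = character(0), bq = integer(0),
                      mapq = integer(0), cigar = character(0)))
  data.frame(pos1 = rep_len(pos1, n), strand = rep_len(strand, n),
             base = rep_len(base, n), bq = rep_len(bq, n),
             mapq = rep_len(mapq, n), cigar = rep_len(cigar, n),
             stringsAsFactors = FALSE)
}
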