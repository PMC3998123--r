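# fixed-format numeric rendering used in VCF bodies; 12 significant digits
# so that posteriors recomputed from emitted BF and PI round-trip to 1e-9
fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[!is.finite(x)] <- "."
  out
}

#' Write variant calls to VCF
#'
#' Emits one VCF 4.2 record per (site, alt allele) with per-sample FORMAT
#' fields: \code{BF} (Bayes factor), \code{PM0} (posterior probability of
#' the error-only null), \code{VF} (combined-strand VAF), \code{FD}/\code{RD}
#' (forward/reverse variant read depth) and \code{FC}/\code{RC}
#' (forward/reverse coverage). The prior used at the site is stored as
#' \code{INFO/PI}. Positions are 1-based in the file (internal 0-based
#' position + 1). Single-base deletions are left-anchored: a DEL call at
#' internal position p becomes a record at POS = p with a 2-base REF
#' (anchor + deleted base) and a 1-base ALT (the anchor).
#'
#' @param calls A \code{variant_calls} data.frame from
#'   \code{\link{call_variants}} (may have zero rows).
#' @param reference FASTA path or named character vector of sequences;
#'   REF alleles are checked against it.
#' @param path Output VCF path.
#' @param samples Sample columns to emit; defaults to the samples present
#'   in \code{calls}, sorted.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(calls, reference, path,
                      samples = sort(unique(calls$sample))) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cohortsnv",
    "##INFO=<ID=PI,Number=1,Type=Float,Description=\"Prior probability of a variant at this site and allele\">",
    "##FORMAT=<ID=BF,Number=1,Type=Float,Description=\"Bayes factor P(D|M0)/P(D|M1)\">",
    "##FORMAT=<ID=PM0,Number=1,Type=Float,Description=\"Posterior probability of the error-only null model\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele frequency, strands combined\">",
    "##FORMAT=<ID=FD,Number=1,Type=Integer,Description=\"Forward-strand variant read depth\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reverse-strand variant read depth\">",
    "##FORMAT=<ID=FC,Number=1,Type=Integer,Description=\"Forward-strand coverage\">",
    "##FORMAT=<ID=RC,Number=1,Type=Integer,Description=\"Reverse-strand coverage\">")
  if (is.character(reference) && !is.null(names(reference))) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          nchar(reference)))
  }
  if (length(samples) == 0) samples <- "SAMPLE"
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    calls <- calls[order(calls$chrom, calls$pos, calls$alt, calls$sample), ,
                   drop = FALSE]
    recs <- unique(calls[c("chrom", "pos", "alt")])
    body <- vapply(seq_len(nrow(recs)), function(r) {
      chrom <- recs$chrom[r]; p0 <- recs$pos[r]; alt <- recs$alt[r]
      sub <- calls[calls$chrom == chrom & calls$pos == p0 &
                     calls$alt == alt, , drop = FALSE]
      refbase <- ref_base(reference, chrom, p0)
      if (!all(sub$ref %in% c("N", refbase)))
        stop(sprintf("REF mismatch at %s:%d: calls say %s, reference says %s",
                     chrom, p0 + 1L, paste(unique(sub$ref), collapse = ","),
                     refbase))
      if (alt == "DEL") {
        if (p0 < 1) stop("cannot left-anchor a deletion at position 0")
        anchor <- ref_base(reference, chrom, p0 - 1L)
        pos1 <- p0               # 1-based anchor position
        ref_field <- paste0(anchor, refbase)
        alt_field <- anchor
      } else {
        pos1 <- p0 + 1L
        ref_field <- refbase
        alt_field <- alt
      }
      gt <- rep(".", length(samples))
      m <- match(sub$sample, samples)
      gt[m[!is.na(m)]] <- paste(
        fmt_num(sub$bf), fmt_num(sub$posterior_m0), fmt_num(sub$vaf),
        sub$x_fwd, sub$x_rev, sub$n_fwd, sub$n_rev,
        sep = ":")[!is.na(m)]
      paste(c(chrom, pos1, ".", ref_field, alt_field, ".", "PASS",
              paste0("PI=", fmt_num(sub$prior[1])),
              "BF:PM0:VF:FD:RD:FC:RC", gt), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
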