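#' Caller configuration
#'
#' Bundles every tunable of the variant caller with its default. Defaults:
#' reference sets exclude samples with VAF >= 0.1 at the tested allele;
#' error rates are pooled over the aggregate control and the target sample
#' with a Jeffreys-like pseudocount of 0.5; the dispersion is estimated
#' per (site, allele) and clamped to [1e-4, 0.1] unless fixed; the null
#' model is the strand-OR null; the Bayes-factor numerator combines its
#' three terms by inclusion-exclusion; calls are emitted at posterior
#' P(M0|D) <= 0.5 with a default prior of 1e-4 for uncatalogued sites.
#'
#' @param vaf_threshold Reference-set VAF exclusion threshold.
#' @param pseudocount Pseudocount in the pooled error-rate estimate.
#' @param rho_min,rho_max Clamp bounds for the dispersion estimate.
#' @param rho_fixed If non-NULL, skip estimation and use this dispersion.
#' @param strand_mode \code{"both"} (strand-OR null; a variant must exceed
#'   the error rate on both strands) or \code{"agnostic"} (single pooled
#'   comparison; more sensitive at low or one-sided coverage, less
#'   specific).
#' @param numerator \code{"inclusion-exclusion"} (third term subtracted,
#'   floored at 0) or \code{"additive"} (plain sum of the three terms).
#' @param nu_mode \code{"raw"} plugs in x/n as the variant-model rate;
#'   \code{"excess"} floors it at the error rate (the variant model
#'   constrains the rate to exceed the error rate).
#' @param mu_pooling \code{"all"} pools the target sample into the error
#'   rate (the null asserts one common rate); \code{"loo"} uses the
#'   controls only.
#' @param posterior_cutoff Call when P(M0|D) <= this value.
#' @param pi0 Default prior probability for sites absent from the
#'   hotspot catalogue.
#' @param exclude Optional polymorphism exclusion list: data.frame with
#'   columns chrom, pos (1-based), alt; matching calls are dropped after
#'   calling.
#' @return A \code{caller_config} list.
#' @export
caller_config <- function(vaf_threshold = 0.1, pseudocount = 0.5,
                          rho_min = 1e-4, rho_max = 0.1, rho_fixed = NULL,
                          strand_mode = c("both", "agnostic"),
                          numerator = c("inclusion-exclusion", "additive"),
                          nu_mode = c("raw", "excess"),
                          mu_pooling = c("all", "loo"),
                          posterior_cutoff = 0.5, pi0 = 1e-4,
                          exclude = NULL) {
  stopifnot(vaf_threshold > 0, vaf_threshold <= 1, pseudocount > 0,
            rho_min > 0, rho_min <= rho_max, rho_max < 1,
            posterior_cutoff >= 0, posterior_cutoff <= 1,
            pi0 > 0, pi0 < 1)
  if (!is.null(rho_fixed))
    stopifnot(rho_fixed >= 0, rho_fixed < 1)
  structure(list(
    vaf_threshold = vaf_threshold, pseudocount = pseudocount,
    rho_min = rho_min, rho_max = rho_max, rho_fixed = rho_fixed,
    strand_mode = match.arg(strand_mode),
    numerator = match.arg(numerator),
    nu_mode = match.arg(nu_mode),
    mu_pooling = match.arg(mu_pooling),
    posterior_cutoff = posterior_cutoff, pi0 = pi0,
    exclude = exclude), class = "caller_config")
}

#' Bayes factor of the error-only null against the variant model
#'
#' The null model M0 states that the sample's allele counts follow the
#' pooled error rate on the forward OR on the reverse strand (so purely
#' single-strand signals remain null); the variant model M1 states that
#' the rates exceed the error rate on both strands. With the per-strand
#' beta-binomial likelihoods \eqn{L_s(\theta)} evaluated at the pooled
#' error rates \eqn{\mu} and the sample VAF plug-ins \eqn{\nu}, the
#' approximate Bayes factor is
#' \deqn{BF = \frac{L_f(\mu_f)L_r(\nu_r) + L_f(\nu_f)L_r(\mu_r)
#'   - L_f(\mu_f)L_r(\mu_r)}{L_f(\nu_f)L_r(\nu_r)}}
#' where the third numerator term removes the doubly counted both-strands
#' null overlap (inclusion-exclusion over the OR); the numerator is
#' floored at 0. Small values favour a variant. All products are computed
#' in log space. Zero coverage on both strands gives BF = 1 (no
#' evidence), as does joint numerator/denominator underflow.
#'
#' In strand-agnostic mode the two strands are pooled and
#' \eqn{BF = L(\mu)/L(\nu)} on the combined counts.
#'
#' @param x_fwd,n_fwd,x_rev,n_rev Variant counts and coverages per strand.
#' @param mu_fwd,mu_rev Pooled error rates per strand.
#' @param nu_fwd,nu_rev Sample VAF plug-ins per strand.
#' @param rho Beta-binomial dispersion.
#' @param strand_mode \code{"both"} or \code{"agnostic"}.
#' @param numerator \code{"inclusion-exclusion"} or \code{"additive"}.
#' @return Vector of Bayes factors (>= 0); vectorized over all arguments.
#' @export
bayes_factor <- function(x_fwd, n_fwd, x_rev, n_rev, mu_fwd, mu_rev,
                         nu_fwd, nu_rev, rho,
                         strand_mode = c("both", "agnostic"),
                         numerator = c("inclusion-exclusion", "additive")) {
  strand_mode <- match.arg(strand_mode)
  numerator <- match.arg(numerator)
  if (strand_mode == "agnostic") {
    x <- x_fwd + x_rev
    n <- n_fwd + n_rev
    mu <- ifelse(n_fwd + n_rev > 0,
                 (mu_fwd * n_fwd + mu_rev * n_rev) / (n_fwd + n_rev),
                 (mu_fwd + mu_rev) / 2)
    nu <- ifelse(n > 0, x / n, 0)
    lnum <- dbetabinom(x, n, mu, rho, log = TRUE)
    lden <- dbetabinom(x, n, nu, rho, log = TRUE)
    bf <- exp(lnum - lden)
    bf[!is.finite(lnum) & !is.finite(lden)] <- 1
    return(bf)
  }
  lf_mu <- dbetabinom(x_fwd, n_fwd, mu_fwd, rho, log = TRUE)
  lr_mu <- dbetabinom(x_rev, n_rev, mu_rev, rho, log = TRUE)
  lf_nu <- dbetabinom(x_fwd, n_fwd, nu_fwd, rho, log = TRUE)
  lr_nu <- dbetabinom(x_rev, n_rev, nu_rev, rho, log = TRUE)
  t1 <- lf_mu + lr_nu
  t2 <- lf_nu + lr_mu
  t3 <- lf_mu + lr_mu
  m <- pmax(t1, t2)
  num_lin <- exp(t1 - m) + exp(t2 - m)
  if (numerator == "inclusion-exclusion")
    num_lin <- num_lin - exp(t3 - m)
  num_lin <- pmax(num_lin, 0)
  log_num <- ifelse(is.finite(m) & num_lin > 0, m + log(num_lin), -Inf)
  log_den <- lf_nu + lr_nu
  bf <- exp(log_num - log_den)
  bf[!is.finite(log_num) & !is.finite(log_den)] <- 1
  bf
}

#' Posterior probability of the error-only null
#'
#' Combines the Bayes factor with the site/allele prior probability of a
#' variant by Bayes' formula:
#' \deqn{P(M_0 | D) = \frac{BF \cdot (1 - \pi)}{BF \cdot (1 - \pi) + \pi}}
#' Monotone increasing in BF and decreasing in the prior. Variants are
#' called below a cutoff on this quantity.
#'
#' @param bf Bayes factor(s), >= 0.
#' @param pi Prior probability of a variant, strictly in (0, 1).
#' @return Posterior probability in \code{[0, 1]}, vectorized.
#' @export
posterior_null <- function(bf, pi) {
  if (any(!is.finite(pi) | pi <= 0 | pi >= 1))
    stop("prior pi must be strictly inside (0, 1)")
  if (any(is.na(bf) | bf < 0))
    stop("Bayes factor must be >= 0")
  ifelse(is.infinite(bf), 1, bf * (1 - pi) / (bf * (1 - pi) + pi))
}

#' Per-gene mutation histogram from a hotspot catalogue
#'
#' Relative frequency of catalogued mutations within one gene:
#' \eqn{h_{jk} = c_{jk} / \sum c}, summed over duplicate (site, allele)
#' records first. The histogram sums to 1 over the gene's catalogued
#' entries.
#'
#' @param records data.frame with columns \code{chrom}, \code{pos}
#'   (0-based), \code{alt} and \code{count} (observation counts >= 1) for
#'   one gene.
#' @return data.frame with columns chrom, pos, alt, h (empty if no
#'   records).
#' @export
build_mutation_histogram <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      alt = character(0), h = numeric(0)))
  stopifnot(all(c("chrom", "pos", "alt", "count") %in% names(records)),
            all(records$count >= 1))
  agg <- stats::aggregate(count ~ chrom + pos + alt, data = records, sum)
  agg$h <- agg$count / sum(agg$count)
  agg[order(agg$chrom, agg$pos, agg$alt), c("chrom", "pos", "alt", "h")]
}

#' Build the per-site prior track
#'
#' Combines per-gene mutation histograms with gene-level mutation
#' probabilities into per-(site, allele) prior probabilities
#' \eqn{\pi_{jk} = P(\mathrm{gene\ mutated}) \cdot h_{jk}}, clipped just
#' below 1. Sites absent from the catalogue receive the default
#' \code{pi0}.
#'
#' @param histograms Named list (gene -> histogram) as produced by
#'   \code{\link{build_mutation_histogram}}.
#' @param gene_probs Single probability applied to every gene, or a named
#'   vector with one entry per gene in \code{histograms}.
#' @param pi0 Default prior for uncatalogued (site, allele) pairs.
#' @return A \code{prior_track}.
#' @export
build_prior_track <- function(histograms, gene_probs = 0.1, pi0 = 1e-4) {
  stopifnot(all(gene_probs > 0), all(gene_probs < 1), pi0 > 0, pi0 < 1)
  entries <- lapply(names(histograms), function(g) {
    h <- histograms[[g]]
    if (nrow(h) == 0) return(NULL)
    gp <- if (length(gene_probs) == 1 && is.null(names(gene_probs)))
      gene_probs
    else {
      if (!g %in% names(gene_probs))
        stop("no gene probability for gene present in histograms: ", g)
      gene_probs[[g]]
    }
    data.frame(chrom = h$chrom, pos = h$pos, alt = h$alt,
               pi = pmin(gp * h$h, 1 - 1e-9), gene = g,
               stringsAsFactors = FALSE)
  })
  pi <- do.call(rbind, entries)
  if (is.null(pi))
    pi <- data.frame(chrom = character(0), pos = integer(0),
                     alt = character(0), pi = numeric(0),
                     gene = character(0))
  structure(list(pi = pi, pi0 = pi0), class = "prior_track")
}

#' Look up prior probabilities for (site, allele) pairs
#'
#' @param track A \code{prior_track} (or NULL for the uniform default).
#' @param chrom,pos,alt Vectors identifying the queries (pos 0-based).
#' @param pi0 Default used when \code{track} is NULL.
#' @return Vector of prior probabilities.
#' @export
prior_lookup <- function(track, chrom, pos, alt, pi0 = 1e-4) {
  n <- max(length(chrom), length(pos), length(alt))
  if (is.null(track)) return(rep(pi0, n))
  stopifnot(inherits(track, "prior_track"))
  key <- paste(chrom, pos, alt)
  m <- match(key, paste(track$pi$chrom, track$pi$pos, track$pi$alt))
  out <- track$pi$pi[m]
  out[is.na(m)] <- track$pi0
  out
}

#' Read a hotspot catalogue
#'
#' TSV input: header columns \code{gene, chrom, pos, ref, alt, count}
#' with 1-based positions; records where alt equals ref are dropped.
#' VCF input (path ending in .vcf): per-record observation counts from
#' INFO/CNT and gene names from INFO/GENE.
#'
#' @param path Catalogue path.
#' @return Named list (gene -> records data.frame with 0-based pos) ready
#'   for \code{\link{build_mutation_histogram}}.
#' @export
read_hotspot_catalogue <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VariantAnnotation required for VCF catalogues")
    v <- VariantAnnotation::readVcf(path, genome = "unknown")
    info <- VariantAnnotation::info(v)
    rr <- SummarizedExperiment::rowRanges(v)
    alt <- as.character(unlist(VariantAnnotation::alt(v)))
    df <- data.frame(
      gene = as.character(info$GENE),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L,
      ref = as.character(VariantAnnotation::ref(v)),
      alt = alt,
      count = as.integer(info$CNT),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = list(chrom = "character"))
    req <- c("gene", "chrom", "pos", "ref", "alt", "count")
    if (!all(req %in% names(df)))
      stop("catalogue must have columns: ", paste(req, collapse = ", "))
    df$pos <- as.integer(df$pos) - 1L
  }
  df <- df[df$alt != df$ref, , drop = FALSE]
  split(df[c("chrom", "pos", "alt", "count")], df$gene)
}

# Bayes factors for every sample at one (site, allele): the vectorized
# core shared by call_variants and the benchmark. Returns a data.frame
# with one row per sample; rows with an empty reference set carry NA bf.
cohort_bayes_factors <- function(tensor, site, allele,
                                 config = caller_config()) {
  x_f <- as.numeric(tensor$counts[, site, allele, 1])
  x_r <- as.numeric(tensor$counts[, site, allele, 2])
  n_f <- as.numeric(tensor$coverage[, site, 1])
  n_r <- as.numeric(tensor$coverage[, site, 2])
  tot_x <- x_f + x_r
  tot_n <- n_f + n_r
  vaf <- ifelse(tot_n > 0, tot_x / tot_n, 0)
  pass <- vaf < config$vaf_threshold
  n_pass <- sum(pass)
  pn <- as.numeric(pass)

  # leave-one-out aggregate controls, vectorized over targets
  XJ_f <- sum(x_f[pass]) - pn * x_f
  XJ_r <- sum(x_r[pass]) - pn * x_r
  NJ_f <- sum(n_f[pass]) - pn * n_f
  NJ_r <- sum(n_r[pass]) - pn * n_r
  m_controls <- n_pass - pn

  cc <- config$pseudocount
  if (config$mu_pooling == "all") {
    mu_f <- (XJ_f + x_f + cc) / (NJ_f + n_f + 2 * cc)
    mu_r <- (XJ_r + x_r + cc) / (NJ_r + n_r + 2 * cc)
  } else {
    mu_f <- (XJ_f + cc) / (NJ_f + 2 * cc)
    mu_r <- (XJ_r + cc) / (NJ_r + 2 * cc)
  }

  rho <- if (!is.null(config$rho_fixed)) config$rho_fixed
  else estimate_rho(vaf[pass & tot_n > 0], tot_n[pass & tot_n > 0],
                    config$rho_min, config$rho_max)

  nu_f <- ifelse(n_f > 0, x_f / n_f, 0)
  nu_r <- ifelse(n_r > 0, x_r / n_r, 0)
  if (config$nu_mode == "excess") {
    nu_f <- pmax(nu_f, mu_f)
    nu_r <- pmax(nu_r, mu_r)
  }

  bf <- bayes_factor(x_f, n_f, x_r, n_r, mu_f, mu_r, nu_f, nu_r, rho,
                     strand_mode = config$strand_mode,
                     numerator = config$numerator)
  bf[m_controls == 0] <- NA_real_

  data.frame(sample = tensor$sample_ids,
             x_fwd = as.integer(x_f), x_rev = as.integer(x_r),
             n_fwd = as.integer(n_f), n_rev = as.integer(n_r),
             vaf_fwd = ifelse(n_f > 0, x_f / n_f, 0),
             vaf_rev = ifelse(n_r > 0, x_r / n_r, 0),
             vaf = vaf,
             mu_fwd = mu_f, mu_rev = mu_r, rho_used = rho,
             n_controls = m_controls, bf = bf,
             stringsAsFactors = FALSE)
}

#' Call variants across a cohort
#'
#' For every (sample, site, allele != reference) hypothesis: selects the
#' reference sample set (combined-strand VAF below the threshold), builds
#' the leave-one-out aggregate control, estimates the per-strand pooled
#' error rates and the dispersion, computes the Bayes factor and converts
#' it to a posterior with the site/allele prior. A call is emitted when
#' the posterior P(M0|D) is at or below the cutoff. Hypotheses whose
#' reference set is empty are skipped and counted in the
#' \code{"skipped"} attribute. An optional polymorphism exclusion list
#' in the config drops matching calls afterwards. The output is
#' deterministic given the inputs and configuration.
#'
#' @param tensor A \code{\link{count_tensor}}.
#' @param prior A \code{prior_track} or NULL (uniform \code{pi0} prior).
#' @param config A \code{\link{caller_config}}.
#' @return A \code{variant_calls} data.frame, sorted by
#'   (chrom, pos, alt, sample), with the Bayes factor, posterior, prior,
#'   per-strand counts, coverages, VAFs and the error-model parameters
#'   used.
#' @export
call_variants <- function(tensor, prior = NULL, config = caller_config()) {
  stopifnot(inherits(tensor, "count_tensor"))
  if (nrow(tensor$sites) == 0 || length(tensor$sample_ids) == 0)
    stop("empty count tensor")
  out <- list()
  skipped <- 0L
  for (j in seq_len(nrow(tensor$sites))) {
    ref <- tensor$ref_allele[j]
    for (k in which(ALLELES != ref)) {
      res <- cohort_bayes_factors(tensor, j, k, config)
      skipped <- skipped + sum(is.na(res$bf))
      pi_jk <- prior_lookup(prior, tensor$sites$chrom[j],
                            tensor$sites$pos[j], ALLELES[k],
                            pi0 = config$pi0)
      post <- rep(NA_real_, nrow(res))
      ok <- !is.na(res$bf)
      post[ok] <- posterior_null(res$bf[ok], pi_jk)
      hit <- which(ok & post <= config$posterior_cutoff)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          sample = res$sample[hit],
          chrom = tensor$sites$chrom[j],
          pos = tensor$sites$pos[j],
          ref = ref, alt = ALLELES[k],
          bf = res$bf[hit], posterior_m0 = post[hit], prior = pi_jk,
          vaf_fwd = res$vaf_fwd[hit], vaf_rev = res$vaf_rev[hit],
          vaf = res$vaf[hit],
          x_fwd = res$x_fwd[hit], x_rev = res$x_rev[hit],
          n_fwd = res$n_fwd[hit], n_rev = res$n_rev[hit],
          mu_fwd = res$mu_fwd[hit], mu_rev = res$mu_rev[hit],
          rho_used = res$rho_used[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               bf = numeric(0), posterior_m0 = numeric(0),
               prior = numeric(0), vaf_fwd = numeric(0),
               vaf_rev = numeric(0), vaf = numeric(0),
               x_fwd = integer(0), x_rev = integer(0),
               n_fwd = integer(0), n_rev = integer(0),
               mu_fwd = numeric(0), mu_rev = numeric(0),
               rho_used = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(config$exclude) && nrow(calls) > 0) {
    ex <- config$exclude
    drop <- paste(calls$chrom, calls$pos, calls$alt) %in%
      paste(ex$chrom, as.integer(ex$pos) - 1L, ex$alt)
    calls <- calls[!drop, , drop = FALSE]
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$alt, calls$sample), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "skipped") <- skipped
  attr(calls, "config") <- config
  class(calls) <- c("variant_calls", "data.frame")
  calls
}
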