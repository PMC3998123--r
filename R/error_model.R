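#' Select the reference sample set for a target sample
#'
#' The aggregate control standing in for a matched normal is built from
#' all other samples that are unlikely to carry the variant themselves:
#' those whose combined-strand VAF at the (site, allele) of interest is
#' below a threshold (typically ~10%). Samples with zero coverage at the
#' site have VAF defined as 0 and are included.
#'
#' @param tensor A \code{\link{count_tensor}}.
#' @param target_sample,site,allele Indices (sample i, site j, allele k).
#' @param vaf_threshold Exclusion threshold on the combined-strand VAF.
#' @return Integer vector of sample indices J(i) (possibly empty).
#' @export
select_reference_set <- function(tensor, target_sample, site, allele,
                                 vaf_threshold = 0.1) {
  stopifnot(inherits(tensor, "count_tensor"))
  x <- tensor$counts[, site, allele, 1] + tensor$counts[, site, allele, 2]
  n <- tensor$coverage[, site, 1] + tensor$coverage[, site, 2]
  vaf <- ifelse(n > 0, x / n, 0)
  setdiff(which(vaf < vaf_threshold), target_sample)
}

#' Aggregate control counts over a reference set
#'
#' Sums per-strand variant counts and coverages at one (site, allele) over
#' the reference sample set, yielding the aggregate control used in place
#' of a matched normal. An empty set yields all-zero controls.
#'
#' @param tensor A \code{\link{count_tensor}}.
#' @param J Integer vector of reference sample indices (target excluded).
#' @param site,allele Site and allele indices.
#' @return List with \code{X_fwd, X_rev} (aggregate variant counts) and
#'   \code{N_fwd, N_rev} (aggregate coverages), plus \code{n_controls}.
#' @export
aggregate_controls <- function(tensor, J, site, allele) {
  stopifnot(inherits(tensor, "count_tensor"))
  list(X_fwd = sum(tensor$counts[J, site, allele, 1]),
       X_rev = sum(tensor$counts[J, site, allele, 2]),
       N_fwd = sum(tensor$coverage[J, site, 1]),
       N_rev = sum(tensor$coverage[J, site, 2]),
       n_controls = length(J))
}

#' Pooled strand-specific error-rate estimates
#'
#' Method-of-moments point estimate of the per-strand error rate under the
#' null: the pooled rate over the aggregate control and the target sample
#' (the null model asserts one common rate), stabilized by a small
#' pseudocount so the estimate is strictly inside (0, 1) even at zero
#' coverage.
#'
#' @param control List as returned by \code{\link{aggregate_controls}}.
#' @param target Per-strand target counts: list with \code{x_fwd, n_fwd,
#'   x_rev, n_rev}. Use zeros for leave-one-out pooling.
#' @param pseudocount Added to the numerator (and twice to the
#'   denominator); default 0.5.
#' @return Named vector \code{c(mu_fwd, mu_rev)}.
#' @export
estimate_error_rates <- function(control, target, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  c(mu_fwd = (control$X_fwd + target$x_fwd + pseudocount) /
      (control$N_fwd + target$n_fwd + 2 * pseudocount),
    mu_rev = (control$X_rev + target$x_rev + pseudocount) /
      (control$N_rev + target$n_rev + 2 * pseudocount))
}

#' Per-strand sample VAF point estimates
#'
#' The plug-in estimates of the sample's allele frequency under the
#' variant model: x/n per strand, 0 at zero coverage.
#'
#' @param target List with \code{x_fwd, n_fwd, x_rev, n_rev}.
#' @return Named vector \code{c(nu_fwd, nu_rev)}.
#' @export
estimate_sample_vaf <- function(target) {
  c(nu_fwd = if (target$n_fwd > 0) target$x_fwd / target$n_fwd else 0,
    nu_rev = if (target$n_rev > 0) target$x_rev / target$n_rev else 0)
}

#' Method-of-moments dispersion estimate
#'
#' Estimates the beta-binomial intraclass correlation rho at one
#' (site, allele) from the spread of per-sample combined-strand VAFs in
#' excess of binomial sampling noise. With mu the coverage-weighted mean
#' VAF, s2 the sample variance of the VAFs and h the mean reciprocal
#' coverage, the estimator is
#' \deqn{\hat\rho = \frac{s^2 - \mu(1-\mu)\,h}{\mu(1-\mu)\,(1 - h)}}
#' clamped to \code{[rho_min, rho_max]}. Degenerate inputs (fewer than two
#' covered samples, zero mean, zero variance) return \code{rho_min}.
#'
#' @param vafs Per-sample combined-strand VAFs (reference-set samples).
#' @param coverages Matching combined-strand coverages.
#' @param rho_min,rho_max Clamp bounds; defaults 1e-4 and 0.1.
#' @return A dispersion value in \code{[rho_min, rho_max]}.
#' @export
estimate_rho <- function(vafs, coverages, rho_min = 1e-4, rho_max = 0.1) {
  stopifnot(length(vafs) == length(coverages), rho_min <= rho_max)
  ok <- is.finite(vafs) & is.finite(coverages) & coverages > 0
  vafs <- vafs[ok]; coverages <- coverages[ok]
  if (length(vafs) < 2) return(rho_min)
  mu <- stats::weighted.mean(vafs, coverages)
  if (mu <= 0 || mu >= 1) return(rho_min)
  s2 <- stats::var(vafs)
  h <- mean(1 / coverages)
  rho <- (s2 - mu * (1 - mu) * h) / (mu * (1 - mu) * (1 - h))
  if (!is.finite(rho)) return(rho_min)
  min(max(rho, rho_min), rho_max)
}
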