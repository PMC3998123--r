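# beta-binomial random draws; size/mu may be vectors, rho scalar
rbetabinom <- function(n, size, mu, rho) {
  size <- rep_len(size, n)
  mu <- rep_len(mu, n)
  if (rho == 0) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulation configuration
#'
#' Describes a synthetic targeted-resequencing cohort: per-site, per-strand
#' coverages, site-specific strand-specific background error rates with
#' beta-binomial dispersion, and implanted true variants at chosen VAFs.
#' This emulates the structure of a deep targeted panel; it does not
#' emulate alignment artifacts, mapping bias or library-specific error
#' spectra.
#'
#' @param n_samples Cohort size.
#' @param n_sites Number of independent panel sites.
#' @param coverage Either \code{list(type = "fixed", value = )} (total
#'   per-sample coverage, split across strands by \code{strand_bias}) or
#'   \code{list(type = "lognormal", median = 128, sdlog = 1.02)} drawn
#'   independently per (sample, site). The default lognormal is calibrated
#'   to a deep panel with median coverage 128x.
#' @param strand_bias Fraction of coverage on the forward strand
#'   (default 0.5, even split).
#' @param error_rate Per-strand baseline error rate; either a scalar or
#'   \code{list(base = , hot_fraction = , hot_rate = )} where a fraction
#'   of sites gets an elevated rate (recurrent-artifact sites).
#' @param rho Beta-binomial dispersion used for background generation.
#' @param implant_vafs VAFs of implanted variants, recycled over implant
#'   sites (one carrier sample per site, assigned round-robin). NULL for
#'   a null-only cohort.
#' @param implant_fraction Fraction of sites receiving an implant
#'   (default 1 when \code{implant_vafs} given).
#' @param dirichlet_alpha If non-NULL, per-site VAF vectors across samples
#'   are drawn from a Dirichlet distribution with this concentration
#'   vector (recycled to \code{n_samples}) instead of fixed implants.
#' @param seed Mandatory integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 500, n_sites = 50,
                       coverage = list(type = "lognormal", median = 128,
                                       sdlog = 1.02),
                       strand_bias = 0.5,
                       error_rate = 1e-3, rho = 1e-4,
                       implant_vafs = NULL, implant_fraction = 1,
                       dirichlet_alpha = NULL, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("sim_config requires an explicit integer seed")
  stopifnot(n_samples >= 2, n_sites >= 1, rho >= 0, rho < 1,
            strand_bias > 0, strand_bias < 1,
            implant_fraction > 0, implant_fraction <= 1)
  er <- if (is.list(error_rate)) error_rate else
    list(base = error_rate, hot_fraction = 0, hot_rate = error_rate)
  stopifnot(er$base >= 0, er$base <= 1, er$hot_rate >= 0, er$hot_rate <= 1,
            er$hot_fraction >= 0, er$hot_fraction <= 1)
  if (!is.null(implant_vafs)) {
    stopifnot(all(implant_vafs > 0), all(implant_vafs <= 1))
    if (any(implant_vafs + max(er$base, er$hot_rate) > 1))
      stop("implant VAF + error rate exceeds 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 coverage = coverage, strand_bias = strand_bias,
                 error_rate = er, rho = rho,
                 implant_vafs = implant_vafs,
                 implant_fraction = implant_fraction,
                 dirichlet_alpha = dirichlet_alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic cohort
#'
#' Draws per-strand coverages from the coverage model, background variant
#' reads beta-binomially with the site's error rate and the configured
#' dispersion, and adds binomial variant reads on both strands for each
#' implanted (carrier, site) pair on top of the background, capped at
#' coverage. The reference allele is A and the variant allele is C
#' throughout. Deterministic given the seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{tensor} (a \code{\link{count_tensor}}) and
#'   \code{truth} (data.frame sample, chrom, pos, alt, vaf of implanted
#'   variants; the \code{carrier} column gives the sample index).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_samples
  nj <- config$n_sites
  k_var <- match("C", ALLELES)

  # site-specific per-strand error rates (shared across samples)
  er <- config$error_rate
  hot <- stats::runif(nj) < er$hot_fraction
  e_site <- ifelse(hot, er$hot_rate, er$base)

  cov_draw <- function(n) {
    cm <- config$coverage
    if (cm$type == "fixed") rep(as.integer(cm$value), n)
    else if (cm$type == "lognormal")
      pmax(1L, as.integer(round(stats::rlnorm(n, log(cm$median), cm$sdlog))))
    else stop("unknown coverage model: ", cm$type)
  }

  n_tot <- matrix(cov_draw(ns * nj), ns, nj)
  n_f <- matrix(stats::rbinom(ns * nj, as.vector(n_tot),
                              config$strand_bias), ns, nj)
  n_r <- n_tot - n_f

  # per-site implant bookkeeping
  implant_site <- rep(FALSE, nj)
  implant_vaf <- rep(NA_real_, nj)
  carrier <- rep(NA_integer_, nj)
  if (!is.null(config$implant_vafs)) {
    implant_site <- seq_len(nj) <= ceiling(nj * config$implant_fraction)
    implant_vaf[implant_site] <- rep_len(config$implant_vafs,
                                         sum(implant_site))
    carrier[implant_site] <- ((which(implant_site) - 1L) %% ns) + 1L
  }

  counts <- array(0L, c(ns, nj, 5L, 2L))
  for (j in seq_len(nj)) {
    xb_f <- rbetabinom(ns, n_f[, j], e_site[j], config$rho)
    xb_r <- rbetabinom(ns, n_r[, j], e_site[j], config$rho)
    if (!is.null(config$dirichlet_alpha)) {
      alpha <- rep_len(config$dirichlet_alpha, ns)
      g <- stats::rgamma(ns, alpha)
      nu <- g / sum(g)
      xb_f <- pmin(xb_f + stats::rbinom(ns, n_f[, j], nu), n_f[, j])
      xb_r <- pmin(xb_r + stats::rbinom(ns, n_r[, j], nu), n_r[, j])
    } else if (implant_site[j]) {
      ci <- carrier[j]; v <- implant_vaf[j]
      xb_f[ci] <- min(xb_f[ci] + stats::rbinom(1, n_f[ci, j], v), n_f[ci, j])
      xb_r[ci] <- min(xb_r[ci] + stats::rbinom(1, n_r[ci, j], v), n_r[ci, j])
    }
    counts[, j, k_var, 1] <- xb_f
    counts[, j, k_var, 2] <- xb_r
    counts[, j, 1L, 1] <- n_f[, j] - xb_f   # remaining reads carry the ref
    counts[, j, 1L, 2] <- n_r[, j] - xb_r
  }

  coverage <- array(0L, c(ns, nj, 2L))
  coverage[, , 1] <- n_f
  coverage[, , 2] <- n_r
  ids <- sprintf("S%04d", seq_len(ns))
  sites <- data.frame(chrom = "sim", pos = seq_len(nj) - 1L)
  tensor <- count_tensor(ids, sites, counts, coverage,
                         ref_allele = rep("A", nj))
  truth <- if (any(implant_site))
    data.frame(sample = ids[carrier[implant_site]],
               carrier = carrier[implant_site],
               chrom = "sim", pos = which(implant_site) - 1L,
               alt = "C", vaf = implant_vaf[implant_site],
               stringsAsFactors = FALSE)
  else
    data.frame(sample = character(0), carrier = integer(0),
               chrom = character(0), pos = integer(0),
               alt = character(0), vaf = numeric(0))
  list(tensor = tensor, truth = truth)
}

#' Detection power of truth-positive hypotheses
#'
#' Fraction of implanted variants whose score (Bayes factor or posterior)
#' falls below the cutoff, optionally per stratum, with an exact binomial
#' confidence interval.
#'
#' @param scores Scores of truth-positive hypotheses (smaller = more
#'   variant-like).
#' @param cutoff Call threshold: a hypothesis counts as detected when
#'   score < cutoff.
#' @param strata Optional factor/vector of stratum labels.
#' @param conf_level Confidence level of the exact CI.
#' @return data.frame with stratum, n, power, ci_lo, ci_hi.
#' @export
evaluate_power <- function(scores, cutoff, strata = NULL,
                           conf_level = 0.95) {
  if (is.null(strata)) strata <- rep("all", length(scores))
  keep <- !is.na(scores)
  if (any(!keep)) warning(sum(!keep), " NA scores dropped")
  scores <- scores[keep]; strata <- strata[keep]
  levs <- unique(strata)
  out <- do.call(rbind, lapply(levs, function(s) {
    sc <- scores[strata == s]
    if (length(sc) == 0) {
      warning("empty stratum omitted: ", s)
      return(NULL)
    }
    hits <- sum(sc < cutoff)
    ci <- stats::binom.test(hits, length(sc),
                            conf.level = conf_level)$conf.int
    data.frame(stratum = s, n = length(sc), power = hits / length(sc),
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve for discriminating truth-positive from
#' truth-negative hypotheses, scoring by \code{-score} (small scores,
#' e.g. small Bayes factors, indicate variants). Computed from ranks with
#' midranks for ties, i.e. the Mann-Whitney statistic.
#'
#' @param scores Numeric scores for all hypotheses.
#' @param labels Truth labels (logical or 0/1); both classes required.
#' @return AUC in \code{[0, 1]}.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("evaluate_auc needs both positive and negative hypotheses")
  r <- rank(-scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Power benchmark over a (VAF, coverage) grid
#'
#' For every grid cell, simulates \code{n_reps} cohorts with one implanted
#' carrier per site at the cell's VAF and fixed total coverage, runs the
#' cohort caller machinery for the carrier hypotheses, and aggregates the
#' detection power at a Bayes-factor cutoff. Each (cell, replicate) uses
#' its own derived seed so cells are independently reproducible. Setting
#' \code{rho_fixed} in \code{caller} mirrors a fixed-dispersion run;
#' leaving it NULL estimates the dispersion from the data.
#'
#' @param vaf_grid,coverage_grid Grids of implant VAFs and total coverages.
#' @param n_reps Replicate cohorts per cell.
#' @param n_samples,n_sites Cohort dimensions per replicate.
#' @param error_rate,rho_true Background generation parameters.
#' @param caller A \code{\link{caller_config}}.
#' @param bf_cutoff Bayes-factor call threshold; the default corresponds
#'   to posterior odds 1 under a uniform prior of 0.05.
#' @param seed Master seed.
#' @return data.frame with one row per cell: vaf, coverage, n, power,
#'   ci_lo, ci_hi.
#' @export
benchmark_power_grid <- function(vaf_grid, coverage_grid, n_reps = 1,
                                 n_samples = 100, n_sites = 50,
                                 error_rate = 1e-3, rho_true = 1e-4,
                                 caller = caller_config(rho_fixed = 1e-4),
                                 bf_cutoff = 0.05 / 0.95, seed) {
  stopifnot(length(vaf_grid) > 0, length(coverage_grid) > 0)
  if (missing(seed)) stop("benchmark_power_grid requires a seed")
  k_var <- match("C", ALLELES)
  grid <- expand.grid(vaf = vaf_grid, coverage = coverage_grid)
  out <- lapply(seq_len(nrow(grid)), function(cell) {
    bfs <- unlist(lapply(seq_len(n_reps), function(rep) {
      cell_seed <- (seed + 7919 * cell + 104729 * rep) %% 2147483647
      sim <- simulate_cohort(sim_config(
        n_samples = n_samples, n_sites = n_sites,
        coverage = list(type = "fixed", value = grid$coverage[cell]),
        error_rate = error_rate, rho = rho_true,
        implant_vafs = grid$vaf[cell], seed = cell_seed))
      vapply(seq_len(n_sites), function(j) {
        res <- cohort_bayes_factors(sim$tensor, j, k_var, caller)
        res$bf[sim$truth$carrier[j]]
      }, numeric(1))
    }))
    p <- evaluate_power(bfs, bf_cutoff)
    data.frame(vaf = grid$vaf[cell], coverage = grid$coverage[cell],
               n = p$n, power = p$power, ci_lo = p$ci_lo, ci_hi = p$ci_hi)
  })
  do.call(rbind, out)
}
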