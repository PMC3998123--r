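#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution in its mean/dispersion
#' (intraclass-correlation) parameterization: the success probability is
#' Beta-distributed with mean \code{mu} and the shape parameters are
#' \eqn{\alpha = \mu(1-\rho)/\rho} and \eqn{\beta = (1-\mu)(1-\rho)/\rho}.
#' The dispersion \eqn{\rho \in [0,1)} is the intraclass correlation of the
#' underlying Bernoulli draws; \eqn{\rho = 0} reduces continuously to the
#' binomial distribution. This is the count model used for per-strand
#' nucleotide counts at a site: \code{mu} is the site-specific error rate
#' (or variant allele frequency) and \code{rho} captures sample-to-sample
#' variability in excess of pure sampling noise.
#'
#' Degenerate means are handled as limits: \code{mu = 0} puts all mass on
#' \code{x = 0}, \code{mu = 1} on \code{x = n}. For very small positive
#' \code{rho} the Beta shapes are huge and the usual
#' \code{lbeta}-difference formula loses precision, so the log-density is
#' then accumulated as an explicit product of ascending-factorial terms.
#'
#' @param x Number of successes (counts of an allele), \code{0 <= x <= n}.
#' @param n Number of trials (strand coverage).
#' @param mu Mean success probability in \code{[0, 1]}.
#' @param rho Dispersion (intraclass correlation) in \code{[0, 1)}.
#' @param log If \code{TRUE}, return the log-density.
#' @return Vector of (log-)probabilities, recycled to common length.
#' @examples
#' dbetabinom(3, 10, mu = 0.3, rho = 1e-12)  # ~ dbinom(3, 10, 0.3)
#' sum(dbetabinom(0:50, 50, mu = 0.1, rho = 0.05))  # 1
#' @export
dbetabinom <- function(x, n, mu, rho, log = FALSE) {
  m <- max(length(x), length(n), length(mu), length(rho))
  x <- rep_len(as.numeric(x), m)
  n <- rep_len(as.numeric(n), m)
  mu <- rep_len(as.numeric(mu), m)
  rho <- rep_len(as.numeric(rho), m)

  if (any(!is.finite(x) | !is.finite(n) | x < 0 | n < 0 | x > n))
    stop("invalid counts: need 0 <= x <= n, finite")
  if (any(!is.finite(mu) | mu < 0 | mu > 1))
    stop("invalid mu: need 0 <= mu <= 1")
  if (any(!is.finite(rho) | rho < 0 | rho >= 1))
    stop("invalid rho: need 0 <= rho < 1")

  lp <- numeric(m)

  deg0 <- mu == 0
  deg1 <- mu == 1
  lp[deg0] <- ifelse(x[deg0] == 0, 0, -Inf)
  lp[deg1] <- ifelse(x[deg1] == n[deg1], 0, -Inf)

  bin <- !deg0 & !deg1 & rho == 0
  if (any(bin))
    lp[bin] <- stats::dbinom(x[bin], n[bin], mu[bin], log = TRUE)

  bb <- !deg0 & !deg1 & rho > 0
  if (any(bb)) {
    a <- mu[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - mu[bb]) * (1 - rho[bb]) / rho[bb]
    xs <- x[bb]
    ns <- n[bb]
    # lbeta-difference is accurate while the shapes stay moderate; beyond
    # that, sum the n log-terms of the rising-factorial ratio exactly.
    big <- (a + b) > 1e6
    out <- numeric(sum(bb))
    if (any(!big)) {
      out[!big] <- lchoose(ns[!big], xs[!big]) +
        lbeta(xs[!big] + a[!big], ns[!big] - xs[!big] + b[!big]) -
        lbeta(a[!big], b[!big])
    }
    if (any(big)) {
      idx <- which(big)
      out[idx] <- vapply(idx, function(i) {
        xi <- xs[i]; ni <- ns[i]
        lchoose(ni, xi) +
          (if (xi > 0) sum(log(a[i] + seq_len(xi) - 1)) else 0) +
          (if (ni - xi > 0) sum(log(b[i] + seq_len(ni - xi) - 1)) else 0) -
          (if (ni > 0) sum(log(a[i] + b[i] + seq_len(ni) - 1)) else 0)
      }, numeric(1))
    }
    lp[bb] <- out
  }

  if (log) lp else exp(lp)
}
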