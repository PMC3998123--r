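# direct linear-space evaluation of the Bayes-factor expression, used as
# the oracle for the log-space implementation
bf_direct <- function(x_f, n_f, x_r, n_r, mu_f, mu_r, nu_f, nu_r, rho) {
  Lf <- function(th) dbetabinom(x_f, n_f, th, rho)
  Lr <- function(th) dbetabinom(x_r, n_r, th, rho)
  num <- Lf(mu_f) * Lr(nu_r) + Lf(nu_f) * Lr(mu_r) - Lf(mu_f) * Lr(mu_r)
  max(num, 0) / (Lf(nu_f) * Lr(nu_r))
}

test_that("log-space Bayes factor matches direct evaluation on random instances", {
  set.seed(303)
  for (i in 1:60) {
    n_f <- sample(5:150, 1); n_r <- sample(5:150, 1)
    x_f <- rbinom(1, n_f, runif(1, 0, 0.3))
    x_r <- rbinom(1, n_r, runif(1, 0, 0.3))
    mu_f <- runif(1, 1e-4, 0.05); mu_r <- runif(1, 1e-4, 0.05)
    nu_f <- x_f / n_f; nu_r <- x_r / n_r
    rho <- runif(1, 1e-4, 0.05)
    got <- bayes_factor(x_f, n_f, x_r, n_r, mu_f, mu_r, nu_f, nu_r, rho)
    want <- bf_direct(x_f, n_f, x_r, n_r, mu_f, mu_r, nu_f, nu_r, rho)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("Bayes factor is symmetric under forward/reverse swap", {
  set.seed(304)
  for (i in 1:20) {
    a <- list(x_f = rbinom(1, 80, 0.1), n_f = 80,
              x_r = rbinom(1, 120, 0.1), n_r = 120,
              mu_f = runif(1, 1e-4, 0.01), mu_r = runif(1, 1e-4, 0.01),
              rho = 1e-3)
    bf1 <- bayes_factor(a$x_f, a$n_f, a$x_r, a$n_r, a$mu_f, a$mu_r,
                        a$x_f / a$n_f, a$x_r / a$n_r, a$rho)
    bf2 <- bayes_factor(a$x_r, a$n_r, a$x_f, a$n_f, a$mu_r, a$mu_f,
                        a$x_r / a$n_r, a$x_f / a$n_f, a$rho)
    expect_identical(bf1, bf2)
  }
})

test_that("Bayes factor behaves at the extremes", {
  # no coverage at all: no evidence, BF = 1
  expect_equal(bayes_factor(0, 0, 0, 0, 1e-3, 1e-3, 0, 0, 1e-4), 1)
  # clean null observation: equals the hand-computed pmf products
  got <- bayes_factor(0, 100, 0, 100, 1e-3, 1e-3, 0, 0, 1e-6)
  want <- bf_direct(0, 100, 0, 100, 1e-3, 1e-3, 0, 0, 1e-6)
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(abs(got - 1), 0.25)   # near 1: nothing to see
  # overwhelming two-strand evidence
  expect_lt(bayes_factor(30, 100, 30, 100, 1e-3, 1e-3, 0.3, 0.3, 1e-4),
            1e-10)
})

test_that("symmetric variant evidence never increases the Bayes factor", {
  n <- 200; mu <- 1e-3; rho <- 1e-4
  bfs <- sapply(0:20, function(x)
    bayes_factor(x, n, x, n, mu, mu, x / n, x / n, rho))
  expect_true(all(diff(bfs) <= 1e-12))
})

test_that("single-strand signal is absorbed by the OR null", {
  n <- 200; mu <- 1e-3; rho <- 1e-4
  for (tot in c(8, 16, 40)) {
    one_sided <- bayes_factor(tot, n, 0, n, mu, mu, tot / n, 0, rho)
    split <- bayes_factor(tot / 2, n, tot / 2, n, mu, mu,
                          tot / 2 / n, tot / 2 / n, rho)
    expect_gte(one_sided, split)
    expect_gt(one_sided, 0.4)   # the artifact is not callable
  }
  # the strand-agnostic null, by contrast, lets one-sided signal through
  ag <- bayes_factor(40, 200, 0, 200, 1e-3, 1e-3, 0.2, 0, 1e-4,
                     strand_mode = "agnostic")
  expect_lt(ag, 1e-6)
})

test_that("posterior follows Bayes' formula and its monotonicities", {
  expect_equal(posterior_null(1, 0.5), 0.5)
  expect_equal(posterior_null(0, 0.3), 0)
  expect_equal(posterior_null(1, 0.1), 0.9)
  # recompute by hand on a grid
  bf <- c(0.01, 0.5, 2, 100); pi <- 0.05
  expect_equal(posterior_null(bf, pi),
               bf * (1 - pi) / (bf * (1 - pi) + pi))
  # monotone in bf, anti-monotone in pi
  expect_true(all(diff(posterior_null(seq(0, 5, 0.5), 0.2)) > 0))
  expect_true(all(diff(posterior_null(2, seq(0.05, 0.95, 0.1))) < 0))
  expect_error(posterior_null(1, 0), "pi")
  expect_error(posterior_null(1, 1), "pi")
  expect_error(posterior_null(-1, 0.5), ">= 0")
})

test_that("mutation histograms normalize per gene and sum duplicates", {
  one <- build_mutation_histogram(
    data.frame(chrom = "c", pos = 10L, alt = "A", count = 5L))
  expect_equal(one$h, 1)
  two <- build_mutation_histogram(
    data.frame(chrom = "c", pos = c(10L, 20L), alt = c("A", "C"),
               count = c(3L, 1L)))
  expect_equal(sort(two$h), c(0.25, 0.75))
  expect_equal(sum(two$h), 1)
  dup <- build_mutation_histogram(
    data.frame(chrom = "c", pos = c(10L, 10L, 20L),
               alt = c("A", "A", "C"), count = c(2L, 1L, 1L)))
  expect_equal(dup$h[dup$pos == 10], 0.75)
  expect_equal(nrow(build_mutation_histogram(NULL)), 0)
})

test_that("prior track multiplies gene probability into the histogram", {
  h <- build_mutation_histogram(
    data.frame(chrom = "c", pos = c(10L, 20L), alt = c("A", "C"),
               count = c(3L, 1L)))
  track <- build_prior_track(list(TP53 = h), gene_probs = 0.01,
                             pi0 = 1e-4)
  expect_equal(prior_lookup(track, "c", 10L, "A"), 0.0075)
  expect_equal(prior_lookup(track, "c", 999L, "A"), 1e-4)   # uncatalogued
  expect_equal(prior_lookup(track, "c", 10L, "G"), 1e-4)    # other allele
  t2 <- build_prior_track(list(g = build_mutation_histogram(
    data.frame(chrom = "c", pos = 1L, alt = "T", count = 1L))),
    gene_probs = c(g = 0.5))
  expect_equal(prior_lookup(t2, "c", 1L, "T"), 0.5)
  expect_error(
    build_prior_track(list(KRAS = h), gene_probs = c(TP53 = 0.1)),
    "KRAS")
})

test_that("hotspot catalogue reader builds a usable prior", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tpos\tref\talt\tcount",
               "TP53\tchr1\t30\tT\tA\t9",
               "TP53\tchr1\t31\tT\tC\t3",
               "TP53\tchr1\t31\tT\tT\t4",   # alt == ref: dropped
               "KRAS\tchr2\t5\tG\tA\t2"), path)
  cat <- read_hotspot_catalogue(path)
  expect_setequal(names(cat), c("TP53", "KRAS"))
  h <- build_mutation_histogram(cat$TP53)
  expect_equal(sum(h$h), 1)
  expect_equal(h$h[h$pos == 29], 0.75)   # file is 1-based, tensor 0-based
  track <- build_prior_track(lapply(cat, build_mutation_histogram),
                             gene_probs = 0.1)
  expect_equal(prior_lookup(track, "chr1", 29L, "A"), 0.075)
})

test_that("the cohort caller finds exactly the implanted variant", {
  set.seed(99)
  ns <- 50
  # background: ~1e-3 error on allele C, both strands, coverage 200/strand
  c_f <- matrix(rbinom(ns * 2, 200, 1e-3), ns, 2)
  c_r <- matrix(rbinom(ns * 2, 200, 1e-3), ns, 2)
  c_f[7, 1] <- c_f[7, 1] + 20L   # sample 7, site 1: 20 extra reads/strand
  c_r[7, 1] <- c_r[7, 1] + 20L
  tensor <- make_tensor(ns, 2, cov_fwd = 200L, cov_rev = 200L,
                        c_fwd = c_f, c_rev = c_r)
  calls <- call_variants(tensor, config = caller_config(rho_fixed = 1e-4))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sample, "S007")
  expect_equal(calls$pos, 0L)
  expect_equal(calls$alt, "C")
  expect_lte(calls$posterior_m0, 0.5)
  # all-zero cohort: no calls
  t0 <- make_tensor(10, 2, cov_fwd = 100L, cov_rev = 100L)
  expect_equal(nrow(call_variants(t0)), 0)
})

test_that("polymorphism carriers are excluded from reference sets, then filtered by list", {
  set.seed(100)
  ns <- 50
  carriers <- 1:40   # germline polymorphism at VAF ~0.5 in 40/50 samples
  c_f <- matrix(0L, ns, 1); c_r <- matrix(0L, ns, 1)
  c_f[carriers, 1] <- rbinom(40, 200, 0.5)
  c_r[carriers, 1] <- rbinom(40, 200, 0.5)
  tensor <- make_tensor(ns, 1, cov_fwd = 200L, cov_rev = 200L,
                        c_fwd = c_f, c_rev = c_r)
  # reference set for a carrier consists of the 10 non-carriers (+ other
  # carriers are excluded by the VAF threshold)
  J <- select_reference_set(tensor, 1, 1, 2, 0.1)
  expect_setequal(J, 41:50)
  calls <- call_variants(tensor, config = caller_config(rho_fixed = 1e-4))
  expect_setequal(calls$sample, sprintf("S%03d", carriers))
  # the exclusion list removes them post hoc (pos is 1-based there)
  ex <- data.frame(chrom = "chr1", pos = 1L, alt = "C")
  calls2 <- call_variants(tensor, config = caller_config(
    rho_fixed = 1e-4, exclude = ex))
  expect_equal(nrow(calls2), 0)
})

test_that("calling is deterministic and VCF fields are self-consistent", {
  set.seed(101)
  ns <- 30
  c_f <- matrix(rbinom(ns, 150, 2e-3), ns, 1)
  c_r <- matrix(rbinom(ns, 150, 2e-3), ns, 1)
  c_f[3, 1] <- 25L; c_r[3, 1] <- 30L
  tensor <- make_tensor(ns, 1, cov_fwd = 150L, cov_rev = 150L,
                        c_fwd = c_f, c_rev = c_r,
                        ref = "T")
  cfg <- caller_config(rho_fixed = 1e-4)
  calls <- call_variants(tensor, config = cfg)
  expect_gte(nrow(calls), 1)
  ref <- fixture_reference()
  v1 <- withr::local_tempfile(fileext = ".vcf")
  v2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, ref, v1)
  write_vcf(call_variants(tensor, config = cfg), ref, v2)
  expect_identical(readLines(v1), readLines(v2))   # byte-identical
  # posterior recomputed from the emitted BF and PI matches emitted PM0
  rec <- grep("^[^#]", readLines(v1), value = TRUE)[1]
  f <- strsplit(rec, "\t")[[1]]
  pi <- as.numeric(sub("PI=", "", f[8]))
  gt <- strsplit(f[10:length(f)], ":")
  gt <- gt[!vapply(gt, function(g) identical(g, "."), logical(1))]
  for (g in gt) {
    bf <- as.numeric(g[1]); pm0 <- as.numeric(g[2])
    expect_lt(abs(posterior_null(bf, pi) - pm0), 1e-9)
  }
})

test_that("hypotheses with empty reference sets are skipped, not called", {
  # 3 samples, all at VAF 0.5: every reference set is empty
  c_f <- matrix(50L, 3, 1); c_r <- matrix(50L, 3, 1)
  tensor <- make_tensor(3, 1, cov_fwd = 100L, cov_rev = 100L,
                        c_fwd = c_f, c_rev = c_r)
  calls <- call_variants(tensor, config = caller_config(rho_fixed = 1e-4))
  expect_equal(sum(calls$alt == "C"), 0)
  expect_gte(attr(calls, "skipped"), 3)
})
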