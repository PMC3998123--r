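---
title: "Cohort-based subclonal variant calling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-based subclonal variant calling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

Targeted panels resequence the same loci across hundreds of samples, so
every site's artifact spectrum can be estimated by pooling all other
samples instead of relying on a matched normal. For sample $i$, site
$j$, allele $k$ and strand $s \in \{f, r\}$, the allele count $X_{ijks}$
out of coverage $n_{ijs}$ is modelled beta-binomially,
$$X \sim \mathrm{BetaBin}(n, \mu, \rho), \qquad
  \alpha = \mu\frac{1-\rho}{\rho},\ \beta = (1-\mu)\frac{1-\rho}{\rho},$$
where $\mu$ is the site/strand-specific rate and $\rho \in [0,1)$ the
intraclass correlation capturing sample-to-sample variability of the
error rate beyond sampling noise; $\rho = 0$ is binomial. $\rho$ carries
no sample index: it is one number per (site, allele), shared across
strands.

For each target sample the **aggregate control** is the element-wise sum
of counts and coverages over the reference set $J(i)$: every other
sample whose combined-strand VAF at $(j,k)$ is below `vaf_threshold`
(default 0.1, so clonal carriers and germline polymorphisms drop out of
the error estimate; zero-coverage samples count as VAF 0 and stay in).

Variant calling is model selection between

* $M_0$: the sample's rate equals the pooled error rate on the forward
  **or** the reverse strand, and
* $M_1$: the rate exceeds the error rate on both strands.

The OR makes one-sided signals — the classic signature of library and
alignment artifacts — null by construction. The Bayes factor is
approximated with plug-in point estimates,
$$\mathrm{BF} =
  \frac{L_f(\hat\mu_f) L_r(\hat\nu_r) + L_f(\hat\nu_f) L_r(\hat\mu_r)
        - L_f(\hat\mu_f) L_r(\hat\mu_r)}
       {L_f(\hat\nu_f) L_r(\hat\nu_r)},$$
with $L_s(\theta)$ the beta-binomial likelihood of the target's counts
on strand $s$ at rate $\theta$. The three numerator terms correspond to
"forward is null", "reverse is null" and their overlap; combining them
by inclusion–exclusion ($P(A\cup B) = P(A)+P(B)-P(A\cap B)$) is the
default, with the numerator floored at zero since the plug-in
approximation can make the subtraction marginally negative. A config
switch (`numerator = "additive"`) keeps the plain sum; the third term is
negligible whenever the observed VAFs differ clearly from the error
rates, so the two choices rarely disagree in practice.

The prior probability $\pi_{jk}$ of a variant converts the Bayes factor
into a posterior by Bayes' formula,
$$P(M_0 \mid D) = \frac{\mathrm{BF}\,(1-\pi)}{\mathrm{BF}\,(1-\pi)+\pi},$$
and calls are emitted at $P(M_0 \mid D) \le 0.5$, the natural Bayes
cutoff. Hotspot catalogues supply informative priors: within each gene
the catalogued observation counts are normalized to a histogram
$h_{jk}$, and $\pi_{jk} = P(\text{gene mutated}) \cdot h_{jk}$ (clipped
below 1); uncatalogued sites get `pi0`.

## Point estimates

* **Error rates.** $\hat\mu_s = (X_s + x_s + c)/(N_s + n_s + 2c)$ pools
  the aggregate control with the target sample, because $M_0$ asserts a
  single common rate; `mu_pooling = "loo"` drops the target for
  sensitivity analyses. The pseudocount $c = 0.5$ (Jeffreys-like)
  keeps the estimate strictly inside $(0,1)$ — a zero error rate would
  make the Bayes factor degenerate.
* **Sample VAFs.** $\hat\nu_s = x_s/n_s$, defined as 0 at zero
  coverage. Under $M_1$ the observed rate is the sum of the true allele
  frequency and the error rate, so the raw ratio is the plug-in for the
  observed-rate parameter; `nu_mode = "excess"` instead floors it at
  $\hat\mu_s$, enforcing the $M_1$ constraint on the plug-in.
* **Dispersion.** No closed-form MLE exists; the method-of-moments
  estimator uses the combined-strand VAFs $\nu_i$ of the reference-set
  samples: with $\bar\mu$ their coverage-weighted mean, $s^2$ their
  sample variance and $h$ the mean reciprocal coverage,
  $$\hat\rho = \frac{s^2 - \bar\mu(1-\bar\mu)h}
                    {\bar\mu(1-\bar\mu)(1-h)},$$
  clamped to $[\rho_{\min}, \rho_{\max}] = [10^{-4}, 0.1]$. The clamp
  guards against negative or runaway moment estimates; degenerate inputs
  (fewer than two covered samples, zero mean or variance) return
  $\rho_{\min}$. For equal coverages the estimator is exactly unbiased
  in expectation, and simulations in the test suite show median recovery
  of $\rho = 0.05$ within ±30% at 500 samples of 200×. `rho_fixed`
  bypasses estimation entirely for fixed-dispersion runs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `vaf_threshold` | 0.1 | reference-set exclusion VAF |
| `pseudocount` | 0.5 | stabilizer in $\hat\mu$ |
| `rho_min`, `rho_max` | 1e-4, 0.1 | dispersion clamp |
| `rho_fixed` | NULL | fixed dispersion (skips estimation) |
| `strand_mode` | "both" | OR-null vs pooled strand-agnostic null |
| `posterior_cutoff` | 0.5 | call threshold on $P(M_0\mid D)$ |
| `pi0` | 1e-4 | prior for uncatalogued sites |
| `min_base_quality` | 25 | pileup base-quality floor |
| `min_mapping_quality` | 30 | pileup mapping-quality floor |

The strand-agnostic mode (`strand_mode = "agnostic"`) compares pooled
counts with a single likelihood ratio; it rescues power at region flanks
where only one read orientation is available, at a cost in specificity
against strand artifacts.

## Numerical choices

The beta-binomial log-pmf is the `lchoose` + `lbeta`-difference form for
moderate shapes; once $\alpha + \beta > 10^6$ (vanishing $\rho$) the
`lbeta` differences lose precision and the implementation switches to an
exact sum of the $n$ log-terms of the rising-factorial ratio. Degenerate
means are limits: $\mu = 0$ puts all mass at $x=0$, $\mu = 1$ at $x=n$,
$\rho = 0$ is `dbinom`. All Bayes-factor products are log-space with a
max-shift before exponentiating; zero coverage on both strands, or joint
numerator/denominator underflow, yields BF = 1 (no evidence). Posterior
consistency is preserved through the VCF: fields are printed with 12
significant digits so $P(M_0\mid D)$ recomputed from the emitted BF and
prior agrees to $10^{-9}$.

Coordinates are 0-based half-open internally; every file interface
(count-table `pos`, VCF `POS`, catalogue and exclusion lists) is
1-based. Quality-filtered bases are removed from counts *and* coverage,
so coverage always equals the allele-count sum over quality-passing
reads and $\hat\mu$ is a rate over usable bases. Single-base deletions
are first-class alleles (DEL); insertions are not modelled. VCF output
left-anchors deletions (2-base REF, 1-base ALT).

## The simulator and what it shows

`simulate_cohort()` generates per-(sample, site, strand) coverages
(fixed, or lognormal with median 128× — matching a deep panel's typical
normal-sample profile; the log-sd 1.02 is a geometric compromise between
the 5th- and 95th-percentile spreads of such a profile, which a
two-parameter lognormal cannot match simultaneously), site-specific
error rates (constant, or a mixture with occasional high-error sites),
beta-binomial background reads, and implanted variants whose reads are
binomial on both strands **on top of** the background — signal plus
noise, since an observed variant rate is the sum of the true allele
frequency and the error rate. A Dirichlet mode draws a full VAF vector
across samples per site for heterogeneous-cohort experiments. Carriers
are assigned round-robin; every cohort is deterministic given its seed,
and the benchmark grid derives an independent seed per (cell, replicate)
so cells are individually reproducible.

The benchmark sizes used by the shipped tests and the acceptance script
are 500-sample cohorts with 400–2000 sites per condition — enough for
±2–3 percentage-point Monte-Carlo error on a power estimate — and the
null-specificity check screens 100 sites × 4 alleles × 500 samples
(~200 000 hypotheses).

What passing these simulations does **not** show: the generator draws a
clean, homogeneous background (one error rate per site, even strand
split unless configured otherwise, no mapping or context-specific
artifact structure). Real panels have strand-biased coverage and heavy-
tailed, context-dependent error spectra; against such backgrounds the
detection power at a given VAF/coverage is lower — low-VAF variants on a
strand-starved site cannot satisfy the both-strand requirement — and
low-VAF discrimination is harder. Published benchmarks on real panel
backgrounds therefore report lower power at 250× (≈70% at VAF 5%) and a
lower AUC at VAF 1% (≈60%) than this clean simulation produces; the
ordering and saturation behaviour (power monotone in VAF and coverage,
near-certain detection of 20% variants, AUC → ~100% at clonal VAFs)
match. We deliberately do not ship an invented strand-bias distribution
calibrated to reproduce those printed numbers.

## Known limitations

* Point-estimate (plug-in) Bayes factors, not full marginal likelihoods:
  fast and well-behaved in deep data, but approximate.
* No matched-normal mode; polymorphisms are handled by the VAF threshold
  in reference-set selection plus an optional post-hoc exclusion list,
  not by a germline genotyper or a live variation database.
* Per-sample dispersion and maximum-likelihood $\rho$ fitting are out of
  scope; $\rho$ is a per-(site, allele) moment estimate.
* Insertions and multi-base indels are not called.
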