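---
title: "Models and methods behind poolacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolacc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poolacc` simulates pooled re-sequencing of isogenic strain panels and
quantifies how faithfully pooled read fractions recover allele
frequencies. This vignette records the generative model, the statistics,
the defaults and why they were chosen, and what the simulations do and do
not establish.

## The generative model

**Strains.** A panel is a binary matrix of homozygous strains × biallelic
sites. Isogenic strains carry a single haplotype, so genotypes are exactly
0 or 1 — no heterozygotes, and one strain contributes one allele per site
regardless of how many individuals of that strain are pooled (genetically
identical individuals only rescale the strain's DNA mass, which the
contribution model absorbs; X-vs-autosome dosage is not modeled).

Sites are independent: population frequency $p_j$ is drawn from a site
frequency spectrum (uniform, a $1/x$ "neutral" grid, or a fixed list), and
each strain carries the allele independently with probability $p_j$.
"Truth" is either $p_j$ itself (*source mode* — the panel is a sample from
a larger reference population) or the realized column mean (*panel mode*).
The distinction matters: in source mode even a perfectly even, infinitely
deep pool cannot reach concordance 1, because the pooled strains are a
finite sample of the population; in panel mode the model matches the
simulation exactly. Library-family experiments use source mode, mirroring
the real situation where pooled strains are scored against a reference
panel's frequencies.

**Pooling.** Each strain's DNA share is a library-level property, fixed
across sites, so unequal contribution is one draw from a symmetric
Dirichlet($\alpha$) per library. The field's empirical observation is a
smooth gradation of shares without a bimodal split (arguing against PCR
jackpotting), and a symmetric Dirichlet is the minimal exchangeable model
with that behavior. The default $\alpha = 20$ gives a visibly unequal but
gradual spread for ~20-strain pools, comparable to what private-SNP
analyses of real small pools show; $\alpha = \infty$ gives the ideal
equal pool. No generative model for contributions is published, so this
is this package's design choice.

**Reads.** Per site, depth $d_j$ comes from the depth model and the
non-reference count is
$$ B_j \sim \mathrm{Binomial}\!\left(d_j,\; q_j(1-\varepsilon) + (1-q_j)\varepsilon\right),
\qquad q_j = \sum_i w_i g_{ij}, $$
which is exactly the marginal of per-read strain picking followed by
per-read allele flipping at error rate $\varepsilon$. Defaults:
$\varepsilon = 0$ for frequency-accuracy work (binomial expectation
simulations ignore error, and at a polymorphic site an error flips an
observed allele, a second-order effect) and $\varepsilon = 10^{-3}$ for
discovery experiments, where errors are the false-positive process and
$10^{-3}$ is a typical post-filter short-read substitution rate.

**Depth.** The default depth model is Poisson($\lambda$) *conditioned* on
$d \ge$ the analysis filter (default 10×) — conditioning, not clipping,
via inverse-CDF sampling of the truncated distribution. Real analyses
restrict to sites passing the filter, so the analyzed depth distribution
is the truncated one; simulating it directly avoids wasting sites. Raw
(unconditioned) draws plus downstream filtering are available with
`condition_depth = FALSE`, and an empirical depth histogram can replace
the Poisson to mimic an observed depth distribution. A truncated Poisson
is more concentrated than real depth distributions (which are overdispersed
by mappability and GC effects), so simulated "expected" accuracies are
upper bounds for a given mean depth.

## Accuracy statistics

**Lin's concordance correlation**
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ penalizes both
scatter and deviation from the identity line. Moments use population
($1/n$) denominators; at the design's $n = 1000$ sites per replicate the
difference from $1/(n-1)$ is ~$10^{-3}$ relative and far below reported
precision.

**Squared relative error** $((f_{\mathrm{est}} - f_{\mathrm{true}})/f_{\mathrm{true}})^2$
is undefined at truth 0 and the implementation raises an error rather than
silently dropping such sites; callers exclude them. Note the statistic is
unbounded as truth $\to 0$: with a *continuous* uniform truth spectrum,
a binomial draw of even one read at a site with truth $10^{-4}$ yields a
relative error of order $10^{5}$, so the upper end of the expected
relative-error range is dominated by near-zero-truth sites. A real strain
panel's truth frequencies are discrete (multiples of $1/N_{\mathrm{panel}}$,
bounded away from 0), which is why published relative-error ranges are
far smaller. Concordance is unaffected.

**Binned resampling.** Raw site sets are dominated by rare alleles, which
would let low-frequency sites drive every statistic. Each replicate
therefore draws 50 sites without replacement from each of 20 half-open
frequency bins of width 5% (the last bin closed at 1), i.e. 1,000 sites
with a flat frequency profile; 100 replicates give the reported min–max
ranges. Sites at exactly 0 or 1 participate in the end bins for
concordance but are excluded from relative error by the zero guard. A bin
with fewer than 50 sites is an error by default; `allow_short_bins`
downscales the per-bin count to the minimum occupancy with a loud
warning, keeping the sample balanced rather than silently unbalancing it.

**Binomial expectation.** The best-case estimate at observed depths is
$B/d$, $B \sim \mathrm{Binomial}(d, f_{\mathrm{true}})$ — read sampling
only, no strain layer. Within each replicate the observed and expected
statistics use the *same* resampled site set, so replicate-to-replicate
variation cancels out of the observed−expected comparison. In
replicate mode the expectation is two independent binomial draws, each at
its own library's observed depths. A useful closed form for uniform truth
and constant depth $d$:
$\mathbb{E}[\rho_c] \approx 2\mathrm{Var}(p) / (2\mathrm{Var}(p) + \mathbb{E}[p(1-p)]/d) = d/(d+1)$,
which the test suite verifies to within 0.005 at $d = 20$ and $40$, and
which explains why doubling depth from 20× to 40× moves expected
concordance only from ~0.95 to ~0.97 while the strain-number effect is
much larger at small pools.

## DNA contributions from private SNPs

Every non-reference read at a SNP private to one strain originated from
that strain, so the pooled frequency of private SNPs estimates the
strain's DNA share. The estimator samples 50 private SNPs per strain per
replicate (without replacement within a replicate, independent across the
10 replicates; with ~250 private SNPs per strain the with/without
replacement distinction is negligible), reports the mean of replicate
means and a ±2 SD band (sample SD over the 10 replicate means), and sorts
strains by mean share. Strains with fewer private SNPs than the per-rep
sample size are dropped with a warning rather than estimated noisily. The
pool-depth filter for private-SNP eligibility is strict (`> 10×`); the
per-strain coverage clause of real-data analyses is exposed as a
predicate hook, since synthetic genotypes are exact.

## SNP discovery

The caller is deliberately transparent: call a site iff it has at least
`min_nonref` non-reference reads *and*
$P[\mathrm{Binomial}(d, \varepsilon) \ge \mathrm{nonref}] < \alpha$
(defaults 2, $10^{-3}$, $10^{-3}$). This is a stand-in for production
genotypers, chosen so that false positive / negative trade-offs are
analytically predictable; it makes no claim to match any particular
caller's behavior.

Rates are reported by folded (minor-allele) frequency bin with cut-points
(0–5%], (5–10%], (10–50%]. False negatives are binned by *truth* folded
frequency; false positives have no truth frequency and are binned by
their *estimated* folded frequency — the published procedure is ambiguous
here, and this choice is documented rather than presented as the
original's. Sites fixed non-reference in the truth are real variants
(not false positives) though their folded frequency 0 keeps them outside
the polymorphism bins. Both truth modes are supported: scoring against
the full source population inflates false negative rates (some sites are
simply absent from the pooled strains), scoring against the pooled
strains only isolates caller performance. Empty bins report `NA`, never a
fabricated 0.

Per-bin false positive *rates* under a shrinking call set are ratios of
two shrinking counts and are not mathematically monotone in
`min_nonref`; the dominance property (raising the count floor never
raises FPR, never lowers FNR) is therefore asserted on aggregate rates on
fixed data, where it holds because low-count calls are disproportionately
error-driven.

## Experiments and reproducibility

`run_library_family()` mirrors the canonical design: A (22 strains, 10×),
B1/B2 (the *same* 42 strains, 20×, independent contribution draws — i.e.
biological replicates), B4 (50 disjoint strains, 20×), and merged
libraries B3 = B1+B2, B5 = B1+B4, B6 = B2+B4 at ~40×. Merging sums raw
counts per site (merging reads, not intersecting call sets; sites absent
from one library contribute (0,0)), and all libraries are restricted to
sites passing the 10× filter in every library before scoring.

`strain_number_sweep()` isolates the strain-number effect by holding the
depth model fixed (default 20× conditioned ≥10) across 22/42/92-strain
pools; the library family instead uses the per-library depths above. The
observed−expected concordance gap decomposes as finite strain sampling
($\mathbb{E}[p(1-p)]/n$) plus contribution noise
($\approx \mathbb{E}[p(1-p)]/(n\alpha+1)$), both shrinking in $n$ — the
mechanism by which pooling more strains, not sequencing deeper, closes
the gap.

Randomness: every operation takes a `seed`; pipelines take one root seed
and split it with `derive_seeds()` (deterministic child seeds below
$2^{31}$), so whole experiments are byte-reproducible from a single
integer while leaving the caller's RNG stream untouched.

## What a green test does not establish

The generator emulates the statistical structure of pooled sequencing —
binomial read sampling, unequal contributions, depth variation, uniform
per-read error. It does not emulate mapping artifacts, reference bias,
indels or structural variation, PCR duplicates, base-quality variation,
or correlated errors; observed accuracies on real data will sit below
these simulations for those reasons, and the simulated "expected" values
are best read as upper bounds at a given depth profile. Truth frequencies
here are continuous, whereas a real reference panel's are discrete with a
floor at $1/N_{\mathrm{panel}}$ — this affects relative-error magnitudes
(see above) but not concordance comparisons.

## Known limitations

* The Dirichlet contribution model is exchangeable: it cannot encode a
  systematically over-represented strain.
* The caller ignores base qualities and strand information.
* `relative_error` requires truth > 0 by construction; analyses of
  monomorphic-reference sites must use other statistics.
* Real-data mode expects biallelic sites; multiallelic records are
  skipped by the VCF reader.
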