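---
title: "Methods: two-sample MR and polygenic scoring with mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and polygenic scoring with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For instrument $i$, one GWAS supplies the effect on the exposure
$\hat\beta_{Xi}$ with standard error $\sigma_{Xi}$, a second (non-overlapping)
GWAS the effect on the outcome $\hat\beta_{Yi}$ with $\sigma_{Yi}$. Under the
instrumental-variable assumptions (relevance, independence from confounders,
no effect on the outcome except through the exposure), each Wald ratio
$r_i = \hat\beta_{Yi}/\hat\beta_{Xi}$ estimates the same causal effect
$\theta$, and the estimators differ in how they pool ratios when some
instruments are invalid:

* **IVW** pools with weights $w_i = 1/\sigma_{Yi}^2$,
  $\hat\theta = \sum w_i \hat\beta_{Xi}\hat\beta_{Yi} / \sum w_i
  \hat\beta_{Xi}^2$ — efficient when *all* instruments are valid, biased by
  any directional pleiotropy. The default multiplicative random-effects
  variant inflates the fixed-effect standard error by
  $\max(1, \sqrt{Q/(n-1)})$ so overdispersion widens, never narrows,
  intervals.
* **MR-Egger** frees the intercept after orienting all rows to
  $\hat\beta_{Xi} \ge 0$; a nonzero intercept estimates the average
  directional pleiotropy (under the assumption that pleiotropic effects are
  independent of instrument strength), at the cost of much lower precision.
  Residual overdispersion inflates both standard errors by
  $\max(1, \sqrt{RSS_w/(n-2)})$ and inference is t-based with $n-2$ df.
* **Weighted median** orders the ratios and interpolates the cumulative
  weight midpoints at 0.5; it is consistent while valid instruments carry
  more than half the weight. Standard errors come from a parametric
  bootstrap: $\beta_X^* \sim N(\hat\beta_X, \sigma_X)$,
  $\beta_Y^* \sim N(\hat\beta_Y, \sigma_Y)$, re-estimating on each draw.
* **Mode estimators** take the argmax of a Gaussian-kernel density over the
  ratios (bandwidth $\varphi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{MAD}/0.6745)\, n^{-1/5}$, density evaluated on a fixed
  10,000-point grid spanning $\bar r \pm 5\,\mathrm{sd}(r)$, first grid
  point taken on ties); consistent when the largest group of instruments
  sharing a ratio is valid (the "zero modal pleiotropy" assumption).
* **Cochran's Q**, $\sum_i (\hat\beta_{Xi}^2/\sigma_{Yi}^2)(r_i -
  \hat\theta)^2 \sim \chi^2_{n-1}$ under homogeneity, flags invalid
  instruments collectively.

### MR-PRESSO

The global test asks whether the observed dispersion around the model
exceeds what sampling error explains. For each SNP the expected outcome
effect uses the leave-one-out IVW slope $\hat\theta_{(-i)}$ (so a gross
outlier cannot mask itself), and the statistic is the weighted residual sum
of squares $\mathrm{RSS} = \sum_i w_i(\hat\beta_{Yi} -
\hat\theta_{(-i)}\hat\beta_{Xi})^2$. Its null distribution is simulated:
$\beta_{Xi}^* \sim N(\hat\beta_{Xi}, \sigma_{Xi})$,
$\beta_{Yi}^* \sim N(\hat\theta_{(-i)}\hat\beta_{Xi}, \sigma_{Yi})$, with
the statistic recomputed identically (including the leave-one-out fits).
Empirical p-values use the add-one convention $(1 + \#\{RSS^* \ge
RSS\})/(n_{sim}+1)$, so the smallest attainable p is $1/(n_{sim}+1)$ and
never zero. Per-SNP outlier p-values compare each observed residual with its
own simulated distribution and are Bonferroni-scaled by $n$ (capped at 1) —
note the practical floor $n/(n_{sim}+1)$: with 20 SNPs, at least ~400
simulations are needed before any outlier call at $\alpha = 0.05$ is even
possible. The distortion test measures
$100(\hat\theta_{all}-\hat\theta_{no})/|\hat\theta_{no}|$ and compares it
with the coefficients obtained by removing equally many random non-outlier
SNPs. The weighted form of the RSS ($w_i = 1/\sigma_{Yi}^2$) is the default;
`weighted = FALSE` switches to raw residuals. Simulation iterations draw
from per-iteration substreams derived from the single user seed and are
merged in iteration order, which makes results bit-identical for any
`n_workers`.

## Harmonization

Effects are aligned to the exposure's effect allele. Swapped allele labels
negate $\hat\beta_Y$ and complement the allele frequency; alleles matching
only after complementary-strand recoding (A↔T, C↔G) are recoded first;
anything else is dropped as incompatible. Palindromic pairs ({A,T}, {C,G})
are strand-ambiguous by construction, so three policies are offered: trust
the labels (action 1), infer orientation from allele frequencies
(action 2, the default — flip when the two frequencies sit on opposite
sides of 0.5, drop as ambiguous when either lies in
$[0.42, 0.58]$), or drop all palindromic rows (action 3). The 0.42
threshold and the action vocabulary follow the convention long established
for two-sample MR harmonization; they are conventions, not estimates, and
both are arguments. Harmonization is involutive: running it on its own
output changes nothing. Indels are dropped because complementary-strand
logic is undefined for them.

Instruments missing from the outcome can be replaced by the best available
LD proxy ($r^2 \ge 0.8$ within 500 kb by default). The proxy's alleles are
translated back into the target's allele frame using the *signed* r from
the panel: $r < 0$ means the proxy's A1 travels with the target's A2.
Proxies whose outcome alleles cannot be resolved against the panel coding
are skipped rather than guessed.

## Clumping, scoring, panels

Clumping is the standard greedy algorithm: candidates with $p \le p_1$
visited in ascending p order (ties by position, then rsid, for
determinism); each surviving candidate becomes an index and claims every
unclaimed variant with $p \le p_2$ within `kb` kilobases at $r^2 \ge$ the
threshold. Defaults ($p_1 = 5\times10^{-8}$, $p_2 = 1$, $r^2 = 0.01$,
250 kb) are the values in wide use for human GWAS. Variants unresolvable in
the panel can neither claim nor be claimed and are dropped with their own
report entry — a conservative choice, since retaining them could leave
correlated pairs in the output.

PRS is the plain sum $\sum_i \hat\beta_i d_{ij}$ over effect-allele dosages
(a sum score, not an average — tools differ and the choice matters for
absolute values). The score is exactly invariant to how the *genotype file*
codes each variant's alleles. Re-expressing a *weight* for the other allele
(swap alleles, negate the weight) shifts every sample by the same constant
$2\hat\beta_i$, leaving all contrasts and downstream regressions untouched;
an exact per-sample invariance under weight recoding would require
frequency-centered dosages, which the plain sum deliberately is not.
Missing genotypes are mean-imputed per SNP by default (`missing =
"strict"` drops incomplete SNPs instead) — both behaviours exist in common
scoring tools, so both are offered.

PLINK 1 filesets are parsed natively (SNP-major 2-bit codes, padding bits
written as zero so round trips are byte-identical); per-chromosome filesets
merge through a `"{chr}"` prefix pattern. LD uses pairwise-complete
Pearson correlation of dosages, and monomorphic variants are an error
rather than a silent NA.

## The simulator: what it does and does not emulate

`simulate_panel()` draws, per haplotype, a latent AR(1) Gaussian process
within blocks (default: blocks of 10 SNPs, $\rho = 0.8$) thresholded at the
MAF quantile; dosages are sums of two haplotypes. This yields blockwise LD
with geometric-style decay — enough structure to exercise clumping, proxy
search and scoring. Thresholding attenuates correlations, so dosage $r^2$
is substantially below $\rho^2$, more so at extreme MAF; tests assert decay
rankings, not latent values. It does **not** emulate realistic human LD
maps, population structure, or relatedness, so passing tests demonstrate
algorithmic correctness, not performance on any particular cohort.

`simulate_gwas_pair()` implements the standard two-sample generative model:
$\gamma_i \sim N(0, \sigma_\gamma^2)$,
$\hat\beta_{Xi} = \gamma_i + N(0, \sigma_{Xi})$,
$\hat\beta_{Yi} = \theta\gamma_i + \alpha_i[i\ \text{invalid}] +
N(0, \sigma_{Yi})$, with GWAS-scale standard errors
$\sigma = (2n\,\mathrm{maf}(1-\mathrm{maf}))^{-1/2}$. Defaults — 100 SNPs,
GWAS n of 100,000 on both sides, $\theta = 0.2$, $\sigma_\gamma = 0.05$
(mean instrument F around 90, i.e. strong instruments), 20% palindromic
variants, 30% of outcome rows reported on the opposite allele — were chosen
once to represent a well-powered human study while giving harmonization
real work. One subtlety is worth stating: with $\gamma$ symmetric about
zero, an additive pleiotropic shift $\alpha$ on the labelled effect allele
is *invisible* to MR-Egger, because the estimator's $\hat\beta_X \ge 0$
orientation flips half the $\alpha$ signs. Pleiotropy only becomes
"directional" in the Egger-detectable sense when it acts on the
exposure-increasing allele; `pleio_directional = TRUE` generates that form
($\alpha_i\,\mathrm{sign}(\gamma_i)$), and the detection tests use it.

## Numerical choices and degenerate inputs

* p-values are floored at $10^{-320}$, never 0; p = 0 on input is clamped,
  not dropped. SE↔p derivation uses `qnorm(p/2, lower.tail = FALSE)`, which
  stays accurate far below the $10^{-16}$ resolution of `1 - p/2`.
* Duplicate rsids keep the smallest p, ties by first occurrence.
* Zero-$\hat\beta_X$ instruments are dropped (with a counted warning) before
  ratio-based estimators rather than producing infinite ratios.
* All-identical ratios collapse the mode's bandwidth to zero; the common
  value is returned directly.
* Liftover drops positions falling in chain gaps — it never approximates —
  and minus-strand chains map through strand-local coordinates
  ($q_{size} - 1 - q$).
* Bootstrap and simulation code derives all substreams from one user seed,
  so results are independent of method order and worker count.

## Problem sizes used in the test suite

Property tests run at deliberately modest sizes — panels of 120–500
samples, 20–100 SNPs, 100–200 simulation replicates, 300–600 MR-PRESSO
iterations — chosen so the full suite completes in a few minutes while
keeping every assertion's Monte-Carlo margin comfortable. The same
generators scale to larger studies by changing `sim_config()`.

## Known limitations

* No multivariable MR, MR-RAPS, Steiger filtering, or sample-overlap
  correction; no shrinkage PRS (LDpred-style) methods.
* PLINK 2 `.pgen`, dosage (non-hard-call) genotypes and phased haplotype r
  are out of scope; LD is composite-genotype correlation.
* rsid↔position resolution is against a user-supplied variant map, not a
  full dbSNP build; strand inference from a reference FASTA is not
  attempted.
* The simulator's LD model is a convenience, not a portrait of any real
  population (see above).
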