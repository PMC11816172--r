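---
title: "Methods: weighted GWAS of repeated semen traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted GWAS of repeated semen traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `wgwas`, the choices
made where the design was genuinely open, the numerical details of the
solvers, and what the synthetic-data generator does and does not emulate.

## The repeatability animal model

Each record of a repeatedly measured trait is modelled as

$$y = \mu + Xf + Za + Wp + \beta_{age}\,\mathrm{Age} + \beta_{int}\,\mathrm{Intv} + e$$

with fixed year–season and parity effects $f$, additive genetic effects
$a \sim N(0, A\sigma^2_a)$ over the pedigree numerator relationship matrix
$A$, one permanent-environment deviate per animal
$p \sim N(0, I\sigma^2_p)$ shared by all of the animal's records, and
residual $e \sim N(0, I\sigma^2_e)$. Heritability is
$h^2 = \sigma^2_a/\sigma^2_{phen}$ and repeatability
$re = (\sigma^2_a+\sigma^2_p)/\sigma^2_{phen}$, so $0 \le h^2 \le re \le 1$
by construction. The model assumes records are conditionally independent
given the animal effects — no dam/litter effects, no
genotype-by-environment interaction, and a strictly additive genetic
architecture.

`build_A()` uses the tabular recursion, which yields inbreeding on the
diagonal automatically ($A_{ii} = 1 + \tfrac12 A_{sd}$). It is verified in
the tests against an exact enumeration of inheritance vectors, an oracle
that shares no code with the recursion.

## AI-REML

`reml_repeatability()` maximizes the restricted likelihood by
average-information updates. Because the permanent-environment design
equals the additive design at the record level ($W = Z$), the record
covariance collapses to $V = ZKZ' + I\sigma^2_e$ with
$K = A_{rr}\sigma^2_a + I\sigma^2_p$ over the recorded animals only, and
the Woodbury identity turns every trace and quadratic form into
animal-dimension algebra. One iteration costs two Cholesky factorizations
of $q \times q$ matrices ($q$ = recorded animals), so 800 animals with
6,400 records fit in well under a second per iteration.

Numerical choices:

* components are bounded below at $10^{-8}\,\mathrm{var}(y)$, which keeps
  $K$ positive definite in the boundary cases ($\sigma^2_a \to 0$ or
  $\sigma^2_p \to 0$);
* an AI step that leaves the parameter space is halved up to 10 times; if
  it still fails, or decreases the likelihood, the EM-REML update (which
  is a scaled gradient step and far more conservative) is used instead;
* convergence is declared at $|\Delta \log L| < 10^{-8}$; non-convergence
  after 100 iterations raises an error carrying the full iteration
  trajectory;
* standard errors come from the inverse AI matrix at convergence; SEs of
  $h^2$ and $re$ by the delta method;
* constant covariates (e.g. an all-equal age column) are dropped from the
  fixed design; genuinely confounded factor columns raise an error naming
  them, after one reference level per factor has been absorbed;
* an animal's first record has no collection interval; the covariate is
  imputed at the mean, which leaves the REML fit invariant to adding
  constants to the response.

The tests pin the implementation to a dense-matrix restricted-likelihood
oracle on a tiny dataset (grid-search dominance and likelihood-value
agreement) and to a 20-replicate parameter-recovery study at the
moderate-heritability regime ($h^2 = 0.30$, $re = 0.40$, 800 animals × 8
records), the regime the simulator uses by default.

## BLUP, reliabilities, deregression, weights

`solve_mme_blup()` solves Henderson's equations at the REML estimates with
ratios $\lambda_a = \sigma^2_e/\sigma^2_a$,
$\lambda_p = \sigma^2_e/\sigma^2_p$. Additive effects are carried for every
pedigree animal, so unrecorded relatives receive EBVs through $A$;
permanent-environment effects only for recorded animals. Reliability is
$REL_i = 1 - PEV_i/\sigma^2_a$ with $PEV$ from the inverse coefficient
matrix; no inbreeding adjustment is applied to the denominator (the
$1+F_i$ variant is not used — the convention must simply be fixed, and the
unadjusted form is the more common one).

`deregress()` implements VanRaden deregression through daughter
equivalents: $k = (1-h^2)/h^2$, $DE = k\,REL/(1-REL)$,
$REL_{PA} = (REL_s + REL_d)/4$, $R_i = (DE_i - DE_{PA})/DE_i$ and
$DEBV_i = PA + (EBV_i - PA)/R_i$. A missing parent contributes EBV 0 and
REL 0 (the population mean with no information), which collapses the
formulas to $R_i = 1$, $DEBV = EBV$ for animals with unknown parents.
Animals with $R_i \le 0$ — EBVs that contain no information beyond the
parent average — are flagged and excluded from the GWAS.

Two conventions here were genuinely open:

* **The DEBV reliability.** It is computed as
  $REL_{DEBV} = (DE_i - DE_{PA})/(DE_i - DE_{PA} + k)$, i.e. the
  reliability corresponding to the animal's own (post-deregression)
  daughter equivalents. The simpler alternative $REL_{DEBV} = REL_i$ is
  available via `rel_debv_method = "rel_i"`.
* **DE scaling.** The deregression step uses $k$-scaled daughter
  equivalents, while the weight computation uses unscaled ones
  ($DE = REL/(1-REL)$). The two scalings are kept exactly as stated in the
  respective formulas rather than reconciled; since $Rel_{Animal}$ is a
  ratio of DE differences, the $k$ factor cancels wherever both terms share
  it, and the numerical effect of the distinction is confined to
  $REL_{DEBV}$.

`compute_weights()` then forms
$Rel_{Animal} = (DE_{DEBV} - DE_{PA})/(DE_{DEBV} - DE_{PA} + 1)$ and

$$Weight = \frac{1-h^2}{c + \frac{1-Rel_{Animal}}{Rel_{Animal}}h^2},$$

monotone in $Rel_{Animal}$ with limits $0$ and $(1-h^2)/c$. The default
$c = 0.1$ — the fraction of genetic variance not captured by markers —
is the value under which DEBVs are treated as highly reliable.

## Weighted association scan

`build_grm()` is VanRaden method 1:
$G = MM'/(2\sum_j p_j(1-p_j))$ with $M$ centered at twice the sample
allele frequency, mean imputation of missing dosages, monomorphic markers
excluded and a $10^{-6}$ ridge. The candidate marker is *not* removed from
$G$ (no leave-one-chromosome-out): $G$ is built once from all markers.
Proximal contamination is accepted in exchange for a single
eigendecomposition.

`fit_null_model()` fits $y = 1\mu + g + e$,
$\mathrm{Var}(y) = G\sigma^2_g + R\sigma^2_e$, $R = \mathrm{diag}(1/w_i)$,
by whitening with $R^{-1/2}$, eigendecomposing $R^{-1/2}GR^{-1/2}$ once and
profiling the restricted likelihood over the single ratio
$\delta = \sigma^2_e/\sigma^2_g$ (golden-section/Brent search on
$\log\delta \in [-12, 12]$). If the whitened GRM spectrum is flat — e.g.
$G = I$ with equal weights — the two components are not separately
identifiable; the fit warns and the total variance is still valid.

`weighted_gwas()` holds the null covariance fixed (the usual two-step
approximation; re-estimating variance components per marker would cost an
eigendecomposition each) and computes, per marker, the generalized least
squares allele-substitution effect and a 1-df Wald test in $O(n)$ after one
$O(n^2 m)$ rotation of the dosage matrix. The weights therefore enter both
the null REML and the per-marker GLS. Monomorphic and all-missing markers
are skipped and counted.

Diagnostics follow the standard conventions: genomic inflation
$\lambda = \mathrm{median}(\chi^2_{obs})/0.4549364$ from raw p-values;
q-values either Benjamini–Hochberg or the Storey estimator ($\pi_0$ on the
$\lambda$-grid $0.05, \dots, 0.95$, cubic smoothing spline evaluated at the
largest grid point, falling back to $\pi_0 = 1$ when there are too few
p-values to smooth); significance at FDR < 0.05. The per-SNP share of
genetic variance is reported as $100 \cdot 2p(1-p)\beta^2/\sigma^2_g$ —
the marker's additive variance under Hardy–Weinberg relative to the
polygenic variance. This convention (rather than, say, a share of
phenotypic variance) is stated here explicitly because reported
alternatives differ and the choice changes the scale of the column.

## Post-GWAS integration

* **Gene windows**: ±1 Mb around each significant SNP, 1-based inclusive
  intersection, clamped at position 1, strand-agnostic; genes sorted by
  distance (0 inside the gene).
* **cis-eQTL**: per gene, simple regression of $\log(x+1)$ expression on
  dosage for markers within ±1 Mb of the gene body (the same window as the
  GWAS annotation, applied symmetrically; the transform can be disabled).
  Zero-variance genes are skipped and counted. Per-tissue q-values use the
  same FDR machinery, and co-localization treats eQTLs at FDR < 0.05 as
  significant — the GWAS convention applied for want of a stated one.
* **LD**: two-locus haplotype frequencies by EM over unphased genotypes
  (double heterozygotes split between phase configurations each iteration;
  linkage-equilibrium initialization; convergence at $10^{-10}$, max 1000
  iterations), then $D$ and $r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$. On data
  without double heterozygotes the EM fixed point equals direct haplotype
  counting, which the tests exploit as an oracle.
* **LSD**: one-way analysis of variance across genotype classes, then
  pairwise t-tests on the pooled within-group mean square with its full
  error degrees of freedom, uncorrected — the least-significant-difference
  procedure. For two groups this is exactly the pooled-variance t-test.
  Stars: \*, \*\*, \*\*\* at 0.05, 0.01, 0.001.
* **Co-localization**: a significant GWAS SNP co-localizes with a window
  gene either directly (the SNP is itself a significant eQTL; $r^2 = 1$)
  or through LD (some significant eQTL marker for that gene has
  $r^2 \ge 0.8$ with it).

## What the simulator emulates — and what it does not

`simulate_population()` produces a closed multi-generation population:
founder haplotypes from a latent Gaussian AR(1) process thresholded at each
marker's allele frequency (marginal MAF exact, inter-marker correlation
decaying with distance at an e-folding scale of 200 kb), then Mendelian
gamete dropping with Haldane recombination at 1 cM/Mb. True breeding values
are marker-based: optional large-effect QTL sized by their variance
fraction plus an infinitesimal tail over all remaining markers, rescaled so
the founder additive variance matches $\sigma^2_a$ exactly.
`simulate_records()` adds year–season and parity effects, age and interval
covariates, the permanent-environment deviate and residual; percent traits
are clipped to [0, 100] (clipping rather than redrawing keeps the moments
close to nominal; the defaults keep the clipping rate below 1%, and the
rate is always reported). `simulate_expression()` makes cis-regulated genes
affine in dosage plus Gaussian noise.

Default conditions (chosen once, as a realistic scaled-down study):
moderate heritabilities and repeatabilities per trait (e.g. sperm motility
at $h^2 = 0.30$, $re = 0.40$; phenotypic SD 10 on a mean of 72), a Poisson
mean of 8 records per animal, 100–200 founders with 2–3 descendant
generations, 5,000 markers on 5 chromosomes of 100 Mb, founder MAF uniform
on (0.05, 0.5).

Not emulated: coalescent-exact LD (the AR(1) founder model is a stand-in
for chip LD, not a population-genetic model), selection, admixture between
breeds, X-chromosome dosage, genotyping error, and non-Gaussian trait
distributions. Passing tests on these data therefore demonstrate the
correctness and calibration of the *estimators*, not robustness to every
feature of real AI-station data.

## Pipeline determinism and problem sizes

All randomness flows from one root seed; each stage derives its own stream
from (seed, stage label), so partial reruns and `--resume` reproduce
byte-identical artifacts. Downstream stages always consume the serialized
artifacts (PED/MAP, CSV, GFF3, TSV) rather than in-memory objects, so a
fresh run and a resumed run are bit-for-bit interchangeable — the
round-trip through the text formats is part of the tested contract.
Minor-allele orientation of dosages is fixed at file-read time and recorded
in the marker map.

The test suite runs its heavier checks at deliberately chosen sizes: REML
recovery at 800 animals × 8 records over 20 replicates, null calibration
and the end-to-end determinism check at 400 animals × 5,000 markers, power
at 400 animals × 1,000 markers over 25 replicates. These sizes give the
Monte-Carlo estimates enough precision for the stated tolerances while
keeping a full run of the suite in the minutes range on one CPU.

## Known limitations

* Single-trait analyses only; no multi-trait REML or ssGBLUP.
* The two-step per-SNP test fixes the null covariance, which is slightly
  anticonservative near very large QTL.
* $\pi_0$ smoothing needs a reasonable spread of p-values; with fewer than
  a handful the Storey estimator degrades gracefully to BH.
* The EM LD estimator assumes Hardy–Weinberg within the sample when
  resolving double heterozygotes.
* Reliability is not adjusted for inbreeding in the PEV denominator.
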