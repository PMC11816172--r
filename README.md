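# wgwas

Weighted genome-wide association for repeatedly measured boar semen traits,
using de-regressed breeding values (DEBVs) as the response.

## The problem

Semen traits of AI-station boars — sperm motility (SPMOT), progressive
motility (SPPMOT), abnormality rate (SPABR) and total sperm count
(SPCOUNT) — are recorded dozens of times per animal, while only a few
hundred animals per breed are genotyped. A GWAS needs a single response
value per animal, and with so few animals the test must squeeze out every
bit of information. The standard recipe, implemented here end to end, is:

1. **Repeatability animal model.** Records are described by
   `y = μ + Xf + Za + Wp + Age + Intv + e`, with fixed year–season and
   parity effects, age and collection-interval covariates, additive genetic
   effects `a ~ N(0, A σ²ₐ)` over the pedigree relationship matrix `A`,
   a permanent-environment effect per animal `p ~ N(0, I σ²ₚ)` and residual
   `e ~ N(0, I σ²ₑ)`. Variance components come from AI-REML; heritability is
   `h² = σ²ₐ/(σ²ₐ+σ²ₚ+σ²ₑ)` and repeatability `re = (σ²ₐ+σ²ₚ)/(σ²ₐ+σ²ₚ+σ²ₑ)`.
2. **BLUP and deregression.** Henderson's mixed-model equations give each
   animal an EBV and a reliability `REL = 1 − PEV/σ²ₐ`. VanRaden
   deregression removes the parent average PA and undoes shrinkage:
   `DEBV = PA + (EBV − PA)/R`, with `R` from daughter equivalents
   `DE = k·REL/(1−REL)`, `k = (1−h²)/h²`.
3. **Weighted single-SNP mixed model.** `y_DEBV = Xb + g + e` with
   `g ~ N(0, G σ²_g)` (VanRaden genomic relationship matrix from all
   markers) and `e ~ N(0, R σ²ₑ)`, where `R` is diagonal with
   `1/Weight`, and `Weight = (1−h²)/(c + h²·(1−Rel)/Rel)` reflects each
   DEBV's information content beyond its parent average (`c` = 0.1, the
   genetic variance not captured by markers). Calibration is checked by
   the genomic inflation factor λ; multiplicity by Storey/BH q-values
   (FDR < 0.05).
4. **Post-GWAS.** Candidate genes within ±1 Mb of significant SNPs,
   cis-eQTL scans of tissue expression, EM-based LD r² between GWAS hits
   and eQTLs, genotype-stratified expression comparisons (least significant
   difference), and GWAS↔eQTL co-localization (direct or LD-mediated at
   r² ≥ 0.8).

Because real nucleus-herd data are private, the package ships a seeded
simulator that generates multi-generation pedigrees, SNP panels with a
realistic MAF spectrum and local LD, repeated records with the exact
additive/permanent-environment/residual structure above, and cis-regulated
expression — so every stage is testable and the whole pipeline reproducible.

## Worked example

```r
library(wgwas)

cfg <- sim_config(seed = 42, n_founders = 100, n_generations = 3,
                  n_markers = 5000, n_chromosomes = 5,
                  qtl_spec = list(list(trait = "spmot", chrom = "2",
                                       pos = 5e7, frac = 0.2)))
pop <- simulate_population(cfg)
rec <- simulate_records(pop$pedigree, pop$truth, cfg)

A  <- build_A(pop$pedigree)
vc <- reml_repeatability(rec, A, "spmot")
vc
#> Repeatability-model variance components (spmot)
#>   sigma_a2 = 31.77 (SE 5.31)
#>   sigma_p2 = 4.069 (SE 2.76)
#>   sigma_e2 = 61.23 (SE 1.67)
#>   h2 = 0.327 (SE 0.044)   repeatability = 0.369 (SE 0.026)
#>   logL = -8223.7675 after 5 iterations (400 animals, 3105 records)

bv <- solve_mme_blup(rec, A, vc, "spmot")
bv <- compute_weights(deregress(bv, pop$pedigree, vc$h2), vc$h2, c = 0.1)

qc   <- genotype_qc(pop$genotypes)        # call rate 0.9, MAF 0.01, HWE 1e-6
grm  <- build_grm(qc$genotypes)
use  <- !bv$excluded
null <- fit_null_model(bv$debv[use], bv$weight[use], grm,
                       animal_ids = bv$animal[use])
gwas <- weighted_gwas(bv$debv[use], qc$genotypes, null)

attr(gwas, "lambda")
#> [1] 0.951
gwas[gwas$q < 0.05, c("marker_id", "chrom", "bp", "maf", "beta", "p", "q", "gvar_pct")]
#>      marker_id chrom       bp       maf     beta            p            q gvar_pct
#>  snp_c2_000503     2 49959038 0.2180451 2.692139 1.984321e-08 9.919622e-05 10.25951
pop$truth$qtl$marker_id
#> [1] "snp_c2_000503"
```

The fitted heritability (0.33) and repeatability (0.37) recover the
simulated 0.30/0.40 regime within sampling error; λ ≈ 0.95 shows the scan is
calibrated; and the one SNP passing FDR < 0.05 is exactly the simulated QTL,
explaining ~10% of the genomic variance (`gvar_pct` =
`100·2p(1−p)β²/σ²_g`).

The full pipeline — simulate (or load PED/MAP + CSV + GFF3/BED + expression
TSV), QC, REML, DEBV, GWAS, gene windows, eQTL, co-localization, with
per-breed × per-trait fan-out, resumability and a final report — runs from a
single config:

```r
run_pipeline("pipeline.yaml")          # or a named list; see ?run_pipeline
```

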