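# allogenomics

Donor/recipient genomic mismatch scoring for organ transplantation, and
longitudinal mixed models of post-transplant kidney function.

HLA matching does not explain why some well-matched kidney grafts fail while
some fully mismatched ones thrive. This package quantifies
histoincompatibility *beyond* the HLA loci: from exome-derived genotypes of
a donor and a recipient it computes the **allogenomics mismatch score
(AMS)** — a burden-style tally of the donor amino-acid alleles, in
transmembrane proteins, that the recipient genome does not encode. Those
residues are candidate non-self epitopes displayed on the surface of donor
cells. The package is for transplant genomics researchers who have
per-sample annotated VCFs and longitudinal graft-function measurements and
want a single pre-transplant score per pair plus the statistical machinery
to relate it to outcome.

## The score

For recipient *r* and donor *d*,

```
Δ(r, d) = Σ_{p ∈ P} δ(G_r,p , G_d,p)
```

where *P* is the panel of missense sites in genes with at least one
transmembrane segment, *G_s,p* is sample *s*'s unordered diploid amino-acid
genotype at protein site *p*, and δ counts the donor amino acids absent
from the recipient genotype — 0, 1 or 2 per site. Two counting modes are
provided (`distinct`, the default, counts different novel residues;
`allele-copy` counts novel allele copies). The score is directional:
it measures donor-to-recipient novelty only.

Association with graft function uses the estimated glomerular filtration
rate (MDRD equation) in a linear mixed model with a per-pair random
intercept,

```
eGFR ~ donor_age + AMS + months + (1 | pair)      (+ hla_abdr)
```

with likelihood-ratio tests of nested models (ML refits) and an
effect-impact report that multiplies each coefficient by the predictor's
effective range.

Because real transplant exomes cannot ship with a package, a
synthetic-cohort generator produces paired diploid genotypes (related and
unrelated pairs, rare-skewed allele frequencies, written as VCF v4.2 +
annotation + clinical tables) with longitudinal eGFR drawn from the mixed
model above, so the entire pipeline is testable end-to-end. See
`vignettes/allogenomics-methods.Rmd` for the full methods account.

## Worked example

Simulate a cohort at the default study scale (53 pairs, 13,000-site panel,
~240 eGFR observations) and fit the models:

```r
library(allogenomics)

cohort <- simulate_cohort(sim_params(seed = 42))
cohort
#> Synthetic transplant cohort: 53 pairs, 13000 panel sites (+ 1300 decoys), 244 eGFR observations
#>   related pairs: 32 | mean AMS (distinct): 1148.6

scores <- truth_scores(cohort)     # per-pair AMS tallied from the genotypes
fit <- fit_longitudinal(cohort$clinical, scores, include_hla = TRUE)
fit
#> Longitudinal eGFR mixed model (REML fit)
#>   244 observations, 53 pairs; logLik -919.088
#>         term  estimate       se  conf_low conf_high
#>  (Intercept) 132.47999 9.677463 113.51251 151.44747
#>    donor_age  -0.84099 0.147732  -1.13054  -0.55144
#>          ams  -0.02238 0.005171  -0.03252  -0.01225
#>       months  -0.20034 0.031491  -0.26206  -0.13862
#>     hla_abdr  -1.56657 0.787800  -3.11063  -0.02251
#>   random intercept SD (pair): 10.38 | residual SD: 8.201
```

Each additional score unit costs about 0.02 mL/min/1.73 m² of eGFR in this
replicate (the generating value is −0.01307; a single 53-pair cohort
estimates it with the uncertainty the `se` column shows). Donor age and
time post-transplant act as expected. The likelihood-ratio test of the
score's effect refits both models by ML:

```r
full    <- fit_longitudinal(cohort$clinical, scores, reml = FALSE)
reduced <- fit_longitudinal(cohort$clinical, scores, include_ams = FALSE, reml = FALSE)
compare_models(full, reduced)
#>       chi2 df      p_value                 full          reduced
#> 1 14.53044  1 0.0001379128 donor_age+ams+months donor_age+months

impact_report(fit)
#>        term    estimate  range     impact
#> 1 donor_age -0.84099043     60 -50.459426
#> 2       ams -0.02238375   1700 -38.052375
#> 3    months -0.20033890    480 -96.162672
#> 4  hla_abdr -1.56657455      6  -9.399447
```

Over its effective range the score's expected impact on eGFR is comparable
to donor age's — the comparison the impact table exists to make.

The same analysis runs from files. `cmd_simulate()` writes VCFs, an
annotation TSV, a transmembrane gene list, a pair manifest and a clinical
CSV; `cmd_score()` reads VCFs back through quality filters, pairing, and
panel selection; `cmd_associate()` fits and reports:

```r
cmd_simulate(sim_params(n_pairs = 8, n_sites = 2000, seed = 42), out_dir = "demo")
cmd_score("demo/manifest.csv", "demo", "demo/tm_genes.tsv",
          annotation_path = "demo/annotation.tsv", out_dir = "demo/out")
#>   pair_id ams n_sites_considered n_sites_contributing     mode
#> 1    P001 202                511                  202 distinct
#> 2    P002 139                447                  139 distinct
#> ...
cmd_associate("demo/out/scores.tsv", "demo/clinical.csv",
              include_hla = TRUE, out_dir = "demo/out")
```

Pipeline scores are tested to equal the generator's own tallies exactly.
A shell entry point wrapping these commands is installed as `exec/ams`
(`ams simulate | score | associate`).

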