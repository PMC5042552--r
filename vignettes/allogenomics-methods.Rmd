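---
title: "Methods: the allogenomics mismatch score and its longitudinal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the allogenomics mismatch score and its longitudinal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allogenomics)
```

## The score

A kidney graft recipient carries two genomes: their own, and the donor's.
Donor protein variants whose amino acids the recipient genome does not encode
are candidate non-self epitopes. The allogenomics mismatch score (AMS)
quantifies this burden for a recipient $r$ and donor $d$ as

$$\Delta(r, d) \;=\; \sum_{p \in P} \delta\!\left(G_{r,p},\, G_{d,p}\right),$$

where $P$ is the set of genomic positions of interest, $G_{s,p}$ is the
unordered diploid amino-acid genotype of sample $s$ at protein site $p$, and
the per-site contribution $\delta$ counts the donor amino acids absent from
the recipient genotype. Each site contributes 0, 1 or 2.

Two readings of $\delta$ are implemented:

* **distinct** (default): the number of *different* donor residues absent
  from the recipient. A donor homozygous for one novel residue contributes 1.
* **allele-copy**: the number of donor allele *copies* with a novel residue;
  the same homozygous donor contributes 2.

The two tallies diverge only for homozygous-novel donor genotypes, and
allele-copy dominates distinct everywhere (a tested invariant). Reports name
the mode used. The score is directional — $\delta(G_r, G_d) \ne
\delta(G_d, G_r)$ in general — because only donor-to-recipient novelty can
elicit a recipient immune response. The reference residue is an ordinary
genotype member: a homozygous-reference donor facing a homozygous-alternate
recipient contributes.

The panel $P$ comprises missense sites in genes with at least one
transmembrane segment, enriching for epitopes displayed at the donor cell
surface. The gene list is an *input* (a Biomart-style export), not a
computation: which annotation source defines "transmembrane" is the user's
choice and is recorded as provenance. Admitted consequence classes are
configurable (`build_panel(consequences =)`); stop-gains and in-frame indels
are excluded by default because the contribution model is a single-residue
substitution count.

## From VCF to paired genotypes

Genotypes arrive as VCF v4.x with either VEP-style CSQ annotation or a
side-car annotation TSV. Choices that shape the paired stream:

* **Quality filters.** A call is retained only if every non-reference allele
  has read support ≥ 3 and the call has ≥ 3 distinct read indices (both
  configurable). Failing calls are demoted to no-calls, never dropped, so
  site accounting is preserved. Homozygous-reference calls always pass (no
  alternate allele to test). Calls lacking the support metadata are retained:
  the filter applies where the caller reported the statistics it thresholds.
  Thresholds are applied per allele.
* **No-call policy.** How to treat a site called in only one sample is a
  genuine design choice; both options are implemented. `require-both`
  (default) scores a site only when both genotypes were observed —
  conservative, and robust to coverage asymmetry between capture kits.
  `assume-hom-ref` completes the uncalled side as homozygous reference, the
  usual exome assumption at covered positions; it is the right choice when
  each sample's VCF lists only its own variant sites.
* **Transcript multiplicity.** A site annotated on several transcripts is
  counted once: canonical transcript if flagged, else the transcript with
  the most severe consequence, ties broken lexicographically by transcript
  id. This is deterministic and prevents double-counting one physical
  mismatch. Multiallelic sites are resolved at the amino-acid level within
  one per-site contribution, never split into pseudo-sites.
* **Phase is ignored.** Genotypes are unordered multisets; $\delta$ is
  phase-free.

## eGFR and the association models

Graft function is the estimated glomerular filtration rate, computed (when
not provided directly) by the four-variable MDRD equation

$$\mathrm{eGFR} = 175 \cdot \mathrm{Scr}^{-1.154} \cdot
\mathrm{age}^{-0.203} \cdot 0.742^{[\mathrm{female}]} \cdot
1.212^{[\mathrm{black}]}$$

in mL/min/1.73 m² (creatinine in mg/dL). A provided eGFR is never
overwritten.

Cross-sectional analysis regresses the outcome at one fixed month on the
score by OLS, reporting slope, adjusted $r^2$ and the two-sided p-value.

The longitudinal model is a linear mixed model with a random intercept per
transplant pair:

$$\mathrm{eGFR} \sim \text{donor age} + \mathrm{AMS} + T + (1\,|\,\text{pair}),$$

optionally extended with the HLA-A/B/DR mismatch count (an integer 0–6).
$T$ is months post-transplant. The random intercept absorbs baseline
graft-function differences between pairs and the correlation of repeated
measurements within a pair. Fitting is by `lme4::lmer`.

* **Intervals.** 95% Wald intervals (estimate ± 1.96·SE) — deterministic and
  standard; profile or bootstrap intervals would be slower and are not
  needed for the effect-impact report.
* **ML vs REML.** Reported single-model estimates default to REML; every
  likelihood-ratio comparison refits both models by maximum likelihood
  (REML likelihoods are not comparable across fixed-effect structures). The
  LRT uses $\chi^2 = 2(\ell_{full} - \ell_{reduced})$ with df equal to the
  difference in fixed-effect count. Comparing a model with itself
  short-circuits to $\chi^2 = 0$, $p = 1$ (df 0 is guarded, not fed to the
  $\chi^2$ distribution). The statistic is invariant to affine rescaling of
  the score (tested).
* **Degenerate designs.** With one observation per pair the random-intercept
  variance is confounded with the residual variance; the fit is returned
  with a warning rather than refused (lme4's observation-count checks are
  relaxed for exactly this case). Singular variance estimates warn too.
* **Effect impact.** A coefficient is converted to an expected total effect
  on eGFR by multiplying it (and its interval endpoints) by the predictor's
  effective range. Ranges are report inputs, defaulting to 480 months,
  60 years of donor age, 1700 score units and 6 HLA mismatches.

## The synthetic cohort generator

No real transplant exomes ship with the package; the generator produces
cohorts with the statistical structure the analysis assumes, so the whole
pipeline can be validated end-to-end.

* **Sites.** 13,000 scoreable sites by default (the order of magnitude of
  contributing exome sites in a validation-scale cohort), assigned to ~1,000
  synthetic transmembrane genes. Minor allele frequencies are drawn from
  Beta(0.2, 2) truncated to (0.0005, 0.5) — a rare-skewed spectrum (median
  MAF < 0.05) reflecting that score-driving polymorphisms are mostly rare.
  A further 10% of sites are decoys (non-transmembrane missense, or
  synonymous) that site selection must reject.
* **Genotypes.** Unrelated pairs: four independent Hardy–Weinberg
  haplotypes per site. Parent-child pairs: the recipient inherits one
  allele identical by descent from the donor at every site (sampling either
  donor haplotype per site, as free recombination would), the other from
  the population. Relatedness lowers the expected score, and the 60%-related
  default produces a cohort score SD of roughly 300 — the realistic spread
  that makes a between-pair coefficient estimable at 53 pairs.
* **Clinical model.** Observations follow
  $\mathrm{eGFR} = 101 - 0.47\,\mathrm{age} - 0.01307\,\mathrm{AMS} -
  0.24\,T - 0.57\,\mathrm{HLA} + b_{pair} + \varepsilon$, with
  $b_{pair} \sim N(0, 12^2)$ and $\varepsilon \sim N(0, 8^2)$
  (mL/min/1.73 m²). The fixed-effect defaults are the effect sizes the
  package's models are meant to recover; the intercept and variance
  components are generator calibration values placing mean eGFR near 55 at
  mean covariates — not estimates of anything. Donor ages are
  N(45, 12) truncated to 18–75, HLA mismatches uniform on 0–6. The default
  schedule (months 12, 24, 36, 48, 60, each observed with probability 0.9)
  yields ~238 observations for 53 pairs. A serum creatinine consistent with
  each eGFR (inverse MDRD at the recipient's age at observation) is written
  so the eGFR-computation path is exercised.
* **Determinism.** All randomness flows from one seed; truncated
  distributions use inverse-CDF draws so the RNG call count is fixed.
  Regenerating with the same seed is bit-for-bit identical, through to the
  written VCFs.

What the generator does *not* emulate: linkage disequilibrium, population
structure and kit-specific coverage asymmetry; sequencing or genotyping
error; HLA haplotype structure (the HLA count is an independent covariate,
whereas real cohorts show moderate AMS–HLA correlation); sibling or other
IBD mixtures beyond parent-child; informative dropout. Passing tests
therefore demonstrate correctness of the scoring arithmetic and the
estimation machinery under the assumed model — not robustness to the
artefacts of real exome data.

## Validation problem sizes

The test suite enumerates all 36 unordered genotype pairs over a 3-letter
alphabet in both modes (bounds 0 and 2 exactly); cross-checks pair totals
against an independent brute-force recount on 1,000 fuzzed sites over 20
seeds; verifies identity, monotonicity and mode dominance on fuzzed
genomes; and confirms that pipeline scores computed from written VCFs equal
the generator's own tallies in both modes and both VCF layouts. Statistical
validation uses 200 simulated pairs for the relatedness direction (Wilcoxon
one-sided), 100 replicate cohorts at the 53-pair scale for coefficient
recovery (score coefficient within 25%, donor-age within 10%, Wald
coverage ≥ 90%) and 200 null-score replicates for LRT calibration
(rejection between 2% and 10% at $\alpha = 0.05$). A noiseless cohort
($\sigma_{pair} = \sigma_{resid} = 0$) is refit to the generating
coefficients within 1e-6.

## Known limitations

* The score does not restrict contributions to peptides that fit the HLA
  groove, does not consider splice-form differences between donor and
  recipient proteomes, and uses a gene-level (not residue-level)
  transmembrane filter.
* Scoring starts from called genotypes; alignment and genotype calling are
  out of scope, as are structural variants.
* With score variation only between pairs, the score coefficient in the
  mixed model is estimated with much less precision than the time
  coefficient; small cohorts give wide intervals, which is why
  validation works at the combined-cohort scale.
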