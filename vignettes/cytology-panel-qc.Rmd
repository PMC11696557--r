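---
title: "Contamination estimation and QC triage for cytology panel sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contamination estimation and QC triage for cytology panel sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoqc)
```

## The problem

Clinical tumor profiling of cytology material — formalin-fixed cell blocks
(CB) and supernatant cell-free DNA (ScfDNA) from residual fixative fluid —
runs on some of the smallest DNA inputs a molecular laboratory accepts.
Beyond the usual sufficiency questions (yield, tumor content, coverage),
cell blocks pass through shared histology equipment (microtome blades, water
baths, pooled processors), which creates a real risk of low-level
cross-contamination by another patient's tissue; and any paired tumor–normal
workflow must guard against outright sample swaps. This package implements
the quantitative side of that quality review: a contamination estimator with
a clinical cutoff, a genotype-concordance identity check, a deterministic
multi-gate triage procedure, panel TMB and actionability summaries, matched
cytology–surgical concordance accounting, and a simulator that generates all
of these inputs with known ground truth.

## Contamination from patient-homozygous SNP sites

Large panels deliberately tile probes over common intergenic/intronic SNPs.
Genotypes called from the matched normal define, at every site where the
patient is homozygous, an *unexpected* allele: hom-ref patients should show
no alt reads, hom-alt patients no ref reads, up to sequencing error. For a
tumor library that is a mixture of patient reads (fraction $1-\alpha$) and
reads from one unrelated contaminant (fraction $\alpha$), with the
contaminant in Hardy–Weinberg equilibrium, the unexpected-read fraction
$d_i$ at site $i$ satisfies

$$\mathrm{E}[d_i] = \alpha\, q_i,$$

where $q_i$ is the population frequency of the unexpected allele ($p_i$ at
hom-ref sites, $1-p_i$ at hom-alt sites — the two site classes contribute
symmetrically): the contaminant's unexpected-allele dosage is
$g_i \sim \mathrm{Binomial}(2, q_i)$, its reads carry the unexpected allele
with probability $g_i/2$, and $\mathrm{E}[g_i/2] = q_i$.

Two estimators invert the signal:

* **Method of moments.** $\hat\alpha = \sum_i w_i d_i / \sum_i w_i q_i$ with
  $w_i = \text{depth}_i$ (so the numerator is simply the pooled unexpected
  read count), clipped to $[0,1]$. Depth weighting is variance-motivated —
  binomial noise in $d_i$ scales as $1/\text{depth}_i$ — and can be switched
  off (`weighted = FALSE`). The closed form makes it auditable by hand and
  it serves as the cross-check for the likelihood fit.
* **Marginal maximum likelihood** (default, the reported estimate). The
  unexpected count at site $i$ is Binomial$(\text{depth}_i,\ \alpha g/2 +
  \varepsilon)$ conditional on the contaminant genotype $g \in \{0,1,2\}$,
  marginalized over HWE weights $(1-q_i)^2,\ 2q_i(1-q_i),\ q_i^2$, with
  $\varepsilon$ the configured symmetric miscall rate (default 0.001).
  Modeling $\varepsilon$ explicitly removes the small positive bias
  ($\approx \varepsilon/\bar q$) that the moment estimator inherits from the
  error floor. The likelihood is maximized by bounded golden-section search
  on $\alpha \in [0, 0.5]$ (`optimize`, tolerance $10^{-6}$); since the
  optimizer never probes endpoints, the fit explicitly compares the interior
  optimum against $\alpha = 0$ so pure samples return exactly zero.
  Likelihood terms are clamped at $10^{-300}$ before logging to keep
  $\alpha$-regions that contradict an observed count finite.

A profile-likelihood interval is available via `confint()`, and
`residuals()`, `fitted()`, `plot()` and `simulate()` support the usual
diagnostics on the per-site table.

**Informative-site filters.** Sites enter the fit only if the tumor depth is
at least `min_depth` (20) and the third-allele fraction
`other_count/depth` is at most 0.02 — somatic events, mapping artifacts or
index hopping can otherwise mimic contamination. Sites overlapping known
somatic variants can be excluded explicitly (`exclude_sites`). When no
informative site survives, the estimate is *not estimable* — a distinct
error condition, never silently $\hat\alpha = 0$.

**Interpretation.** $\hat\alpha \ge 0.02$ is clinically significant: 2% is
the variant-calling threshold, so contamination at that level can inject
false calls. The cutoff is inclusive, and is treated as a read fraction (the
source convention does not distinguish read from mass fraction; reads are
what the counts measure). Estimates from samples below 50× coverage are
labeled `low_coverage_artifact_possible` rather than contaminated — sparse
counts inflate the rate — and such samples are excluded from headline
contamination rates; a softer caveat flags fits whose informative-site
median depth is below 200×.

## Genotype calling and identity checking

The normal-sample caller is a hard-threshold rule on the alt-read fraction:
`no_call` below 20× depth; `hom_ref` at ≤ 0.05; `hom_alt` at ≥ 0.95; `het`
within [0.30, 0.70]; ambiguous fractions are `no_call`. These bands are not
taken from the source record; they were chosen so that homozygote
misclassification — which would feed false unexpected reads into the
estimator — is vanishingly rare at panel depths of several hundred fold,
and all are configurable.

Identity is the fraction of co-called SNP sites with identical diploid
calls. Unrelated individuals match at rate $\sum_g P(g)^2$ per site
(0.375 at $p = 0.5$; roughly 0.4–0.6 averaged over a common-SNP spectrum),
while same-patient pairs sit near 1 (tumors deviate only at aneuploid or
LOH sites). The default swap threshold of 0.80 bisects that gap; whether a
production pipeline restricts concordance to a curated subset of sites is
not recoverable from the source, so all co-called panel sites are used.

## Triage

Gates run in the physical pipeline order — tumor content, DNA input,
coverage, base quality, contamination — and the first failure fixes the
single outcome category (the source reports categories but not a precedence
for multi-failure samples; processing order is the natural tie-break).
Boundary semantics are strict on the failure side: purity `< 10%` fails
(10% passes), concentration strictly below the era threshold fails,
coverage strictly below 50× fails, while the contamination cutoff is
inclusive (`>= 2%`).

* **Tumor content:** fail below 10% tumor unless manual enrichment
  (macro-dissection) is feasible.
* **DNA input:** era policy — 0.9 ng/µL until September 2021, 0.54 ng/µL
  after; at the 55 µL maximum assay volume these reproduce the 50 ng and
  30 ng minimum inputs under round-half-up (0.9·55 = 49.5 → 50;
  0.54·55 = 29.7 → 30). ScfDNA samples are deliberately sequenced below
  these thresholds and bypass the gate.
* **Coverage:** below 50× fails; [50, 200)× is flagged low (sensitivity
  concerns at the 2% calling threshold) without failing.
* **Base quality:** a boolean input. The corresponding failure mode
  ("adequate coverage but high background noise and low base quality") is
  qualitative in the source and not reducible to a formula from available
  fields, so the gate consumes an upstream judgement.
* **Contamination with rescue:** a significantly contaminated sample whose
  expected clonal driver VAF (purity/2, as a fraction) exceeds
  `margin × α̂` remains *partially evaluable*: variants with VAF ≤ α̂ are
  filtered as potentially contaminant-derived, higher-VAF calls are kept.
  The source quantifies "very high tumor content" no further; the default
  margin of 2 requires real signal to sit at least a factor of two above
  the contamination band, and is configurable.

`expected_target_copies()` covers the input-sufficiency arithmetic: DNA
input mass × ddPCR-derived amplifiable copies per nanogram, so the lowest
accepted input of 30 ng at the lower 95% bound of 220.5 copies/ng still
queries 6615 target molecules.

## TMB, actionability, matched-pair concordance

TMB divides the nonsynonymous mutation count (drivers included, synonymous
always excluded) by the panel's targeted megabases; samples strictly above
10 mutations/Mb are TMB-high. The targeted megabases per panel version
(341/410/468/505 genes) are *not* printed in the source record; the built-in
values are documented estimates and any clinical use should pass
`target_mb` explicitly. Actionability levels are consumed as annotations
(no knowledge-base lookup, keeping the package self-contained and
version-stable) and ranked L1 > L2 > L3A > L3B > L4 > oncogenic-no-level >
VUS, with targetable defined as L1–L3B; resistance (R1) is an independent
axis reported as a flag, never ranked against therapeutic levels.

Matched cytology–surgical comparison keys variants on genomic identity
(chrom, pos, ref, alt) — gene-level matching would over-merge distinct
events. Per pair it reports shared/exclusive counts and the surgical
recovery fraction; across pairs, shared/exclusive proportions are pooled
per actionability level, and the VAF shift between preparations is tested
on the pooled shared pairs with a two-sided Mann–Whitney test (one pooled
p-value, matching how the comparison is reported for the whole cohort;
time between collections is carried as metadata only, with no adjustment
attempted). Group comparisons elsewhere use Mann–Whitney for continuous
metrics and Pearson's chi-squared for r×c tables, falling back to Fisher's
exact test for 2×2 tables with any expected count below 5.

## The synthetic cohort

The raw clinical data are protected, so the simulator generates every input
with known truth:

* **Panel:** SNP frequencies Uniform(0.05, 0.5) by default — panel SNPs are
  chosen to be common; the source states neither the exact count nor the
  frequency source, so these are configurable defaults, not inferences.
* **Genotypes:** alt dosage Binomial(2, p) per site (HWE); the contaminant
  is an independent draw from the same population (related contaminants are
  out of scope).
* **Mixture:** per-site depth Poisson(mean depth), optionally negative
  binomial (`overdispersion`) since real panel coverage is overdispersed;
  expected alt fraction $(1-\alpha)d_p/2 + \alpha d_c/2$, perturbed
  symmetrically by the error rate (default 0.001); alt count binomial.
  Reads always conserve: ref + alt + other = depth.
* **Somatic variants:** VAF = purity·CCF/2 for diploid heterozygous events,
  CCF 1 for clonal (70% by default) else Uniform(0.1, 1); placed away from
  the SNP panel, so somatic events never interact with contamination sites
  — a simplification.
* **Cohort manifests:** each sample draws an outcome category (defaults:
  80.6% pass; 11.3/4.6/1.8/1.6/0.1% for the five failure modes, the
  published outcome frequencies) and then metrics that fail exactly the
  intended gate while passing all others. Samples destined for the
  DNA-input failure are forced to CB preparation because ScfDNA bypasses
  that gate. Contamination-failure samples draw purity in [10, 30]% and
  α above purity/400 so the rescue provably cannot apply.

What passing tests on this simulator do **not** show: robustness to related
contaminants (allele sharing halves the signal), FFPE deamination damage,
GC-driven coverage waves, multi-source contamination, somatic LOH
overlapping SNP sites, or read-level artifacts — none of which the
generator emulates (read-level/BAM simulation and indel/CNV/rearrangement
simulation are explicit non-goals). Parameter recovery here validates the
estimator's math, not its behavior on every pathological library.

## Problem sizes and numerical conventions

The estimator-recovery checks use 200 replicates per contamination level
{0.02, 0.05, 0.10} with 1000 patient-homozygous sites at 500× mean depth and
error 0.001 (mean $\hat\alpha$ within ±0.005; false-flag rate at α = 0
below 1%); identity checks use 10,000-site panels at p = 0.5 and 50 seeded
swap trials; the triage round trip uses a 20,000-sample cohort. These sizes
put simulation error well below the tolerances being asserted while keeping
the default test run fast. Presentation rounding is round-half-up at the
printed precision (so 80.55% prints as 81%), with raw fractions always
retained; two published rates whose printed values are inconsistent with
their own printed counts are carried in the fixture as flagged entries that
are recomputed and reported but not asserted, and one (the paired-set shared
fraction, printed 49.8% vs recomputed 49.9%) is checked with a ±0.1
tolerance because the source's rounding convention there is unclear.

## Limitations

The single-contaminant, unrelated, autosomal-diploid model is the standard
idealization: a related contaminant biases $\hat\alpha$ downward, and copy
number changes at SNP sites violate the dosage/2 assumption (mitigated by
the third-allele and explicit-exclusion filters). The 2% cutoff, band
thresholds and gate boundaries are policy values — faithful to the source
where stated, documented package choices where not — and every one of them
is a configurable argument rather than a constant buried in code.
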