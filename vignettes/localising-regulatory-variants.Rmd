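---
title: "Localising functional regulatory variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising functional regulatory variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulocal)
```

# The problem

A GWAS association at a non-coding locus rarely identifies its functional
variant: extensive linkage disequilibrium (LD) means tens to hundreds of
variants carry statistically equivalent association evidence. `regulocal`
implements the desk portion of a sequential localisation strategy —
candidate selection, cis-eQTL scanning, trait–expression colocalisation,
regulatory-annotation overlap, and allele-specific chromatin-accessibility
statistics — that funnels a locus-wide variant pool down to the few
variants worth assaying in the laboratory, and designs the allele-specific
EMSA probes for those assays.

# Models and procedures

## Candidate selection

LD with the lead SNP is measured as the squared Pearson correlation of
genotype dosages over pairwise-complete samples (composite LD). This is
the standard surrogate for haplotype r² when phase is unavailable; an
EM haplotype-frequency estimator is deliberately out of scope. Selection
is a union rule: a variant is retained if r² ≥ 0.8 with the lead
(inclusive, because the stated rule is "≥"), if its trait association
reaches p < 5 × 10⁻⁸ (strict, "<") within 500 kb of the anchor gene, or if
it shows significant eQTL evidence while in strong LD. Sites that are
monomorphic among informative samples have *undefined* LD and are reported
with a flag rather than silently assigned r² = 0. Raising any threshold
can only shrink the candidate set, and removing one evidence table removes
exactly the variants whose sole provenance was that table — both properties
are exercised in the test suite.

Two points the source protocol leaves open are resolved as configuration:
the eQTL inclusion threshold (not stated; we default it to the GWAS
threshold 5 × 10⁻⁸, `p_eqtl`) and whether the 500 kb window also applies to
eQTL hits (`window_eqtl`, default off). The anchor position is supplied by
the user (`gene_anchor_pos`); distance is interpreted to the supplied
coordinate, which callers may set to the nearest gene-body edge.

## Marginal association

Both the lipid-trait and expression scans use ordinary least squares of
the phenotype on an intercept plus allele dosage (`stats::lm.fit`), with
the standard error from the residual variance on n − 2 degrees of freedom
and a two-sided Student-t p-value. No covariates are fitted — the emulated
protocol reports none — but the scan operates on any phenotype vector the
caller provides, so adjusted residuals can be passed in. Phenotypes are
used as given; the simulator produces standardised values. A perfect fit
(zero residual variance) is reported with `se = 0`, `p = 0` and a
degeneracy flag rather than an error, and monomorphic variants are listed
in a skip report.

## Colocalisation

Evidence for association at variant j is Wakefield's asymptotic Bayes
factor under a normal effect prior with variance w: with V = se²,
z = β̂/se and shrinkage r = w/(V + w),

  log ABF_j = ½ [ log(1 − r) + r z² ].

When only (p, MAF, n) are available, z is recovered from the two-sided
p-value and V ≈ 1/(2 n f (1 − f)) for a standardised trait; when both
parameterisations are present, (β̂, se) wins. Assuming at most one causal
variant per trait, the five hypothesis weights are accumulated entirely in
log space (log-sum-exp; no raw Bayes factor is ever materialised):

- S₁ = logΣ exp(l₁ⱼ), S₂ analogously, S₁₂ = logΣ exp(l₁ⱼ + l₂ⱼ)
- L₀ = 0, L₁ = log p₁ + S₁, L₂ = log p₂ + S₂,
  L₃ = log p₁ + log p₂ + logdiff(S₁ + S₂, S₁₂), L₄ = log p₁₂ + S₁₂
- pp = softmax(L₀…L₄).

The L₃ term subtracts the shared-variant diagonal from the product of the
single-trait sums; with exactly one shared variant it is −∞ and pp(H3) is
exactly zero. If numerical noise ever makes S₁₂ exceed S₁ + S₂ the
difference is clamped to −∞ with a warning. The implementation is verified
to 10⁻¹⁰ against an exhaustive enumeration oracle that sums raw Bayes
factors over all causal-configuration pairs for loci of up to six
variants, and the posterior vector sums to one within 10⁻¹².

Priors default to p₁ = p₂ = 10⁻⁴, p₁₂ = 10⁻⁵ and w = 0.15² = 0.0225
(phenotype-SD² units), the conventional defaults of the summary-statistic
colocalisation methodology for quantitative traits; the emulated study
does not print the values it used, so ours are surfaced in every result
object and are configurable. A posterior strictly greater than 0.75 is
labelled strong evidence; at exactly 0.75 the call is inconclusive.

## Regulatory-annotation overlap

Variant positions are 1-based (VCF convention), intervals 0-based
half-open (BED convention); the conversion happens in exactly one place
(`annotate_variant()`). A variant is *within* a feature when
start ≤ pos − 1 < end, *near* when the base-pair distance to the nearest
interval edge is ≤ 500 bp, else *none*. The source material writes both
"within 500 bp" and "< 500 bp"; we resolve the boundary as inclusive and
expose `near_bp`. Overlap and nearest-feature queries go through the
IRanges interval index; a naive O(V·I) distance scan serves as the test
oracle. Per-variant summary status is within > near > none across tracks,
and multi-cell-type tracks are merged per label.

## Allele-specific FAIRE statistics

Heterozygotes are called from the control (non-enriched) arm: control BAF
within 0.5 ± 0.15 (inclusive). The 0.15 half-width is not stated by the
emulated protocol; it cleanly separates the simulated heterozygote cloud
(sd ≈ 0.02–0.05) from the homozygote clusters at 0 and 1 and is
configurable. The test is a paired two-sided t-test on the per-sample
differences FAIRE − control over heterozygotes (n − 1 df). The enrichment
percentage is defined as the *relative* change of the enriched allele's
mean fraction — 0.500 → 0.602 reads as 20.4% — because the emulated
report's arithmetic is consistent with that reading; whether it meant a
relative change or absolute percentage points is not derivable from its
text, so an absolute mode is provided (`mode = "absolute"`). Zero variance
in the differences is handled explicitly: t = 0, p = 1 when the mean
difference is also zero, and a degenerate flag with p reported as 0
otherwise. No multiple-testing correction is applied across variants (the
emulated protocol applies none); raw p-values are reported. The reporter
assay uses per-well reporter/control ratios compared between allele groups
with a Welch two-sample t-test.

## Probe design

Probes are the 2·flank + 1 bases centred on the variant with each allele
substituted at the centre, plus exact reverse complements (via
Biostrings). Only SNVs are supported — the assays this feeds accept only
point substitutions — and a reference/allele mismatch at the centre warns
and proceeds with the declared alleles, since probes are genomic context
plus allele substitution by construction.

# The synthetic-locus generator

Real loci of this kind come with genotypes, two phenotypes, annotation
tracks and paired BAF measurements that cannot be redistributed, so the
package generates them. The generator is deliberately mechanistic rather
than population-genetic:

- **Haplotypes** follow a founder-copy model: each LD block carries
  `n_founders` founder haplotypes (sites i.i.d. Bernoulli(0.5)); a sample
  haplotype copies one founder per block, switching founders between
  adjacent blocks with probability `recomb_prob`, then flips each site
  with probability `mutation_prob`. This gives direct, testable LD
  control: two founders with no mutation give r² = 1 for every segregating
  pair in a block, and within-block LD decays monotonically in the
  mutation rate. Defaults (60 variants in blocks of 15, 4 founders,
  recomb 0.1, mutation 0.01, positions spanning ~250 kb) emulate a
  haplotype-block locus with one large strong-LD cluster around the causal
  variant.
- **Phenotypes** are linear: β per allele copy of the causal dosage plus
  Gaussian noise, in SD units (β = 0.4, noise SD 1, n = 2000 by default —
  at a MAF of ~0.3 this puts ~6% of phenotype variance on the causal
  variant, comfortably past genome-wide significance at n = 2000, as a
  shared-causal lipid/expression locus demands). Scenarios H0–H4 encode
  which colocalisation hypothesis is true.
- **Annotations** place an interval covering each "within" variant and an
  interval 1–500 bp from each "near" variant, then verify the realised
  labels of *all* variants against the intended ones and retry placement
  if variants interfere.
- **BAF records** centre heterozygotes at 0.5 (control) and 0.5 + shift
  (FAIRE), homozygotes at 0/1, add Gaussian read-out noise and clip to
  [0, 1] (clipping, not resampling — the bias is negligible at the stated
  noise levels of 0.02–0.05).
- All randomness flows from one integer seed per bundle; identical seeds
  give bit-identical bundles. Ground truth is written as a JSON sidecar
  that the pipeline itself never reads.

In the calibration experiments (`simulate_coloc_replicate()`), causal
variants are required to be polymorphic (MAF ≥ 0.1): with four founders a
block's founder pool is occasionally monomorphic at a site, and a
"causal" variant nobody segregates at is not a meaningful realisation of a
shared-causal scenario. Under H4 the eligible variant nearest the locus
centre is used; under H3 the pair from the first and last blocks with the
smallest realised dosage r², so the two signals are genuinely separated.

What the generator does **not** emulate: realistic recombination maps or
coalescent genealogies, population structure, genotyping error and
missingness patterns, imputation uncertainty, expression-array
normalisation artefacts, or LD between the locus and the rest of the
genome. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under a controlled LD
architecture, not performance on any real cohort; the real-data candidate
counts and posteriors of the emulated study depend on datasets this
package does not ship and are not reproduced here.

# Numerical choices and problem sizes

- All hypothesis-weight arithmetic is in log space; posteriors are
  renormalised once at the end.
- Thresholds: r² inclusive (≥), p-values strict (<), near-distance
  inclusive (≤), posterior threshold strict (>).
- Degenerate inputs (perfect fits, zero-variance differences, monomorphic
  sites, single shared variants) all have defined, documented behaviour
  and dedicated tests rather than incidental NaNs.
- The packaged calibration experiments use 100 replicate loci of 60
  variants at n = 2000 for the colocalisation operating characteristics,
  1000 replicate variants at 10 heterozygotes for FAIRE type-I error and
  power, and 100 random instances of ≤ 6 variants for the enumeration
  oracle — sizes chosen so the full suite runs in a couple of minutes on a
  single core while keeping Monte-Carlo error well inside the asserted
  margins.

# Interfaces

The package's functions are the interface: `run_pipeline()` +
`validate_config()` orchestrate a YAML-configurable run, and each stage is
equally usable on its own from R scripts. File formats are deliberately
minimal and text-based (GT-only VCFv4.2, 4-column BED, TSV summary
statistics with the schema `variant chrom pos ref alt beta se p n maf
trait`, BAF TSV `sample variant treatment baf`, FASTA, JSON truth
sidecars), so fixtures are reproducible and diffable.

# Known limitations

- Single-causal-variant assumption per trait in the colocalisation model;
  allelic series at one locus will spread posterior mass between H3 and
  H4.
- Dosage r² understates haplotype r² under strong departure from
  Hardy–Weinberg; acceptable for the simulator's random-mating output.
- The eQTL scan fits no covariates or latent factors.
- The FAIRE module takes array BAF values as given; probe-intensity
  normalisation and standard-curve extrapolation for assays absent from
  the array are upstream of this package.
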