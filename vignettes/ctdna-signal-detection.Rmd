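---
title: "Tumor-informed ctDNA signal detection: model, filters and design choices"
author: "ctdnaSieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaSieve)
```

## The problem

A tumor-informed liquid-biopsy analysis asks one question per patient: do
the somatic SNVs found in this patient's tumor tissue leave a detectable
trace in their plasma cell-free DNA? At whole-genome scale the per-site
evidence is minuscule — at a realistic ctDNA fraction of 0.5% and ~50x
plasma coverage, a typical variant contributes a fraction of an alternate
read — so the signal must be integrated across thousands of tumor variants,
and the integrated statistic is only as good as the noise that survives
filtering. `ctdnaSieve` implements that integration: forced-call
observations of tumor variants across a patient's sample set (tumor,
matched normal, patient plasma, tumor-free control plasmas, and a plasma
pool from other cancer patients) are pushed through a ladder of noise
filters, and the surviving variants are summarised as a signal-to-noise
ratio and a z-score against a control-plasma noise model.

The package operates strictly downstream of variant calling: its input is a
table (multi-sample VCF or TSV) of read depth (DP) and alternate allelic
depth (AD) per variant and sample. Alignment, duplicate marking, somatic
calling and forced genotyping are upstream concerns.

## Data model

A `PatientTable` extends `RangedSummarizedExperiment`: rows are the
patient's tumor SNVs (a width-1 `GRanges` with `ref`, `alt` and an optional
population allele frequency `popAF`), columns are samples with a `role`
(tumor / normal / plasma / control / pool), and the two assays are the
integer matrices `DP` and `AD`. VAF is never stored; it is recomputed as
AD/DP on demand with the convention VAF = 0 when DP = 0 (a site with no
coverage contributes no alternate evidence; the convention biases averages
toward zero, never upward, and parsed zero-depth cells are reported in a
warning). Any VAF column present in an input file is ignored for the same
single-source-of-truth reason.

## The filter ladder

Three methods share five basic threshold filters evaluated on the tumor and
matched normal, all inclusive on the keep side (keep iff tumor AD >= 8,
tumor DP >= 12, tumor VAF >= 0.2, normal AD <= 0, normal DP >= 10 at the
shipped defaults), plus a population allele-frequency filter that removes
variants with known population frequency above 1e-5 — variants absent from
the population database are kept, since somatic variants are not expected
in population catalogues. On top of these:

* **Method 1** removes sites in an external panel of normals (PON), e.g.
  the 1000-genomes PON.
* **Method 2** removes sites in the *merged* PON: the external PON united
  with a self-generated PON built from the cohort's own normal samples
  (membership rule: AD >= 1 in at least 2 distinct normals; both knobs are
  exposed because PON construction conventions vary).
* **Method 3** adds the **plasma-pool filter**: a variant is removed when
  any plasma sample from *other* patients shows AD strictly greater
  than 1. A patient-specific somatic variant should not recur in unrelated
  plasmas, so reads there mark a position-specific sequencing artefact; a
  single pool read is tolerated as ordinary error. Removal excludes the
  variant from *all* downstream computation — the patient-plasma signal and
  the control-plasma noise model alike.

Every filter is evaluated per variant against the *original* table, and the
survivors are the variants whose failed-label set is empty. This makes
composition order irrelevant by construction (the pool filter gives the
same survivors whether applied before or after the PON — asserted in the
tests), and it yields a complete per-variant verdict table that the
UpSet-style accounting consumes: `exclusiveIntersectionCounts()` groups
removed variants by their exact failed-label combination, so the counts
partition the removals and per-label marginals are recoverable by summing
the combinations containing the label.

## Signal statistics

With kept variants in hand, for metric VAF or AD:

* `aveVarDet` — the arithmetic mean of the plasma metric over kept
  variants. An option `detectedOnly` restricts the average to variants with
  plasma AD >= 1; the default averages all kept variants so that the
  numerator and the noise model run over the same variant set.
* the **noise model** — each control plasma contributes its mean metric
  over the same kept variants; `muNoise` and `sigmaNoise` are the mean and
  sample (n−1) standard deviation of those per-control values.
* **S2N** = aveVarDet / muNoise, and **z** = (aveVarDet − muNoise) /
  sigmaNoise.
* the **binary** variant ignores magnitudes entirely: the statistic is the
  count of kept variants detected in plasma (AD >= 1 by default), with the
  same count per control as the noise model.

Two averaging structures are defensible for mu/sigma: over per-control
means, or over all (variant, control) pairs. The package defaults to
per-control means — the per-sample average is the natural null replicate of
the patient-plasma statistic, and sigma is then a between-sample standard
deviation with n_controls − 1 degrees of freedom — and exposes the pooled
alternative behind `pooled = TRUE`.

Significance is a one-sided Student-t comparison: `significance(z, alpha,
df)` with shipped defaults alpha = 0.05 and df = 7, giving the critical
value 1.895 (to three decimals). A normal one-sided 5% value would be
1.645 and df = 8 would give 1.860; the package pins df = 7 as its operating
default and leaves `df` a parameter, because with nine controls either 8 or
7 (one lost to the mean, arguably one more to the shared variant set) is
arguable. Degenerate noise (sigma = 0) is an error rather than an infinite
z; muNoise = 0 with nonzero signal yields S2N = +Inf with a warning.

```{r significance}
significance(2.1, alpha = 0.05, df = 7)
```

## The synthetic cohort generator

Real forced-call tables from patients cannot be shipped, so the package
carries a generator whose defaults *are* its study conditions: 2000 tumor
SNVs per patient; mean depths 24x tumor, 17x normal, 52x patient plasma,
49x control/pool plasma (Poisson per site, negative binomial behind
`depthDispersion`); 9 controls and 9 pool samples; tumor-tissue VAF uniform
on [0.2, 0.8] (a high-tumor-cell-fraction spectrum consistent with the
tumor VAF >= 0.2 filter); per-base substitution error 1e-3, split evenly
across the three non-reference bases so a specific alternate allele arises
at e/3; a ctDNA fraction (`tumorFraction`) of 0.005 by default — a
realistic pretreatment value for advanced disease and the operating point
of the package's power checks; 2% of sites are recurrent artefact sites
drawing alternate reads at probability 0.02 in *every* plasma-derived
sample (patient plasma, controls, pool alike — the shared-position
signature the pool filter exploits); and 1% of variants leak heterozygous
germline signal (expected VAF 0.5) into the matched normal, where the
normal-AD filter removes them. Artefact prevalence and intensity are
synthetic choices documented here, not estimates from data: they are set to
produce clearly visible control-plasma outliers at desk scale.

Plasma alternate reads arise at probability `tumorFraction * vT +
background`: the tumor-tissue VAF is taken to fold in purity and zygosity,
so no separate diploid model is layered on. Cohorts share one site
universe (and hence one artefact-site set) and derive per-patient
substreams from a master seed, so they are reproducible file-for-file;
`SimTruth` flags per variant whether it is an artefact site or a germline
leak, enabling exact precision/recall audits of the pool filter
(`recoveryReport()`).

What the generator does *not* emulate: trinucleotide-context error
profiles, strand or fragment-level features, copy-number or clonal
structure, batch effects between plasmas, and caller-induced censoring of
low-support sites. Passing tests therefore demonstrate the statistical
machinery under the stated noise model, not performance on real cfDNA.

## Downsampling

`downsamplePlasma()` emulates read-level downsampling at the count level:
each alternate and each reference read is kept independently with
probability `fraction`, so kept counts are binomial and AD <= DP is
preserved; only the patient plasma is thinned by default (controls are used
at native depth, matching a design where only the plasma's required depth
is in question). Because the thinned reads are an exchangeable subsample,
the *expected* VAF is unchanged — thinning adds variance to the VAF
statistics but does not shift their mean — whereas the AD-based and binary
statistics degrade mechanically: the plasma AD numerator scales with
depth while the control-plasma noise model does not. The package's
degradation checks therefore assert on the AD z-score (mean z at fraction
0.4 below mean z at full depth over 50 seeded cohorts, alongside the
thinned-depth expectation), and this distinction is worth remembering when
comparing VAF-based results across sequencing depths.

## Numerical and design notes

* Thresholds compare with >= / <= exactly as written above; the pool rule
  is strictly "> 1" and is depth-independent.
* Multiallelic VCF lines are split per alternate allele; indels are skipped
  with a counted warning (the method is SNV-focused); missing genotypes
  (./.) become DP = 0, AD = 0 with a warning.
* Verdicts are computed against the unfiltered table, so filter composition
  commutes and the accounting is order-independent.
* Intersection combinations below `minCount` (default 15) are suppressed
  from display but always retained in the returned map, so partition and
  marginal identities hold exactly.
* All simulation and thinning restore the caller's global RNG state;
  substream seeds stay inside the 32-bit integer range.
* Problem sizes used by the shipped checks (500 null replicates, 50–100
  signal replicates, 1000 random tables against brute-force oracles) are
  chosen to give stable Monte-Carlo estimates at desk scale; the
  acceptance script prints every quantity with the replicate count it used.

## Known limitations

* The per-seed probability that the z-score improves from Method 2 to
  Method 3 under the default conditions is about 0.88 (the S2N improves in
  essentially every replicate, and median z improves strongly): the z
  difference carries the sampling noise of two 8-df standard-deviation
  estimates. Expect individual replicates — like individual patients — in
  which the pool filter does not raise z.
* df = 7 is an operating default, not a derivation; users with different
  control counts should set `df` (and `alpha`) deliberately.
* The pool filter can in principle remove a true recurrent driver variant
  shared across patients; with recurrent SNVs rare at whole-genome scale
  this costs little signal, but pool membership is manifest-driven and
  should exclude samples suspected of cross-contamination.
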