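---
title: "Cancer-specific exon discovery: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer-specific exon discovery: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csefinder)
```

This vignette documents the statistical model behind `csefinder`, the
design of its synthetic-cohort generator, and the rationale for the
validation suite. Genomic coordinates are 1-based and closed throughout,
matching GTF conventions.

## 1. Quantification

Exon read counts follow union/nonunique semantics, as used by common
exon-level counters:

* a junction read whose aligned blocks overlap two exons increments both;
* each reported alignment record of a multi-mapped read is counted at its
  locus (mapping quality 0 is retained);
* `N`-gapped (spliced) segments do not create overlap;
* a record is assigned to an exon when the overlap reaches `min_overlap`
  base pairs (default 1).

The library size is the number of exonic records by default
(`library_mode = "exonic"`), or all mapped records with
`library_mode = "mapped"`.

Normalization is FPKM with a read-length-aware effective length:

$$\mathrm{FPKM} = \frac{c \cdot 10^9}{\max(L, r)\cdot N},$$

where $c$ is the exon count, $L$ the exon length, $r$ the read length
(default 100) and $N$ the library size. The $\max(L, r)$ floor prevents
exons shorter than a read from being inflated.

## 2. Rank-sum statistic and composite

For one exon, one tumor type with values $x_1,\dots,x_{n_1}$ and one
normal tissue with values $y_1,\dots,y_{n_2}$:

$$U = \sum_{i=1}^{n_1}\sum_{j=1}^{n_2} S(x_i, y_j), \qquad
S(x, y) = \begin{cases} 1 & y < x\\ \tfrac12 & y = x\\ 0 & y > x,\end{cases}$$

computed via mid-ranks as $U = R_x - n_1(n_1+1)/2$. The normal
approximation uses the plain (untied) null variance by default,

$$z = \frac{U - n_1 n_2/2}{\sqrt{n_1 n_2 (n_1+n_2+1)/12}},$$

with an optional tie-corrected variance (`tie_correction = TRUE`).

Percentile ranks are mid-ranks scaled to $(0,1)$:
$p_i = (\mathrm{midrank}_i - 0.5)/N$; each row of a rank matrix averages
exactly $0.5$. The weight of a tumor–normal pair is the difference of
median percentile ranks, $w = \tilde p_{\text{tumor}} -
\tilde p_{\text{normal}}$, and per-exon composites are weighted Stouffer
sums over all $k$ pairs of a compartment:

$$Z = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}.$$

Ranks are computed per compartment (solid vs brain tumors, each pooled
with all normal tissues); `rank_scope = "pair"` restricts ranking to each
pair's samples.

## 3. Selection, curation, tiering, classification

**Selection** requires, per exon: $Z > 1$ (strict); at least one tumor
type with median percentile rank strictly above 0.5; and at most five
normal tissues above their median. Because an exon that is exactly zero in
every sample of a normal tissue gives those samples a shared mid-rank
below 0.5, exact zeros — not rank margins — are what certify tissue
silence.

**Localization** keeps surfaceome/matrisome genes (an oncofetal allowlist
is exempt) and removes blacklisted genes.

**Curation** applies four checks per candidate; a gene is kept only if all
applicable checks pass:

* *cross-resource*: tumor types represented in multiple data sources must
  show median percentile rank above 0.5 in every source;
* *tumor proteomics*: at least `min_psm` peptide-spectrum matches; absence
  of coverage fails safe;
* *brain-normal*: brain-compartment candidates with normal-brain median
  rank at or above 0.75 are removed;
* *positional bias*: for genes with at least three exons, a Pearson
  regression of mean normal expression on the strand-aware exon index
  (1 = 5′-most); $p < 0.01$ with $r > 0$ removes the gene. This targets a
  known artifact: 3′-biased library preparation in normal compendia
  depletes 5′ exon coverage, so 5′ exons of broadly expressed genes
  masquerade as tumor-specific.

**Tiering** demotes a target to Tier 2, with a named reason, on any of:
expression at or above the 0.75 rank in a paired normal tissue (e.g.
adrenocortical carcinoma vs adrenal gland); a bone-marrow logistic
classifier on $\log_2(\text{median BM FPKM} + 1)$ predicting "expressed"
(missing gene fails safe; under perfect separation a ridge-regularized fit
is used); or high normal-tissue protein abundance, where "high" is decided
by a cutoff on $\log_{10}$ normalized PSM fit as the equal-posterior point
of a two-component equal-variance Gaussian mixture, falling back to the
median when the fitted component means nearly coincide.

**Classification** labels a target *AS* (alternative splicing) when some
annotated transcript covers less than 40% of the gene's CSE base pairs
(coverage is relative to that transcript's own exonic length) and at least
one CSE exon is differentially included; single-transcript genes are
always gene-level. The representative AS exon is the CSE exon with the
highest composite (ties broken by genomic start). Variants within ±10 bp
of its boundaries are tested for association with exon expression by a
one-sided Welch $t$ (carriers greater), restricted to tumor types whose
median rank is at or above 0.5.

**Scoring** bins each sample into quartile scores 0–3 using type-7
quantile breaks computed from values at or above 1 FPKM (sub-floor values
bin 0), averages bins per tumor type / normal tissue and then across
types, and reports the per-type fraction of top-quartile samples as
prevalence.

## 4. Synthetic-cohort design

The generator is the package's test bed: its defaults define the study
conditions and every planted truth is recorded in `bundle$truth`.

* **Targets.** Planted gene-level targets are expressed in several tumor
  types and planted *below the detection floor* in all normal tissues
  (0.05 FPKM against a 0.25 FPKM floor, quantized to zero counts). This is
  deliberate: the selection rule's power comes from ties at zero, so the
  generator realizes tissue silence the same way real data would — exact
  zeros — rather than through rank margins. Planted AS targets express
  only a cassette exon that one transcript skips.
* **Confounders with known correct outcomes.** Six tiering confounders
  (re-expression in the paired normal tissue, bone-marrow expression, high
  normal protein) must each end in Tier 2 with the matching named check.
  Two positional-bias confounders are broadly expressed genes whose
  *normal-library* coverage ramps linearly from 0 at the 5′ end to full at
  the 3′ end; their 5′ exons then satisfy the selection rule spuriously,
  and the curation regression must remove them.
* **Determinism.** Every stochastic component draws from a stream-derived
  seed (`sub_seed`), all below $2^{31}$, and the global RNG state is
  restored afterwards; identical seeds give byte-identical bundles and
  exports.

## 5. Validation strategy

The test suite validates each primitive against an independent oracle
(brute-force pair enumeration for $U$, closed-form $z$, hand-counted SAM
fixtures, algebraic composite identities), and the end-to-end pipeline
against planted truth: recovery sensitivity/precision, AS exon identity,
confounder demotion and bias removal. Null cohorts with no planted signal
calibrate the false-target rate, and known Gaussian mixtures calibrate the
nPSM cutoff. `scripts/acceptance.R --seed <s> --out <f>` reproduces these
quantities as JSON.

```{r example}
bundle <- simulate_bundle(sim_config(n_genes = 30,
                                     n_planted_gene_level = 8L,
                                     n_planted_as = 2L,
                                     samples_per_tumor_group = 8L,
                                     samples_per_normal_tissue = 10L),
                          seed = 42)
run <- run_pipeline(bundle)
run
evaluate_recovery(run, bundle$truth)[c("sensitivity", "precision")]
```
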