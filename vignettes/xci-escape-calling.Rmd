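---
title: "Calling Xi escape and reactivation from allele-specific RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling Xi escape and reactivation from allele-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcireact)
```

## The measurement and its obstacles

In a female human cell, transcripts from the two X chromosomes can only be
told apart at heterozygous SNPs. `xcireact` works with SNPs ascertained from
two isogenic clonal lines that express opposite X haplotypes: because each
clone is functionally hemizygous for X-linked expression, any position with
a different consensus base between the clones is a heterozygous SNP of the
parental line, and the clone identity phases the alleles. At each SNP the
allele carrying the majority of reads in the unfused cells (day 0) is
defined as the active-X (Xa) allele; the minor allele reports the inactive X
(Xi). Per-gene Xi expression is the ratio Xi/(Xa+Xi) over all SNP-overlapping
reads of the gene.

Two obstacles shape the model. First, in inter-species fusion experiments a
fraction of reads aligns to both genomes; these are discarded before
counting (only human-specific reads are used). Second — and centrally — a
silenced gene still shows occasional Xi-allele reads from base-call errors,
so "is this gene expressed from the Xi?" is a detection problem whose null
depends on depth and base quality.

## The mixture model

For gene *g* with `n` allelic reads of which `x` support the Xi allele:

* **silenced component**, prior weight π₀: `x ~ Binomial(n, ε_g)`. The
  per-gene error rate is derived from the summed Phred quality of the
  Xi-supporting bases: with mean quality q̄ = (Xi quality sum)/x, a base is
  miscalled with probability 10^(−q̄/10), and only one of the three possible
  miscalls produces the Xi allele, so ε_g = ⅓·10^(−q̄/10). Genes with no Xi
  reads fall back to the dataset-wide mean quality. ε is bounded to
  [10⁻⁶, 0.05].
* **expressed component**, weight 1−π₀: `x ~ BetaBinomial(n, α, β)`. The
  beta-binomial absorbs the biological overdispersion of Xi fractions across
  escaping and reactivated genes, which a shared binomial could not.

The three observables the model consumes — the Xi read count, the Xi base
quality sum, and the Xi ratio — enter through `x`, ε_g, and `x/n`
respectively. One observation per (gene, timepoint) is used: transcription
is a gene-level process, so the generator also draws an expressed gene's Xi
fraction once per gene, shared across its SNPs.

The per-gene score is the posterior probability of the silenced component,

τ₀(g) = π₀·L₀ / (π₀·L₀ + (1−π₀)·L₁),

so small τ₀ means strong evidence of Xi expression, and τ₀ is monotone
non-increasing in `x` at fixed `n`. A gene is called *expressed from the Xi*
when its Xi ratio exceeds 0.10 **or** τ₀ ≤ 0.05. The phrase "probability of
escaping XCI" admits either orientation; this package adopts the
silenced-posterior reading (≤ 0.05 significance direction), and
`call_xi_expression(tau_direction = "escape_posterior")` reports the
complement for the opposite convention — the call itself is identical. No
multiple-testing correction is applied; τ₀ is a posterior, not a p-value,
but users comparing many genes should be aware calls are marginal.

```{r fit-demo}
cfg <- simulation_config(n_genes = 200, frac_escape = 0.15,
                         frac_reactivated = 0,
                         xi_fraction_expressed = list(alpha = 30, beta = 70),
                         depth_per_gene = list(min = 50, max = 1000),
                         seed = 5)
ds <- simulate_allelic_dataset(cfg)
asn <- assign_haplotypes(ds$counts[ds$counts$sample == "day0", ])
s <- aggregate_gene(ds$counts, asn)
fit <- fit_mixture(s[s$sample == "day0", ])
fit
```

### Fitting: EM with a numeric M-step

E and M steps alternate until the relative log-likelihood change falls below
10⁻⁸ (at most 500 iterations). π₀ has a closed-form update; (α, β) are
updated by bounded quasi-Newton optimisation on (logit mean, log
concentration), and an update is accepted only when it does not decrease the
expected complete-data log-likelihood, preserving the EM ascent guarantee —
the returned log-likelihood trace is non-decreasing and tests assert it.
Ten seeded restarts are run as short EM chains (25 iterations each) and the
best chain is continued to convergence; this protects against label
switching and poor basins at negligible cost. α and β are kept in
[10⁻³, 10⁴] by bounding the concentration inside the optimiser (so the bound
cannot distort the component mean) and projecting any residual violation.

Degenerate inputs are handled explicitly: a dataset with zero Xi reads
everywhere returns a flagged fit with π₀ = 1 rather than an error, and EM
non-convergence returns `converged = FALSE` with a warning. On data with no
expressed genes at all, the expressed component has nothing to explain and
may drift slowly toward the error distribution; the fit is then reported
unconverged, which is honest — and the resulting calls are still
conservative (τ₀ ≈ 1 throughout).

### Classification across timepoints

Only genes with at least 20 SNP-overlapping allelic reads at **both**
timepoints are classified (`min_reads = 20`, inclusive: 20 passes, 19 does
not; a strictly-greater variant is available via `strict = TRUE`). Calls at
day 0 and day N then give: escape (expressed at both), reactivation-
sensitive (day N only), refractory (neither). Genes expressed at day 0 only
have no named category; they are binned refractory with an explicit
`day0_only` flag rather than silently. A later timepoint (e.g. day 6) can
promote refractory genes that show significant Xi expression there and not
at day 0.

## What the synthetic generator emulates — and what it does not

`simulate_allelic_dataset()` reproduces the statistical structure the
analysis assumes: ~183 X-linked genes carrying ~2 heterozygous SNPs each
(379 total in the `paperlike` preset), per-gene depths spanning the 20-read
filter from both sides (log-normal, median ≈ 200, truncated to [5, 5000]),
a silenced majority whose Xi reads arise purely from Phred-governed miscalls
(uniform over the three alternative bases, so ⅓ hit the Xi allele), and a
minority of escaping (8%) / reactivation-sensitive (10%) genes whose Xi
fractions are drawn from Beta(3, 7) — mean 0.3 with substantial spread,
matching the overdispersion the beta-binomial component is there for. The
class fractions mirror the reported ~10% reactivation-sensitive yield and a
similar order of escapees; depth and quality distributions are not reported
by the study, so the defaults above are declared choices, kept configurable.

The generator does **not** emulate: alignment artefacts (reads are counts,
not sequences), reference bias between alleles, positional error profiles or
quality miscalibration, expression-level differences between genes beyond
depth, or correlated errors across SNPs of a gene. Passing tests therefore
show the inference is correct *under its own model assumptions* and robust
to the sampling noise those assumptions produce — not that real RNA-seq
meets those assumptions.

## Bench-assay modules

**2^−ΔCt.** `relative_expression()` is the textbook 2^−(Ct_target −
Ct_reference) with configurable amplification efficiency (default 2.0,
perfect doubling, for all amplicons). Replicates reduce to mean ± s.e.m.
with unadjusted two-sided t-tests against the day-0 condition.

**RFLP-qPCR.** Restriction digestion destroys allele-2 templates at the SNP
site and all templates at a control site in the same exon. On digested
material the SNP amplicon measures R = f + u(1−f), with f the true allele-1
fraction and u the residual undigested fraction reported by the control
site; `allele1_fraction()` inverts this, clamped to [0, 1]. The model
assumes the control site reports the same per-template cut probability as
the SNP site. u ≥ 0.5 is treated as digestion failure (error), and small
negative corrected fractions (≤ 0.05 in magnitude) are clamped to zero with
a warning. Whether the control site is normalised against the total amplicon
on digested material or against its own undigested measurement is accepted
via `pairing =`; the default is digested-vs-total.

**RNA-FISH.** The XIST pattern rule is qualitative in origin; its constants
are made explicit here: signal threshold = background mean + 3 background
s.d., "constant pixel intensity" = coefficient of variation ≤ 0.35 within
the run, compact span ≥ 2 µm, and runs shorter than 0.2 µm are ignored as
pixel noise (without this floor, a single noisy pixel above threshold would
turn a background-only profile into "diffuse"). All constants are
configurable; classification is invariant to uniform intensity rescaling.
Allelic signal counting merges signals within 1 µm by single linkage — the
distance rule is the stated criterion, single linkage the declared
tie-break for chains — and reports 1 / 2 / >2 / undetected. Proportions are
computed within each biological replicate and then averaged (the replicate,
not the cell, is the unit of independence); the exact-zero-variance t-test
path degenerates to p ∈ {0, 1} and is flagged.

## Numerical choices and tie-breaks

* Day-0 allele-count ties leave Xa undefined; the SNP is flagged and
  excluded from aggregation by default (conservative; `drop_ties = FALSE`
  keeps them with allele1 as Xa).
* Genes whose non-tied SNPs disagree on which allele index is Xa are
  phase-inconsistent — mixing phases corrupts the Xi ratio — and are flagged
  and excluded from model fitting by default.
* Bases below Phred 13 are excluded from counts and quality sums
  (configurable); SNP discovery requires depth ≥ 10 and consensus purity
  ≥ 0.9 in each clone. The source analysis does not state its discovery
  thresholds; these are explicit defaults, not inferred intent.
* Zero-depth genes carry an undefined (NA) Xi ratio and are refused by
  `escape_probability()` with instructions to filter first.
* Timepoints are fitted jointly by default (shared error model and expressed
  component), which stabilises small datasets; per-sample fits are a
  configuration away.

## Problem sizes used in the test suite

The automated checks run at sizes chosen to give tight statistical bounds
while keeping the suite quick: parameter recovery on 500 genes × 5 seeds
(recovery of π₀ within ±0.05 and of the expressed mean within ±0.03),
EM-versus-grid-search likelihood comparisons on 20 instances of ≤ 30 genes
(50³ grid), false-call control on 20 fully silenced datasets of 1000 genes,
and end-to-end classification at the 183-gene study scale, where ≥ 95% of
well-covered genes (≥ 100 reads) must match the generating truth.

## Known limitations

* The silenced-component error model trusts Phred calibration; systematically
  optimistic qualities would inflate Xi-expression calls.
* Reference/mapping bias between alleles is not modelled; in real data it
  shifts Xi ratios at affected SNPs.
* The classifier treats timepoints as independent given the shared fit; it
  does not borrow strength across timepoints for borderline genes.
* FISH scoring operates on 1-D profiles and 2-D signal coordinates;
  volumetric (z-stack) analysis is out of scope.
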