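---
title: "Methods: models, parameters and design choices in clonepulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in clonepulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonepulse` analyses paired-timepoint single-cell targeted-amplicon DNA
genotyping with simultaneous surface-protein (ADT) readout, the data
shape produced by droplet microfluidic platforms on bone-marrow aspirates
from patients with myelodysplastic syndromes before and after
hypomethylating-agent therapy. This vignette documents the statistical
models, the defaults and why they were chosen, the synthetic data's
design, and the package's known limitations. Everything stated here is
computed by the test suite or by `scripts/acceptance.R`; no empirical
claim goes beyond what those runs measure.

## Genotype quality control

Every per-call, per-variant and per-cell rule uses a strict comparator,
because that is how the thresholds are defined for this assay class:

| rule | threshold | comparator |
|---|---|---|
| genotype quality | 30 | keep if > |
| read depth | 10 | keep if > |
| alternate-allele fraction (non-WT calls) | 0.20 | keep if > |
| variant genotyped fraction | 0.50 | keep if > |
| variant mutated fraction | 0.01 | drop if < |
| cell genotyped fraction | 0.50 | drop if < |
| population minor-allele frequency | 0.01 | drop if > |

The alternate-allele-fraction rule is applied to non-reference calls
only: a wild-type call has no alternate reads by definition, and
applying the rule to it would erase every reference genotype.
"Mutated" means a HET or HOM call throughout. Variants that fail only
the genotyped-fraction rule but look well supported — median quality and
median alternate fraction above the per-call floors among their mutated
cells — are kept as *reported-only*: visible in result tables, never
used to define a clone. "Well supported" is not quantified in the
protocols this pipeline follows, so the per-call floors are reused; both
knobs sit in `qc_thresholds()`.

Filters run calls → variants → cells and are idempotent; relaxing any
threshold can only grow the kept set (both properties are tested).

## Allele dropout

At a germline heterozygous site every cell is truly HET, so apparent WT
or HOM calls measure dropout:

ADO% = 100 · (n_WT + n_HOM) / n_genotyped.

Germline heterozygous variants are selected jointly from the two
timepoints: mutated in ≥ 92% of genotyped cells at both, with
VAF-by-cell-count — 100 · (n_HET + 2 n_HOM) / (2 n_genotyped) — inside
[49.2, 52.7]% at both. The sample estimate averages the five selected
variants whose VAF is nearest 50; when fewer than five qualify, all are
averaged and a warning is raised. The ≥ 92% criterion is taken over
*genotyped* cells (the protocol text does not name the denominator;
genotyped cells makes the criterion independent of missingness). The
estimator is unbiased under symmetric dropout: across 50 seeded
simulations at a planted 10% rate, the mean estimate lands within ±0.5
points of 10 (`scripts/acceptance.R`).

## Clones, artifact removal, phylogeny, dynamics

A clone is a set of cells with an identical (variant → zygosity) vector
over the kept variants. Cells with any MISSING call among kept variants
are reported as unassigned rather than imputed — clone identity requires
a complete signature, and no imputation rule is defensible at these
panel sizes. Clones below 1% of assigned cells pool into a `minor`
bucket unless they carry a whitelisted variant.

Symmetric dropout converts cells of a clone with a HET site into an
apparent clone differing by exactly one HET→WT or HET→HOM substitution.
Such candidates are merged into the larger clone when their size does
not exceed `parent × ADO/100 × 1.5`; the 1.5 safety factor replaces
manual inspection with a reproducible rule (the factor is exposed).
Because dropout to a *specific* direction occurs at rate ADO/2, the rule
is conservative by construction: simulated clones at three times the
expectation are never removed (tested).

The phylogeny is the partial order of signatures under mutation-set
inclusion with zygosity progression (WT < HET < HOM at a site; HET may
precede HOM, never the reverse). Each clone's parent is its largest
proper ancestor (most mutations, ties by cell count), the root is the
wild-type clone (a virtual root if no WT cell exists), and pairs of
variants that violate nested ancestry (both exclusive patterns and the
joint pattern observed) are reported as conflicts instead of aborting.
Shannon diversity over mutant clones uses the natural logarithm via
`vegan::diversity()`.

Paired dynamics are classified with two exposed thresholds,
`shrink_factor = 0.5` and `new_clone_min = 0.02`: **shrinkage** when
every diagnosis mutant clone falls below half its diagnosis fraction of
all cells and no new clone at ≥ 2% appears; **expansion** when a new
clone at ≥ 2% appears or a minority clone more than doubles; **stable**
otherwise. These two numbers operationalize qualitative pattern
descriptions; at 3,000 cells per sample and 5% ADO the classifier
recovers the generating pattern in ≥ 95% of seeded cohorts (acceptance
suite). Patients without any detectable mutant clone are excluded from
dynamics-by-response association, mirroring how such a case cannot be
scored.

## Ploidy and CNV

Amplicons seen (≥ 1 read) in under half the cells are dropped; counts
are divided by the cell total and then by the amplicon mean, after which
every amplicon has mean 1 across cells. Ploidy is

ploidy(clone, amplicon) = 2 · median over clone cells / median over baseline cells,

with the wild-type clone as the diploid baseline, so the baseline sits
at exactly 2 by construction. The median is used on both sides — a
mean-based baseline would not satisfy the self-reference identity and
the median is what the clone-level summary uses downstream; it also
makes the estimate robust to 5% label contamination (tested at < 0.15
ploidy shift). Region calls use midpoints between integer copy states:
loss < 1.5, gain > 2.5 (both exposed). Per-cell total normalization is
compositional: a copy-number event spanning a large share of the panel
inflates the remaining amplicons. With the 519-amplicon default panel
the planted monosomy/trisomy recover to 1.0 ± 0.2 and 3.0 ± 0.3; on a
drastically reduced panel the same events read ~1.1/3.3, which is why
panel-scale controls matter.

CNV-defined clones are also detectable from genotype data alone: a
deletion pushes the within-cell alternate fraction of a germline
heterozygous variant on the region towards 0 or 1, a duplication towards
1/3 or 2/3. `detect_cnv_clone()` compares each clone's per-cell alt
fractions against the wild-type clone's (mean shift > 0.15 with rank-sum
confirmation) and infers direction from which target set the mean is
nearest. Raw (pre-QC) calls should be passed: per-call QC blanks
strongly shifted alleles. A region without heterozygous variants returns
*not evaluable*, distinct from negative.

## Protein lane

Cells with total ADT counts below 200 or above 100,000 are discarded
(boundaries kept). Counts are scaled to counts-per-million over **all**
antibodies including isotypes, a +1 pseudocount added, and the centered
log-ratio taken; CLR rows sum to zero to 1e-9 (tested). Denoising then
subtracts each cell's mean isotype CLR from every target antibody and
floors at zero — a deliberately simple, fully specified stand-in for
published isotype-regression methods, applied after CLR in that order.

Clustering is PCA (15 components) → exact k-nearest-neighbour graph
(k = 20, via the RANN backend) → shared-nearest-neighbour weighting →
Louvain at resolution 0.8 with a fixed random seed, through Seurat's
graph machinery. None of these four values is prescribed by the
protocols this pipeline follows; all are exposed. Clusters whose mean
CLR profile has across-antibody variance below 0.05 carry no lineage
signal and are dropped as technical artifacts.

Annotation evaluates ordered marker rules on the **standardized**
cluster-mean profile (z-scores across antibodies). Raw denoised CLR
means carry an additive per-cluster library-size shift — cells with low
ADT totals have noisier isotype estimates and systematically higher
floored values — and z-scoring cancels it, so the default cutoffs
(high > 2, low < 0.5 profile SDs) are scale-free. The default rule table
encodes HSPC, CMP, immature erythroid, monocyte, granulocyte, T, NK, B
and one rare CD11c+CD45+CD49d+CD62P+ population, rolled into six
compartments (progenitors, immature erythroid, myeloid, T, NK, B);
populations drawing > 90% of their cells from one sample are excluded
from compartments as sample-private.

LISI (local inverse Simpson index) calibrates Gaussian neighbour weights
to a target perplexity and returns 1/Σ p² over label probabilities — the
effective number of labels near a cell. Resolving L labels requires a
perplexity comfortably above L: at perplexity 30 a perfectly mixed
28-sample cohort reads ~10–15 (the kernel simply cannot hold 28 labels),
while at perplexity 500 it reads above 25. The mixing diagnostic in the
acceptance script therefore uses perplexity 500; the per-cell default
stays 30 for local structure.

## Compositional testing

Cell-type counts per sample are modeled as Dirichlet-multinomial within
each condition level, fitted by bounded maximum likelihood on log-α (the
box bound handles the near-multinomial regime, where the likelihood is
flat in total concentration and unbounded optimization overflows; at the
bound the α-ratios still track proportions, which is all the effect
scale uses). Effects are log-fold-changes of α-ratios against a
reference population auto-selected as the one with the smallest
coefficient of variation of its proportion — the most compositionally
stable anchor. Inclusion probabilities come from a bootstrap over
samples within condition: the fraction of replicates whose effect
matches the point estimate's sign with magnitude ≥ `min_effect`
(default log 1.5). The magnitude requirement plays the spike-and-slab
role of the Bayesian model this test mirrors; without it, pure
sign-stability over-flags at small sample counts. Populations are
declared credible by expected-false-discovery control at FDR 0.1: the
largest inclusion-ordered prefix whose mean (1 − inclusion) stays at or
below the threshold. Calibration and power are measured in the
acceptance suite (null flagged fraction ≈ 0 at the default settings;
a 3-fold depletion of one of eight populations at 6 vs 6 samples and
3,000 cells is flagged in ≥ 90% of seeds). Timepoint contrasts default
to unpaired, matching the reference model's design; the pairing key is
carried for count bookkeeping.

The small-sample tests (two-sided Fisher exact with the
probability-mass-≤-observed convention, exact Wilcoxon signed-rank and
rank-sum, Spearman, Bonferroni) wrap the corresponding base-R
implementations; the test suite verifies each against an independent
enumeration oracle.

## Synthetic cohort design

The generator inverts the clone definition: it draws cells from
specified clone proportions, writes each clone's signature (plus
germline heterozygous variants, HET in all cells), then corrupts the
truth with symmetric allele dropout (HET → WT or HOM with probability
ADO/2 each), uniform genotype errors, MISSING calls, and depth/quality
failures injected independently of genotype so the QC filters have real
work. Amplicon depths are negative-binomial with per-cell lognormal
library sizes, scaled by clone copy number over planted CNV regions;
ADT counts are negative-binomial around cell-type-specific means plus a
flat shared isotype background.

Defaults mirror the study conditions: 14 patients with paired samples,
3,000 cells per sample (≈ 90,000 cells over 28 samples), a 519-amplicon
/ 53-gene panel, 42 target + 3 isotype antibodies, 5 germline
heterozygous variants per patient, ADO 5%, depth NB(mean 40, size 8),
genotype error 0.2%, missingness 3%. The cohort splits into 8
responders (7 shrinkage, 1 with no mutant clone detectable on the
panel) and 6 nonresponders (5 stable, 1 expansion); one stable
nonresponder carries a monosomy-7 clone and another a trisomy-8 clone.
The first acquired mutation is biased towards TET2, mutant clones are
floored at 6% of cells (clones far below that are indistinguishable
from dropout artifacts at these depths), and surviving mutant cells in
responders shift away from the HSPC state post-treatment, giving the
integration stage a planted genotype-phenotype signal. Between-sample
variability in the compositional test fixtures uses Dirichlet
concentration 100 (≈ 10% CV for a 25% population — replicate-level
variation). No protocol this pipeline follows publishes a quantitative
sequencing-noise model; the NB dispersions and rates above are the
package's choices and all sit in `sim_config()`.

What the generator does **not** emulate: doublets, ambient-protein
contamination beyond the flat background, read-level errors (it starts
at matrices), batch effects, or clone-specific amplification biases.
Passing tests therefore demonstrate correctness of the estimators under
the stated noise model, not robustness to every artifact of real
instruments.

## Problem sizes used in tests

The unit suite runs cohorts of 40–800 cells per sample with 4–8 amplicon
panels; the acceptance checks use the sizes their properties require
(2,000 cells for ADO recovery over 50 seeds, 3,000 cells × 100 seeds ×
3 patterns for dynamics, 1,200 cells × 50 seeds for ploidy, 6 vs 6
samples × 3,000 cells × 20 seeds for composition, and the full
study-scale cohort — 14 patients × 2 × 3,000 cells on the 519-amplicon
panel — for the end-to-end determinism run). These sizes were chosen so
each check's statistical resolution comfortably exceeds its tolerance.

## Known limitations

- Clone calling is exact-match: hypermutable or high-ADO data will
  inflate the unassigned set rather than borrow strength across cells.
- The phylogeny is a deterministic partial order, not a likelihood-based
  tree; conflicting sites are reported, not resolved.
- The compositional test's inclusion probabilities are bootstrap
  frequencies, not posterior probabilities; with very few samples per
  group (3–4) they are coarse-grained at 1/n_boot.
- Ploidy inherits the compositional bias of total-count normalization
  when altered regions dominate the panel (quantified above).
- Annotation quality is bounded by the marker-rule table; populations
  without discriminating markers in the panel cannot be separated.
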