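---
title: "Methods: joint 5mC/5hmC decomposition and differential hydroxymethylation dynamics"
author: "hydroxydyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint 5mC/5hmC decomposition and differential hydroxymethylation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxydyn)
```

# Scope and data model

`hydroxydyn` analyses DNA methylation (5mC) and hydroxymethylation
(5hmC) from per-CpG count tables of two complementary assays:
WGBS-like bisulfite sequencing, whose unconverted fraction estimates
`m + h`, and ACE-seq-like APOBEC deamination sequencing, whose
unconverted fraction estimates `h` alone. The package starts from
counts (not levels) because the decomposition and the caller both need
the underlying sequencing evidence; alignment, read trimming and
read-level allele splitting are upstream of its scope, and
differential gene expression is consumed as a finished table.

Coordinates are 0-based half-open everywhere (BED/bedGraph
convention). CpGs are reported once per symmetric dyad at the
plus-strand cytosine; `collapse_cpg_dyads()` folds minus-strand G
counts into the plus-strand record and is idempotent. Collapsing is a
reader option rather than an always-on step, because public count
tables differ in whether they are already dyad-collapsed.

# The decomposition model

At one CpG with BS evidence $(k_{bs}, n_{bs})$ and ACE evidence
$(k_{ace}, n_{ace})$, the model is

$$k_{bs} \sim \mathrm{Binom}(n_{bs},\ m + h), \qquad
  k_{ace} \sim \mathrm{Binom}(n_{ace},\ h),$$

maximised over the probability simplex $m, h \ge 0$, $m + h \le 1$.
Because the two likelihood factors depend on the distinct parameters
$p_1 = m + h$ and $p_2 = h$ linked only by the order constraint
$p_2 \le p_1$, the constrained MLE is closed form:

* interior case ($k_{bs}/n_{bs} \ge k_{ace}/n_{ace}$):
  $\hat h = k_{ace}/n_{ace}$, $\hat m = k_{bs}/n_{bs} - \hat h$;
* boundary case (the unconstrained $\hat m$ would be negative):
  $\hat m = 0$ and the two assays pool,
  $\hat h = (k_{bs} + k_{ace})/(n_{bs} + n_{ace})$. These sites are
  flagged as **conflicts**.

A generic EM (as used by multi-assay consensus tools) would converge
to the same point; the closed form is preferred because it is exact,
vectorises over millions of sites, and is pinned in the test suite by
an exhaustive grid-search oracle over all count configurations with
coverage up to 12. "Conflict" is interpreted as precisely the
negative-unconstrained-$\hat m$ mode — the only negative-estimate mode
a two-assay design admits. Conflicted sites are filtered by default
(the convention for downstream analyses); `filter_conflicts = FALSE`
retains the boundary estimates with their flag, since whether such
sites should be kept is a judgement call that depends on the
application.

`decompose_track()` requires a minimum coverage of 3 reads per assay
by default. No coverage floor is canonical for this step; 3 is low
enough to retain most sites at typical low-input coverage while
excluding the 1–2-read sites whose levels are pure noise, and it is a
plain argument.

```{r}
mle_decompose(8, 10, 3, 10)    # interior
mle_decompose(2, 10, 5, 10)    # boundary: conflict, pooled h = 7/20
```

# The differential caller

`call_dmrs()` implements a window-based caller in five stages, each
exposed as its own function:

1. **Tiling** (`tile_and_filter`): non-overlapping 100-bp tiles; only
   tiles with ≥ 2 usable CpGs are retained. A usable CpG has coverage
   in both groups after replicates are aggregated by summing counts
   (for count tracks) or coverage-weighted averaging (for level
   tracks). CpGs in dropped tiles are invisible to all later stages:
   the tiling's only role is CpG-density filtering.
2. **Sliding windows** (`sliding_window_test`): 1000-bp windows
   advanced by 300 bp; each window is scored by a classic
   equal-variance two-sample Student's t-test comparing the per-CpG
   levels of group A against group B. The per-CpG levels are the test
   unit because with n = 2 replicates per group a replicate-level test
   is degenerate. Windows with < 2 usable CpGs are skipped.
   Zero-variance windows get p = 1 when the group means agree and
   p = 0 otherwise — deterministic and conservative where the t
   statistic is undefined.
3. **Merging** (`merge_significant_windows`): windows with p < 0.1 are
   merged wherever their extents overlap, and every region statistic
   (means, difference, t-test p, CpG count) is recomputed over the
   merged extent from the underlying CpG levels — the thresholds below
   are applied to merged-extent means, not to window minima.
4. **Classification and same-class merging** (`classify_regions`,
   `merge_same_class`): 5mC mode — difference > 0.25 hyper, < −0.25
   hypo, |difference| < 0.15 with both group means > 0.65 stable-high;
   5hmC mode — |difference| > 0.03 hyper/hypo, stable split at the
   0.05 floor into stable-high and stable-low (the stable-low class is
   the natural complement of the stated stable-high rule). The
   "both means" reading applies the floor to each group separately.
   Same-chromosome, same-class regions within 10 kb merge; the
   operation is idempotent.
5. **Retention** (`finalize_regions`): Benjamini–Hochberg adjustment
   across all candidate regions; hyper/hypo retained with ≥ 3 CpGs and
   q < 0.1; stable classes retained with q > 0.05 (loci without
   significant differences). The `stable_q_direction` parameter
   exposes the alternative q < 0.05 reading rather than resolving the
   ambiguity silently.

The whole pipeline is validated two ways: bit-level agreement with an
independent brute-force enumeration on ≤ 50-kb toy genomes, and
planted-truth recovery on the generator (below). Exact antisymmetry
under group exchange and idempotence of both merges are property
tests.

# Enrichment and annotation

`enrichment_score()` builds a 2×2 table of cumulative base pairs —
region bp inside/outside an element versus remaining background bp
inside/outside — and applies a two-sided Fisher exact test with bp as
counts; the enrichment score is $-\log_{10} p$. Sidedness is a
declared choice (two-sided). The background defaults to the caller's
retained-tile territory, i.e. enrichment is measured relative to
callable space; regions extending past the background are clipped (a
warning) so the table margins stay consistent. On genome-scale tables
an optional common down-scaling factor keeps the exact test cheap; it
is off at toy scale. The test path is pinned to an exact
hypergeometric enumeration oracle at 1e-9 relative error.

Enhancers are assigned to the gene with the nearest TSS measured from
the enhancer center, strictly within 100 kb; exact ties break to the
lower-coordinate TSS so assignment is deterministic. Enhancer 5hmC
classes (newly generated / stable-high / bivalent / other) are defined
by overlap with gain DhMRs and stable-high regions and partition the
input by construction.

# Dynamics summaries and the reactivation screen

* `categorize_dynamics()` runs the 5hmC caller with the later stage as
  group A, so gain = hyper, loss = hypo, and the stable classes carry
  the 0.05 floor split.
* `delta_correlation()` is the Pearson correlation of region-wise
  (Δ5mC, Δ5hmC) pairs between two stages; it requires ≥ 3 regions.
* `chromosome_summary()` averages a level track in precomputed tiles
  (100 kb by default), reports per-chromosome medians and a two-sided
  Wilcoxon rank-sum test of X tiles against pooled autosomal tiles.
* `gicr_panel()` reports coverage-weighted mean 5mC/5hmC per
  (gICR, allele, stage); regions without covered CpGs are absent, not
  zero, so missingness is never mistaken for hypomethylation.
* `xa_ratio()` uses read-sum semantics — summed normalized counts on X
  divided by the autosomal sum — rather than per-gene means, matching
  a "transcript reads relative to autosomal reads" definition.
* `reactivation_screen()` applies two criteria: transcriptional
  reactivation (control mean expression ≤ `silent_max_expr`, default
  5 normalized counts — "low expression or silence" needs an
  operational number and this one is exposed and documented) with
  log2FC ≥ 1 at p ≤ 0.01; and regulatory evidence — the gene's
  promoter or linked enhancer overlaps ≥ 1 *ectopically generated*
  gain DhMR (control 5hmC < 0.05, aligned with the caller's
  stable-high floor; gain regions at or above it are "enhanced", not
  ectopic) and ≥ 1 hypo DMR from the same contrast. The screen is
  monotone: tightening any threshold can only remove genes.

# The synthetic methylome generator

The generator (`truth_config()` / `simulate_counts()`) emulates the
structure of a stage- and allele-resolved early-embryo methylome
study so that every downstream stage can be validated against planted
truth without any external data. Its defaults are the study
conditions:

* genome: 4 autosomes + chrX, 2 Mb each; CpGs at geometric spacing
  with mean 100 bp; coverage Poisson with mean 30 per assay;
* sample design: 2 replicates × group × sex × parental allele, over
  MEF, SCNT 2-cell, SCNT 4-8-cell, SCNT blastocyst, WT 2-cell and
  TET3-overexpression 2-cell groups;
* global "up-down" 5hmC means (0.02 → 0.06 → 0.04 → 0.01) and
  "demethylation – de novo – demethylation" 5mC means
  (0.75 → 0.55 → 0.65 → 0.40) across the stage series;
* a multiplicative 5hmC deficit (×0.5) on chrX in XX samples;
* maternal gICRs at m = 0.85 through the 4-8-cell stage dropping to
  0.45 at blastocyst with 5hmC held at the stage baseline;
* planted recovery DMRs (Δm = 0.5 between the SCNT and WT 2-cell
  groups), planted 5hmC-gain regions, and 300 coupling regions whose
  (Δm, Δh) pairs across MEF → 2-cell are drawn from a bivariate normal
  with correlation −0.7.

Two design points deserve comment. First, stage means differ globally,
so a naive generator would make *every* window differential between
stages. Real methylomes vary regionally; the generator therefore adds
1-kb block-level heterogeneity (additive Gaussian for 5mC, log-normal
multiplicative for 5hmC — the multiplicative form keeps low 5hmC
levels positive without truncation artefacts), drawn per stage and
shared by all groups of the same stage. Between-stage contrasts then
show a realistic mixture of gain/loss/stable territory, while
same-stage contrasts (SCNT vs WT 2-cell) are exactly null outside
planted regions — which is what makes the planted-DMR recovery and the
null false-positive experiments well-posed. Second, planted effects
are chosen ≥ 2× the caller thresholds (recovery is about parameter
recovery, not borderline behaviour), and recovery DMRs are 5 kb wide:
merged extents overhang planted edges by up to ~900 bp per side
(window minus step), so narrower plants would dilute the
merged-extent mean difference toward the 0.25 threshold.

The noise model is pure binomial sampling; an optional false
non-conversion rate ε is available for robustness experiments but off
by default, since no error model is part of the analysis being
emulated. Reproducibility is per-sample: substream seeds are derived
by stable hashing of the sample id, so simulating any subset of the
design yields identical tracks.

What the generator does *not* emulate: sequence-dependent CpG density
(CpG islands), correlated biological replicate effects, bisulfite
conversion failure gradients, copy-number or mappability artefacts,
and read-level phenomena (PCR duplicates, allele dropout). Passing
recovery tests therefore demonstrates correctness of the analytical
chain under the declared sampling model, not robustness to every
failure mode of real libraries.

# Numerical and validation choices

* Window/region t statistics are computed from cumulative sums; the
  degenerate zero-variance cases are decided before division.
* BH adjustment is applied across all candidate regions entering
  retention, not per class.
* The decomposition oracle uses a 1e-3 grid with prefix-argmax over
  the order constraint, so exhaustive enumeration of all coverage ≤ 12
  configurations stays under a minute.
* Validation problem sizes: a ~10-Mb default genome (~100k CpGs) for
  recovery experiments, ≤ 50-kb toy genomes for bit-level oracle
  comparisons, a 20-Mb chrX for the X-deficit check (≥ 200 100-kb
  tiles), and 5-seed batches for null behaviour. The gICR panel check
  aggregates cells over replicates and both sexes before comparison,
  matching how heatmap cells summarise an n = 2-per-sex design and
  keeping the per-cell sampling error (~0.007) well inside the ±0.03
  check.

# Known limitations

* The caller tests per-CpG levels, not counts; very uneven coverage
  within a window is weighted equally per CpG. A beta-binomial or
  smoothing-based model is out of scope by design.
* Base pairs are treated as independent Fisher counts, as the
  cumulative-length formulation demands; enrichment p-values are
  therefore anti-conservative in an absolute sense and best read as
  ranking scores (which is how the −log10 score is used).
* With n = 2 replicates the between-group t-test leans on per-CpG
  variation; tracks from fewer than 2 usable CpGs per window are
  silently invisible.
* The X/A expression ratio and the screen consume normalized
  expression tables as-is; no normalization is performed internally.
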