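---
title: "Methods and design notes for axonedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for axonedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonedit)
```

# The two analyses

A-to-I editing converts adenosine to inosine, which sequencers read as
guanosine, so at a known editable adenosine the editing level in one sample is
the G fraction among A+G calls, $p = g/(a+g)$. C and T calls at the site are
treated as contamination and never enter the denominator. `axonedit`
implements two analyses on such counts.

## Differential editing between two compartments

Given $n$ replicate samples per compartment (default design: 4 axon/cell-body
pairs, 8 libraries), a site enters the analysis only if its **total** read
depth (all four bases — the filter is about read support, not about the A/G
subset) is at least `min_coverage = 20` in *every* sample. For each retained
site the replicate levels are compared with a single two-sample $t$ statistic
and its two directional tails are kept:
$p_{A>B} = P(T \ge t)$ and $p_{B>A} = P(T \le t)$; for a continuous statistic
these are exact complements. The Welch (unequal-variance) form with
Welch–Satterthwaite degrees of freedom is the default; a paired one-sample
form on the per-animal differences is available (`paired = TRUE`) since the
replicates come from paired dissections, but the unpaired Welch test is the
documented default because the upstream recipe specifies only "two one-tailed
t-tests" and Welch is the robust unpaired choice. Levels are tested on the raw
fraction scale (no arcsine or logit transform) for the same reason.

Each tail's p-value vector is adjusted across sites with the
Benjamini–Hochberg step-up procedure **separately**, and the call is

* `A_higher` iff $q_{A>B} \le$ `fdr_level` (default 0.1, inclusive),
* `B_higher` iff $q_{B>A} \le$ `fdr_level`,
* `no_change` otherwise.

For complementary one-tailed p-values and any FDR level below 0.5 the two
calls are mutually exclusive; the code still asserts this and would fail
loudly rather than return an inconsistent table. The summary reports, besides
the three call counts (always an exact partition of the tested sites), the
*raw* direction split — strictly $\bar p_A > \bar p_B$, with ties counted
separately — and a binned histogram of $\Delta = \bar p_A - \bar p_B$
(default bin width 0.05 on $[-1, 1]$; the original figure's binning is not
stated, so it is configurable).

**Degenerate variance.** With few replicates and high coverage both groups
can be constant. By the continuity limit of the $t$ tail: equal constants give
$p = 0.5$ in both tails; unequal constants give 0 in the favored tail and 1 in
the other.

**Global summaries.** Two per-sample summaries are produced over the retained
sites: the unweighted mean editing level, and the *editing index*
$\sum_i g_i / \sum_i (a_i + g_i)$. The index is described upstream only as
"the weighted average of editing levels"; weighting by A+G coverage is the
established editing-index convention and is what makes the index equal the
mean exactly under uniform coverage — an identity the tests verify. Summaries
are computed per sample and reported as mean ± SD across replicates rather
than from pooled counts, matching how the replicate error bars were described.

## In vitro editing detection on an amplicon

For a substrate with $m$ adenosines (126 in the motivating experiment),
sequenced deeply in $k$ experimental and $k$ control replicates (5+5), the
null hypothesis at each position is that all G calls are sequencing errors:
$X \sim \mathrm{Bin}(a+g,\ p_0)$ with $p_0 = 0.001$, the error floor for
Q > 30 bases. The p-value is the exact upper tail $P(X \ge g)$ evaluated with
the binomial survival function — no normal approximation, which matters
because the interesting p-values are astronomically small at $10^5\times$
coverage. BH correction is applied **within one replicate's dataset** (the
natural reading of "an editing event within a dataset"), and a per-replicate
event is real when the adjusted p-value is strictly below 0.001.

Per-position editing percentages ($100\,g/(a+g)$, reported in percent units
so 0.78 means 0.78%) are averaged across replicates; SEM is the sample SD
(with $n-1$) over $\sqrt n$. Two detection flags are reported side by side
because the upstream description does not say how per-replicate calls were
combined:

* `detected`: the adjusted-p event fires in at least
  `min_replicates_detected` (default 3 of 5) experimental replicates;
* `flagged` (in the merged site report): the mean experimental percentage
  exceeds twice the mean control percentage, strictly (`fold > 2`). This
  explicit reporting rule reproduces the published 5-detected / 17-undetected
  split on the printed per-position means, including the boundary cases that
  sit exactly at fold 2 and are correctly excluded by strictness.

The fold over control `mean_exp / mean_ctl` is undefined (NA) when the
control mean is zero. Positions present in the results but absent from the
known-site list are kept and marked `putative_novel` rather than rejected.

# The synthetic-data generator

`simulate_compartment_counts()` emulates the paired two-compartment RNA-seq
design: per-site true levels for each compartment, and for every site ×
sample

1. coverage $\sim$ NB(mean `coverage_mean`, size `coverage_dispersion`),
   floored at 1 read (`Inf` size = fixed coverage, used by tests that need
   exact uniform depth);
2. a realized replicate level drawn from a beta law with the true level as
   mean and variance $\rho L(1-L)$ (`overdispersion_rho`; $\rho = 0$ is the
   degenerate no-biological-noise case);
3. $g \sim \mathrm{Bin}(\text{cov},\ L(1-e) + (1-L)e)$ with the symmetric
   miscall rate $e$ = `error_rate`, and $a = \text{cov} - g$. Only A and G
   calls are emitted, since the analyses use nothing else.

Defaults state the world the analyses target: 4 pairs, 92% of sites truly
higher in compartment A, level differences uniform on 0.05–0.3 over baseline
levels uniform on 0.05–0.5, coverage mean 100 with NB size 5 (typical
bulk-RNA-seq overdispersion), $e = 0.001$, and $\rho = 0.01$ — a mild
between-animal variability (SD of ~5 percentage points at mid levels) chosen
once because no replicate-dispersion estimate is published; it is a visible
config field, not a constant. `simulate_assay_counts()` does the same for the
amplicon assay: control replicates carry error only, experimental replicates
edit exactly the positions given, at $10^5$ A+G calls per position (MiSeq
amplicon scale).

What the generator does **not** emulate: read-level artifacts (no FASTQ, no
alignment errors, no indels, no strand bias), C/T contamination, coverage
correlation along a transcript, or dependence between sites. A green test on
synthetic data therefore establishes that the statistics behave as designed
under the stated model — FDR control, power, parameter recovery — not that
any upstream alignment or pileup pipeline is artifact-free.

# Numerical and interface choices

* Coordinates are 1-based on the transcript/amplicon sense strand; all sites
  are A on that strand (A→G only, never T→C), because the reference is an
  assembled transcriptome. The upstream quantifier's flag string (no minimum
  variant count or frequency, no coverage floor at quantification time, base
  quality ≥ 30, mapping quality ≥ 40) is mirrored in
  `quality_filter_config()`; the mapping-quality filter applies where counts
  are produced from alignments and is carried for provenance. The negative
  sign sometimes printed on the base-quality flag is read as a typographic
  artifact for $Q \ge 30$, consistent with the explicit prose filter.
* The pileup reader implements the classic 6-column text dialect, including
  `^X`/`$` read boundaries, `+N`/`-N` indels (no quality entries), and `*`,
  `<`, `>`, `N` placeholders (consume a quality entry, never counted).
  Base/quality length disagreement is a hard parse error.
* Duplicate (site, sample) count rows are an error, never silently summed.
* BH adjustment is the standard step-up `cummin` implementation, hand-written
  and cross-checked in tests against a brute-force evaluation of the
  definition and against `stats::p.adjust`.
* TSV writers print doubles with 17 significant digits so write → read
  round-trips are bit-identical; all run parameters land in
  `run_metadata.json`.
* Thresholds follow the stated conventions exactly: coverage filter and FDR
  call are inclusive (≥ 20 reads, q ≤ 0.1), the detection cut is strict
  (adjusted p < 0.001), and the fold rule is strict (> 2).

# Known limitations

* With 4 replicates per group the Welch t-tail is an approximation; at very
  low coverage the level distribution is discrete and p-values are mildly
  conservative/anticonservative site by site. The FDR-control test exercises
  exactly the default design to confirm the realized error rate.
* The caller tests each site independently; no shrinkage across sites and no
  transcript-level aggregation.
* Editing discovery is out of scope: only previously known sites are
  quantified.
* The amplicon caller assumes a common error floor $p_0$ for all positions;
  position-specific error (e.g. homopolymer context) is not modeled.
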