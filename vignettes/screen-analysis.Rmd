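---
title: "Multidimensional siRNA screen analysis: models, rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional siRNA screen analysis: models, rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctascreen)
```

## The analysis problem

Cancer–testis antigens (CTAs) are genes whose expression is normally
restricted to testis but which reactivate in tumours. An arrayed siRNA
screen asks, for every CTA and every cell line in a panel, whether
depleting the gene changes a phenotype: ATP-based viability (CTG),
caspase-3/7 apoptosis (APO), EdU-incorporation proliferation, or the
activity of a ligand-induced signalling reporter (HIF, Wnt, TGFβ, NF-κB
luciferase). `ctascreen` implements the full decision pipeline around such a
screen:

1. **Presence calling** — which CTAs are expressed in which lines, from
   NanoString-style counts with qPCR rescue of ambiguous probes.
2. **Testbed selection** — choosing a fixed-size cell-line panel that
   covers as many expressed CTAs as possible (maximum coverage).
3. **Normalization** — viability correction, ratio to the non-targeting
   control, and per-stratum z-scores.
4. **Hit calling** — threshold rules with a Student's t-test significance
   filter, reporter penetrance rules, retest selection, and single-siRNA
   pool deconvolution.
5. **Overlap statistics** — upper-tail hypergeometric tests between gene
   sets, and per-gene Kolmogorov–Smirnov effect comparisons.

Because raw plate data of this kind are rarely available, the package
carries a first-class synthetic-data generator with planted ground truth;
every downstream stage is tested against what the generator planted.

## Presence calls and relative expression

A probe is *ambiguous* when its counts stay below 1,000 in **every** cell
line; ambiguity is a property of the probe, not of a single cell. Ambiguous
probes are re-measured by qPCR and a gene is considered expressed in a line
when Ct < 35 cycles; a qPCR reaction with no Cq is treated as not
expressed. For unambiguous probes the per-line rule is count ≥ 1,000 in
that line — the threshold is configurable because only the ambiguity rule
is fully determined by the screen design; the per-line rule for unambiguous
probes is this package's reading. Ambiguous cells with no qPCR record are
flagged `unresolved` rather than silently called absent. CTA families
measured by one cross-hybridizing probe (GAGE, SPANX, MAGEA3/6, …) can be
expanded through an optional probe→family map.

Relative expression uses the comparative method,
$2^{-\Delta\Delta C_T}$ with
$\Delta\Delta C_T = (C_T^{tgt,treated} - C_T^{ref,treated}) -
(C_T^{tgt,control} - C_T^{ref,control})$.

## Testbed selection

Selecting the panel is the classical maximum-coverage problem: pick
`panel_size` columns of the presence matrix maximizing the number of rows
with at least one `TRUE`. The package ships two solvers:

* `select_panel_greedy()` — adds the line with the largest marginal gain at
  each step, ties broken lexicographically; guarantees at least
  $(1 - 1/e) \approx 0.632$ of the optimum, and its marginal gains are
  non-increasing.
* `select_panel_exact()` — exhaustive enumeration, feasible for study-scale
  instances (19 candidates choose 11 is 75,582 subsets, evaluated with one
  matrix product), refused above a configurable subset cap.

Greedy is *not* guaranteed to equal the optimum: on random instances at the
generator's presence density it matches the exhaustive solver on roughly
19 of every 20 instances and is within the $(1-1/e)$ bound on all of them.
Both behaviours are asserted in the test suite.

## Normalization model

Within one stratum — an (assay, cell line, condition) block — processing is:

1. **Viability correction** (where the assay has a paired readout):
   `corrected = raw / paired_viability`, per well. CTG is the paired
   channel for cell-biological assays, renilla luciferase for the
   dual-luciferase HIF reporter. This removes death phenotypes from
   signalling readouts.
2. **Control normalization**: replicate means divided by the mean of the
   non-targeting control wells; the control itself maps to exactly 1.
3. **z-scores**: over the pooled-reagent gene set of the stratum,
   `z = (r − mean(r)) / sd(r)` with the sample (n−1) standard deviation;
   controls are excluded. Vehicle and ligand conditions of reporter assays
   are separate strata.

Two orderings of steps 1–2 are defensible from the screen's description;
the default corrects each well first and then normalizes, the only order in
which both the control ratio and the per-well correction semantics hold
simultaneously. `correct_after_normalize = TRUE` gives the alternative
(dividing the control-normalized assay ratio by the control-normalized
viability ratio). z-scores are computed on ratios by default; `log_ratios =
TRUE` uses log2 ratios. With fewer than 3 genes a stratum has no meaningful
spread and z-scores are not assigned; a zero-spread stratum yields all-zero
z with a warning.

Transfection QC uses
$\mathrm{efficiency} = 1 - L^{siUBB} / L^{siCTRL}$, the viability
signal lost on transfecting siRNA against essential ubiquitin-B.

## Hit-calling rules

* **Cell-biological**: a pool is an outlier at z > +2 (apoptosis — caspase
  activity rises) or z < −2 (viability, proliferation — signal falls), and
  becomes a hit only if an unpaired two-sided Student's t-test (pooled
  variance) of its corrected replicate values against the control wells
  gives P ≤ 0.05. Fewer than two replicates on either side makes the call
  `unresolved`. The t-test is evaluated for outliers, which is where the
  filter can change a call. No multiple-testing correction is applied at
  the screen stage.
* **Reporter**: positive if reduction > 60% in a single line, or > 30% in
  at least 3 lines ("more than two" read literally; `reporter_min_lines =
  2` gives the inclusive reading). For screens scored in both conditions,
  either basal or ligand-induced positivity suffices; provenance records
  which clause and condition fired. Reductions are computed on
  viability-corrected, control-normalized ratios.
* **Retest selection** uses the looser 1.5 s.d. cut in the assay's
  direction. The screen used both a 2.0 outlier threshold and a 1.5 s.d.
  retest criterion; the package exposes both rather than reconciling them.
* **Deconvolution**: a constituent single siRNA is *active* when its
  control-normalized effect reaches, by default, 50% of the pool's observed
  effect in the same direction (the notion of "active" is not standardized;
  the threshold is configurable and always recorded). A pool is *validated*
  — evidence of on-target activity — when ≥ 2 of its 4 singles are active.
* **KS comparison**: one gene's effects across lines versus all other
  genes', D = sup |F₁ − F₂|. The p-value follows the standard two-sample
  policy: the exact null distribution for small tie-free samples (identical
  to the full permutation distribution) and the asymptotic Kolmogorov
  distribution for larger ones. The asymptotic formula alone is visibly
  biased at n ≤ 8 — deviations near 0.05 from the permutation p — which is
  why the exact small-sample path is the default.

## Overlap statistics

`hypergeometric_upper_tail(N, K, n, k)` returns
$P(X \ge k) = \sum_{j=k}^{\min(K,n)} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$,
with the tail including $k$ itself (the standard enrichment convention),
evaluated in log space so tails near $10^{-11}$ and beyond remain accurate.
The universe must be supplied explicitly — defaulting it to $A \cup B$
silently inflates enrichment and is refused by design.

## What the simulator emulates — and what it does not

`generate_expression_data()` draws a Bernoulli presence truth per
gene×line, counts around `count_scale_present` (default 5,000) or
`count_scale_absent` (150) with multiplicative log-normal noise, and Ct
values around 28 (expressed) or 38 (silent) cycles for exactly the probes
that end up ambiguous. Defaults describe a screen-sized study: 150 CTA
probes, 19 candidate lines, half of the cells expressed.

`generate_screen_data()` lays out, per (assay, line) block: one pooled
reagent per gene, 8 non-targeting control wells, 2 siUBB wells (85% kill),
with 2 replicates by default (screen-scale figure legends report n = 2;
recovery analyses in this package use 3). Hits are planted per (gene,
assay) at `hit_fraction` (default 5%) **only where the gene is present** —
a phenotype requires expression of its target. A decrease-direction hit has
expected control-normalized ratio `1 − effect_size` (default 0.5);
increase-direction (apoptosis) hits use the log-symmetric factor
`1/(1 − effect_size)`, this package's choice since only the decrease side
is externally constrained. Reporter blocks get vehicle and ligand wells
with ligand mean = `induction_fold` (default 8) × vehicle mean; hits act on
the induced signal by default. Noise is multiplicative log-normal with unit
mean, parameterized by a CV (default 10%): plate-reader luminescence is
positive and right-skewed. Per-single activity flags are drawn once per
gene (probability 0.75 for hit pools, 0.05 otherwise); active singles
reproduce the pool's full effect, inactive ones none.

Random streams are split per (assay, line) block by hashing the seed with
the block key, so adding an assay never perturbs draws of existing blocks,
and a fixed seed makes every table bit-identical across runs.

Deliberately **not** simulated: plate-positional and edge effects (a
`plate` column is emitted as a hook, but no B-score/median-polish step
exists because none is part of the analysis being modelled),
transfection-efficiency heterogeneity across wells, partial single-siRNA
effect sizes, and count-level platform normalization. Passing recovery
tests therefore shows the decision rules are implemented and calibrated
correctly — not that they would be robust to spatial artifacts or reagent
heterogeneity in real plates.

## Numerical choices and problem sizes

* Sample (n−1) s.d. throughout; z-scores are exactly mean-0/sd-1 per
  stratum by construction (asserted to 1e−9).
* Greedy ties and exact-solver ties resolve to the lexicographically
  smallest line (set), making selections reproducible.
* The exact solver's subset cap defaults to 10⁶ subsets; the study-scale
  19-choose-11 instance runs in under a second via one matrix product.
* Recovery analyses in the test suite use 500 genes × 2 lines × 3
  cell-biological assays × 3 replicates over 20 seeds, and a 2,000-gene
  null screen; the deconvolution calibration uses 10,000 hit genes. These
  sizes give Monte-Carlo standard errors well below the tolerances they
  are tested against while keeping a full run in seconds.
* With a 5% hit fraction the hit genes inflate the stratum s.d., which
  *shields* null genes from the ±2 cut — measured false-positive rates are
  near zero while sensitivity stays above 0.99. At hit fractions ≳ 20% the
  same mechanism compresses hit z-scores toward the bulk and sensitivity
  degrades; z-scoring presumes hits are rare.

## Known limitations

* The per-line presence rule for unambiguous probes, the "active single"
  threshold, and the apoptosis-direction effect parameterization are this
  package's choices where the underlying screen design is silent; all are
  configurable and recorded in output provenance.
* The t-test at n = 2 replicates (the screen-scale default) is extremely
  low-powered; calls at that depth lean almost entirely on the z rule.
* `select_panel_greedy()` can return a strictly sub-optimal panel (~5% of
  random instances); use the exact solver when the instance allows.
* Unresolved presence cells are excluded (treated as absent) by panel
  selection and screen simulation; they are reported, not imputed.
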