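---
title: "Methods: cohort-level intrinsic disorder analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level intrinsic disorder analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcohort)
```

`idpcohort` measures intrinsic disorder at the level of a protein cohort:
per-residue propensity profiles, whole-protein binary order/disorder
calls, charge–hydropathy vs CDF phase-space classification, compositional
bias against a folded reference, and interval statistics over predicted
disorder-based binding sites. This vignette is the package's account of
the underlying models, the parameters that matter, the numerical
conventions, and what the shipped tests do and do not establish.

## The models

### Windowed propensity profiles

A residue scale maps each of the 20 standard amino acids to a number
(`scale_top_idp()` is signed, higher = disorder-prone;
`scale_kyte_doolittle()` is hydropathy min–max normalized to [0, 1] via
`(v + 4.5)/9`, higher = order-prone). The profile value at position *i* is
the mean scale value over a symmetric window (default width 21, the
conventional smoothing width for order/disorder propensity). The edge
policy is *shrink*: windows are truncated at the termini, so a profile has
exactly one value per residue — the alternative (undefined termini) would
corrupt per-protein content accounting. Ambiguity codes (X, B, Z, U, O)
are excluded from window means rather than imputed, because no scale
values exist for them; a window containing only ambiguity codes falls back
to the whole-sequence mean.

### Charge–hydropathy unfoldability

The CH-plot boundary line `|⟨R⟩| = 2.785 ⟨H⟩ − 1.151` separates natively
unfolded from compact proteins in (mean normalized hydropathy, mean
absolute net charge per residue) space. Applied over a sliding window,
`unfoldability(i) = 2.785 ⟨H⟩_w − |⟨R⟩_w| − 1.151`, negative = disordered.
The charge map is the formal-charge convention D, E → −1; K, R → +1;
everything else (including H) 0; pH-dependent charge models are out of
scope. Constants and scale values live in editable config files
(`inst/extdata/config/`), so exact published variants can be swapped in
without code changes.

`ch_point()` reports `dCH = |⟨R⟩| − (2.785 ⟨H⟩ − 1.151)` for the whole
sequence: the *vertical* (charge-axis) signed distance to the boundary,
not the perpendicular distance. The vertical convention was chosen because
it makes `dCH` exactly the negated single-window unfoldability, an
algebraic identity the test-suite checks to 1e−12 on random sequences — a
free cross-validation between the two modules.

### CDF classification

For a calibrated profile (scores in [0, 1], 0.5 = threshold), the
cumulative fraction `F(t)` of residues with score ≤ *t* is evaluated at
the boundary's threshold points; curves above the boundary are
order-like. Two statistics are reported deliberately: `dCDF`, the
unweighted mean of `F(t) − boundary(t)` (the x-axis of the CH–CDF plane,
positive = ordered), and the strict-majority-of-points binary call. They
can disagree for curves that hug the boundary, which is informative in
itself.

The packaged default boundary is a documented monotone diagonal
(`cdf_boundary_default.txt`); it is a placeholder calibration, not a
published predictor-specific boundary, and every test that asserts exact
numbers constructs its own explicit boundary instead of relying on it.
Users with a predictor-calibrated boundary drop it in via
`read_cdf_boundary()`.

### CH–CDF quadrants

Quadrants of the (dCDF, dCH) plane: Q1 disordered by CH only, Q2 ordered
by both, Q3 disordered by CDF only (putative molten globules / mixed
proteins), Q4 disordered by both (extended disorder). How exact zeros are
assigned is nowhere standardized; the package's documented tie rule sends
zeros to the ordered side of each axis, so (0, +) is Q2 and (0, 0) is Q3.

### Composition profiling

The fractional difference `(C_X − C_ref)/C_ref` compares a query set's
pooled residue fractions against a reference. By construction the value
is 0 at equality and −1 when the query lacks the residue entirely;
residues with zero reference fraction are reported as `NA` with a warning
rather than ±∞. The display order ranks residues by increasing
disorder-promoting potential (TOP-IDP order; configurable, since only the
grouping into order- and disorder-promoting blocks is canonical).

The bootstrap resamples *proteins*, not residues: the cohort is the
sampling unit that varies between studies, and residue-level resampling
would understate the between-protein variance. Intervals are percentile
CIs, deterministic given a seed. Whether published profile error bars of
this kind are bootstrap or analytic is generally unstated; bootstrap was
adopted as the assumption-free choice.

The shipped reference compositions (`composition_ordered_synthetic.txt`,
`composition_disordered_synthetic.txt`) are *synthetic stand-ins*, built
from average proteome frequencies biased toward the consensus
order-promoting (C, W, I, Y, F, L, H, V, N, M) and disorder-promoting
(A, G, R, T, S, K, Q, E, P, D) residue groups. They are config files
precisely so a curated reference (PDB-Select-25-derived, DisProt-derived)
can replace them verbatim.

## The annotated spliceosome cohort

`spliceosome_annotation()` loads the packaged table of 109 yeast
spliceosomal proteins: complex membership, molecular weight and length,
whole-protein disorder content under four predictors, and predicted
binding-site intervals (α-MoRFs and ANCHOR-indicated binding sites) in
1-based inclusive coordinates, the notation of the source table.

Data-quality conventions, all load-time decisions of this package:

- **Lenient mode is the default** because the printed table contains two
  malformed interval tokens (`1-0` on Ntr2, `55-52` on Prp16). They are
  flagged into separate columns and a validation report, excluded from all
  statistics, and never silently dropped; strict mode (for new data)
  raises instead.
- **Boundary content values** (exactly 0.10 / 0.30) fall in the
  *moderately disordered* class; the conventional strict inequalities
  (<10 %, >30 %) leave the boundaries open and a rule had to be fixed.
- **Carrier percentages round half away from zero** to integers, matching
  the precision such tables are reported at.
- The cohort is "all 109 rows": several proteins appear twice under
  distinct accessions (e.g. two Prp5 and two Spp381 entries), and both
  rows are kept as printed. One narrative length for Snu66 (687 residues)
  disagrees with the tabulated 587; the table value is authoritative for
  the fixture.
- Binarization of calibrated scores uses ≥ 0.5 (the threshold itself
  counts as disordered), the convention of the major per-residue
  predictors; signed windowed profiles use 0 as their natural threshold.

The directly countable statistics — 7/6/5/11 MoRFs for Prp3, Spp381,
Yju2, Snu66; 77 of 109 AIBS carriers (71 %); 61 % MoRF carriers — are
reproduced by the test-suite and `scripts/acceptance.R` from the table
alone. Statistics that would require proprietary per-residue predictor
output over the real sequences (long-region prevalence under a specific
neural-network predictor, the empirical CH–CDF quadrant split of the real
cohort, the content-class split) are *not* reproduction targets: the
machinery computes them from any supplied score files, but no claim is
made about matching numbers we cannot recompute.

## The synthetic generator

`synthetic_spec()` + `sample_cohort()` generate proteins as two-state
(ordered/disordered) Markov chains over residues: switch probabilities
`1/Lo`, `1/Ld` give geometric segment lengths with means `Lo`, `Ld` — the
simplest model producing "segments of disorder" without claiming any
generative mechanism for real sequences — and a stationary disordered
fraction `θ = Ld/(Lo + Ld)`, an identity the constructor enforces.
Residues are drawn i.i.d. from state-dependent compositions (defaults: the
packaged reference compositions, making the composition-recovery test
self-consistent); the emitted score is the state indicator, moving-average
smoothed (default window 5), plus Gaussian noise (default sd 0.1), clipped
to [0, 1].

Defaults are the package's study conditions: 200 proteins × 500 residues,
θ = 0.5, Ld = Lo = 40, σ = 0.1. Under these conditions the pipeline
recovers mean disorder content to well within ±0.05 and long-region
prevalence to within ±5 percentage points, and fully ordered / fully
disordered cohorts classify 100 % to the correct side of the CDF axis —
all recomputed, not asserted, by the acceptance checks.

Known distortions, documented rather than hidden: clipping slightly biases
scores near 0 and 1 toward the interior, and smoothing blurs segment
boundaries by up to half a window; the noiseless, unsmoothed mode exists
for exact identities (there, binarized content equals the true label
fraction exactly). What the generator does *not* emulate: realistic domain
architecture, sequence evolution, predictor-specific error structure, or
actual spliceosomal sequences — so passing recovery tests demonstrates
correctness of the machinery, not predictor accuracy on real proteomes.

## Reproducibility and numerics

All randomness flows through explicit integer seeds (`withr::with_seed`,
so the global RNG state is never clobbered). Identical seeds give
byte-identical cohorts, bootstrap intervals and pipeline reports; report
files are written atomically (temp file, then rename) and contain no
timestamps. Windowed means are computed by cumulative sums with
ambiguity-aware counts (O(n) per protein, exact for the shrink policy).
Test problem sizes (100-case property loops, cohorts of 200 × 500) keep
the full suite under half a minute while leaving sampling error far below
the asserted tolerances.

## Limitations

- No neural-network or energy-based predictor is reimplemented; imported
  score files are trusted after range/length validation.
- The default CDF boundary is a placeholder calibration (above).
- Formal charge at neutral pH only; no His protonation, no zwitterionic
  termini.
- The bootstrap treats the reference composition as fixed; uncertainty in
  the reference is not propagated.
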