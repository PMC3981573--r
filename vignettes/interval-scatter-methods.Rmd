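---
title: "Interval-summary scatter layouts for expression time courses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-summary scatter layouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timescatter)
```

## The problem and the model

Whole-profile clustering of gene-expression time courses groups genes by
similarity over the *entire* experiment. A biologically meaningful event
confined to a sub-interval — say, a rise then fall in expression between two
developmental stages — contributes little to whole-profile distance, so the
genes that share it are routinely scattered across clusters and the pattern
is lost. The layout implemented here attacks this directly: for a selected
time window $[s, e]$ of one condition, each gene $g$ is reduced to a single
point

$$x_g = v_g(e) - v_g(s) \qquad (\text{difference mode}), \qquad
  x_g = v_g(e) / v_g(s) \qquad (\text{fold-change mode}),$$
$$y_g = \operatorname{mean}\{\, v_g(s),\ v_g(t_k)\ \text{for } s < t_k < e,\ v_g(e) \,\},$$

where $v_g(t)$ is the gene's piecewise-linear (in recorded time) expression
curve and $t_k$ are the measured grid times. The y-axis is mean activity
over the window, the x-axis change in activity from window start to end.
Sweeping the window and recomputing produces an animation; genes sharing an
interval-confined pattern move coherently (a rise then fall appears as a
swing to the right of the plot and then to the left), which is what makes
unsuspected patterns findable. Difference mode works on any real-valued
data, including log-scaled and normalized values (where a difference *is* a
log fold change); fold-change mode is defined only for same-sign, nonzero
endpoints and is intended for unlogged data.

### Zero-duration windows

A window with $s = e = t$ is legal and useful ("park the selection on one
time point and press play"). Its $y$ is simply $v_g(t)$. A literal $x$
would be 0 everywhere, so the change-in-value is instead interpolated from
the nearest proper intervals before and after $t$: with one-step differences
$d_k = v_g(t_{k+1}) - v_g(t_k)$, the zero-duration $x$ at an interior grid
point $t_k$ is the unweighted midpoint $(d_{k-1} + d_k)/2$, the endpoint
grid points take their single flanking difference, and positions strictly
between grid points interpolate the grid values of $x$ linearly. We chose
the unweighted midpoint because the sources describing this layout specify
interpolation from the flanking intervals without stating weights; the
midpoint is the symmetric choice and keeps the sign of $x$ equal to the
local slope sign on monotone series. Fold-change mode applies the same
construction to log ratios and exponentiates.

### Snapping and queries

Interactive dragging produces unsnapped windows whose endpoint values are
display interpolations. So that *queries* never depend on display
artifacts, box queries are only evaluable on snapped selections: each
endpoint moved to the nearest measured grid time, ties resolved to the
earlier point. `snap()` is idempotent, and `evaluate_box()` refuses
unsnapped intervals.

## Missing values

Missing cells (empty, `NA`, or SOFT's `null`) are linearly interpolated *in
recorded time* wherever a measured value exists both earlier and later in
the same gene and condition; the non-uniform grids typical of developmental
series (e.g. days 4, 5, 6, 8, 16, 25, 30) make index-linear interpolation
misleading, which is why time-linear was chosen. Leading and trailing gaps
are never extrapolated: the gene is excluded from exactly those frames
whose window touches the uncovered span, and included elsewhere. Filled
values are flagged, and the flags propagate to marker classes so reduced
evidence gets reduced ink: a frame point whose window *endpoint* rests on a
filled cell is `xy_interpolated` (both coordinates depend on the fill), one
with only *interior* filled cells is `y_interpolated`, all others
`measured`. Whether interpolation should be linear is not dictated by the
data; linear is the assumption made here and recorded in this vignette.

## Transforms and provenance

Import-time rescaling options are per-value `log2`, `log10` and `cube_root`
(the odd-symmetric option usable on negative data), plus rescaling to a
reference: a named time point (e.g. `V10`), or a per-gene combination —
median, or an error-weighted mean across the gene's time points with
inverse-replicate-variance weights, falling back to equal weights for a
gene whenever any needed variance is unavailable (no formula for the
error weighting is prescribed by the sources; inverse variance is the
standard choice and is recorded in the provenance). On a log-scaled dataset
the reference is subtracted (reference maps to 0); on unlogged data values
are divided (fold change, reference maps to 1); which applies is determined
by the dataset's transform log, never guessed. Because analysts change
rescaling mid-session, transforms are never inverted: the dataset retains
its raw imported values and an ordered transform log, and any change
replays the log from raw (`replay_transforms()` reproduces the current
values bit-for-bit). Pattern files embed the canonical transform strings
(`"log2"`, `"rescale_to:V10"`, ...) so a collaborator reproduces
coordinates exactly.

## Patterns: rounding, simplification, algebra

A stored pattern is a Boolean expression (`AND`/`OR`/`NOT`) over box
queries plus the dataset id, the transform provenance, optional cached
result genes and annotations, serialized as versioned JSON with a canonical
expression text (operands of `AND`/`OR` are flattened and sorted, so
semantically equal patterns serialize identically). Two decisions the
serialized format records explicitly because the behavior is not otherwise
derivable:

* **Rounding grid.** Thresholds are restricted to rounded values so shared
  patterns are communicable. The step is span/100 floored to a 1–2–5
  "nice" step (span 10 → 0.1; span 7 → 0.05), matching typical axis-label
  granularity; rounding is idempotent.
* **Bounds are closed** (`min ≤ v ≤ max`), so genes sitting exactly on a
  threshold are included, deterministically.
* **Negation never selects genes for lacking data**: `NOT` complements
  against the genes included (not frame-excluded) in its operand's frames,
  and excluded genes match no leaf.

Edges at or beyond the data extent are dropped when a query is stored
(`simplify_query()`), leaving only the threshold the user actually set;
dropping *all* edges would select everything and is refused.

## Grouping overlays

Up to four gene groupings can be overlaid simultaneously, colored from a
fixed four-slot qualitative palette (Brewer-style, embedded as constants so
rendering needs no external lookups). The overlay geometry is the convex
hull of the member points, offset outward by a padding (default 2% of the
larger axis span) via a sampled disc Minkowski sum, then smoothed by
Chaikin corner-cutting. Concave or alpha-shape outlines were considered and
rejected: the convex construction is deterministic, parameter-free beyond
the padding, and its known cost — occasionally circling non-members — is
inherent to this encoding and accepted. Members are strictly inside the
outline on every animation frame because the outline is recomputed per
frame.

## The synthetic-data generator

All tests and the acceptance script run on generated data, so what the
generator does and does not emulate bounds what passing tests show.
Background series are Gaussian random walks with a per-gene drift
(step $\sim N(\mu_g, \sigma_w^2)$, $\mu_g \sim N(0, \sigma_d^2)$) plus
i.i.d. observation noise per replicate, replicates collapsed by mean at
import. The drift term is deliberate: it gives genes large, smooth
whole-profile differences — so baseline hierarchical clustering groups by
overall trend and splits a planted interval group — while per-step changes
stay small and, being monotone, cannot mimic the rise-then-fall *reversal*
that a two-box interval query keys on. A pure driftless walk cannot satisfy
both requirements at once.

Defaults (chosen once, by the margin analysis below): per-replicate
observation noise sd `noise_sd = 0.2` (the "baseline noise scale" in which
effects and thresholds are expressed), 4 replicates (effective noise sd
0.1), walk step sd 0.05, drift sd 0.06 per step. A planted group of effect
size 6 then has peak height 1.2 while a background gene's one-step change
has sd $\sqrt{0.05^2 + 2 \cdot 0.1^2} \approx 0.15$; the documented query
threshold of 3 × noise scale = 0.6 sits roughly 4 of those sd below the
planted signal and 4 above the background, so exact recovery
(precision = recall = 1) holds by construction at effect/noise ≥ 6 and
degrades monotonically as noise grows. What the generator does **not**
emulate: intensity-dependent variance, probe effects, correlated gene
modules, heavy-tailed outliers. Passing tests demonstrate the machinery,
not robustness to those realities.

Two ready-made shapes mirror published study geometries: `mammary17`
(8,500 genes, 17 time points across four developmental stages whose
repeating per-stage day values are mapped onto one strictly increasing
pseudo-time axis, stage-prefixed labels `V10 ... I20` retained — required
by the strict time-monotonicity invariant) and `osteoblast7` (20,000
genes, days 4–30, growth-factor vs control conditions, with planted
"early rising", "downward" and "upward" groups).

## Numerical choices, degenerate inputs, limitations

* Grid-time matching uses an absolute tolerance of 1e-12 (1e-9 for
  snap-status checks); time grids are user units (days), order unity to
  tens, where these tolerances are far below measurement resolution.
* The unsnapped mean-activity $y$ uses the sample set
  {endpoints + interior grid values}; when a sweeping endpoint crosses a
  grid time the sample set gains or loses one member, so $y$ takes an
  $O(1/T)$ step there. Between crossings both coordinates are continuous;
  $x$ is continuous everywhere. A time-weighted (trapezoidal) mean would be
  globally continuous but was rejected so that the snapped value equals the
  plain mean of recorded points.
* Zero-duration layout needs at least two covered time points; genes with
  fewer are excluded, and a condition with fewer than two grid points is
  rejected at construction.
* Replicate collapsing at import is the arithmetic mean ignoring missing
  replicates (all-missing slots stay missing); the error-weighted options
  are reference-rescale combination rules, not collapse rules.
* Rendering is a pure function of (frame, config): reruns are
  byte-identical PNGs, which the suite asserts. Animations default to a
  fixed global axis extent so per-frame autoscaling cannot destroy motion
  perception.
* Problem sizes used by the test suite and acceptance script — 200 × 10 for
  the layout oracle, 5,000 genes for planted-pattern recovery plus
  clustering baseline, 50 frames for outline containment, 50,000 × 12 for
  the scale smoke test — were chosen as the smallest sizes at which the
  properties are meaningfully exercised.
* Known limitations: no model-based imputation (k-NN/SVD) or smoothing;
  no MAGE-TAB parsing (explicitly refused rather than misparsed); no GIF
  assembly (numbered PNGs only); fold-change mode is undefined across sign
  changes and is refused there rather than patched.

## A worked sweep

```{r example}
spec <- fixture_spec(
  n_genes = 500, times = 0:9,
  planted = list(list(name = "swing", n = 30, interval = c(3, 5),
                      shape = "rise_fall", effect = 6)),
  seed = 7)
fx <- generate_fixture(spec)
ds <- fx$dataset

# the planted rise-then-fall is invisible to a full-profile view but
# separates cleanly in the two flanking interval frames
th <- 3 * spec$noise_sd
hits <- evaluate_expression(ds,
  q_and(box_query("c1", 3, 4, x_min = th),
        box_query("c1", 4, 5, x_max = -th)))
length(hits)
setequal(hits, fx$truth$groups$swing$members)
```
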