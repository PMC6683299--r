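---
title: "Comparing scanpaths with transition distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing scanpaths with transition distributions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazetrans)
```

## The problem

When clinicians read a 12-lead ECG, where they look — and in what order —
carries information about their reasoning. Summary eye-tracking metrics
(fixation count, mean fixation duration) often fail to separate groups that
clearly behave differently, because they discard the *sequence*. This
package compares groups of viewers through the distribution of their gaze
*transitions* between areas of interest (AOIs), at two granularities:

* **lead AOIs** — the semantic sub-panels of the stimulus (the 12 leads and
  a rhythm strip), drawn top-down from a layout file;
* **grid AOIs** — a uniform grid whose cell size is derived bottom-up from
  density clustering of the pooled fixation points, fine enough to expose
  *within*-lead behaviour (attention to parts of the waveform).

The central question a test answers: do two groups of participants (for
example, those who saw the patient's clinical history before the ECG and
those who did not, or those who interpreted it correctly and those who did
not) move their eyes between AOIs according to different distributions?

## The statistic

For each group, all scanpaths on a stimulus are mapped to AOI label
sequences and pooled into a directed transition count matrix; entry
$(i, j)$ counts consecutive fixation pairs moving from AOI $i$ to AOI $j$,
including self-transitions (dwelling "within" an AOI). Sequences never
bridge trials. The matrix, normalised by its grand total and flattened over
the $k = L^2$ directed pairs, is a probability vector; two groups are
compared with the Hellinger distance

$$H(P, Q) = \frac{1}{\sqrt{2}}\sqrt{\sum_{i=1}^{k}
  \left(\sqrt{p_i} - \sqrt{q_i}\right)^2},$$

which is symmetric, bounded in $[0, 1]$, zero iff $P = Q$ and one iff the
supports are disjoint.

**Joint versus row-wise.** Whether the comparison should use this flattened
joint distribution or the rows of the row-stochastic Markov chain
(conditional distributions, averaged) is genuinely open; the joint
flattening matches the single-vector form of the distance and needs no
convention for empty rows, so it is the default. `hellinger_rows()`
provides the row-wise mode.

**Outside fixations.** Under the lead scheme, fixations landing in no lead
map to an explicit `outside` label that participates as a regular state.
Excluding it would silently change $k$; exclusion is available by passing a
layout whose regions tile the canvas.

## Inference: participant-shuffling permutation test

Observed group distance in hand, participants are pooled and reassigned
uniformly at random into groups of the *original* sizes $(n_1, n_2)$ —
sizes are preserved because post hoc accuracy groups are typically unequal
— and the distance is recomputed for each of the $N$ shuffles (default
10,000). The summary is:

* $M$, $SD$ — mean and standard deviation of the null distances;
* $d = (H_d - M)/SD$ — the null-standardised deviation of the observed
  distance (defined as 0 when $SD = 0$ and $H_d = M$);
* $p = (1 + \#\{H^{null} \ge H_d\}) / (1 + N)$ — the add-one empirical
  p-value, which is never zero; its floor at 10,000 shuffles is
  $1/10{,}001$, reported as $p < 0.001$.

Shuffling operates at the participant level (a participant's scanpaths
travel together), which is the exchangeable unit in a between-group
comparison of repeated-measures data.

**Condition filters follow the group slot.** The primary comparison
contrasts the history-first participants' *history-condition* scanpaths
with the history-last participants' *no-history* scanpaths — each group's
first exposure, so the history manipulation is between subjects. Under
permutation, a reassigned participant contributes the trials of its new
slot; attaching the filter to the participant instead would make the null
non-exchangeable.

**Accuracy splits.** Post hoc accuracy comparisons take participants
correct in *both* conditions versus incorrect in *both*, per stimulus;
participants mixed across conditions are excluded. This yields the unequal
group sizes such tables report, and keeps the two groups cleanly
interpretable.

## Data-driven grid derivation

1. Pool the fixation points of one stimulus across all participants and
   both conditions (both comparison groups must share one support).
2. `select_epsilon()`: sort each point's distance to its `min_pts`-th
   nearest neighbour (default `min_pts = 5`) and take the knee of the
   curve — the point of maximum perpendicular deviation from the chord
   joining its endpoints. Deterministic; flat curves (uniform density)
   return a plateau value.
3. `dbscan_cluster()`: a self-contained deterministic DBSCAN. A point is
   core when its closed eps-ball holds at least `min_pts` points; clusters
   are density-reachability components; border points claimed by several
   clusters go to the first reaching core point in (x, y, index) scan
   order, making results independent of input order up to relabeling.
4. `derive_grid()`: the grid's cell side is the clustering's *optimal
   diameter* and the grid is anchored at the canvas origin with
   `ceiling(extent / side)` cells per axis, edge cells truncated.

Two diameter rules are exposed. The default (`"eps"`) uses the selected
radius — the natural density scale. With very dense pooled clouds
(hundreds of fixations per cluster) the k-distance knee sits at the
*intra*-cluster spacing and yields a very fine grid; the alternative
`"mean_cluster"` (mean of each cluster's maximal pairwise point distance)
then recovers the cluster-sized scale. Which is "the" optimal diameter is
not decidable from the method's description alone; both are first-class
options and the choice is a reported parameter of any analysis.

Grids are derived per stimulus (not globally): stimuli differ in where
fixations cluster, and the per-stimulus choice only requires that both
*groups* share a support, which they do by construction.

## The synthetic study generator

`simulation_scenario()` / `simulate_study()` generate complete synthetic
studies with the structure the analysis assumes, so the whole pipeline is
testable without any recorded data:

* **Design** — 31 participants by default, assigned alternately to
  history-first (16) and history-last (15) order groups (counterbalancing),
  9 stimuli each viewed in both conditions (558 trials).
* **Scanpaths** — each order group follows its own Markov chain over the
  generating AOIs. The default chain is a "reading" chain: probability 0.5
  of staying within the current lead, 0.3 of advancing to the next lead in
  print order, the rest spread uniformly — a caricature of systematic ECG
  reading. The default group-2 chain is a magnitude-0.25 perturbation of
  group 1's, so the default world contains a real transition difference.
* **Fixations per trial** — negative binomial with mean 60 and dispersion
  10, floored at 2 (every trial contributes at least one transition).
  A trial of a few dozen fixations with no time limit is typical of
  whole-ECG interpretation; the value is a scenario input, not an estimate.
* **Coordinates** — 2-D Gaussian around the AOI centre (sd 18 px),
  truncated to the AOI rectangle by inverse-CDF sampling. Truncation makes
  the generating AOI exactly recoverable by assignment, which is what lets
  tests treat AOI labels as ground truth. A field dataset has leakier
  scatter; nothing in the analysis depends on the truncation.
* **Durations** — log-normal (meanlog $\log 250$ ms, sdlog 0.4): positive
  and right-skewed like real fixation durations; onsets accumulate
  durations plus a 30 ms saccade gap.
* **Responses** — per-group, per-stimulus Bernoulli accuracy (default
  0.64 everywhere); correct trials emit the canonical diagnosis text,
  incorrect ones an umbrella term ("arrhythmia") that the scorer must
  reject.
* **Perturbation** — `perturb_chain()` mixes each row with its own cyclic
  shift: $(1-m)\,\text{row} + m\,\text{shift}$. Deterministic, magnitude 0
  is the identity, magnitude 1 the shifted rows — a simple dial for power
  studies.

What a green simulation-based test establishes: the statistic, the null,
and the pipeline behave correctly *given* Markovian scanpaths with
recoverable AOIs. What it cannot establish: anything about tracking noise,
drift, calibration error, non-Markov gaze dynamics, or the ecological
validity of any particular chain.

## Numerical and degenerate-input choices

* Coordinates are screen pixels, origin top-left, y downward; all
  rectangles and grid cells are half-open $[x_0, x_1) \times [y_0, y_1)$,
  so point-in-region tests are unambiguous and the grid partitions the
  canvas exactly.
* Out-of-bounds fixations are dropped on read by default (clamping is the
  config alternative); the count is logged. Trials left with zero
  fixations simply contribute no transitions; a *group* with zero
  transitions is an explicit inference error naming the group.
* `hellinger()` returns the boundary values exactly: bit-identical inputs
  give 0 and disjoint supports give 1, with no floating-point residue.
* Permuted groups are compared through the Bhattacharyya identity
  $H = \sqrt{1 - \sum_i \sqrt{p_i q_i}}$ on the union support restricted
  to pairs observed anywhere in the data (unobserved pairs contribute
  nothing to either sum) — an exact sparsification that keeps 10,000
  shuffles fast on fine grids.
* Per-cell seeds are derived from the master seed and the (stimulus,
  scheme, comparison) identity by a stable 31-bit string hash, so any
  cell's result is independent of execution order and the whole run is
  bitwise reproducible.
* McNemar uses the continuity-corrected statistic with the correction
  floored at zero, $\chi^2 = \max(0, |b-c|-1)^2/(b+c)$, df = 1; symmetric
  discordance therefore gives $\chi^2 = 0$, $p = 1$. Wilcoxon signed-rank
  drops zero differences, mid-ranks ties, and is exact for $n \le 25$
  without ties, otherwise normally approximated with tie and continuity
  corrections (verified against `stats::wilcox.test`).
* Response scoring is normalised exact-set membership (case, whitespace,
  trailing periods), not fuzzy matching: every scoring decision is
  auditable from the answer key.

## Known limitations

* Only axis-aligned rectangular AOIs; no overlapping or free-form
  data-driven AOIs (the uniform grid exists precisely to avoid them).
* First-order transitions only; no higher-order models or string-edit
  scanpath comparison.
* The DBSCAN implementation is quadratic in the number of points — ample
  for fixation clouds (thousands of points), not meant for raw gaze
  samples. `select_epsilon()` thins clouds beyond 4,000 points
  deterministically before the all-pairs computation.
* The analytic (asymptotic) null of the Hellinger distance is out of
  scope; inference is purely by resampling.
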