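---
title: "Methods: scoring, grouping and evolution analysis of coached cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, grouping and evolution analysis of coached cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortcoach)
```

`cohortcoach` is a headless analytics engine for virtual-coaching programs
in older-adult cohorts. It answers three questions a coaching caregiver or
researcher asks of program data: *How active was each participant, day by
day, in each coaching dimension?* *Which participants resemble each other
at baseline, so they can receive comparable coaching plans?* and *Did
in-program activity in one dimension go along with assessed improvement in
another?* This vignette describes the models and procedures behind each
answer, the tunable parameters, the synthetic cohort generator the test
suite relies on, and the package's known limitations.

## The data model

Two bodies of data are analyzed together:

* **Assessments.** A caregiver-supervised battery administered at two
  timepoints (baseline and final, about five months apart): the Fullerton
  Functional Fitness items (chair stand, arm curl, two-minute step, chair
  sit-and-reach, back scratch, foot up-and-go) for the Physical dimension;
  MoCA, MCS-A and MAI for the Cognitive dimension; and the MNA mini for
  the Nutritional dimension. Each variable carries an *orientation*: +1
  when a higher score is better and -1 for the timed foot up-and-go test.
  Variables measured in two trials are reduced to the best result
  (orientation-corrected extremum) at ingestion. No social assessment
  instrument is part of the battery, so the Social dimension has daily
  activity but no assessed improvement.
* **Daily questionnaires.** Self-reported items answered every day over a
  150-day window, each belonging to one of the four coaching dimensions
  (Physical, Cognitive, Social, Nutritional) with a signed expert-assigned
  weight. Three physical-activity items and the five food-group items are
  administered three times a day. A few items ("Have you been outside your
  house?", "Have you been to a shop?", "Have you eaten one or more meals
  outside of home?", "Have you prepared your own food at least once?")
  count toward two dimensions; they are stored once, under a shared answer
  key, and feed both dimensions with each dimension's own weight.

Answers are encoded as nonnegative indices: Yes/No as 1/0, ordered scales
by rank with the smallest/least category at 0, and free counts clipped at
the item's cap (4 where stated; a configurable 10 for water glasses and
alcohol units, where no cap is stated). Two ordered scales have no
intrinsic "smallest" pole — the social-preference item ("Decrease a lot"
... "Increase a lot") and the satiety item ("I ate too little" ... "I ate
too much"). We code both ascending from the printed first pole
("Decrease a lot" = 0, "I ate too little" = 0); because the scale
definition lives in the question specification table, either direction
can be configured per question without touching code.

Missing answers are recorded as missing at ingestion, never silently
zeroed; the scoring step decides their contribution (below).

## Daily dimension activity

The daily activity level of dimension $D$ for one participant is the
weighted sum of encoded answers over that dimension's questions,

$$\mathrm{activity}_D(\mathrm{day}) \;=\; \sum_{i \in D} w_i \, a_i,$$

with $w_i$ the signed question weight and $a_i$ the encoded answer index.
Thrice-daily questions contribute one term per administration, i.e. the
day's *total* activity is summed, not averaged — a deliberate choice: the
weighted sum ranges over question instances, and summing keeps a
twice-as-active day twice as large. Missing answers contribute 0, and each
participant-day-dimension cell records a *completeness* (answered slots /
expected slots) so that days below a configurable completeness floor can
be dropped (default floor 0: keep everything, since zero-filling biases
scores down but preserves the day ordering that trajectory smoothing
needs).

The score is linear in the weights, a weight-0 question can never change
it, and raising the answer of a negative-weight question can only lower
it; all three properties are enforced by the test suite.

## Robust standardization

Before participants are compared, every assessment variable is
z-standardized so that no variable dominates the distance merely through
its units. The moments are fitted robustly on the *baseline* values:
values outside the Tukey fences $[Q_1 - k\,\mathrm{IQR},\; Q_3 +
k\,\mathrm{IQR}]$ (linear-interpolation quartiles, $k = 1.5$; both
configurable) are excluded from the mean/sd fit, then every value —
including the excluded ones — is transformed with the fitted moments.
Outlying participants are therefore not discarded, only prevented from
biasing the scale. Final-assessment values are transformed with the same
baseline-fitted model, so pre/post change is expressed on one scale;
fitting the two timepoints jointly was the alternative, but baseline-only
fitting keeps the grouping (which uses only the first assessment) and the
change scores on the same footing. The sample (n−1) standard deviation is
used. A variable whose Tukey-clean subset has (near-)zero spread is
flagged *degenerate*: it standardizes to 0 with a warning and is excluded
from distances.

## Grouping by weighted similarity

Participants are compared on their standardized baseline vectors with a
weighted Manhattan distance

$$d(u, v) \;=\; \sum_{i=1}^n w_i\,|u_i - v_i|,$$

where the weights come from a five-level importance vocabulary — very low
(0), low (0.5), medium (1), high (1.5), very high (2) — set per coaching
dimension and overridable per variable. If a pair of participants shares
only part of the variable set (missing values), the sum over the shared
variables is rescaled by (total weight)/(shared weight), a pairwise-
deletion convention that keeps distances comparable across pairs.

Groups are formed by hierarchical agglomerative clustering with *average
linkage* (UPGMA): starting from singletons, the pair of clusters with the
smallest mean pairwise inter-cluster distance is merged, and the merge
height records that mean. Average linkage is monotone, so the dendrogram
heights never invert. The agglomerator is written in this package (the
incremental size-weighted update is algebraically exact for average
linkage) and is verified, merge by merge, against an exhaustive
brute-force agglomerator on hundreds of random instances, and against
`stats::hclust(method = "average")` as an independent cross-check. Ties
are broken on the lowest pair of cluster creation ids, which makes the
merge sequence deterministic and oracle-matchable.

Cutting the dendrogram at a dissimilarity threshold yields the flat
grouping. The default threshold semantics is a *fraction of the maximum
merge height* — a normalized dissimilarity in (0, 1], which is how a
threshold like 0.98 on standardized data is most naturally read — with an
absolute mode and an exact-`k` mode also provided, because the analysis
workflow (pick a cut by inspecting the dendrogram, the group sizes and the
radar profiles) sometimes wants each. Cluster ids are assigned by
decreasing size, so Group 0 is always the dominant group. Clusters
smaller than `min_cluster_size` (default 3, configurable) are flagged as
*outlier groups*: in practice groups of 1–2 participants are individuals
too different from the rest to support group-level insight, and they are
excluded from insight extraction but never from the output.

## Improvement estimation and trajectories

A participant's improvement in a dimension is the unweighted mean, over
that dimension's assessment variables, of the orientation-corrected
standardized change:

$$\mathrm{change}_D \;=\; \frac{1}{|V_D|}\sum_{v \in V_D}
\mathrm{orientation}_v \,\bigl(z_v^{\mathrm{final}} -
z_v^{\mathrm{baseline}}\bigr).$$

Changes within $\pm\varepsilon$ of zero (default $\varepsilon = 0.1$
standardized units, configurable — a band below which a change is noise
rather than signal) are categorized *same* (yellow); otherwise the sign
selects *improved* (green) or *worsened* (red), with a shade in $[0,1]$
equal to $|\mathrm{change}|$ relative to the cohort's largest
$|\mathrm{change}|$ in that dimension, so the darkest line in a view is
always the largest mover.

Daily activity series are smoothed with a centered moving window of odd
length $n$ (statistic mean, max or min). The window shrinks at the series
boundaries rather than padding, missing days are excluded from the window
statistic, and an all-missing window stays missing. A trajectory view
overlays the smoothed series of every member of a group (or of the whole
cohort), colored by each member's improvement in a — possibly different —
dimension; this is the view that reveals, e.g., whether members who kept
nutritional activity high improved physically. Range filtering (the
parallel-coordinate brushing operation) subsets participants whose change
lies inside closed intervals per dimension, on the standardized change
scale.

## The synthetic cohort generator

Because the analysis stages must be testable without any study data, the
package ships a generator that emulates the structure the pipeline
assumes: 68 participants by default, 150 days, two assessments, four
dimensions. Its moving parts:

* **Groups.** Each planted group has a proportion, per-variable baseline
  mean shifts in standardized units, and a mean daily activity level per
  dimension. Raw assessment values are produced as `mean + sd * z` with
  per-variable location/spread chosen at realistic instrument magnitudes
  (e.g. chair-stand repetitions around 12.5 ± 4.6, MoCA around 25.5 ± 3);
  within-group z spread is 1. The default configuration plants two main
  groups that differ chiefly in nutritional level (and slightly
  cognitively), the larger one lower — the constellation under which the
  group-conditional evolution analysis is informative — plus 4 outlier
  participants shifted 6 standardized units with random sign per
  variable, so they resemble neither group nor each other.
* **Daily activity.** Each participant's daily target score per dimension
  is their personal level (group level + N(0, 1.5)) plus stationary AR(1)
  noise (ρ = 0.6, innovation sd 2 — autocorrelated enough that a 7-day
  moving window visibly denoises, the regime smoothing is meant for),
  clamped to the dimension's representable score range. Targets are then
  inverted into valid answer indices by greedy allocation, strongest
  weights first (negative weights absorb negative residuals); any valid
  inverse is acceptable because only the encoded weighted sum matters
  downstream. Questions shared between dimensions are allocated by the
  first dimension processed and contribute fixed terms to the later one.
  A group activity level outside the representable range is rejected with
  the offending dimension named.
* **Effects.** A planted effect (group g, activity dimension A →
  assessment dimension B, coefficient β) adds β × (within-group
  standardized mean activity in A) to the member's standardized change in
  B; changes otherwise are N(0, 0.3). Final raw values apply the change
  through each variable's orientation. Two-trial variables emit a
  plausible worse second trial so the best-of-two reduction is exercised
  end to end.
* **Missingness.** Every single answer is dropped independently with
  probability 0.05 by default.

Everything is deterministic under the configured seed, and the planted
truth (group labels, outlier flags, effect coefficients, per-participant
mean activity) is exported alongside the data.

What the generator does *not* emulate: real marginal answer
distributions (allocation is greedy, so a participant may report all
activity in one question), floor/ceiling effects of the instruments,
informative missingness, dropout, or drift in activity level over the
program. Passing tests therefore demonstrate that the pipeline recovers
structure *of the kind it models* — planted groups, planted
activity-improvement links — not that such structure exists in any real
cohort.

## Numerical and design choices

* Quartiles by linear interpolation (type 7), fence multiplier 1.5;
  the robust-fit guard against an empty in-fence subset is unreachable
  for $k \ge 0$ but present.
* Agglomeration tie-break: lowest (creation-id) pair, lexicographically.
* Degenerate variables standardize to 0 and never enter distances.
* The dendrogram cut uses `stats::cutree` on the package's own tree
  (the tree structure is the standard `hclust` form), and Newick export
  goes through `ape`.
* Improvement aggregates per-variable changes by *unweighted* mean within
  a dimension; the similarity weight vocabulary deliberately does not
  leak into improvement, which should reflect the instruments, not the
  user's grouping priorities.
* Scale directions for the preference/satiety items, count caps for
  uncapped count items, ε, k, the smoothing window, and the minimum
  cluster size are all configuration, with the defaults above.

Problem sizes in the test suite are chosen to keep the full suite around
three minutes: brute-force oracle comparisons run at n ≤ 8 over hundreds
of random instances, end-to-end checks at the full 68 × 150 cohort scale,
and the multi-seed effect-recovery property over 50 generator seeds.

## Known limitations

* No imputation: missing answers contribute zero activity, which biases
  low-completeness days downward (mitigate with the completeness floor).
* No statistical tests of group differences are performed; views and
  associations are descriptive.
* The improvement scale mixes instruments via standardization; a
  dimension's change is only as comparable as the baseline-fitted moments
  are stable.
* Only average linkage is built in (the agglomerator is the package's
  contribution and the one the workflow uses); other linkages would need
  their own update rules and oracles.
* The Social dimension has activity but no assessment variables, so
  improvement in it is undefined and requests for it are rejected.
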