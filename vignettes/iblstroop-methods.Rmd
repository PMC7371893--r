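---
title: "Modelling Stroop performance in DMD with instance-based learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Stroop performance in DMD with instance-based learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iblstroop)
library(dplyr)
```

## The scientific problem

Duchenne muscular dystrophy (DMD) is caused by mutations in the dystrophin
gene, whose 79 exons also host internal promoters for short brain-expressed
isoforms.  One of them, Dp140, is transcribed from a promoter around exon 44:
copy-number variants (CNVs) confined upstream of it leave the isoform intact
("Dp140 positive"), while CNVs reaching exon 44 or beyond are predicted to
abolish it ("Dp140 negative").  Dp140-negative boys show broader cognitive
involvement, particularly on working-memory measures.  `iblstroop` packages a
computational account of one such measure — timed performance on the Stroop
Color and Word Task (SCWT) — together with the surrounding analysis pipeline:
a synthetic-cohort generator, neuropsychological index scoring, Dp140
classification of CNVs, and a group-comparison statistics report.

## The memory model

Performance is modelled with instance-based learning on ACT-R's declarative
memory equations.  Task knowledge is a set of *instances*, each a
Situation–Decision–Utility record whose situation slots are a `color` and a
`word` attribute.  The activation of instance $i$ probed at event $t$ is

$$A_i = B_i + \sum_{l} P_l\, M_{li} + \varepsilon_i,$$

with the base level reflecting recency and frequency of past use,

$$B_i = \ln \sum_{t_j} (t - t_j)^{-d},$$

where the $t_j$ are the instance's past retrieval events counted in *event
time* (each retrieval attempt advances the clock by one; seconds appear only
in latencies), and $d \in [0, 10]$ is the decay.  $M_{li} \in [-1, 0]$ is the
partial-matching similarity between the probe's slot $l$ and the instance's
value (0 for a match, $-1$ for a full mismatch by default; a graded
similarity table is optional), weighted by the penalty $P_l$ (default 1).
The noise is logistic, $\varepsilon = s \ln\{(1-u)/u\}$, $u \sim U(0,1)$,
with scale $s \in [0, 10]$.  Retrieval returns the activation arg-max, and
its latency is

$$RT = F e^{-f A},$$

seconds, with latency factor $F \in [0,1]$ (fixed at its default 1 in all
fits) and latency exponent $f \in [0,1]$.  With noise off, ties go to the
earliest-created instance, which makes every simulation reproducible.

Two published operating points anchor the package
(`group_params()`): control $F=1, f=0.003, d=5, s=2$ and DMD (Dp140
negative) $F=1, f=0.005, d=4, s=2$.

## The simulated task

A session presents three 100-item sheets, 45 s each, in the standard order:

* **word** sheet — colour words in neutral ink; the probe requests the word;
* **color** sheet — neutral tokens in coloured ink; the probe requests the ink;
* **color-word** sheet — always-incongruent colour words in a different ink;
  the probe requests the ink *with the printed word as a context slot*, so
  partial matching penalises the colour-naming instance.  This penalty is the
  model's Stroop interference: colour-word naming is strictly slower per item
  than colour naming from the same memory state.

The memory store starts with one word-reading and one colour-naming instance
per colour (a baseline event each) — pre-experimental familiarity, without
which the first sheet would have nothing to retrieve.  Every attempt leaves
its retrieval event in memory, so completions on the first two sheets are
exactly the instances whose retrieval times the colour-word sheet inherits.
Item time is $RT$ plus a fixed non-retrieval overhead `t_nonretrieval`.  Its
default is 0 s: with $F = 1$ the latency law alone yields roughly 44–46
word-sheet items in 45 s at the control operating point, inside the 45–60
band implied by the published group counts, and any positive overhead would
leave that band.  A sheet stops when the next item would exceed the budget;
the per-sheet counts W, C, CW and the effect scores
$C - CW$, $CW/W$, $CW/C$ summarise a session.

The simulator has two engines: a transparent pure-R reference and a compiled
(Rcpp) loop used by default.  They consume identical random draws and are
tested to produce bit-identical sessions; the compiled engine exists because
the grid search below evaluates ~27,000–100,000 sessions per fit.

## Fitting and its identifiability limits

Fitting is deliberate enumeration ("hit and trial"): `grid_fit()` simulates
`sessions_per_point = 20` sessions at every lattice point (default: $d, s$ by
1 over $[0,10]$, $f$ by 0.001 over $[0, 0.01]$ — the lattice the published
values sit on — $F$ fixed at 1), averages per-sheet counts, and minimises the
fitness, the mean absolute count deviation from the human per-sheet means;
the mean square deviation (MSD) is reported both over sheet means and over
individual sessions.  All lattice points reuse the same per-session seeds
(common random numbers), so with noise off the surface is deterministic, and
session $i$ of a cohort is identical whatever the cohort size.  Ties are
broken lexicographically by $(d, s, f, F)$.

`recover_params()` extends the common random numbers to the target cohort
itself: the generating point then reproduces its own data exactly (fitness
0), and the experiment probes *grid identifiability* — whether any other
point matches the target equally well.  Two structural limits emerged and
are worth stating plainly:

* **The latency exponent $f$ is only weakly identifiable.**  Sheet counts
  are integers; with $F = 1$ and $f \le 0.01$ an $f$-step of 0.001 changes
  per-item time by ~0.1%, which rarely flips any 45-s count.  Zero-fitness
  ties therefore extend across several $f$ values and the lexicographic
  tie-break returns the smallest.  Decay $d$ and noise $s$ recover exactly
  at both published operating points; $f$ recovers only up to its tie set.
* **The attainable count space is narrow.**  With $F = 1$, per-item time is
  pinned near 1 s for every admissible parameter value, so simulated sheets
  complete ~38–46 items and W, C and CW differ by a few items at most.
  Human groups show W ≈ 52–60 versus CW ≈ 24–28.  Both groups' targets are
  therefore far outside the model's reachable set, fitted MSDs are large for
  both, and which group fits *worse* depends on where the sampled cohort
  means happen to fall — the MSD ordering between groups is not a stable
  model prediction at these parameter ranges.  The acceptance suite states
  this check at face value and it fails; the grid trace returned by
  `tidy()` on a fit makes the underlying surface easy to inspect.

## The synthetic cohort generator

No subject-level data are distributed, so cohorts are generated to the
published group summaries (`group_profiles()`: control $n=80$, Dp140
positive $n=14$, Dp140 negative $n=53$).  Choices:

* **Truncated-normal marginals, independent across measures.**  Only means
  and SDs are published; no covariance is available.  Measures are bounded
  by task maxima (15 words per RAVLT trial, sheet length for Stroop counts).
  The location parameter of each truncated normal is solved numerically so
  the *truncated* mean equals the published mean; otherwise near-ceiling
  measures (RAVLT trial 5, mean 12.71 of 15) would systematically
  undershoot.  The realised SD of a truncated draw is slightly below the
  nominal SD for those measures; means were prioritised because every
  downstream index is a ratio of means.
* **Unpublished trial means.**  RAVLT trials 2–4 are interpolated linearly
  between trials 1 and 5 and rescaled so the five trials sum to the
  published learning capacity; list B is the published proactive-interference
  ratio times trial 1 (SD carried over from trial 1).
* **Recall grids.**  Per subject, a 5 × 15 binary trial-by-position grid is
  generated whose row sums equal the (integerised) trial scores and whose
  expected primacy/middle/recency masses match the published
  serial-position targets (trial 1 directly; trials 2–5 share the remaining
  total in proportion to the trial means).  Words are allocated to bins by
  randomized rounding — unbiased for the 0-, 1- and 2-remainder cases that
  occur away from ceiling — then uniformly to positions within a bin, so
  primacy + middle + recency equals the trial score *exactly* for every row.

What passing tests on such cohorts show is that the pipeline computes what
it claims on data with the published first- and second-moment structure;
they cannot show anything about covariance between measures, skew, outliers
or item-level behaviour of real subjects.

## Neuropsychological indices and genotype calls

Scoring follows the standard definitions: learning capacity
$\sum_{k=1}^5 T_k$; proactive interference $B/T_1$; retroactive interference
$T_6/T_5$; forgetting speed $T_7/T_6$; long-term percent retention
$100\,T_7/T_5$ (the standard definition; the published distal value differs
by ~1% because the printed value averages per-subject ratios).  Undefined
ratios (zero denominators) propagate as `NA`, never as dropped rows.  The
digit-span attention fraction has no published formula; both plausible
variants, $(DSF-DSB)/DSF$ and $(DSF-DSB)/(DSF+DSB)$, are provided and
neither reproduces all three published group means, so the variant used is
recorded in the output.  The memory efficiency index is exposed as a
pluggable callable (its formula lives in an external reference) with the
interpretive cut-offs 1.2 and 1.9 attached.  IQ follows the ICD-10 bands
(> 84 adequate, 70–84 borderline, 50–69 mild, 35–49 moderate, < 35
severe/profound intellectual disability).

`classify_dp140()` is a pure function of mutation kind and exon range:
deletions/duplications ending at exon 43 or earlier are Dp140 positive,
anything reaching exon 44 is negative, and point mutations or absent CNVs
are unknown.  Exon 44 itself classifies negative — the published case list
includes a deletion ending at exon 44 among the Dp140-affecting mutations —
but such calls carry a low-confidence flag because the transcription start
site is not precisely confirmed; duplications follow the deletion rule and
say so in their rationale.

## Statistics report

`stats_report()` mirrors the study's analysis plan per measure: a
Lilliefors-corrected Kolmogorov–Smirnov normality check per group (exact
Shapiro–Wilk below n = 5), then one-way ANOVA (Welch variant when a
Bartlett test rejects equal variances) with Bonferroni-corrected pairwise
t tests for normal measures, or Kruskal–Wallis (Mann–Whitney for two
groups) with Bonferroni-corrected pairwise Wilcoxon tests otherwise,
α = 0.05, p values reported to three decimals.  Groups with fewer than two
observations skip the measure with a warning.

## Problem sizes and numerical choices

The test suite simulates cohorts of 20–80 sessions, fits on the full
default lattice (1331 points), and runs the recovery and group-comparison
experiments at the published group sizes (53 and 80); generator-faithfulness
checks use 2000–5000 synthetic subjects.  Base-level sums are evaluated
directly (event counts stay below ~300 per session, so no approximation to
the power-law sum is needed).  The truncated-normal location solver brackets
its root near the target mean, where the normal CDF is well conditioned.
Seeds: every user-facing simulation takes a `seed` argument; cohorts derive
one sub-seed per session so results are independent of cohort size.

## Known limitations

* One model per group; no per-subject parameters, no congruent-trial
  facilitation, no error responses (completions only), no spreading
  activation or blending.
* The latency law with $F = 1$ cannot reach human word-reading rates
  (~0.75 s/item), so absolute fitted fitness is large by construction and
  between-group MSD orderings are unstable (see above).
* Generated cohorts are marginal reconstructions; correlations between
  measures are absent by design.
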