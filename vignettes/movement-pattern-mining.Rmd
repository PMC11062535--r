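---
title: "Mining movement patterns from wearable GPS and separating playing positions"
author: "MoveMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining movement patterns from wearable GPS and separating playing positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MoveMiner)
```

## The problem

Wearable GPS units sample a team-sport athlete's kinematics at 10 Hz. Most
practice summarises these streams into aggregate indicators (total distance,
time above a speed threshold), which discard *how* movement was performed:
the order in which speeds, speed changes and direction changes follow one
another. MoveMiner implements a movement-profiling pipeline that keeps that
order: it discretizes each 0.1 s sample into a symbolic *movement unit*,
mines frequent movement *patterns* of three structural kinds from each
player-match, quantifies how similar the pattern vocabularies of the three
miners are, and asks which kind of pattern best separates players into two
positional groups (in the motivating application, rugby league hookers and
wingers).

## From kinematics to symbols

Every fix is described by three banded descriptors:

* velocity (m/s): Walk $[0, 1.70)$, Jog $[1.70, 3.90]$, Run
  $(3.90, 5.00)$, Sprint $[5.00, \infty)$;
* acceleration (m/s²): Deceleration $(-\infty, -0.20]$, Neutral
  $(-0.20, 0.20)$, Acceleration $[0.20, \infty)$;
* turning angle (degrees, the absolute heading change between consecutive
  displacement vectors, folded into $[0, 180]$): Straight $[0, 10)$,
  Acute-change $[10, 45)$, Large-change $[45, 90)$, Backwards $[90, 180]$.

The $4 \times 3 \times 4 = 48$ descriptor triples are mapped bijectively
onto the characters `a`–`z`, `A`–`V` in velocity-major, acceleration-middle,
turning-minor order. The full table is printed by `movementAlphabet()`. The
enumeration is the unique simple ordering consistent with every attested
character assignment of the motivating study (e.g. `e` =
Walk/Neutral/Straight, `u` = Jog/Acceleration/Straight, `S` =
Sprint/Acceleration/Straight).

```{r}
csv <- system.file("extdata", "worked_example_gps_synthetic.csv",
                   package = "MoveMiner")
trace <- readGpsCsv(csv)[[1]]
discretizeTrace(trace)
```

The bundled example file is a synthetic numeric realisation of a published
ten-row worked example (values drawn inside the printed descriptor bands);
its discretization is the reference string `ijfeikhddb`.

Two channels may be absent. Without a device acceleration channel,
`deriveAcceleration()` uses a central finite difference of velocity at
10 Hz (one-sided at the endpoints). Without a turning-angle channel,
`turningAngles()` derives angles from coordinates using great-circle initial
bearings (`geosphere`); the first and last fix of a trace cannot form a
three-fix corner and are defined to turn 0°, and displacements under a
configurable motion epsilon (default 0.01 m) carry the previous moving
heading forward so bearings are never computed from GPS jitter alone.

**Inactive periods.** A continuous match recording contains standing and
off-field stretches that would otherwise be mined as long runs of
low-velocity symbols. `splitInactive()` deletes maximal runs in which
velocity stays below `vMin` for at least `tMin` seconds, and the surviving
stretches become the *discrete movement sequences* of that player-match
(its mining corpus). The reference rule the pipeline inherits was published
only by citation, so the thresholds are explicit parameters: the defaults,
velocity < 0.2 m/s sustained ≥ 2.0 s, mark clear standing still at a
duration well above one play-the-ball cycle, and shorter dips are kept as
ordinary slow movement.

## Three kinds of frequent pattern

All miners use *sequence-level support*: the fraction of sequences in the
player-match corpus containing at least one occurrence of the pattern. This
is the standard support notion for sequence databases; occurrence counts
within one long sequence would otherwise let a single repetitive segment
dominate.

**Closed contiguous patterns** (`lccspmMine()`). A contiguous pattern is a
substring: movement units strictly adjacent in time. The miner returns all
substrings of at most $\ell$ units (default 20, a 2 s window) with support
at least `minsup` (default 0.05) that are *closed*: no frequent contiguous
super-pattern of length ≤ $\ell$ has the same support count. Closure is
decided through one-character extensions, which is exact because any
equal-support super-pattern is reachable through a chain of one-character
extensions whose supports are sandwiched between the two ends. Patterns of
exactly $\ell$ units cannot be extended under the cap, so they are closed
whenever frequent — a deliberate boundary convention forced by the cap's
definition.

**Longest-common-subsequence patterns** (`smpLcsMine()`). Subsequence
patterns keep temporal order but allow omissions. Following the clustered
sequential-movement-pattern approach, corpus sequences are grouped into
`min(nClusters, n)` clusters (default 25) and each cluster is reduced to
the progressive `lcsPair()` fold of its members. The published description
leaves the clustering internals open; this implementation uses
complete-linkage agglomerative clustering on normalised Levenshtein
distance (distance divided by the longer length), folds members in
decreasing-length-then-lexicographic order, and breaks dynamic-programming
backtrack ties by skipping a character of the first argument. Each choice
is arbitrary but fixed, making the stage fully deterministic — the
instability of re-run-dependent LCS mining was the original motivation for
stabilised variants, so determinism is treated as a requirement, and all
three choices are configurable at the function boundary.

**Frequent closed itemsets** (`aprioriCloseMine()`). Itemset patterns
ignore order and repetition: each sequence is reduced to its set of
distinct characters, and the miner returns the frequent closed itemsets,
items sorted lexicographically. Rather than a level-wise candidate sweep,
the implementation enumerates the intersection-closure of the transaction
family — every closed itemset is the intersection of the transactions
containing it — then support-counts and filters. On a 48-character
alphabet this is exact and fast; a powerset reference miner
(`aprioriCloseOracle()`) and an exhaustive substring reference miner
(`lccspmOracle()`) provide independent ground truth for the test suite on
small corpora.

Patterns longer than 20 items are excluded throughout; the LCCspm length
cap enforces this during mining and `filterMaxItems()` applies it to the
other two miners afterwards.

`unionPatternSets()` forms the duplicate-free union of the per-corpus sets
of one algorithm. Pattern identity is (kind, items): supports differ per
corpus and are kept as provenance — for each unique pattern, the
player-matches that extracted it and its support there. The number of
extracting corpora is the pattern's cross-corpus frequency, the only count
available for ranking once corpora are pooled.

## Comparing pattern vocabularies

`jaccardSimilarity()` computes $J(X, Y) = |X \cap Y| / |X \cup Y|$ between
unique pattern sets; `exactOverlap()` the exact-match intersection;
`topBottomOverlap()` the overlap among each side's $k$ most and $k$ least
frequent patterns (default $k = 50$, with frequency-then-lexicographic tie
breaks); `positionPartition()` splits one algorithm's patterns into those
performed by both positions and those unique to each, with counts
satisfying $|A\text{ only}| = |A| - |\text{shared}|$ exactly. Scores are
reported with half-up rounding at the printed precision
(`roundHalfUp()`). The choice $k = 50$ is inherited from the motivating
study, where it is about one-third of the smallest unique set; it has no
internal justification beyond that and is a free parameter here.

## Separating positions

`buildFeatureMatrix()` turns per-corpus pattern sets into a
`SummarizedExperiment`: one binary feature per unique pattern, one column
per player-match observation, 1 when that observation's mined set contains
the pattern. `runCrossValidation()` fits five classifiers under plain
shuffled 10-fold cross-validation (shuffle seed 10, no stratification) and
averages accuracy, precision, recall and F1 over folds:

| classifier | implementation | settings |
|---|---|---|
| DecisionTree | `rpart` | unrestricted growth (`minsplit = 2`, `cp = 0`), mirroring common library defaults of splitting to pure leaves |
| GaussianNaiveBayes | `e1071::naiveBayes` | per-class sd floored at $\sqrt{10^{-9} \max_j \mathrm{var}_j}$ and vanished densities clamped at $10^{-300}$, the usual variance-smoothing needed for binary presence features that are constant within a class |
| RandomForest | `randomForest` | seed 1 before each fit |
| LogisticRegression | `glmnet` | L1 penalty, $\lambda = 1/n_{\mathrm{train}}$, the per-observation penalty weight equivalent to the common C = 1 convention |
| MLP | `nnet` | one hidden layer of 8 units, 300 iterations maximum, seed 5 |

The perceptron's hidden layer is deliberately small: at the problem sizes
this package targets (tens of observations, $10^2$–$10^3$ features) a
wider layer multiplies quasi-Newton training cost without changing the
comparative question the classifier set answers. Precision, recall and F1
are averaged over the two classes weighted by class support (macro
averaging is available via `average = "macro"`); the positive class is
deliberately not singled out, and per-fold values are returned alongside
the aggregates. `logisticImportance()` ranks patterns by the absolute L1
logistic coefficient — the only non-negative transform consistent with
reporting signed linear weights as positive importance scores — with
lexicographic tie breaks.

## The synthetic cohort generator

Real athlete-tracking data are proprietary, so the package carries its own
generative model. A `PositionArchetype` is a first-order Markov chain over
the 48 movement units plus planted motifs (short unit strings inserted as
atomic blocks at a Poisson rate per 100 symbols). The transition kernel
factorises into smooth velocity changes, an acceleration band that agrees
with the sign of the velocity change, mostly-straight turning, and a
per-position velocity-band bias. `defaultArchetypes()` makes the hooker
archetype walk/jog-heavy with jog-flavoured motifs (`uuv`, `mnm`) and the
winger archetype sprint-heavy with sprint-flavoured motifs (`GSS`, `TST`);
the motif sets are disjoint, emulating the tactical contrast between the
two roles. Default motif rate is 2 insertions per 100 symbols.

`unitsToGps()` inverts symbols to numbers by drawing uniformly inside each
descriptor band (open bounds shrunk by $10^{-3}$; the unbounded ends
capped at 9 m/s and ±4 m/s²). Uniform emission is a deliberate choice:
only band membership matters downstream, and uniformity makes the
round-trip `discretizeTrace(unitsToGps(s)) == s` exact by construction in
angle-channel mode. Coordinate mode instead synthesises a
latitude/longitude track whose heading changes realise the drawn angles
(turn direction random, walking speeds floored at 0.3 m/s so every step is
a measurable displacement); recovery is then through the bearing
computation and is band-accurate rather than value-exact, and the first
and last fix are constrained to Straight because no three-fix corner
exists there.

`generateCohort()` assembles player-match traces: an active unit stream
per player-match, cut into segments with sub-threshold-velocity gap blocks
(velocity < 0.15 m/s, 2.5–5 s) spliced between them, so inactive-period
splitting is genuinely exercised rather than bypassed, and the ground
truth (active stream, segments, motifs) is returned alongside. Defaults —
10 players per position, 3 matches each, 60 s of active movement, 8 gaps
per active minute — are the package's reference cohort: large enough for
10-fold cross-validation (60 observations) and for motif supports to be
estimated per corpus (~9 segments each), small enough that the full
pipeline runs in minutes on one CPU. Everything is bit-reproducible under
the master seed.

What the generator does *not* emulate: session structure and fatigue,
pitch geometry, GPS noise and dropouts, autocorrelated accelerations
beyond first-order dynamics, and squad-level heterogeneity between players
of one position. Tests passing on synthetic cohorts therefore demonstrate
the pipeline's correctness and its ability to recover planted structure,
not field performance on real tracking data.

## Numerical choices and degenerate inputs

* Band boundaries follow the published inclusivities exactly (Jog closed
  at 3.90 m/s, Run open below it); support thresholds compare
  `support/n >= minsup - 1e-12` to keep exact fractions stable.
* Empty traces and all-inactive traces are legal: they yield empty corpora,
  which the miners refuse with a clear error rather than returning an
  empty vocabulary silently.
* `lcsPair("", t)` is the empty string; single-symbol corpora are closed
  by definition; a single-sequence corpus has exactly one closed itemset.
* Cross-validation demands both labels present and at least as many
  observations as folds; fold sizes differ by at most one; identical
  feature rows for both classes degrade to chance-level accuracy without
  error.
* All stage randomness flows from explicit seeds (cohort master seed, fold
  shuffle seed 10, random forest seed 1, perceptron seed 5), so every
  result in the package is reproducible bit for bit.

## Scale of the bundled experiments

The package's own checks run the pipeline at desk scale, chosen once: the
motif-recovery experiment uses 50 corpora of 20 sequences × 100 symbols
with a motif planted at 2 per 100 symbols and mining at support 0.05,
length cap 20; the separation experiment mines the reference cohort at
support 0.4 and length cap 5 before classification. The lower support and
cap in the classification stage reflect corpus size, not a change of
method: a full 80-minute match yields thousands of symbols per corpus and
dozens of segments, where the study settings (0.05, 20) are informative,
while a 60 s synthetic trace with ~9 segments would turn support 0.05 into
"present anywhere" and flood the feature space with singleton substrings.
Function defaults remain the study settings.

## Known limitations

* The LCS clustering internals (distance, linkage, fold order) are
  package choices where the source description is silent; alternatives
  would produce different but equally defensible subsequence vocabularies.
* Itemset mining on corpora with very many distinct transactions can in
  principle grow a large closure family; the miner caps the family size
  and asks for a higher support threshold instead of exhausting memory.
* Coordinate-mode turning recovery is limited by bearing numerics near
  band boundaries; the angle-channel mode is exact and is the default for
  synthetic cohorts.
* The classifier stage answers a comparative question (which pattern kind
  separates positions best); absolute accuracies on synthetic cohorts are
  not predictions of real-data performance.
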