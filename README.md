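# MoveMiner

Movement-pattern mining and positional classification from wearable GPS
time series, in R.

## What it does, and for whom

Sports scientists and performance analysts working with 10 Hz GPS traces
from team-sport athletes usually summarise them into aggregate indicators
(total distance, high-speed running metres). Those summaries discard the
*order* in which movements happen. MoveMiner keeps it:

1. **Discretization.** Each 0.1 s fix is banded by velocity
   (Walk `[0, 1.70)` / Jog `[1.70, 3.90]` / Run `(3.90, 5.00)` / Sprint
   `[5.00, ∞)` m·s⁻¹), acceleration (Deceleration `≤ −0.20` / Neutral /
   Acceleration `≥ 0.20` m·s⁻²) and turning angle (Straight `[0, 10)` /
   Acute-change `[10, 45)` / Large-change `[45, 90)` / Backwards
   `[90, 180]` degrees), and the 48 possible descriptor triples are encoded
   as single characters `a`–`z`, `A`–`V`. Sustained low-velocity stretches
   (inactive periods) are cut out, leaving a set of discrete movement
   sequences per player-match — the mining corpus.
2. **Pattern mining**, three structural kinds per corpus:
   - *closed contiguous* patterns (substrings, length ≤ 20 units, support
     ≥ 5 % by default) — `lccspmMine()`;
   - *longest-common-subsequence* patterns from agglomerative clusters of
     sequences — `smpLcsMine()`;
   - *frequent closed itemsets* of movement-unit characters —
     `aprioriCloseMine()`.
   Brute-force reference miners (`lccspmOracle()`, `aprioriCloseOracle()`)
   back the closure algorithms in the test suite.
3. **Comparison.** Unique pattern vocabularies per algorithm (set union
   with per-corpus provenance), Jaccard similarity
   `J(X, Y) = |X ∩ Y| / |X ∪ Y|`, exact-match overlap, overlap among each
   side's 50 most/least frequent patterns, and per-position partitions.
4. **Separation.** A binary pattern-presence feature matrix (observations =
   player-matches) feeds five classifiers — decision tree, Gaussian naive
   Bayes, random forest, L1 logistic regression, multi-layer perceptron —
   under shuffled 10-fold cross-validation, reporting aggregated accuracy,
   precision, recall and F1, plus a top-20 importance ranking from the
   logistic coefficients.
5. **Synthetic cohorts.** Because real athlete-tracking data are
   proprietary, `generateCohort()` simulates two-position cohorts from
   48-state Markov archetypes with planted motifs and inactive gaps, and
   `unitsToGps()` inverts symbols to in-band kinematics so the whole
   pipeline — including discretization — is exercised end to end.

## Worked example

```r
library(MoveMiner)

## ten GPS fixes (synthetic realisation of a published worked example)
csv <- system.file("extdata", "worked_example_gps_synthetic.csv",
                   package = "MoveMiner")
trace <- readGpsCsv(csv)[[1]]
discretizeTrace(trace)
#> [1] "ijfeikhddb"

## a synthetic cohort: 6 players per position, 2 matches, 40 s active play
cohort <- generateCohort(cohortConfig(playersPerPosition = 6,
                                      matchesPerPlayer = 2,
                                      activeDuration = 40, seed = 42))
corpora <- lapply(cohort$traces, makeCorpus)
corpora[[1]]
#> MovementCorpus: player hooker_01, match m01 (hooker)
#>   4 discrete sequence(s), 442 movement units in total

sets <- list(
  LCCspm = lapply(corpora, lccspmMine, minsup = 0.4, l = 5),
  LCS = lapply(corpora, function(cp) filterMaxItems(smpLcsMine(cp))),
  AprioriClose = lapply(corpora, function(cp)
    filterMaxItems(aprioriCloseMine(cp, minsup = 0.4)))
)
unions <- lapply(sets, unionPatternSets)
sapply(unions, function(u) nrow(patternTable(u)))
#>       LCCspm          LCS AprioriClose
#>          377           38          410

round(similarityMatrix(unions), 3)
#>              LCCspm   LCS AprioriClose
#> LCCspm        1.000 0.002        0.036
#> LCS           0.002 1.000        0.002
#> AprioriClose  0.036 0.002        1.000

fm <- buildFeatureMatrix(sets$LCCspm, unions$LCCspm)
cv <- runCrossValidation(fm)
cv$aggregate
#>          classifier accuracy precision recall    f1
#>        DecisionTree    0.800     0.789  0.800 0.767
#>  GaussianNaiveBayes    0.900     0.850  0.900 0.867
#>        RandomForest    1.000     1.000  1.000 1.000
#>  LogisticRegression    0.967     0.983  0.967 0.967
#>                 MLP    0.917     0.869  0.917 0.887

head(logisticImportance(fm), 5)
#>  rank pattern score
#>     1     GSS 2.626
#>     2       O 0.637
#>     3     mnm 0.549
#>     4     uuv 0.509
#>     5       h 0.462
```

Reading the output: the unique vocabularies of the three miners barely
overlap (Jaccard ≤ 0.04 here), the closed contiguous features separate the
two synthetic positions almost perfectly, and the most important logistic
features are exactly the motifs planted in the generating archetypes
(`GSS` for wingers, `mnm`/`uuv` for hookers) — the pipeline recovers the
structure it was given.

`runPipeline(outDir)` chains every stage (simulate → discretize → mine ×3 →
compare → classify) and writes TSV/CSV/JSON artifacts plus a manifest with
seeds, parameters and file hashes; `inst/scripts/run_pipeline.R` wraps it
for shell use.

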