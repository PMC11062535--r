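## End-to-end orchestration: simulate -> discretize -> mine x3 -> compare
## -> classify, with file outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated list. Mining defaults
#' follow the study settings (support 5\%, length cap 20 units, 25 LCS
#' clusters, 10-fold shuffled cross-validation with shuffle seed 10,
#' most/least-frequent-50 overlap). The demo-scale pipeline run lowers the
#' mining setting via \code{mining} to keep the pattern space proportionate
#' to short synthetic traces; see the package vignette.
#'
#' @param mining list(minsup, l, nClusters).
#' @param split list(vMin, tMin) for inactive-period splitting.
#' @param cv list(folds, shuffleSeed, average, mlpSize).
#' @param classifiers classifier names for the separation stage.
#' @param k top/bottom overlap depth.
#' @param seed master seed for simulation stages.
#' @return Validated configuration list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(mining = list(minsup = 0.05, l = 20L,
                                         nClusters = 25L),
                           split = list(vMin = 0.2, tMin = 2.0),
                           cv = list(folds = 10L, shuffleSeed = 10L,
                                     average = "weighted", mlpSize = 8L),
                           classifiers = .CLASSIFIERS,
                           k = 50L, seed = 1L) {
  cfg <- list(mining = mining, split = split, cv = cv,
              classifiers = classifiers, k = as.integer(k),
              seed = as.integer(seed))
  .checkMinsup(cfg$mining$minsup)
  if (is.null(cfg$mining$l) || cfg$mining$l < 1) stop("mining$l must be >= 1")
  if (is.null(cfg$mining$nClusters) || cfg$mining$nClusters < 1) {
    stop("mining$nClusters must be >= 1")
  }
  if (cfg$split$vMin < 0 || cfg$split$tMin <= 0) {
    stop("split thresholds must be positive")
  }
  if (cfg$cv$folds < 2L) stop("cv$folds must be >= 2")
  if (cfg$k < 1L) stop("k must be >= 1")
  bad <- setdiff(cfg$classifiers, .CLASSIFIERS)
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Discretize a GPS CSV into a sequence TSV
#'
#' @param gpsCsv input GPS CSV path ([readGpsCsv()] dialect).
#' @param out output sequence TSV path.
#' @param vMin,tMin inactive-period thresholds (m/s, s).
#' @return The list of \linkS4class{MovementCorpus} objects, invisibly.
#' @export
runDiscretize <- function(gpsCsv, out, vMin = 0.2, tMin = 2.0) {
  traces <- readGpsCsv(gpsCsv)
  corpora <- lapply(traces, makeCorpus, vMin = vMin, tMin = tMin)
  empty <- vapply(corpora, function(cp) length(cp@sequences) == 0L,
                  logical(1L))
  if (any(empty)) {
    warning(sum(empty), " trace(s) were entirely inactive and produced ",
            "no sequences")
  }
  writeSequenceTsv(corpora, out)
  message(sprintf("discretized %d trace(s) into %d sequence(s)",
                  length(traces),
                  sum(vapply(corpora, function(cp) length(cp@sequences),
                             integer(1L)))))
  invisible(corpora)
}

.mineOne <- function(corpus, algorithm, cfg) {
  switch(algorithm,
    lccspm = lccspmMine(corpus, minsup = cfg$minsup, l = cfg$l),
    lcs = filterMaxItems(smpLcsMine(corpus, nClusters = cfg$nClusters),
                         maxItems = cfg$l),
    aprioriclose = filterMaxItems(
      aprioriCloseMine(corpus, minsup = cfg$minsup), maxItems = cfg$l),
    stop("unknown algorithm: ", algorithm,
         " (expected lccspm, lcs or aprioriclose)")
  )
}

#' Mine per-corpus pattern sets and their union from a sequence TSV
#'
#' @param sequenceTsv path written by [writeSequenceTsv()].
#' @param algorithm \code{"lccspm"}, \code{"lcs"} or \code{"aprioriclose"}.
#' @param outPatterns,outUnion output TSV paths (NULL to skip writing).
#' @param minsup,l,nClusters mining parameters; the length cap \code{l}
#'   also filters LCS/AprioriClose patterns.
#' @return List with \code{sets} (per-corpus \linkS4class{PatternSet}s,
#'   empty corpora skipped) and \code{union} (\linkS4class{PatternUnion}),
#'   invisibly.
#' @export
runMine <- function(sequenceTsv, algorithm, outPatterns = NULL,
                    outUnion = NULL, minsup = 0.05, l = 20L,
                    nClusters = 25L) {
  algorithm <- match.arg(algorithm, c("lccspm", "lcs", "aprioriclose"))
  .checkMinsup(minsup)
  corpora <- readSequenceTsv(sequenceTsv)
  corpora <- Filter(function(cp) length(cp@sequences) > 0L, corpora)
  if (!length(corpora)) stop("no non-empty corpora in ", sequenceTsv)
  cfg <- list(minsup = minsup, l = l, nClusters = nClusters)
  sets <- lapply(corpora, .mineOne, algorithm = algorithm, cfg = cfg)
  un <- unionPatternSets(sets)
  if (!is.null(outPatterns)) writePatternTsv(sets, outPatterns)
  if (!is.null(outUnion)) writeUnionTsv(un, outUnion)
  message(sprintf("%s: mined %d corpora, %d unique pattern(s)",
                  algorithmTag(un), length(sets), nrow(un@patterns)))
  invisible(list(sets = sets, union = un))
}

#' Compare pattern unions: similarity, overlap and position partitions
#'
#' @param unions list of \linkS4class{PatternUnion}s (>= 2); unions of a
#'   repeated algorithm are deduplicated with a warning.
#' @param outDir optional directory for \code{similarity.csv},
#'   \code{overlap_<A>_<B>.tsv} and \code{partition_<algorithm>.tsv}.
#' @param k top/bottom overlap depth (default 50).
#' @return List with \code{similarity} (matrix), \code{overlaps} (per pair:
#'   exact overlap plus [topBottomOverlap()] report) and \code{partitions}
#'   (per algorithm, when provenance carries two positions), invisibly.
#' @export
runCompare <- function(unions, outDir = NULL, k = 50L) {
  tags <- vapply(unions, algorithmTag, character(1L))
  if (anyDuplicated(tags)) {
    warning("duplicate unions for: ",
            paste(unique(tags[duplicated(tags)]), collapse = ", "),
            "; keeping the first of each")
    unions <- unions[!duplicated(tags)]
    tags <- tags[!duplicated(tags)]
  }
  if (length(unions) < 2L) stop("need unions from at least two algorithms")
  names(unions) <- tags
  sim <- similarityMatrix(unions)
  pairs <- utils::combn(tags, 2L, simplify = FALSE)
  overlaps <- lapply(pairs, function(pr) {
    a <- unions[[pr[1L]]]
    b <- unions[[pr[2L]]]
    list(pair = pr, exact = exactOverlap(a, b),
         topBottom = topBottomOverlap(a, b, k = k))
  })
  names(overlaps) <- vapply(pairs, paste, character(1L), collapse = "_")
  partitions <- lapply(unions, function(un) {
    byPos <- patternsByPosition(un)
    if (length(byPos) != 2L) return(NULL)
    positionPartition(byPos)
  })
  partitions <- Filter(Negate(is.null), partitions)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sim, file.path(outDir, "similarity.csv"))
    for (nm in names(overlaps)) {
      ov <- overlaps[[nm]]
      rx <- ov$topBottom$ranksX
      ry <- ov$topBottom$ranksY
      df <- data.frame(pattern = ov$exact,
                       freqA = rx$n_corpora[match(ov$exact, rx$items)],
                       rankA = rx$rank[match(ov$exact, rx$items)],
                       freqB = ry$n_corpora[match(ov$exact, ry$items)],
                       rankB = ry$rank[match(ov$exact, ry$items)])
      utils::write.table(df, file.path(outDir,
                                       sprintf("overlap_%s.tsv", nm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (nm in names(partitions)) {
      pt <- partitions[[nm]]
      df <- data.frame(
        pattern = c(pt$shared, pt$onlyA, pt$onlyB),
        side = rep(c("shared", "A_only", "B_only"),
                   c(length(pt$shared), length(pt$onlyA),
                     length(pt$onlyB))))
      utils::write.table(df, file.path(outDir,
                                       sprintf("partition_%s.tsv", nm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(list(similarity = sim, overlaps = overlaps,
                 partitions = partitions))
}

#' Classify positions from mined pattern sets
#'
#' Builds the binary presence feature matrix from the per-corpus sets and
#' their union, runs the cross-validated classifiers, and ranks the
#' top-\code{topN} patterns of the L1 logistic model.
#'
#' @param sets per-corpus \linkS4class{PatternSet}s (one per observation).
#' @param un their \linkS4class{PatternUnion}.
#' @param outMetrics optional JSON-lines path: one record per classifier
#'   with the aggregated metrics.
#' @param outImportance optional TSV path \code{rank pattern score}.
#' @param folds,shuffleSeed,average,mlpSize see [runCrossValidation()].
#' @param classifiers classifier subset.
#' @param topN importance ranking length.
#' @return List with \code{cv} ([runCrossValidation()] result),
#'   \code{importance} and \code{featureMatrix}, invisibly.
#' @export
runClassify <- function(sets, un = unionPatternSets(sets),
                        outMetrics = NULL, outImportance = NULL,
                        classifiers = .CLASSIFIERS, folds = 10L,
                        shuffleSeed = 10L, average = "weighted",
                        mlpSize = 8L, topN = 20L) {
  fm <- buildFeatureMatrix(sets, un)
  cv <- runCrossValidation(fm, classifiers = classifiers, folds = folds,
                           shuffleSeed = shuffleSeed, average = average,
                           mlpSize = mlpSize)
  imp <- logisticImportance(fm, topN = topN)
  if (!is.null(outMetrics)) {
    con <- file(outMetrics, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(cv$aggregate))) {
      rec <- c(list(algorithm = cv$algorithm),
               as.list(cv$aggregate[i, , drop = FALSE]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  if (!is.null(outImportance)) {
    utils::write.table(imp, outImportance, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(list(cv = cv, importance = imp, featureMatrix = fm))
}

#' Run the full movement-profiling pipeline on a synthetic cohort
#'
#' Simulates a cohort, writes its GPS CSV, discretizes and splits it,
#' mines all three pattern types per player-match, compares the unions,
#' classifies positions per algorithm, and writes a manifest recording the
#' package version, seeds and every stage parameter.
#'
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @param cohort a [cohortConfig()]; its seed is taken from
#'   \code{config$seed} unless supplied explicitly.
#' @param archetypes two \linkS4class{PositionArchetype}s.
#' @return List with the stage results (\code{cohort}, \code{corpora},
#'   \code{mined}, \code{comparison}, \code{classification},
#'   \code{manifest}), invisibly.
#' @export
runPipeline <- function(outDir, config = pipelineConfig(),
                        cohort = cohortConfig(seed = config$seed),
                        archetypes = defaultArchetypes()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  coh <- step("simulate", {
    co <- generateCohort(cohort, archetypes)
    writeGpsCsv(co$traces, file.path(outDir, "gps.csv"))
    co
  })
  corpora <- step("discretize", {
    runDiscretize(file.path(outDir, "gps.csv"),
                  file.path(outDir, "sequences.tsv"),
                  vMin = config$split$vMin, tMin = config$split$tMin)
  })
  mined <- step("mine", {
    out <- lapply(c("lccspm", "lcs", "aprioriclose"), function(alg) {
      runMine(file.path(outDir, "sequences.tsv"), alg,
              outPatterns = file.path(outDir,
                                      sprintf("patterns_%s.tsv", alg)),
              outUnion = file.path(outDir, sprintf("union_%s.tsv", alg)),
              minsup = config$mining$minsup, l = config$mining$l,
              nClusters = config$mining$nClusters)
    })
    names(out) <- c("lccspm", "lcs", "aprioriclose")
    out
  })
  comparison <- step("compare", {
    runCompare(lapply(mined, `[[`, "union"), outDir = outDir, k = config$k)
  })
  classification <- step("classify", {
    out <- lapply(names(mined), function(alg) {
      runClassify(mined[[alg]]$sets, mined[[alg]]$union,
                  outMetrics = file.path(outDir,
                                         sprintf("metrics_%s.jsonl", alg)),
                  outImportance = file.path(outDir,
                                            sprintf("importance_%s.tsv",
                                                    alg)),
                  classifiers = config$classifiers,
                  folds = config$cv$folds,
                  shuffleSeed = config$cv$shuffleSeed,
                  average = config$cv$average, mlpSize = config$cv$mlpSize)
    })
    names(out) <- names(mined)
    out
  })
  manifest <- step("manifest", {
    files <- setdiff(list.files(outDir, recursive = TRUE), "manifest.json")
    man <- list(
      package = "MoveMiner",
      version = as.character(utils::packageVersion("MoveMiner")),
      seed = config$seed,
      cohort = unclass(cohort),
      parameters = unclass(config),
      files = as.list(tools::md5sum(file.path(outDir, files)))
    )
    names(man$files) <- files
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  invisible(list(cohort = coh, corpora = corpora, mined = mined,
                 comparison = comparison, classification = classification,
                 manifest = manifest))
}
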