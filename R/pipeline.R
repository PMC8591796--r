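## End-to-end orchestration: simulate/ingest -> accumulate (physical + EQD2)
## -> DVH + dosiomic features per dose variant -> redundancy filter (dosiomic
## groups) -> repeated-holdout LASSO modeling of the four groups -> summaries,
## pairwise comparisons and mean ROC curves.

#' Run configuration
#'
#' Exactly one input mode: a [cohortSpec()] to simulate, or a directory
#' written by [writeCohort()].
#'
#' @param cohort a [cohortSpec()], or NULL when `cohortDir` is given.
#' @param cohortDir directory of a written cohort, or NULL.
#' @param lq an [lqParams()].
#' @param dvh a [dvhSpec()].
#' @param discretization a [discretizationSpec()].
#' @param modeling a [modelingConfig()].
#' @param targetSpacing analysis grid spacing in mm.
#' @param gldmAlpha GLDM dependence tolerance.
#' @param outDir optional output directory for CSV/JSON artifacts.
#' @return A named list of class `RunConfig`.
#' @export
runConfig <- function(cohort = deskCohortSpec(), cohortDir = NULL,
                      lq = lqParams(), dvh = dvhSpec(),
                      discretization = discretizationSpec(),
                      modeling = deskModelingConfig(),
                      targetSpacing = c(1.5, 1.5, 1.5),
                      gldmAlpha = 0L, outDir = NULL) {
  if (is.null(cohort) == is.null(cohortDir))
    stop("exactly one input mode: give a cohort spec or a cohort directory")
  structure(list(cohort = cohort, cohortDir = cohortDir, lq = lq, dvh = dvh,
                 discretization = discretization, modeling = modeling,
                 targetSpacing = targetSpacing, gldmAlpha = gldmAlpha,
                 outDir = outDir),
            class = "RunConfig")
}

# Recursively strip S3 classes so configs serialize as plain JSON.
.plainList <- function(x) {
  if (is.list(x)) lapply(unclass(x), .plainList) else x
}

# FNV-1a hash of the serialized configuration, for output provenance.
.configDigest <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(
    .plainList(config), auto_unbox = TRUE, digits = NA, null = "null")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31 - 2^30), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Extract the four per-group feature tables from a cohort
#'
#' Per patient: resample every fraction and the mask to the analysis grid,
#' accumulate the physical sum and the EQD2 grid, and extract DVH and
#' dosiomic feature vectors from each. Returns the four modeling substrates.
#'
#' @param cohort a `SyntheticCohort` from [simulateCohort()], or the list
#'   returned by [readCohort()] provided its `table` has `label`.
#' @param config a [runConfig()].
#' @return Named list of four [FeatureTable-class] objects: `DVH`, `DVHEQD2`,
#'   `DO`, `DOEQD2`.
#' @export
featureStage <- function(cohort, config = runConfig()) {
  labels <- cohort$table$label
  perPatient <- lapply(cohort$patients, function(p) {
    # fractions delivered with the same arrangement are numerically identical;
    # resample each distinct fraction once and accumulate with multiplicity
    fr <- fractions(p$series)
    groups <- integer(length(fr))
    reps <- list()
    for (i in seq_along(fr)) {
      hit <- 0L
      for (u in seq_along(reps))
        if (identical(fr[[reps[[u]]]]@values, fr[[i]]@values)) { hit <- u; break }
      if (hit == 0L) { reps[[length(reps) + 1L]] <- i; hit <- length(reps) }
      groups[i] <- hit
    }
    counts <- tabulate(groups, nbins = length(reps))
    uniq <- lapply(reps, function(i)
      resampleToIso(fr[[i]], targetSpacing = config$targetSpacing))
    mask <- resampleToIso(p$mask, config$targetSpacing)
    acc <- function(weight) {
      tot <- weight(uniq[[1L]]@values) * counts[1L]
      if (length(uniq) > 1L)
        for (u in 2:length(uniq))
          tot <- tot + weight(uniq[[u]]@values) * counts[u]
      DoseGrid(tot, uniq[[1L]]@spacing, uniq[[1L]]@origin)
    }
    dphys <- acc(identity)
    deqd2 <- acc(function(v) eqd2Scalar(v, config$lq))
    suppressWarnings(list(
      dvh = extractDvhFeatures(dphys, mask, config$dvh),
      dvhEqd2 = extractDvhFeatures(deqd2, mask, config$dvh),
      do = extractDosiomicFeatures(dphys, mask, config$discretization,
                                   config$gldmAlpha),
      doEqd2 = extractDosiomicFeatures(deqd2, mask, config$discretization,
                                       config$gldmAlpha)))
  })
  ids <- cohort$table$patientId
  stack <- function(field) {
    m <- do.call(rbind, lapply(perPatient, `[[`, field))
    rownames(m) <- ids
    m
  }
  list(DVH = FeatureTable(stack("dvh"), labels, "DVH"),
       DVHEQD2 = FeatureTable(stack("dvhEqd2"), labels, "DVHEQD2"),
       DO = FeatureTable(stack("do"), labels, "DO"),
       DOEQD2 = FeatureTable(stack("doEqd2"), labels, "DOEQD2"))
}

#' Tidy per-patient feature CSV
#'
#' Long-format export of a feature table: `patient_id, dose_variant,
#' feature, value`.
#' @param table a [FeatureTable-class].
#' @return data.frame in tidy layout.
#' @export
tidyFeatureTable <- function(table) {
  X <- table@values
  variant <- if (grepl("EQD2$", table@groupTag)) "eqd2" else "physical"
  data.frame(patient_id = rep(rownames(X), times = ncol(X)),
             dose_variant = variant,
             feature = rep(colnames(X), each = nrow(X)),
             value = as.vector(X))
}

#' Run the whole pipeline
#'
#' Simulates or loads the cohort, extracts the four feature groups, filters
#' the dosiomic groups for redundancy, models all four groups on identical
#' split partitions, and aggregates summaries, the six pairwise comparisons
#' and mean ROC curves. With `outDir` set, writes tidy feature CSVs, a
#' summary CSV per group, a comparisons CSV, a mean-ROC CSV and a JSON
#' manifest carrying the configuration and its digest.
#'
#' @param config a [runConfig()].
#' @return List with `tables` (filtered), `results`, `summaries`,
#'   `comparisons`, `roc`, `configDigest`, `cohortTable`.
#' @export
runAll <- function(config = runConfig()) {
  cohort <- if (!is.null(config$cohortDir)) readCohort(config$cohortDir)
            else simulateCohort(config$cohort)
  tables <- featureStage(cohort, config)
  thr <- config$modeling$spearmanThreshold
  tables$DO <- suppressWarnings(spearmanRedundancyFilter(tables$DO, thr))
  tables$DOEQD2 <- suppressWarnings(spearmanRedundancyFilter(tables$DOEQD2, thr))
  results <- lapply(tables, runGroup, config = config$modeling)
  summaries <- lapply(results, summarizeGroup)
  pairs <- combn(names(results), 2, simplify = FALSE)
  comparisons <- lapply(pairs, function(p)
    compareGroups(results[[p[1]]], results[[p[2]]]))
  roc <- rocCurveMean(results)
  digest <- .configDigest(config)
  out <- list(tables = tables, results = results, summaries = summaries,
              comparisons = comparisons, roc = roc, configDigest = digest,
              cohortTable = cohort$table)
  if (!is.null(config$outDir)) .writeRunOutputs(out, config)
  out
}

.writeRunOutputs <- function(out, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  for (tag in names(out$tables))
    write.csv(tidyFeatureTable(out$tables[[tag]]),
              file.path(config$outDir, paste0("features_", tag, ".csv")),
              row.names = FALSE)
  for (tag in names(out$summaries)) {
    s <- out$summaries[[tag]]
    tab <- s$orTable
    tab$config_digest <- out$configDigest
    write.csv(tab, file.path(config$outDir, paste0("summary_", tag, ".csv")),
              row.names = FALSE)
  }
  cmp <- do.call(rbind, lapply(out$comparisons, function(cc)
    data.frame(groupA = cc$groups[1], groupB = cc$groups[2],
               statistic = cc$statistic, pValue = cc$pValue,
               meanDelta = cc$meanDelta, paired = cc$paired)))
  cmp$config_digest <- out$configDigest
  write.csv(cmp, file.path(config$outDir, "comparisons.csv"),
            row.names = FALSE)
  roc <- out$roc
  roc$config_digest <- out$configDigest
  write.csv(roc, file.path(config$outDir, "mean_roc.csv"), row.names = FALSE)
  aucs <- data.frame(
    group = names(out$summaries),
    aucMean = vapply(out$summaries, `[[`, numeric(1), "aucMean"),
    aucSD = vapply(out$summaries, `[[`, numeric(1), "aucSD"),
    aucP10 = vapply(out$summaries, `[[`, numeric(1), "aucP10"),
    aucP90 = vapply(out$summaries, `[[`, numeric(1), "aucP90"))
  jsonlite::write_json(
    list(configDigest = out$configDigest, auc = aucs,
         config = .plainList(config)),
    file.path(config$outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  invisible(NULL)
}
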