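## Aggregation of repeated-split results: AUC summaries, selection
## frequencies, odds ratios on the raw feature scale, inter-group Z-tests,
## modality association and mean ROC curves.

#' Summarize a group's repeated-split results
#'
#' AUC mean/SD and 10th/90th percentiles (linear interpolation between order
#' statistics) over all splits; per-feature selection frequency (fraction of
#' splits with a nonzero coefficient); per-feature odds ratios adjusted back
#' to the raw feature scale, `OR = exp(beta_norm / (max - min))` per unit of
#' the raw feature using that split's training bounds, summarized by median
#' and 10th/90th percentiles.
#'
#' @param result a [GroupResult-class].
#' @param orIncludeZeros if `TRUE` (default), splits where the feature was
#'   not selected contribute an OR entry of 0 to the percentile summary;
#'   if `FALSE`, such splits are excluded.
#' @return List with `groupTag`, `nSplits`, `aucMean`, `aucSD`, `aucP10`,
#'   `aucP90`, `selectionFrequency` (named vector) and `orTable`
#'   (data.frame: feature, frequency, orMedian, orP10, orP90).
#' @export
summarizeGroup <- function(result, orIncludeZeros = TRUE) {
  splits <- result@splits
  aucs <- testAUCs(result)
  feats <- result@featureNames
  selMat <- vapply(splits, function(s) feats %in% s$selected,
                   logical(length(feats)))
  selMat <- matrix(selMat, nrow = length(feats))
  freq <- rowMeans(selMat)
  names(freq) <- feats
  orRows <- lapply(seq_along(feats), function(j) {
    ors <- vapply(splits, function(s) {
      b <- s$coefficients[[feats[j]]]
      if (b == 0) return(NA_real_)
      rng <- s$bounds["max", feats[j]] - s$bounds["min", feats[j]]
      if (rng <= 0) return(NA_real_)
      exp(b / rng)
    }, numeric(1))
    if (orIncludeZeros) ors[is.na(ors)] <- 0 else ors <- ors[!is.na(ors)]
    if (length(ors) == 0L)
      return(c(orMedian = NA_real_, orP10 = NA_real_, orP90 = NA_real_))
    c(orMedian = median(ors),
      orP10 = unname(quantile(ors, 0.10, type = 7)),
      orP90 = unname(quantile(ors, 0.90, type = 7)))
  })
  orTable <- data.frame(feature = feats, frequency = unname(freq),
                        do.call(rbind, orRows), row.names = NULL)
  list(groupTag = result@groupTag, nSplits = length(splits),
       aucMean = mean(aucs), aucSD = sd(aucs),
       aucP10 = unname(quantile(aucs, 0.10, type = 7)),
       aucP90 = unname(quantile(aucs, 0.90, type = 7)),
       selectionFrequency = freq, orTable = orTable)
}

#' Z-test comparison of two groups' AUC distributions
#'
#' Paired mode (default; valid when the groups share split partitions, which
#' [runGroup()] guarantees under a common configuration) tests the mean of
#' the per-split AUC differences d with a two-sided normal p-value. Because
#' repeated holdout splits reuse the same patients, the naive standard error
#' `sd(d)/sqrt(n)` drastically understates the variability of `mean(d)` and
#' produces severely anti-conservative p-values; the default therefore
#' applies the Nadeau-Bengio variance correction for resampled estimates,
#' `se = sd(d) * sqrt(1/n + nTest/nTrain)`, with the test/train ratio taken
#' from the groups' modeling configuration. The uncorrected statistic is
#' available via `correction = "none"`. Unpaired mode: two-sample z on the
#' AUC samples. Degenerate paired cases: all-zero differences give p = 1;
#' zero-variance differences with nonzero mean give p = 0 with a warning.
#'
#' @param a,b [GroupResult-class] objects with equal split counts.
#' @param paired use the paired form (requires shared partitions).
#' @param correction variance correction for the paired statistic:
#'   `"nadeau-bengio"` (default) or `"none"`.
#' @return List with `groups`, `statistic`, `pValue`, `paired`, `meanDelta`.
#' @export
compareGroups <- function(a, b, paired = TRUE,
                          correction = c("nadeau-bengio", "none")) {
  correction <- match.arg(correction)
  x <- testAUCs(a)
  y <- testAUCs(b)
  if (length(x) != length(y)) stop("groups have different split counts")
  tag <- c(a@groupTag, b@groupTag)
  if (paired) {
    d <- x - y
    if (sd(d) == 0) {
      if (mean(d) == 0)
        return(list(groups = tag, statistic = 0, pValue = 1, paired = TRUE,
                    meanDelta = 0))
      warning("zero-variance nonzero AUC differences; reporting p = 0")
      return(list(groups = tag, statistic = sign(mean(d)) * Inf, pValue = 0,
                  paired = TRUE, meanDelta = mean(d)))
    }
    testFrac <- a@config$testFraction
    if (is.null(testFrac)) testFrac <- 0.2
    rho <- if (correction == "nadeau-bengio") testFrac / (1 - testFrac) else 0
    z <- mean(d) / (sd(d) * sqrt(1 / length(d) + rho))
    list(groups = tag, statistic = z, pValue = 2 * pnorm(-abs(z)),
         paired = TRUE, meanDelta = mean(d))
  } else {
    se <- sqrt(sd(x)^2 / length(x) + sd(y)^2 / length(y))
    z <- (mean(x) - mean(y)) / se
    list(groups = tag, statistic = z, pValue = 2 * pnorm(-abs(z)),
         paired = FALSE, meanDelta = mean(x) - mean(y))
  }
}

#' Chi-square association between RT modality and RP status
#'
#' Pearson chi-square (no continuity correction) on a modality x outcome
#' contingency table.
#'
#' @param counts 2 x K (or K x 2) contingency matrix of counts.
#' @return List with `statistic`, `df`, `pValue`.
#' @export
modalityOutcomeChisq <- function(counts) {
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       pValue = unname(ct$p.value))
}

#' Vertically averaged ROC curves
#'
#' Per split, the empirical ROC is interpolated linearly onto a fixed grid of
#' false-positive rates and the true-positive rates are averaged across
#' splits.
#'
#' @param results a [GroupResult-class] or list of them.
#' @param fprGrid grid of false-positive rates (default 101 points on 0..1).
#' @return data.frame with `group`, `fpr`, `meanTpr`.
#' @export
rocCurveMean <- function(results, fprGrid = seq(0, 1, length.out = 101)) {
  if (is(results, "GroupResult")) results <- list(results)
  out <- lapply(results, function(gr) {
    tprMat <- vapply(gr@splits, function(s)
      .rocAtGrid(s$testScores, s$testLabels, fprGrid),
      numeric(length(fprGrid)))
    data.frame(group = gr@groupTag, fpr = fprGrid,
               meanTpr = rowMeans(matrix(tprMat, nrow = length(fprGrid))))
  })
  do.call(rbind, out)
}

.rocAtGrid <- function(scores, labels, fprGrid) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # collapse score ties to a single operating point
  last <- !duplicated(sc, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(1, sum(labels == 1)))
  fpr <- c(0, fp[last] / max(1, sum(labels == 0)))
  approx(fpr, tpr, xout = fprGrid, ties = max, rule = 2)$y
}
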