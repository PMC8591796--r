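## Repeated-holdout LASSO-logistic modeling of a feature group.
##
## Protocol per split: random 80/20 partition (redrawn if the test side is
## single-class) -> per-feature min-max normalization with bounds from the
## training rows only -> inverse-penalty strength tuned by repeated inner
## 5-fold CV maximizing mean validation AUC (minority oversampling applied
## inside each inner-training fold only) -> final L1-logistic fit on the
## oversampled training set -> test AUC. All randomness of split k flows from
## a per-split child seed, so any split is reproducible in isolation.

#' Modeling configuration
#'
#' @param nSplits number of random train/test splits (study protocol: 1000).
#' @param testFraction held-out fraction per split (0.2).
#' @param cvRounds,cvFolds inner cross-validation: `cvRounds` repetitions of
#'   `cvFolds`-fold CV (study protocol: 20 x 5).
#' @param regGrid grid of inverse penalty strengths C (larger C = weaker
#'   penalty); default 13 log-spaced points over 1e-3..1e3. Ties in mean
#'   inner AUC resolve to the strongest penalty (smallest C).
#' @param spearmanThreshold redundancy-filter cutoff on |Spearman rho|.
#' @param seed master RNG seed; per-split child seeds are derived from it.
#' @param stratified stratify the 80/20 partition by outcome (default FALSE:
#'   plain random partition with single-class redraw).
#' @param maxRedraws bound on redraws of a single-class test partition.
#' @return A named list of class `ModelingConfig`.
#' @export
modelingConfig <- function(nSplits = 1000L, testFraction = 0.2,
                           cvRounds = 20L, cvFolds = 5L,
                           regGrid = 10^seq(-3, 3, length.out = 13),
                           spearmanThreshold = 0.8, seed = 1L,
                           stratified = FALSE, maxRedraws = 100L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("test fraction must be in (0, 1)")
  if (length(regGrid) < 1L || any(regGrid <= 0))
    stop("regularization grid must be non-empty and positive")
  structure(list(nSplits = as.integer(nSplits), testFraction = testFraction,
                 cvRounds = as.integer(cvRounds), cvFolds = as.integer(cvFolds),
                 regGrid = sort(regGrid), spearmanThreshold = spearmanThreshold,
                 seed = as.integer(seed), stratified = stratified,
                 maxRedraws = as.integer(maxRedraws)),
            class = "ModelingConfig")
}

#' Desk-scale modeling preset
#'
#' A reduced protocol (200 splits, 2 x 5 inner CV, 7-point grid) sized for
#' synthetic desk-scale cohorts; the full study protocol is
#' `modelingConfig()`'s defaults.
#' @param ... overrides passed to [modelingConfig()].
#' @export
deskModelingConfig <- function(...) {
  args <- list(nSplits = 200L, cvRounds = 2L, cvFolds = 5L,
               regGrid = 10^seq(-2, 2, length.out = 7))
  args[names(list(...))] <- list(...)
  do.call(modelingConfig, args)
}

#' Greedy Spearman redundancy filter
#'
#' Walks features in canonical (column) order; a feature is kept iff its
#' absolute Spearman rank correlation with every already-kept feature is at
#' or below the threshold. Applied to the dosiomic groups only in the study
#' protocol (DVH groups are small and kept whole). Constant features have
#' undefined rho and are kept with a warning.
#'
#' @param table a [FeatureTable-class].
#' @param threshold redundancy cutoff on |rho| (default 0.8).
#' @return The filtered [FeatureTable-class], column order preserved.
#' @export
spearmanRedundancyFilter <- function(table, threshold = 0.8) {
  X <- table@values
  const <- apply(X, 2, function(col) min(col) == max(col))
  if (any(const))
    warning("constant feature(s) with undefined Spearman rho kept: ",
            paste(colnames(X)[const], collapse = ", "))
  rho <- suppressWarnings(cor(X, method = "spearman"))
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    r <- abs(rho[j, keep])
    if (all(is.na(r) | r <= threshold)) keep <- c(keep, j)
  }
  FeatureTable(X[, keep, drop = FALSE], table@labels, table@groupTag)
}

#' Min-max normalization with training-set bounds
#'
#' Maps each feature to `(x - min)/(max - min)` using bounds from `train`
#' only; rows of `applyTo` may fall outside `[0, 1]` (not clipped). A
#' constant training feature maps to all zeros (with a warning).
#'
#' @param train numeric matrix whose column ranges define the bounds.
#' @param applyTo optional matrix to transform with the same bounds.
#' @return List with `train`, `applied` (or NULL) and `bounds` (2 x p matrix,
#'   rows `min` and `max`).
#' @export
minmaxNormalize <- function(train, applyTo = NULL) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    warning("constant training feature(s) mapped to 0: ",
            paste(colnames(train)[rng == 0], collapse = ", "))
  }
  scaleOf <- ifelse(rng == 0, 1, rng)
  norm <- function(m) sweep(sweep(m, 2, lo), 2, scaleOf, "/") *
    rep(as.numeric(rng != 0), each = nrow(m))
  list(train = norm(train),
       applied = if (!is.null(applyTo)) norm(applyTo) else NULL,
       bounds = rbind(min = lo, max = hi))
}

#' Oversample the minority class to balance a training set
#'
#' Keeps all rows and appends minority rows drawn with replacement until the
#' class counts are equal. Consumes the current RNG stream (seed it for
#' reproducibility).
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1), one per row.
#' @return List with balanced `X`, `y` and the `rowIndex` into the original
#'   rows (originals first, resampled minority rows appended).
#' @export
oversampleMinority <- function(X, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  idx <- seq_along(y)
  if (n1 != n0) {
    minority <- which(y == (if (n1 < n0) 1 else 0))
    extra <- sample(minority, abs(n0 - n1), replace = TRUE)
    idx <- c(idx, extra)
  }
  list(X = X[idx, , drop = FALSE], y = y[idx], rowIndex = idx)
}

# Mann-Whitney AUC of scores against binary labels; ties handled by midranks.
# Returns NA if either class is absent.
.aucScore <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of predicted scores against binary labels
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#' @param scores numeric predictions (any monotone score).
#' @param labels binary 0/1 outcomes.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
aucFromScores <- function(scores, labels) .aucScore(scores, labels)

.lambdaOf <- function(C, n) 1 / (n * C)

# glmnet requires >= 2 predictor columns; pad single-feature tables with an
# all-zero dummy (coefficient identically 0, dropped from results).
.padX <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, ".pad" = 0)
}

# Fit glmnet at one inverse-penalty C, embedding the target lambda in a short
# descending path for numerical stability.
.fitAtC <- function(X, y, C) {
  lam <- .lambdaOf(C, nrow(X))
  p <- ncol(X)
  path <- lam * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(.padX(X), y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE, thresh = 1e-10)
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
  beta <- beta[seq_len(p + 1L)]
  names(beta) <- c("(Intercept)", colnames(X))
  beta[abs(beta) < 1e-8] <- 0
  beta
}

#' Fit an L1-regularized (LASSO) logistic model
#'
#' Thin wrapper around [glmnet::glmnet()] (`alpha = 1`, binomial family, no
#' internal standardization: the pipeline pre-normalizes features to 0-1).
#' Coefficients below 1e-8 in magnitude are reported as exactly 0, which is
#' the embedded feature-selection rule.
#'
#' @param X numeric feature matrix (normalized training rows).
#' @param y binary 0/1 outcome vector.
#' @param C inverse penalty strength (> 0); the glmnet penalty is
#'   `lambda = 1/(n C)`.
#' @return List with `intercept`, named `coefficients`, `selected` (names of
#'   nonzero coefficients) and `C`.
#' @export
fitLassoLogistic <- function(X, y, C) {
  if (C <= 0) stop("inverse penalty strength must be > 0")
  beta <- .fitAtC(X, y, C)
  list(intercept = unname(beta[1L]),
       coefficients = beta[-1L],
       selected = names(beta[-1L])[beta[-1L] != 0],
       C = C)
}

#' Tune the penalty by repeated inner cross-validation
#'
#' For every grid value of the inverse penalty C, computes the mean
#' validation AUC over `cvRounds` x `cvFolds` inner folds (minority
#' oversampling applied inside each inner-training fold only; one glmnet path
#' fit per fold covers the whole grid). Returns the argmax; ties resolve to
#' the strongest penalty. Folds whose validation side is single-class are
#' skipped with a warning; if all folds are skipped an error is raised.
#'
#' @param X normalized training matrix.
#' @param y binary training labels.
#' @param config a [modelingConfig()].
#' @return List with `C` (chosen), `meanAUC` (per grid value).
#' @export
tuneRegularization <- function(X, y, config) {
  grid <- config$regGrid
  if (length(grid) == 1L) return(list(C = grid, meanAUC = NA_real_))
  n <- nrow(X)
  aucs <- matrix(NA_real_, 0, length(grid))
  for (r in seq_len(config$cvRounds)) {
    foldId <- sample(rep(seq_len(config$cvFolds), length.out = n))
    for (f in seq_len(config$cvFolds)) {
      val <- which(foldId == f)
      trn <- which(foldId != f)
      if (length(unique(y[val])) < 2L) {
        warning("inner fold with single-class validation skipped")
        next
      }
      if (length(unique(y[trn])) < 2L) next
      os <- oversampleMinority(X[trn, , drop = FALSE], y[trn])
      lam <- .lambdaOf(grid, nrow(os$X))
      fit <- glmnet::glmnet(.padX(os$X), os$y, family = "binomial", alpha = 1,
                            lambda = sort(lam, decreasing = TRUE),
                            standardize = FALSE, thresh = 1e-8)
      pred <- glmnet::predict.glmnet(fit, .padX(X[val, , drop = FALSE]),
                                     s = lam)
      aucs <- rbind(aucs, vapply(seq_along(grid), function(k)
        .aucScore(pred[, k], y[val]), numeric(1)))
    }
  }
  if (nrow(aucs) == 0L) stop("all inner folds were skipped; cannot tune")
  meanAUC <- colMeans(aucs, na.rm = TRUE)
  best <- max(meanAUC)
  chosen <- grid[which(meanAUC >= best - 1e-12)][1L] # smallest C among ties
  list(C = chosen, meanAUC = setNames(meanAUC, format(grid)))
}

.drawSplit <- function(n, labels, config) {
  nTest <- max(1L, round(n * config$testFraction))
  for (try in seq_len(config$maxRedraws)) {
    if (config$stratified) {
      pos <- which(labels == 1); neg <- which(labels == 0)
      nPosT <- max(1L, round(length(pos) * config$testFraction))
      nNegT <- max(1L, round(length(neg) * config$testFraction))
      testIdx <- sort(c(sample(pos, nPosT), sample(neg, nNegT)))
    } else {
      testIdx <- sort(sample(n, nTest))
    }
    trainIdx <- setdiff(seq_len(n), testIdx)
    if (length(unique(labels[testIdx])) == 2L &&
        length(unique(labels[trainIdx])) == 2L)
      return(list(train = trainIdx, test = testIdx, redraws = try - 1L))
  }
  stop("could not draw a two-class test partition within the redraw bound")
}

.runOneSplit <- function(X, y, config, splitSeed, k) {
  set.seed(splitSeed)
  part <- .drawSplit(nrow(X), y, config)
  nm <- minmaxNormalize(X[part$train, , drop = FALSE],
                        X[part$test, , drop = FALSE])
  tuned <- tuneRegularization(nm$train, y[part$train], config)
  os <- oversampleMinority(nm$train, y[part$train])
  fit <- fitLassoLogistic(os$X, os$y, tuned$C)
  scores <- as.numeric(nm$applied %*% fit$coefficients + fit$intercept)
  list(split = k, seed = splitSeed,
       trainIdx = part$train, testIdx = part$test, redraws = part$redraws,
       bounds = nm$bounds, chosenC = tuned$C,
       intercept = fit$intercept, coefficients = fit$coefficients,
       selected = fit$selected,
       testScores = scores, testLabels = y[part$test],
       testAUC = .aucScore(scores, y[part$test]))
}

#' Run the repeated-holdout protocol on one feature group
#'
#' Applies the per-split protocol described above `nSplits` times. The split
#' partitions depend only on the master seed, the number of patients and the
#' labels, so groups modeled with the same configuration share identical
#' partitions and can be compared pairwise.
#'
#' @param table a [FeatureTable-class] (redundancy-filter dosiomic tables
#'   first with [spearmanRedundancyFilter()]).
#' @param config a [modelingConfig()].
#' @return A [GroupResult-class].
#' @export
runGroup <- function(table, config = modelingConfig()) {
  X <- table@values
  y <- table@labels
  set.seed(config$seed)
  splitSeeds <- sample.int(2147483646L, config$nSplits)
  splits <- lapply(seq_len(config$nSplits), function(k)
    .runOneSplit(X, y, config, splitSeeds[k], k))
  new("GroupResult", groupTag = table@groupTag,
      featureNames = colnames(X), labels = y, splits = splits,
      config = unclass(config))
}

#' Replay one stored split (leakage / reproducibility audit)
#'
#' Re-runs the whole per-split protocol from the stored per-split seed using
#' only the original table, and returns the freshly computed split result.
#' Identity with the stored one certifies that normalization bounds,
#' oversampling and tuning use training rows only.
#'
#' @param table the [FeatureTable-class] the group was modeled on.
#' @param result a [GroupResult-class].
#' @param k split index to replay.
#' @return A split-result list comparable to `splitResults(result)[[k]]`.
#' @export
refitSplit <- function(table, result, k) {
  stored <- result@splits[[k]]
  cfg <- do.call(modelingConfig, result@config[setdiff(names(result@config),
                                                       character(0))])
  .runOneSplit(table@values, table@labels, cfg, stored$seed, k)
}
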