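## Synthetic fractionated-cohort generator.
##
## Emulates the statistical structure the analysis assumes: ~100 patients,
## 62% RP-positive prevalence, prescriptions of 30-60 Gy at 1.8-3 Gy per
## fraction, fraction-to-fraction beam-arrangement variation (so per-voxel
## fraction size varies and EQD2 differs from the physical sum), a two-lobed
## ellipsoidal lung mask, and a plantable logistic association between RP and
## both a mid-dose DVH metric (V40) and a texture characteristic (NGTDM
## busyness, driven by the correlation length of a multiplicative smooth
## noise field). Ground-truth covariates are the realized feature values
## computed on the native summed grid, not the nominal knobs.

#' Synthetic cohort specification
#'
#' @param nPatients cohort size (study scale: 101; desk preset: 60).
#' @param positiveFraction target RP grade >= 1 prevalence (0.62).
#' @param gridDim,spacing native dose-grid geometry (desk preset: 24^3 voxels
#'   at 6 mm, resampled to 1.5 mm by the analysis pipeline).
#' @param prescriptionRange total prescription range in Gy.
#' @param fractionDoseRange prescription dose per fraction range in Gy.
#' @param beamHeterogeneity probability that a fraction is delivered with a
#'   re-sampled beam arrangement (same target dose, different spatial
#'   distribution).
#' @param beamSigmaRange per-patient range of the beams' Gaussian cross-profile
#'   width (fraction of grid extent); varies field sizes across patients.
#' @param attenuationRange per-patient range of the linear depth-attenuation
#'   factor.
#' @param noiseAmplitude relative amplitude of the smooth multiplicative
#'   noise field that creates dose texture.
#' @param correlationLengthRange per-patient range (in voxels) of the noise
#'   field's Gaussian correlation length; short lengths produce busy texture.
#' @param labelModel named list of log-odds coefficients on the standardized
#'   ground-truth covariates `v40` and `busyness`; the intercept is solved so
#'   the expected prevalence equals `positiveFraction`.
#' @param gradeProportions proportions of RP grades 0/1/2 (0.38/0.57/0.05).
#' @param modalityProportion probability a patient is tagged 3DCRT (vs IMRT);
#'   modality is independent of outcome.
#' @param seed master seed for the cohort.
#' @return A named list of class `CohortSpec`.
#' @export
cohortSpec <- function(nPatients = 101L, positiveFraction = 0.62,
                       gridDim = c(24L, 24L, 24L), spacing = c(6, 6, 6),
                       prescriptionRange = c(30, 60),
                       fractionDoseRange = c(1.8, 3.0),
                       beamHeterogeneity = 0.3,
                       beamSigmaRange = c(0.17, 0.25),
                       attenuationRange = c(0.25, 0.45),
                       noiseAmplitude = 0.10,
                       correlationLengthRange = c(0.7, 3.0),
                       labelModel = list(v40 = 1.2, busyness = -1.2),
                       gradeProportions = c(0.38, 0.57, 0.05),
                       modalityProportion = 0.85,
                       seed = 1L) {
  stopifnot(positiveFraction > 0, positiveFraction < 1,
            fractionDoseRange[1] >= 1.8, fractionDoseRange[2] <= 3.0)
  structure(list(nPatients = as.integer(nPatients),
                 positiveFraction = positiveFraction,
                 gridDim = as.integer(gridDim), spacing = as.numeric(spacing),
                 prescriptionRange = prescriptionRange,
                 fractionDoseRange = fractionDoseRange,
                 beamHeterogeneity = beamHeterogeneity,
                 beamSigmaRange = beamSigmaRange,
                 attenuationRange = attenuationRange,
                 noiseAmplitude = noiseAmplitude,
                 correlationLengthRange = correlationLengthRange,
                 labelModel = labelModel,
                 gradeProportions = gradeProportions,
                 modalityProportion = modalityProportion,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Desk-scale cohort preset
#'
#' 60 patients on the default 24^3 / 6 mm grid; pair with
#' [deskModelingConfig()] for quick end-to-end runs.
#' @param ... overrides passed to [cohortSpec()].
#' @export
deskCohortSpec <- function(...) {
  args <- list(nPatients = 60L)
  args[names(list(...))] <- list(...)
  do.call(cohortSpec, args)
}

# Two-lobed ellipsoidal lung with a mediastinal corridor cut out.
.lungMask <- function(spec) {
  d <- spec$gridDim
  x <- (seq_len(d[1]) - 0.5) / d[1]
  y <- (seq_len(d[2]) - 0.5) / d[2]
  z <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  lobe <- function(cx) ((X - cx) / 0.17)^2 + ((Y - 0.5) / 0.30)^2 +
    ((Z - 0.5) / 0.40)^2 <= 1
  m <- (lobe(0.28) | lobe(0.72)) & abs(X - 0.5) > 0.08
  RoiMask(array(as.numeric(m), d), spec$spacing)
}

# Four beam field templates (AP/PA/left/right), Gaussian cross profiles
# through the mediastinal target with linear depth attenuation; each is
# normalized to 1 at the grid centre.
.beamFields <- function(spec, sigma = 0.21, attn = 0.35) {
  d <- spec$gridDim
  x <- (seq_len(d[1]) - 0.5) / d[1]
  y <- (seq_len(d[2]) - 0.5) / d[2]
  z <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  prof <- function(u, v) exp(-((u - 0.5)^2 + (v - 0.5)^2) / (2 * sigma^2))
  att <- function(depth) 1 - attn * depth
  fields <- list(ap = prof(X, Z) * att(Y),
                 pa = prof(X, Z) * att(1 - Y),
                 lt = prof(Y, Z) * att(X),
                 rt = prof(Y, Z) * att(1 - X))
  ctr <- ceiling(d / 2)
  lapply(fields, function(f) f / f[ctr[1], ctr[2], ctr[3]])
}

# Smooth unit-variance Gaussian random field via separable circular
# convolution of white noise with a Gaussian kernel of sd `ell` voxels.
.smoothNoise <- function(d, ell) {
  arr <- array(rnorm(prod(d)), d)
  if (ell > 0.05) {
    for (axis in 1:3) {
      n <- d[axis]
      half <- min(n %/% 2, max(1L, ceiling(3 * ell)))
      k <- exp(-(seq(-half, half))^2 / (2 * ell^2))
      k <- k / sum(k)
      kpad <- numeric(n)
      kpad[((seq(-half, half)) %% n) + 1] <-
        kpad[((seq(-half, half)) %% n) + 1] + k
      K <- fft(kpad)
      arr <- apply(arr, setdiff(1:3, axis), function(line)
        Re(fft(fft(line) * K, inverse = TRUE)) / n)
      arr <- aperm(arr, order(c(axis, setdiff(1:3, axis))))
    }
  }
  arr / sd(arr)
}

#' Generate one synthetic patient
#'
#' Builds the lung mask, samples a prescription and fraction count, composes
#' per-fraction dose grids from weighted beam fields (re-weighted with
#' probability `beamHeterogeneity` per fraction) modulated by a smooth
#' patient-specific noise field, and records ground-truth covariates (V40 and
#' NGTDM busyness of the native summed physical dose).
#'
#' @param spec a [cohortSpec()].
#' @param patientSeed integer seed for this patient.
#' @param patientId identifier string.
#' @return List with `series` ([FractionSeries-class]), `mask`
#'   ([RoiMask-class]), `trueV40`, `trueBusyness`, `prescription`,
#'   `fractionDose`, `nFractions`, `modality`.
#' @export
generatePatient <- function(spec, patientSeed, patientId = "P1") {
  set.seed(patientSeed)
  mask <- .lungMask(spec)
  beams <- .beamFields(spec,
                       sigma = runif(1, spec$beamSigmaRange[1],
                                     spec$beamSigmaRange[2]),
                       attn = runif(1, spec$attenuationRange[1],
                                    spec$attenuationRange[2]))
  prescription <- runif(1, spec$prescriptionRange[1], spec$prescriptionRange[2])
  fd <- if (runif(1) < 0.6) spec$fractionDoseRange[1] else
    runif(1, spec$fractionDoseRange[1], spec$fractionDoseRange[2])
  nFrac <- max(1L, as.integer(round(prescription / fd)))
  ell <- runif(1, spec$correlationLengthRange[1],
               spec$correlationLengthRange[2])
  noise <- .smoothNoise(spec$gridDim, ell)
  texture <- pmax(0, 1 + spec$noiseAmplitude * noise)
  baseW <- rgamma(length(beams), shape = 1)
  baseW <- baseW / sum(baseW)
  mix <- function(w) {
    f <- beams[[1]] * w[1]
    for (b in 2:length(beams)) f <- f + beams[[b]] * w[b]
    f / sum(w)  # fields are centre-normalized, so mix is 1 at target
  }
  fracs <- vector("list", nFrac)
  for (i in seq_len(nFrac)) {
    w <- baseW
    if (runif(1) < spec$beamHeterogeneity) {
      w <- rgamma(length(beams), shape = 1)
      w <- w / sum(w)
    }
    fracs[[i]] <- DoseGrid(fd * mix(w) * texture, spec$spacing)
  }
  series <- FractionSeries(patientId, fracs)
  dsum <- sumFractions(series)
  # ground-truth texture covariate: busyness of the dose field rescaled to a
  # common mean lung dose, so the covariate tracks spatial texture (the noise
  # correlation length) and not the prescription level
  sc <- 20 / meanLungDose(dsum, mask)
  dref <- DoseGrid(gridValues(dsum) * sc, spec$spacing)
  busy <- suppressWarnings(
    ngtdmFeatures(discretizeDose(dref, mask))[["ngtdm_Busyness"]])
  modality <- if (runif(1) < spec$modalityProportion) "3DCRT" else "IMRT"
  list(series = series, mask = mask,
       trueV40 = relativeVolumeAbove(dsum, mask, 40),
       trueBusyness = busy,
       prescription = prescription, fractionDose = fd, nFractions = nFrac,
       modality = modality)
}

#' Plant the RP outcome on generated patients
#'
#' Standardizes the stored ground-truth covariates across the cohort, forms
#' the linear predictor from the label-model coefficients, solves the
#' intercept so the expected prevalence matches `positiveFraction`, and draws
#' RP grades (positives split between grades 1 and 2 by the specified
#' proportions).
#'
#' @param patients list of [generatePatient()] outputs.
#' @param spec the [cohortSpec()] used.
#' @return data.frame with `patientId`, `rpGrade`, `label`, `linearPredictor`,
#'   `probability`, `trueV40`, `trueBusyness`, `modality`, `prescription`,
#'   `fractionDose`, `nFractions`.
#' @export
plantOutcome <- function(patients, spec) {
  zstd <- function(v) if (length(v) > 1 && sd(v) > 0) (v - mean(v)) / sd(v)
                      else v * 0
  v40 <- vapply(patients, `[[`, numeric(1), "trueV40")
  busy <- vapply(patients, `[[`, numeric(1), "trueBusyness")
  lp <- spec$labelModel$v40 * zstd(v40) + spec$labelModel$busyness * zstd(busy)
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - spec$positiveFraction,
                c(-30, 30))$root
  pr <- plogis(b0 + lp)
  label <- rbinom(length(pr), 1, pr)
  pGrade2 <- spec$gradeProportions[3] /
    (spec$gradeProportions[2] + spec$gradeProportions[3])
  grade <- ifelse(label == 1, 1L + rbinom(length(pr), 1, pGrade2), 0L)
  data.frame(
    patientId = vapply(patients, function(p) patientId(p$series), character(1)),
    rpGrade = grade, label = as.integer(label),
    linearPredictor = b0 + lp, probability = pr,
    trueV40 = v40, trueBusyness = busy,
    modality = vapply(patients, `[[`, character(1), "modality"),
    prescription = vapply(patients, `[[`, numeric(1), "prescription"),
    fractionDose = vapply(patients, `[[`, numeric(1), "fractionDose"),
    nFractions = vapply(patients, `[[`, numeric(1), "nFractions"))
}

#' Simulate a full synthetic cohort
#'
#' @param spec a [cohortSpec()].
#' @return List of class `SyntheticCohort` with `patients` (list), `table`
#'   (the [plantOutcome()] data.frame) and `spec`.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  set.seed(spec$seed)
  patientSeeds <- sample.int(2147483646L, spec$nPatients)
  patients <- lapply(seq_len(spec$nPatients), function(i)
    generatePatient(spec, patientSeeds[i], sprintf("P%03d", i)))
  set.seed(spec$seed + 1L) # label stream separate from patient streams
  tab <- plantOutcome(patients, spec)
  structure(list(patients = patients, table = tab, spec = spec,
                 patientSeeds = patientSeeds),
            class = "SyntheticCohort")
}

#' Write / read a cohort in the fixture format
#'
#' `writeCohort` writes one directory per patient (mask plus one `.dgrid`
#' volume per fraction), a cohort CSV and a JSON manifest with the spec and
#' seeds; `readCohort` reconstructs the fraction series and masks.
#'
#' @param cohort a [simulateCohort()] result.
#' @param dir output directory (created if needed).
#' @return `writeCohort`: the manifest path, invisibly. `readCohort`: a list
#'   with `patients` (each: `series`, `mask`) and `table`.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    pid <- patientId(p$series)
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    writeVolume(p$mask, file.path(pdir, "mask.dgrid"))
    fr <- fractions(p$series)
    for (i in seq_along(fr))
      writeVolume(fr[[i]], file.path(pdir, sprintf("fraction_%03d.dgrid", i)))
  }
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(spec = unclass(cohort$spec),
                            patientSeeds = cohort$patientSeeds),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  patients <- lapply(tab$patientId, function(pid) {
    pdir <- file.path(dir, pid)
    mask <- readVolume(file.path(pdir, "mask.dgrid"), mask = TRUE)
    files <- sort(list.files(pdir, pattern = "^fraction_.*\\.dgrid$",
                             full.names = TRUE))
    series <- FractionSeries(pid, lapply(files, readVolume))
    list(series = series, mask = mask)
  })
  list(patients = patients, table = tab)
}
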