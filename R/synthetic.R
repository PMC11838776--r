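## Synthetic multi-dataset human cohorts and rat LPS phantoms with the
## statistical structure the quantification method assumes: two-tissue
## kinetics whose binding rate follows a regional expression pattern,
## genotype/age/sex modulation, dataset sensitivity offsets, and
## frame-duration-scaled noise.

#' Default region roster for synthetic human cohorts
#'
#' A reduced brain parcellation mirroring the anatomy the method trains
#' on: bilateral thalamus and pallidum as high-expression training regions,
#' occipital and dorsal/ventrolateral cerebellar regions as low-expression
#' training regions, and a spread of cortical plus cerebellar regions as
#' the cortex-and-cerebellum (CC) prediction domain. Each region carries a
#' lobe assignment and a baseline delivery `K1`.
#'
#' @return data.frame with columns `roi_id`, `lobe`, `class_label`
#'   (low/high/unlabelled), `cc` (logical, prediction domain) and
#'   `baseK1` (mL/cm3/min).
#' @export
defaultRegionRoster <- function() {
  df <- rbind(
    data.frame(roi_id = c("thalamus_l", "thalamus_r",
                          "pallidum_l", "pallidum_r"),
               lobe = "subcortical", class_label = "high", cc = FALSE,
               baseK1 = 0.125),
    data.frame(roi_id = c("occipital_sup_l", "occipital_sup_r",
                          "occipital_inf_l", "occipital_inf_r"),
               lobe = "occipital", class_label = "low", cc = TRUE,
               baseK1 = 0.105),
    data.frame(roi_id = c("cerebellum_dorsal_l", "cerebellum_dorsal_r"),
               lobe = "cerebellum", class_label = "low", cc = TRUE,
               baseK1 = 0.10),
    data.frame(roi_id = c("frontal_sup", "frontal_mid", "frontal_inf",
                          "precentral"),
               lobe = "frontal", class_label = "unlabelled", cc = TRUE,
               baseK1 = 0.115),
    data.frame(roi_id = c("temporal_sup", "temporal_mid", "insula"),
               lobe = "temporal", class_label = "unlabelled", cc = TRUE,
               baseK1 = 0.11),
    data.frame(roi_id = c("parietal_sup", "parietal_inf", "postcentral"),
               lobe = "parietal", class_label = "unlabelled", cc = TRUE,
               baseK1 = 0.112),
    data.frame(roi_id = c("occipital_mid_l", "occipital_mid_r"),
               lobe = "occipital", class_label = "unlabelled", cc = TRUE,
               baseK1 = 0.105),
    data.frame(roi_id = c("cerebellum_crus_l", "cerebellum_crus_r",
                          "cerebellum_medial"),
               lobe = "cerebellum", class_label = "unlabelled", cc = TRUE,
               baseK1 = 0.10))
  rownames(df) <- NULL
  df
}

#' Deterministic regional expression map for a roster
#'
#' Assigns target-expression scores that reproduce the qualitative
#' pattern the method trains on: high-labelled (thalamic/pallidal
#' analogue) regions occupy the top band, low-labelled (occipital/
#' cerebellar analogue) regions the bottom band, and the remaining CC
#' regions an evenly spread middle band (the medial cerebellar analogue
#' sits at the top of the middle band). The map is a pure function of the
#' roster - no randomness - so cohort seeds change noise realisations but
#' never the ground-truth structure.
#'
#' @param roster data.frame as from [defaultRegionRoster()].
#' @return expression-map data.frame (`roi_id`, `expression`,
#'   `class_label`).
#' @export
generateExpressionMap <- function(roster = defaultRegionRoster()) {
  stopifnot(nrow(roster) > 0L,
            all(c("low", "high") %in% roster$class_label))
  n_hi <- sum(roster$class_label == "high")
  n_lo <- sum(roster$class_label == "low")
  n_mid <- sum(roster$class_label == "unlabelled")
  expr <- numeric(nrow(roster))
  expr[roster$class_label == "high"] <-
    seq(0.85, 1.00, length.out = max(n_hi, 1L))
  expr[roster$class_label == "low"] <-
    seq(0.02, 0.14, length.out = max(n_lo, 1L))
  mid <- which(roster$class_label == "unlabelled")
  expr[mid] <- seq(0.20, 0.62, length.out = max(n_mid, 1L))
  medial <- which(roster$roi_id == "cerebellum_medial")
  if (length(medial)) expr[medial] <- 0.58
  data.frame(roi_id = roster$roi_id, expression = expr,
             class_label = roster$class_label)
}

#' Configuration of a synthetic human cohort
#'
#' Encodes the generative model: per-dataset sample sizes and log-scale
#' sensitivity offsets, the frame schedule, the region roster and its
#' expression map, the genotype mix and the MAB binding factor, age/sex
#' effects, dose and weight distributions, the kinetic parameter map
#' (binding `k3` rises linearly with regional expression) and the
#' frame-count noise heuristic (Gaussian, variance proportional to
#' activity over frame duration).
#'
#' @param nSubjects named integer vector, subjects per dataset.
#' @param datasetOffsets numeric, additive log-scale sensitivity per
#'   dataset (global multiplicative factor `exp(offset)` on measured
#'   activity).
#' @param schedule a [FrameSchedule-class].
#' @param roster region roster (see [defaultRegionRoster()]).
#' @param habFraction fraction of high-affinity binders.
#' @param mabFactor multiplicative factor on `k3` for mixed-affinity
#'   binders (stand-in for the in-vivo affinity ratio).
#' @param ageRange years, uniform draw; `ageSlope` relative change of `k3`
#'   per year away from 40.
#' @param maleFraction fraction of males; `femaleFactor` multiplicative
#'   `k3` factor for females.
#' @param doseMean,doseSd injected dose, MBq; `weightMean,weightSd` kg.
#' @param k2,k4 efflux and dissociation rates, 1/min.
#' @param k3Base,k3Span binding rate `k3 = k3Base + k3Span * expression`.
#' @param subjectBindingSd,regionJitterSd log-normal standard deviations
#'   of the per-subject global binding factor and the per-subject,
#'   per-region binding jitter, emulating the large inter- and
#'   intra-individual TSPO signal variability the method is designed to
#'   absorb.
#' @param inputJitterSd,k1JitterSd log-normal standard deviations of the
#'   per-subject input-amplitude jitter and the per-region delivery
#'   jitter. Setting these and the binding variability to 0 with a zero
#'   `noiseScale` yields identical TACs for subjects with identical
#'   covariates.
#' @param vb fractional blood volume.
#' @param bindingScale global multiplier on `k3` (1 = healthy; 1.3 mimics
#'   a +30% disease elevation, 0.4 a -60% blocking scan).
#' @param noiseScale noise multiplier; 0 gives noiseless cohorts.
#' @param seed integer, mandatory.
#' @return validated list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(nSubjects = c(ds1 = 72L, ds2 = 27L, ds3 = 26L),
                         datasetOffsets = c(ds1 = 0, ds2 = -0.15,
                                            ds3 = 0.15),
                         schedule = pbr28Schedule(),
                         roster = defaultRegionRoster(),
                         habFraction = 0.7, mabFactor = 0.5,
                         ageRange = c(20, 70), ageSlope = 0.004,
                         maleFraction = 0.6, femaleFactor = 0.95,
                         doseMean = 330, doseSd = 33,
                         weightMean = 75, weightSd = 12,
                         k2 = 0.04, k3Base = 0.02, k3Span = 0.13,
                         k4 = 0.02, vb = 0.03,
                         subjectBindingSd = 0.3, regionJitterSd = 0.15,
                         inputJitterSd = 0.10, k1JitterSd = 0.05,
                         bindingScale = 1, noiseScale = 0.7,
                         seed = 1L) {
  stopifnot(length(nSubjects) == length(datasetOffsets),
            all(nSubjects >= 1L),
            habFraction >= 0, habFraction <= 1,
            maleFraction >= 0, maleFraction <= 1,
            mabFactor > 0, noiseScale >= 0, bindingScale > 0,
            is(schedule, "FrameSchedule"))
  if (missing(seed) && is.null(seed)) stop("seed is mandatory")
  if (!all(c("low", "high") %in% roster$class_label))
    stop("roster needs at least one low and one high region")
  structure(as.list(environment()), class = "CohortConfig")
}

## subject-specific tri-exponential input model, scaled by dose/weight
.subjectInput <- function(doseOverWeight, jitter = rep(1, 3)) {
  scale <- doseOverWeight / 4.4     # reference ~330 MBq / 75 kg
  triExpInput(amplitudes = scale * c(30, 6, 3) * jitter,
              rates = c(3.5, 0.35, 0.015), peakTime = 1.0)
}

#' Generate a synthetic multi-dataset human cohort
#'
#' Draws per-subject covariates, builds a dose-scaled tri-exponential
#' input, simulates a two-tissue TAC per region (binding `k3` follows the
#' regional expression score, modulated by genotype, age and sex, and by
#' `bindingScale`), applies the dataset sensitivity factor and adds
#' zero-mean Gaussian noise with variance proportional to activity over
#' frame duration. All randomness is governed by `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return list with `tacs` (a [TacExperiment-class], kBq/mL, subjects
#'   attached), `subjects` (covariate DataFrame), `inputs` (named list of
#'   true [TriExpFit-class] input models per subject), `expressionMap`,
#'   `roster`, and `truth` (data.frame of generating kinetic parameters
#'   per subject x region).
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()))
  set.seed(config$seed)

  roster <- config$roster
  emap <- generateExpressionMap(roster)
  sched <- config$schedule
  dsNames <- names(config$nSubjects)
  if (is.null(dsNames)) dsNames <- paste0("ds", seq_along(config$nSubjects))

  subjects <- do.call(rbind, lapply(seq_along(dsNames), function(d) {
    n <- config$nSubjects[d]
    data.frame(
      subject_id = sprintf("%s_s%02d", dsNames[d], seq_len(n)),
      age = round(stats::runif(n, config$ageRange[1], config$ageRange[2]), 1),
      sex = ifelse(stats::runif(n) < config$maleFraction, "male", "female"),
      genotype = ifelse(stats::runif(n) < config$habFraction, "HAB", "MAB"),
      injected_dose = pmax(stats::rnorm(n, config$doseMean, config$doseSd),
                           config$doseMean / 3),
      weight = pmax(stats::rnorm(n, config$weightMean, config$weightSd),
                    config$weightMean / 3),
      dataset_id = dsNames[d],
      group_label = "HC")
  }))
  rownames(subjects) <- NULL

  nR <- nrow(roster)
  inputs <- list()
  rowsAct <- vector("list", nrow(subjects) * nR)
  truth <- vector("list", nrow(subjects))
  rid <- 0L
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    dow <- s$injected_dose / s$weight
    jit <- exp(stats::rnorm(3, 0, config$inputJitterSd))
    inp <- .subjectInput(dow, jit)
    inputs[[s$subject_id]] <- inp
    gfac <- if (s$genotype == "HAB") 1 else config$mabFactor
    afac <- 1 + config$ageSlope * (s$age - 40)
    sfac <- if (s$sex == "male") 1 else config$femaleFactor
    sens <- exp(config$datasetOffsets[[s$dataset_id]])
    bfac <- exp(stats::rnorm(1, 0, config$subjectBindingSd))
    rjit <- exp(stats::rnorm(nR, 0, config$regionJitterSd))
    k3s <- (config$k3Base + config$k3Span * emap$expression) *
      gfac * afac * sfac * bfac * rjit * config$bindingScale
    K1s <- roster$baseK1 * exp(stats::rnorm(nR, 0, config$k1JitterSd))
    for (r in seq_len(nR)) {
      p <- compartmentParams(K1 = K1s[r], k2 = config$k2,
                             k3 = max(k3s[r], 1e-4), k4 = config$k4,
                             vb = config$vb)
      ct <- simulateTissueTac(p, inp, sched) * sens
      if (config$noiseScale > 0) {
        sd_ <- config$noiseScale *
          sqrt(pmax(ct, 0) / frameDuration(sched))
        ## non-negativity floor, as iterative (OSEM-style) reconstructions
        ## enforce on the measured activity
        ct <- pmax(ct + stats::rnorm(length(ct), 0, sd_), 0)
      }
      rid <- rid + 1L
      rowsAct[[rid]] <- ct
    }
    truth[[i]] <- data.frame(subject_id = s$subject_id,
                             roi_id = roster$roi_id,
                             K1 = K1s, k2 = config$k2, k3 = k3s,
                             k4 = config$k4, vb = config$vb,
                             expression = emap$expression,
                             class_label = roster$class_label,
                             sens = sens)
  }
  act <- do.call(rbind, rowsAct[seq_len(rid)])
  te <- TacExperiment(act, sched,
                      subjectId = rep(subjects$subject_id, each = nR),
                      roiId = rep(roster$roi_id, nrow(subjects)),
                      subjects = subjects)
  list(tacs = te, subjects = S4Vectors::DataFrame(subjects),
       inputs = inputs, expressionMap = emap, roster = roster,
       truth = do.call(rbind, truth))
}

#' Default rat region roster (13 bilateral ROIs)
#'
#' @return character vector of ROI base names; the first seven are the
#'   regions lesioned by the intracerebral LPS challenge in the default
#'   phantom (cortex, basal ganglia, corpus callosum, amygdala, septal
#'   area, ventricles, white matter).
#' @export
ratRegionRoster <- function() {
  c("cortex", "basal_ganglia", "corpus_callosum", "amygdala",
    "septal_area", "ventricles", "white_matter",
    "hippocampus", "thalamus", "hypothalamus", "cerebellum",
    "brainstem", "midbrain")
}

#' Configuration of the rat LPS phantom
#'
#' @param nIc,nIp,nVehicle animals per group (intracerebral LPS,
#'   intraperitoneal LPS, vehicle).
#' @param lesionRois ROI base names elevated ipsilaterally in ic-LPS
#'   animals.
#' @param lesionFactor multiplicative `k3` elevation in the lesioned ROIs.
#' @param ipFactor global mild bilateral `k3` elevation in ip-LPS animals.
#' @param schedule a [FrameSchedule-class] (default 60-minute binning).
#' @param noiseScale as in [cohortConfig()].
#' @param seed integer, mandatory.
#' @return list of class `"RatConfig"`.
#' @export
ratConfig <- function(nIc = 4L, nIp = 8L, nVehicle = 8L,
                      lesionRois = ratRegionRoster()[1:7],
                      lesionFactor = 3, ipFactor = 1.5,
                      schedule = pbr28ShortSchedule(),
                      noiseScale = 0.05, seed = 1L) {
  stopifnot(nIc >= 1L, nIp >= 1L, nVehicle >= 1L, lesionFactor > 0,
            ipFactor > 0, all(lesionRois %in% ratRegionRoster()))
  structure(as.list(environment()), class = "RatConfig")
}

#' Generate the rat LPS phantom scan sets
#'
#' Simulates 13 bilateral ROI TACs per animal for three groups: ic-LPS
#' animals carry elevated binding in the configured ipsilateral ROIs only,
#' ip-LPS animals a mild global bilateral elevation, vehicle animals
#' baseline kinetics. ROI ids are `<roi>_ipsi` / `<roi>_contra`.
#'
#' @param config a [ratConfig()].
#' @return list with `tacs` (a [TacExperiment-class] over all animals),
#'   `subjects`, `inputs`, `lesionRois`, and `truth`.
#' @export
generateRatPhantom <- function(config = ratConfig()) {
  stopifnot(inherits(config, "RatConfig"))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()))
  set.seed(config$seed + 7L)

  rois <- ratRegionRoster()
  groups <- rep(c("ic-LPS", "ip-LPS", "Vehicle"),
                c(config$nIc, config$nIp, config$nVehicle))
  ids <- sprintf("rat%02d", seq_along(groups))
  subjects <- data.frame(
    subject_id = ids, age = 0.25, sex = "male", genotype = "HAB",
    injected_dose = pmax(stats::rnorm(length(ids), 15, 1), 5),
    weight = pmax(stats::rnorm(length(ids), 0.30, 0.02), 0.15),
    dataset_id = "rat", group_label = groups)
  sched <- config$schedule
  k3base <- 0.02 + 0.10 * seq(0.1, 0.9, length.out = length(rois))
  names(k3base) <- rois
  baseK1 <- stats::setNames(rep(0.35, length(rois)), rois)

  inputs <- list(); rowsAct <- list(); truth <- list()
  for (i in seq_along(ids)) {
    s <- subjects[i, ]
    inp <- .subjectInput(s$injected_dose / s$weight / 11,
                         exp(stats::rnorm(3, 0, 0.08)))
    inputs[[s$subject_id]] <- inp
    for (roi in rois) {
      for (hemi in c("ipsi", "contra")) {
        k3 <- k3base[[roi]]
        if (s$group_label == "ic-LPS" && hemi == "ipsi" &&
            roi %in% config$lesionRois)
          k3 <- k3 * config$lesionFactor
        if (s$group_label == "ip-LPS") k3 <- k3 * config$ipFactor
        p <- compartmentParams(K1 = baseK1[[roi]], k2 = 0.05, k3 = k3,
                               k4 = 0.02, vb = 0.03)
        ct <- simulateTissueTac(p, inp, sched)
        if (config$noiseScale > 0)
          ct <- pmax(ct + stats::rnorm(length(ct), 0,
                                       config$noiseScale *
                                         sqrt(pmax(ct, 0) /
                                                frameDuration(sched))), 0)
        rowsAct[[length(rowsAct) + 1L]] <- ct
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = s$subject_id,
                     roi_id = paste(roi, hemi, sep = "_"),
                     group = s$group_label, k3 = k3,
                     lesioned = (hemi == "ipsi" &&
                                   s$group_label == "ic-LPS" &&
                                   roi %in% config$lesionRois))
      }
    }
  }
  truth <- do.call(rbind, truth)
  te <- TacExperiment(do.call(rbind, rowsAct), sched,
                      subjectId = truth$subject_id,
                      roiId = truth$roi_id, subjects = subjects)
  list(tacs = te, subjects = S4Vectors::DataFrame(subjects),
       inputs = inputs, lesionRois = config$lesionRois, truth = truth)
}
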