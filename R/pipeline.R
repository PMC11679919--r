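# End-to-end runs: atlas construction from simulated task data, and the
# two-group resting-state analysis under an atlas. Every stochastic stage
# derives its seed deterministically from the master seed.

#' Build a run configuration
#'
#' One structured configuration for the whole pipeline. Defaults are the
#' desk-scale study conditions: a 20x20x20 grid with 30 contiguous regions
#' (the 246-region whole-brain configuration is supported by raising
#' \code{nRegions}), 21 task subjects under the default alternating
#' paradigm, 4 active regions per emotion category at effect size 3 with
#' unit noise, and a 46-patient / 20-control resting cohort.
#'
#' @param gridShape integer(3) voxel grid.
#' @param nRegions parcellation regions.
#' @param nTaskSubjects task-stage subjects (default 21).
#' @param paradigm a \linkS4class{TaskParadigm}.
#' @param nActiveRegions active regions implanted per category.
#' @param activeVoxelFraction fraction of an active region's voxels carrying
#'   the effect.
#' @param effectSize stimulus effect in noise-sd units (noiseSd 1).
#' @param baseline baseline signal level.
#' @param noiseSd Gaussian noise sd.
#' @param rfeC box constraint for all RFE fits.
#' @param fcThreshold external-voxel correlation threshold (strict >).
#' @param nPatients,nControls resting cohort sizes.
#' @param restDurationS resting run length (s).
#' @param restTrS resting repetition time (s).
#' @param alffAmplitude,alffFreqHz implanted sinusoid amplitude and
#'   frequency for the patient-group clusters.
#' @param nAlffClusterVoxels voxels per implanted cluster.
#' @param classifier a \linkS4class{ClassifierConfig}.
#' @param alffBandHz ALFF band (default 0.01-0.08 Hz).
#' @param q FDR level (default 0.01).
#' @param connectivity cluster connectivity (default 26).
#' @param masterSeed master seed; stage seeds derive from it.
#' @param outputDir optional directory; when set, every stage writes its
#'   artifacts (NIfTI volumes, TSV tables, JSON summaries) under it.
#' @return a named list of class "RunConfig".
#' @export
runConfig <- function(gridShape = c(20, 20, 20), nRegions = 30,
                      nTaskSubjects = 21, paradigm = defaultTaskParadigm(),
                      nActiveRegions = 4, activeVoxelFraction = 0.5,
                      effectSize = 3, baseline = 100, noiseSd = 1,
                      rfeC = 1, fcThreshold = 0.95,
                      nPatients = 46, nControls = 20, restDurationS = 300,
                      restTrS = 2, alffAmplitude = 1.5, alffFreqHz = 0.04,
                      nAlffClusterVoxels = 6,
                      classifier = classifierConfig(),
                      alffBandHz = c(0.01, 0.08), q = 0.01,
                      connectivity = 26, masterSeed = 1, outputDir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

# stage seed offsets (stable identifiers, not tunables)
.stageOffsets <- c(parcellation = 1, taskSim = 2, roiRfe = 3, voxelRfe = 4,
                   restSim = 5, classify = 6, truth = 7)

stageSeed <- function(cfg, stage) deriveSeed(cfg$masterSeed, .stageOffsets[[stage]])

# pick active regions and implant clusters deterministically from the seed
.makeTruth <- function(cfg, parcellation) {
  withLocalSeed(stageSeed(cfg, "truth"), {
    ids <- sample(regionIds(parcellation))
    act <- list(positive = sort(ids[seq_len(cfg$nActiveRegions)]),
                negative = sort(ids[cfg$nActiveRegions + seq_len(cfg$nActiveRegions)]))
    # implant one patient-group cluster inside a positive-active region so the
    # resting-stage effect lies inside the atlas by construction
    host <- act$positive[1]
    vx <- regionVoxels(parcellation, host)
    lin <- ijkToLinear(vx, dim(labelVolume(parcellation)))
    n <- min(cfg$nAlffClusterVoxels, nrow(vx))
    cluster <- vx[order(lin)[seq_len(n)], , drop = FALSE]
    groundTruth(
      activePositive = act$positive, activeNegative = act$negative,
      activeVoxelFraction = cfg$activeVoxelFraction,
      effectSize = cfg$effectSize,
      alffClusters = list(list(group = "patient", voxels = cluster,
                               amplitude = cfg$alffAmplitude,
                               freqHz = cfg$alffFreqHz)))
  })
}

#' Build the positive and negative emotion atlases end to end
#'
#' Simulates the task cohort, segments blocks, assembles region-level
#' feature matrices, selects characteristic regions and sub-ROIs by
#' CV-averaged SVM-RFE, recruits external voxels by functional connectivity,
#' and assembles the two atlases. Deterministic per master seed.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{positive} and \code{negative}
#'   \linkS4class{EmotionAtlas}, the \code{parcellation}, \code{truth},
#'   \code{blocks} (per category), and an \code{audit} list of RFE results.
#' @export
runBuildAtlas <- function(config) {
  parcellation <- makeParcellation(config$gridShape, config$nRegions,
                                   seed = stageSeed(config, "parcellation"))
  truth <- .makeTruth(config, parcellation)

  subjects <- lapply(seq_len(config$nTaskSubjects), function(s)
    simulateTaskSubject(config$paradigm, parcellation, truth,
                        baseline = config$baseline, noiseSd = config$noiseSd,
                        seed = deriveSeed(stageSeed(config, "taskSim"), s),
                        subjectId = sprintf("sub%02d", s)))
  blocks <- unlist(lapply(subjects, segmentBlocks, paradigm = config$paradigm),
                   recursive = FALSE)

  out <- list(parcellation = parcellation, truth = truth, blocks = list(),
              audit = list())
  for (category in c("positive", "negative")) {
    catBlocks <- Filter(function(b) blockCategory(b) == category, blocks)
    fm <- assembleFeatureMatrix(catBlocks, parcellation, category, "roi")
    rois <- selectCharacteristicRois(fm, C = config$rfeC,
                                     seed = stageSeed(config, "roiRfe"))
    subs <- selectCharacteristicSubrois(catBlocks, parcellation,
                                        rois$regionIds, C = config$rfeC,
                                        seed = stageSeed(config, "voxelRfe"),
                                        category = category)
    ext <- fcExternalVoxels(catBlocks, parcellation, subs$subrois,
                            threshold = config$fcThreshold)
    atlas <- assembleAtlas(subs$subrois, ext, parcellation, category)
    out[[category]] <- atlas
    out$blocks[[category]] <- catBlocks
    out$audit[[category]] <- list(roiRfe = rois$rfe, voxelRfes = subs$rfes)
  }

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeParcellation(parcellation, file.path(config$outputDir, "parcellation.nii"))
    writeGroundTruth(truth, file.path(config$outputDir, "ground_truth.json"))
    for (category in c("positive", "negative")) {
      writeAtlasMask(out[[category]],
                     file.path(config$outputDir, paste0(category, "_atlas")))
      writeRfeAudit(out$audit[[category]]$roiRfe,
                    file.path(config$outputDir, paste0(category, "_roi_rfe.tsv")))
    }
  }
  out
}

#' Run the two-group resting-state analysis under an atlas
#'
#' Simulates the resting cohort, extracts per-subject atlas features,
#' performs the cost-sensitive RBF-SVM grid search (patient = positive
#' class), computes per-subject ALFF maps, and runs the covariate-adjusted
#' voxelwise comparison with BH-FDR control and cluster extraction.
#'
#' @param config a \code{\link{runConfig}} list.
#' @param atlas an \linkS4class{EmotionAtlas} (or list of atlases for
#'   concatenated features, e.g. \code{list(pea, nea)}).
#' @param parcellation the cohort \linkS4class{Parcellation}.
#' @param truth a \linkS4class{GroundTruth} carrying the resting implants.
#' @param scope "brain" (test all foreground voxels, default) or "atlas"
#'   (restrict the voxelwise test to atlas voxels).
#' @return list with \code{report} (\linkS4class{ClassificationReport}),
#'   \code{comparison} (\linkS4class{GroupComparison}), \code{cohort} and
#'   \code{maps}.
#' @export
runGroupAnalysis <- function(config, atlas, parcellation, truth,
                             scope = c("brain", "atlas")) {
  scope <- match.arg(scope)
  cohort <- simulateRestCohort(config$nPatients, config$nControls,
                               parcellation, truth,
                               durationS = config$restDurationS,
                               trS = config$restTrS,
                               baseline = config$baseline,
                               noiseSd = config$noiseSd,
                               seed = stageSeed(config, "restSim"))
  feats <- cohortAtlasFeatures(cohort, atlas, parcellation,
                               bandHz = config$alffBandHz)
  cc <- config$classifier
  cc@seed <- stageSeed(config, "classify")
  report <- gridSearchCslSvm(feats$X, feats$y, cc, positiveClass = "patient")

  maps <- lapply(cohort, alffMap, bandHz = config$alffBandHz,
                 parcellation = parcellation)
  isPat <- vapply(cohort, subjectGroup, "") == "patient"
  manifest <- cohortManifest(cohort)
  mask <- if (scope == "atlas") {
    a1 <- if (is(atlas, "EmotionAtlas")) list(atlas) else atlas
    Reduce(`|`, lapply(a1, function(a) atlasMask(a) > 0))
  } else labelVolume(parcellation) > 0
  comparison <- groupComparison(maps[isPat], maps[!isPat], parcellation,
                                age = manifest$age[c(which(isPat), which(!isPat))],
                                sex = manifest$sex[c(which(isPat), which(!isPat))],
                                mask = mask, q = config$q,
                                connectivity = config$connectivity)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    write.table(clusterTable(comparison),
                file.path(config$outputDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      accuracy = report@accuracy, precision = report@precision,
      recall = report@recall, f_score = report@fScore,
      best_C = report@bestC, best_gamma = report@bestGamma),
      file.path(config$outputDir, "classification_report.json"),
      auto_unbox = TRUE)
  }
  # maps ordered patients first to match the comparison input
  list(report = report, comparison = comparison, cohort = cohort,
       maps = c(maps[isPat], maps[!isPat]))
}
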