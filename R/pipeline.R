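#' Default pipeline run configuration
#'
#' Assembles the configuration consumed by [runStage()]/[runPipeline()]:
#' synthetic phantom and cohort settings, extraction settings, grid
#' settings and output locations. Every stage derives its RNG stream from
#' the single `seed`.
#'
#' @param outDir output directory for stage artifacts.
#' @param seed master seed.
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged shallowly per section).
#' @return a `RunConfig` list.
#' @export
defaultRunConfig <- function(outDir = tempfile("petrad_run_"), seed = 1L,
                             ...) {
  cfg <- list(
    seed = as.integer(seed),
    outDir = outDir,
    phantom = list(nPatients = 3L, dim = c(48L, 48L, 48L), spacing = 4,
                   background = 1, noiseSD = 0.05,
                   radiusRange = c(14, 26), peakRange = c(6, 14)),
    cohort = list(n = 177L, prevalence = 0.40, testFraction = 0.3),
    extract = list(nBins = 64L, minMTV = 10),
    grid = list(k = 5L, innerK = 3L, dropPerStep = 1L,
                paperProtocol = FALSE, features = NULL,
                params = list(trees = 100L, gbdt_nrounds = 50L,
                              adaboost_m = 25L)),
    survive = list(landmarks = c(12, 36, 60)))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file (.yaml/.yml/.json); fields override the
#'   defaults of [defaultRunConfig()].
#' @param outDir,seed optional overrides taking precedence over the file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path, outDir = NULL, seed = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  cfg <- do.call(defaultRunConfig, c(
    list(outDir = if (!is.null(outDir)) outDir else
           if (!is.null(raw$outDir)) raw$outDir else tempfile("petrad_run_"),
         seed = if (!is.null(seed)) seed else
           if (!is.null(raw$seed)) raw$seed else 1L),
    raw[setdiff(names(raw), c("outDir", "seed"))]))
  cfg
}

.stageOrder <- c("simulate", "segment", "extract", "crosscombo",
                 "radscore", "evaluate", "survive")
.stageNeeds <- list(simulate = character(0), segment = "simulate",
                    extract = "simulate", crosscombo = "simulate",
                    radscore = "crosscombo", evaluate = "radscore",
                    survive = "radscore")

.manifestPath <- function(cfg) file.path(cfg$outDir, "manifest.json")

.readManifest <- function(cfg) {
  p <- .manifestPath(cfg)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list()
}

.recordStage <- function(cfg, stage, files, settings = list()) {
  man <- .readManifest(cfg)
  man[[stage]] <- list(
    files = as.list(tools::md5sum(files)),
    seed = cfg$seed, settings = settings)
  jsonlite::write_json(man, .manifestPath(cfg), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

.requireStage <- function(cfg, stage) {
  for (need in .stageNeeds[[stage]]) {
    man <- .readManifest(cfg)
    if (is.null(man[[need]]))
      stop("stage '", stage, "' requires stage '", need,
           "' to be run first")
  }
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic phantoms + cohort, split 7:3),
#' `segment` (41%-SUVmax segmentation and metabolic metrics of the
#' phantoms), `extract` (110-feature table for the phantom patients),
#' `crosscombo` (7x7 grid on the training cohort), `radscore` (RadScore fit,
#' cutoffs, scored cohorts), `evaluate` (five logistic models, ROC AUCs,
#' calibration, DCA, nomogram) and `survive` (KM/log-rank/Cox by RadScore
#' group). Artifacts are written as CSV/JSON/NIfTI under `cfg$outDir` and
#' hashed into `manifest.json`; a stage whose prerequisites have not run
#' fails with an error naming the missing stage.
#'
#' @param cfg a `RunConfig` from [defaultRunConfig()]/[readRunConfig()].
#' @param stage one of the stage names above.
#' @return character vector of artifact paths, invisibly.
#' @export
runStage <- function(cfg, stage) {
  stage <- match.arg(stage, .stageOrder)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .requireStage(cfg, stage)
  t0 <- Sys.time()
  files <- switch(stage,
    simulate = .stageSimulate(cfg),
    segment = .stageSegment(cfg),
    extract = .stageExtract(cfg),
    crosscombo = .stageCrossCombo(cfg),
    radscore = .stageRadScore(cfg),
    evaluate = .stageEvaluate(cfg),
    survive = .stageSurvive(cfg))
  message(sprintf("[petrad] stage %-10s %6.1fs  (%d artifact%s)", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  length(files), if (length(files) == 1) "" else "s"))
  .recordStage(cfg, stage, files,
               settings = switch(stage,
                 simulate = cfg[c("phantom", "cohort")],
                 segment = cfg$extract, extract = cfg$extract,
                 crosscombo = cfg$grid, radscore = cfg$grid,
                 evaluate = list(), survive = cfg$survive))
  invisible(files)
}

#' Run the full pipeline
#'
#' @param cfg a `RunConfig`.
#' @param stages stages to run in order (default: all).
#' @return named list of artifact paths per stage, invisibly.
#' @export
runPipeline <- function(cfg, stages = .stageOrder) {
  out <- lapply(stages, function(s) runStage(cfg, s))
  names(out) <- stages
  invisible(out)
}

# ---- stage implementations --------------------------------------------------

.phantomDir <- function(cfg) file.path(cfg$outDir, "phantoms")

.stageSimulate <- function(cfg) {
  ph <- cfg$phantom
  pdir <- .phantomDir(cfg)
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  extent <- ph$dim * ph$spacing
  # textured lesions only: a uniform lesion has a degenerate (constant) VOI
  textures <- c("gaussian-noise", "checker", "radial-gradient")
  for (i in seq_len(ph$nPatients)) {
    si <- .subSeed(cfg$seed, i)
    ls <- .withSeed(si, {
      r <- stats::runif(1, ph$radiusRange[1], ph$radiusRange[2])
      lesionSpec(center = extent / 2, radii = r,
                 peak = stats::runif(1, ph$peakRange[1], ph$peakRange[2]),
                 texture = textures[(i - 1L) %% length(textures) + 1L])
    })
    p <- makePhantom(phantomSpec(dim = ph$dim, spacing = ph$spacing,
                                 background = ph$background,
                                 noiseSD = ph$noiseSD, lesions = list(ls),
                                 seed = si))
    vf <- file.path(pdir, sprintf("p%02d_volume.nii.gz", i))
    mf <- file.path(pdir, sprintf("p%02d_mask01.nii.gz", i))
    writeVolume(p$volume, vf)
    writeMask(p$masks[[1]], mf)
    files <- c(files, vf, mf)
  }
  tab <- simulateCohort(cohortSpec(n = cfg$cohort$n,
                                   prevalence = cfg$cohort$prevalence,
                                   seed = .subSeed(cfg$seed, 101L)))
  sp <- splitCohort(tab, cfg$cohort$testFraction,
                    seed = .subSeed(cfg$seed, 102L))
  cf <- file.path(cfg$outDir, "cohort.csv")
  tf <- file.path(cfg$outDir, "cohort_train.csv")
  vf2 <- file.path(cfg$outDir, "cohort_validation.csv")
  utils::write.csv(tab, cf, row.names = FALSE)
  utils::write.csv(sp$train, tf, row.names = FALSE)
  utils::write.csv(sp$validation, vf2, row.names = FALSE)
  c(files, cf, tf, vf2)
}

.stageSegment <- function(cfg) {
  pdir <- .phantomDir(cfg)
  vols <- sort(list.files(pdir, "_volume\\.nii\\.gz$", full.names = TRUE))
  rows <- lapply(vols, function(vf) {
    v <- readVolume(vf)
    ctr <- as.integer(dim(voxelData(v)) / 2)
    m <- segmentLesion(v, seed = ctr)
    keep <- filterLesions(list(m), v, minMTV = cfg$extract$minMTV)
    if (!length(keep)) return(NULL)
    mm <- metabolicMetrics(v, keep[[1]])
    sf <- sub("_volume", "_seg", vf)
    writeMask(keep[[1]], sf)
    data.frame(patient_id = sub("_volume.*", "", basename(vf)),
               lesion_id = lesionId(keep[[1]]), suvmax = mm$suvmax,
               suvmean = mm$suvmean, mtv_cm3 = mm$mtv_cm3, tlg = mm$tlg)
  })
  out <- file.path(cfg$outDir, "segmentation_metrics.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
  c(out, sort(list.files(pdir, "_seg\\.nii\\.gz$", full.names = TRUE)))
}

.stageExtract <- function(cfg) {
  pdir <- .phantomDir(cfg)
  vols <- sort(list.files(pdir, "_volume\\.nii\\.gz$", full.names = TRUE))
  patients <- lapply(vols, function(vf) {
    v <- readVolume(vf)
    ctr <- as.integer(dim(voxelData(v)) / 2)
    m <- segmentLesion(v, seed = ctr)
    list(volume = v, masks = list(m))
  })
  names(patients) <- sub("_volume.*", "", basename(vols))
  tab <- extractCohortFeatures(patients, minMTV = cfg$extract$minMTV,
                               nBins = cfg$extract$nBins)
  out <- file.path(cfg$outDir, "phantom_features.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  side <- file.path(cfg$outDir, "extraction_settings.json")
  jsonlite::write_json(cfg$extract, side, auto_unbox = TRUE, pretty = TRUE)
  c(out, side)
}

.gridFeatureCols <- function(cfg, train) {
  if (!is.null(cfg$grid$features)) return(cfg$grid$features)
  intersect(defaultCohortFeatures(), names(train))
}

.stageCrossCombo <- function(cfg) {
  train <- utils::read.csv(file.path(cfg$outDir, "cohort_train.csv"),
                           check.names = FALSE)
  feats <- .gridFeatureCols(cfg, train)
  g <- runGrid(as.matrix(train[feats]), train$outcome, k = cfg$grid$k,
               seed = .subSeed(cfg$seed, 201L), innerK = cfg$grid$innerK,
               dropPerStep = cfg$grid$dropPerStep,
               paperProtocol = cfg$grid$paperProtocol,
               params = cfg$grid$params)
  hm <- file.path(cfg$outDir, "heatmap.csv")
  utils::write.csv(aucMatrix(g), hm)
  folds <- as.data.frame.table(g@foldAUC,
                               responseName = "auc")
  names(folds)[1:3] <- c("selector", "classifier", "fold")
  ff <- file.path(cfg$outDir, "grid_folds.csv")
  utils::write.csv(folds, ff, row.names = FALSE)
  gj <- file.path(cfg$outDir, "grid.json")
  jsonlite::write_json(list(selector = g@selector, classifier = g@classifier,
                            mean_auc = unname(aucMatrix(g)[g@selector,
                                                           g@classifier]),
                            k = g@k, seed = g@seed, features = feats),
                       gj, auto_unbox = TRUE, pretty = TRUE)
  c(hm, ff, gj)
}

.stageRadScore <- function(cfg) {
  train <- utils::read.csv(file.path(cfg$outDir, "cohort_train.csv"),
                           check.names = FALSE)
  val <- utils::read.csv(file.path(cfg$outDir, "cohort_validation.csv"),
                         check.names = FALSE)
  gj <- jsonlite::read_json(file.path(cfg$outDir, "grid.json"),
                            simplifyVector = TRUE)
  feats <- gj$features
  model <- fitRadScore(as.matrix(train[feats]), train$outcome,
                       selector = gj$selector, classifier = gj$classifier,
                       seed = .subSeed(cfg$seed, 301L),
                       pfsEvent = train$pfs_event, osEvent = train$os_event,
                       innerK = cfg$grid$innerK,
                       dropPerStep = cfg$grid$dropPerStep,
                       params = cfg$grid$params)
  for (dset in c("train", "val")) {
    d <- get(dset)
    d$radscore <- radScore(model, d)
    d$radscore_high <- as.integer(d$radscore >= model@cutoffs["outcome"])
    d$radscore_high_pfs <- as.integer(d$radscore >= model@cutoffs["pfs"])
    d$radscore_high_os <- as.integer(d$radscore >= model@cutoffs["os"])
    assign(dset, d)
  }
  tf <- file.path(cfg$outDir, "cohort_train_scored.csv")
  vf <- file.path(cfg$outDir, "cohort_validation_scored.csv")
  utils::write.csv(train, tf, row.names = FALSE)
  utils::write.csv(val, vf, row.names = FALSE)
  rj <- file.path(cfg$outDir, "radscore.json")
  jsonlite::write_json(list(selector = model@selector,
                            classifier = model@classifier,
                            features = model@features,
                            weights = model@weights,
                            center = model@center, scale = model@scale,
                            cutoffs = as.list(model@cutoffs)),
                       rj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(tf, vf, rj)
}

.stageEvaluate <- function(cfg) {
  train <- utils::read.csv(file.path(cfg$outDir, "cohort_train_scored.csv"),
                           check.names = FALSE)
  val <- utils::read.csv(file.path(cfg$outDir,
                                   "cohort_validation_scored.csv"),
                         check.names = FALSE)
  cand <- c("sex", "age60", "ldh_high", "b_symptoms", "ecog2", "ipi3",
            "nccn_ipi_high", "stage34", "extranodal2", "bone_marrow",
            "bulky", "non_gcb", "suvmax_high", "mtv_high", "tlg_high",
            "radscore_high")
  cand <- cand[vapply(cand, function(v)
    length(unique(train[[v]])) > 1, logical(1))]
  scr <- screenPredictors(train, cand)
  uf <- file.path(cfg$outDir, "univariate.csv")
  utils::write.csv(scr$univariate, uf, row.names = FALSE)
  mf <- file.path(cfg$outDir, "multivariate.csv")
  msel <- if (length(scr$selected) >= 1) scr$selected else "radscore_high"
  utils::write.csv(multivariateLogistic(train, msel)$table, mf,
                   row.names = FALSE)
  models <- buildModels(train, val)
  mo <- file.path(cfg$outDir, "models.csv")
  utils::write.csv(models, mo, row.names = FALSE)
  fits <- attr(models, "fits")
  cal <- calibrationBootstrap(fits$combined, train, reps = 200,
                              seed = .subSeed(cfg$seed, 401L))
  cf <- file.path(cfg$outDir, "calibration.csv")
  utils::write.csv(cbind(cal$curve, slope = cal$slope,
                         intercept = cal$intercept), cf, row.names = FALSE)
  pred <- stats::predict(fits$combined, newdata = train, type = "response")
  df <- file.path(cfg$outDir, "dca_train.csv")
  utils::write.csv(dca(pred, train$outcome), df, row.names = FALSE)
  nm <- nomogramPoints(fits$combined, train)
  nf <- file.path(cfg$outDir, "nomogram.csv")
  utils::write.csv(nm$points, nf, row.names = FALSE)
  c(uf, mf, mo, cf, df, nf)
}

.stageSurvive <- function(cfg) {
  files <- character(0)
  for (dset in c("train", "validation")) {
    d <- utils::read.csv(file.path(cfg$outDir,
                                   sprintf("cohort_%s_scored.csv", dset)),
                         check.names = FALSE)
    for (ep in c("pfs", "os")) {
      tm <- d[[paste0(ep, "_months")]]
      ev <- d[[paste0(ep, "_event")]]
      grp <- d[[paste0("radscore_high_", ep)]]
      km <- lapply(split(seq_along(tm), grp), function(i)
        kmEstimate(tm[i], ev[i], landmarks = cfg$survive$landmarks))
      kmtab <- do.call(rbind, lapply(names(km), function(g)
        cbind(group = g, km[[g]]$curve)))
      kf <- file.path(cfg$outDir, sprintf("km_%s_%s.csv", ep, dset))
      utils::write.csv(kmtab, kf, row.names = FALSE)
      files <- c(files, kf)
      res <- list(endpoint = ep, cohort = dset)
      if (length(unique(grp)) > 1) {
        cx <- coxHR(tm, ev, grp)
        lr <- logrankTest(tm, ev, grp)
        res <- c(res, list(hr = cx$hr, ci = cx$ci, p = cx$p,
                           n = as.list(cx$n), logrank_p = lr$p))
      }
      jf <- file.path(cfg$outDir, sprintf("cox_%s_%s.json", ep, dset))
      jsonlite::write_json(res, jf, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      files <- c(files, jf)
    }
  }
  files
}
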