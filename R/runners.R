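## Pipeline runners: the command-style surface tying the modules together.
## Each runner takes a config (list or JSON file path) plus an output
## directory, writes its outputs as CSV/JSON, and drops a resolved-config
## copy (with the package version) next to them. All randomness flows from
## the single `seed` entry of the config. The thin command-line wrapper in
## inst/cli/hypermeg.R dispatches to these functions.

.resolveConfig <- function(config, defaults) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  utils::modifyList(unclass(defaults), unclass(config))
}

.writeResolved <- function(cfg, outDir, stage) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg$package_version <- as.character(utils::packageVersion("hyperMEG"))
  cfg$stage <- stage
  jsonlite::write_json(cfg, file.path(outDir, "resolved-config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg
}

.log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Simulate a synthetic two-group cohort to disk
#'
#' Generates a [makeTwoGroupCohort()] cohort and writes one JSON graph file
#' per subject/session plus a manifest recording the cohort
#' specification, seed and ages.
#'
#' @param config List (or JSON path) with any of the [synthCohortSpec()]
#'   fields; unknown fields are ignored.
#' @param outDir Output directory.
#' @param quiet Suppress log lines.
#' @return The manifest, invisibly.
#' @export
runSimulate <- function(config = list(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- .resolveConfig(config, as.list(synthCohortSpec()))
  cfg <- .writeResolved(cfg, outDir, "simulate")
  spec <- do.call(synthCohortSpec, cfg[names(cfg) %in%
                                         names(formals(synthCohortSpec))])
  cohort <- makeTwoGroupCohort(spec)
  files <- vapply(cohort$graphs, function(g) {
    f <- file.path(outDir, sprintf("graph_%s_%s.json", subjectId(g),
                                   session(g)))
    writeBrainGraph(g, f)
    basename(f)
  }, "")
  manifest <- list(spec = unclass(spec), ages = as.list(cohort$ages),
                   truth = cohort$truth, files = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("simulate", length(files), " graphs -> ", outDir, " (",
       format(Sys.time() - t0, digits = 3), ")", quiet = quiet)
  invisible(manifest)
}

.loadCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  graphs <- lapply(manifest$files, function(f) readBrainGraph(file.path(dir, f)))
  list(graphs = graphs, manifest = manifest)
}

#' Train an embedding model on a cohort and write per-graph embeddings
#'
#' Trains one model (default: learned-curvature HGCN) on all cohort graphs
#' and writes per-graph embedding CSVs (coordinates + radius per node), the
#' model checkpoint, and a radius table.
#'
#' @param config List or JSON path: `cohortDir`, plus optional `model`
#'   (`"hgcn"`/`"gcn"`), `curvatureMode`, `D`, `epochs`, `lr`, `seed`.
#' @param outDir Output directory.
#' @param quiet Suppress log lines.
#' @return List with the trained model and embeddings, invisibly.
#' @export
runEmbed <- function(config = list(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- .resolveConfig(config, list(cohortDir = NULL, model = "hgcn",
                                     curvatureMode = "learned", D = 3L,
                                     epochs = 100L, lr = 0.02, seed = 1L))
  if (is.null(cfg$cohortDir)) stop("config field cohortDir is required")
  cfg <- .writeResolved(cfg, outDir, "embed")
  cohort <- .loadCohort(cfg$cohortDir)
  tc <- trainConfig(epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed,
                    curvatureMode = cfg$curvatureMode, D = cfg$D)
  model <- trainModel(cohort$graphs, tc, type = cfg$model)
  writeModel(model, file.path(outDir, "model.json"))
  embs <- lapply(cohort$graphs, function(g) embedGraph(model, g))
  for (i in seq_along(embs)) {
    g <- cohort$graphs[[i]]; e <- embs[[i]]
    df <- data.frame(roi = nodeMeta(g)$roi, embCoords(e),
                     radius = nodeRadius(e))
    utils::write.csv(df, file.path(outDir,
      sprintf("embedding_%s_%s.csv", subjectId(g), session(g))),
      row.names = FALSE)
  }
  ages <- unlist(cohort$manifest$ages)
  tab <- radiusTable(embs, cohort$graphs, ages = ages)
  utils::write.csv(tab, file.path(outDir, "radius_table.csv"),
                   row.names = FALSE)
  .log("embed", length(embs), " embeddings (model=", cfg$model,
       ", D=", cfg$D, ") -> ", outDir, " (",
       format(Sys.time() - t0, digits = 3), ")", quiet = quiet)
  invisible(list(model = model, embeddings = embs, radiusTable = tab))
}

#' Run the link-prediction benchmark and write the report
#'
#' Cross-validated MAP for the requested models and dimensions, written as
#' a CSV report (one row per model x dimension, with learned curvatures)
#' plus a per-fold JSON.
#'
#' @param config List or JSON path: `cohortDir`, `models`, `dims`, `k`,
#'   `epochs`, `lr`, `seed`, optional `foldsToRun`.
#' @param outDir Output directory.
#' @param quiet Suppress log lines.
#' @return The report `data.frame`, invisibly.
#' @export
runLinkPrediction <- function(config = list(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- .resolveConfig(config, list(cohortDir = NULL,
                                     models = c("hgcn_learned", "gcn"),
                                     dims = 2L, k = 5L, epochs = 40L,
                                     lr = 0.02, seed = 1L,
                                     foldsToRun = NULL))
  if (is.null(cfg$cohortDir)) stop("config field cohortDir is required")
  cfg <- .writeResolved(cfg, outDir, "linkpred")
  cohort <- .loadCohort(cfg$cohortDir)
  tc <- trainConfig(epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed)
  res <- linkPredictionExperiment(cohort$graphs, models = cfg$models,
                                  dims = cfg$dims, cfg = tc, k = cfg$k,
                                  seed = cfg$seed,
                                  foldsToRun = cfg$foldsToRun)
  utils::write.csv(res$report, file.path(outDir, "linkpred_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$perFold, file.path(outDir, "linkpred_folds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("linkpred", nrow(res$report), " model x dim rows -> ", outDir, " (",
       format(Sys.time() - t0, digits = 3), ")", quiet = quiet)
  invisible(res$report)
}

#' Classify groups from PLV, radius and combined features
#'
#' Builds the three feature sets from a cohort and its embeddings and runs
#' the cross-validated SVM for each, writing one report CSV.
#'
#' @param config List or JSON path: `cohortDir`, `embedDir` (output of
#'   [runEmbed()]), `k`, `seed`, `kernel`, `sessionFilter`.
#' @param outDir Output directory.
#' @param quiet Suppress log lines.
#' @return The report `data.frame`, invisibly.
#' @export
runClassify <- function(config = list(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- .resolveConfig(config, list(cohortDir = NULL, embedDir = NULL,
                                     k = 5L, seed = 1L, kernel = "radial",
                                     sessionFilter = "pre"))
  if (is.null(cfg$cohortDir) || is.null(cfg$embedDir))
    stop("config fields cohortDir and embedDir are required")
  cfg <- .writeResolved(cfg, outDir, "classify")
  cohort <- .loadCohort(cfg$cohortDir)
  model <- readModel(file.path(cfg$embedDir, "model.json"))
  embs <- lapply(cohort$graphs, function(g) embedGraph(model, g))
  rows <- lapply(c("plv", "radius", "combined"), function(fs) {
    feats <- buildFeatures(cohort$graphs, embs, featureSet = fs,
                           sessionFilter = cfg$sessionFilter)
    rep <- classifyGroups(feats$x, feats$y, k = cfg$k, seed = cfg$seed,
                          kernel = cfg$kernel)
    data.frame(featureSet = fs, macroF1 = rep$macroF1, auc = rep$auc)
  })
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(outDir, "classification_report.csv"),
                   row.names = FALSE)
  .log("classify", "3 feature sets -> ", outDir, " (",
       format(Sys.time() - t0, digits = 3), ")", quiet = quiet)
  invisible(report)
}

#' Subnetwork hierarchy analysis of an embedded cohort
#'
#' Writes the radius table and the FDR-corrected group-difference report
#' across the eight subnetworks.
#'
#' @param config List or JSON path: `embedDir` (output of [runEmbed()]),
#'   `method`, `nPerm`, `seed`, `sessionFilter` (`NULL` pools sessions).
#' @param outDir Output directory.
#' @param quiet Suppress log lines.
#' @return The report `data.frame`, invisibly.
#' @export
runHierarchy <- function(config = list(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- .resolveConfig(config, list(embedDir = NULL, method = "permutation",
                                     nPerm = 2000L, seed = 1L,
                                     sessionFilter = NULL))
  if (is.null(cfg$embedDir)) stop("config field embedDir is required")
  cfg <- .writeResolved(cfg, outDir, "hierarchy")
  tab <- utils::read.csv(file.path(cfg$embedDir, "radius_table.csv"))
  if (!is.null(cfg$sessionFilter)) tab <- tab[tab$session %in%
                                                cfg$sessionFilter, ]
  utils::write.csv(tab, file.path(outDir, "radius_table.csv"),
                   row.names = FALSE)
  report <- testSubnetworkHierarchy(tab, method = cfg$method,
                                    nPerm = cfg$nPerm, seed = cfg$seed)
  utils::write.csv(report, file.path(outDir, "hierarchy_report.csv"),
                   row.names = FALSE)
  .log("hierarchy", sum(report$flagged), " subnetwork(s) flagged -> ",
       outDir, " (", format(Sys.time() - t0, digits = 3), ")", quiet = quiet)
  invisible(report)
}
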