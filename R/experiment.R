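# End-to-end synthetic experiment orchestration: generate -> train ->
# predict -> gamma -> report, plus the test-split summary.

#' Desk-scale experiment configuration
#'
#' The default profile for end-to-end runs on one CPU: 300/40/40 fields on
#' the 128 x 96 analysis grid, a depth-3 base-16 network trained 24 epochs
#' at Adam 2e-3 with late step decay, and both standard criteria (3%/3 mm
#' and 2%/2 mm at 5% threshold). Matches `inst/config/quicktest.yaml`. See
#' the vignette for how the scale was chosen.
#'
#' @return nested configuration list.
#' @export
quicktestConfig <- function() {
  list(
    dataset = list(train = 300L, val = 40L, test = 40L, nx = 128L, ny = 96L,
                   seed = 11L, sampler = list()),
    detector = list(),
    network = list(depth = 3L, baseChannels = 16L),
    train = list(learningRate = 2e-3, batchSize = 12L, epochs = 24L,
                 seed = 7L, lrDecayAt = c(15L, 21L)),
    gamma = list(criteria = list(c(3, 3), c(2, 2)), thresholdPercent = 5))
}

#' Read an experiment configuration from YAML
#'
#' Values missing from the file fall back to [quicktestConfig()].
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readExperimentConfig <- function(path) {
  utils::modifyList(quicktestConfig(), yaml::read_yaml(path))
}

#' Run the end-to-end synthetic verification experiment
#'
#' Generates a paired dataset, trains the response network, predicts the
#' transmission image for every test field, compares it against the
#' synthetic measured image with each gamma criteria set, and assembles a
#' per-field report. When `outDir` is given, a manifest (config + seeds), a
#' CSV/JSON report and the loss history are written there; every number in
#' the report is recomputable from the manifest alone.
#'
#' @param config nested list as from [quicktestConfig()], or a YAML path.
#' @param outDir optional output directory.
#' @return list with `report` (a [VerificationReport-class]), `model`
#'   (the [TrainedModel-class]), `bundle` (the [DatasetBundle-class]) and
#'   `detector` (the [DetectorModel-class]).
#' @export
runExperiment <- function(config = quicktestConfig(), outDir = NULL) {
  if (is.character(config)) config <- readExperimentConfig(config)
  ds <- config$dataset
  if ((ds$test %||% 0L) < 1L)
    stop("nothing to evaluate: config has zero test fields")
  detector <- do.call(detectorModel, config$detector %||% list())
  message("stage generate: ", ds$train, "/", ds$val, "/", ds$test,
          " fields at ", ds$nx, " x ", ds$ny)
  bundle <- generateDataset(c(ds$train, ds$val, ds$test), nx = ds$nx,
                            ny = ds$ny, model = detector, seed = ds$seed,
                            sampler = ds$sampler %||% list())
  net_spec <- networkSpec(config$network$depth, config$network$baseChannels,
                          ds$nx, ds$ny)
  tr <- config$train
  message("stage train: depth ", net_spec@depth, ", base ",
          net_spec@baseChannels, ", ", tr$epochs, " epochs")
  model <- trainResponseNet(bundle, net_spec,
                            trainSpec(learningRate = tr$learningRate,
                                      batchSize = tr$batchSize,
                                      epochs = tr$epochs, seed = tr$seed,
                                      lrDecayAt = tr$lrDecayAt %||% integer(0)))
  crits <- lapply(config$gamma$criteria, function(cr)
    gammaCriteria(cr[1], cr[2],
                  thresholdPercent = config$gamma$thresholdPercent %||% 5))
  message("stage gamma: ", length(bundle@splitTest), " test fields, ",
          length(crits), " criteria")
  rows <- list()
  for (i in bundle@splitTest) {
    predicted <- predictTI(model, bundle@inputs[[i]])
    measured <- transmissionImage(bundle@targets[[i]], provenance = "synthetic")
    for (cr in crits) {
      g <- gammaIndex(measured, predicted, cr)
      rows[[length(rows) + 1L]] <- data.frame(
        field = i, split = "test", dosePercent = cr@dosePercent,
        dtaMm = cr@dtaMm, passRate = g@passRate, meanGamma = g@meanGamma,
        nEvaluated = g@nEvaluated)
    }
  }
  report <- new("VerificationReport", entries = do.call(rbind, rows),
                config = config, seed = as.integer(ds$seed))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = config,
           package_version = as.character(utils::packageVersion("epidverify"))),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(report@entries, file.path(outDir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report@entries, file.path(outDir, "report.json"),
                         dataframe = "rows", digits = NA)
    utils::write.csv(model@lossHistory, file.path(outDir, "loss.csv"),
                     row.names = FALSE)
  }
  list(report = report, model = model, bundle = bundle, detector = detector)
}

#' Summarise the test split of a verification report
#'
#' @param report a [VerificationReport-class] (or the list returned by
#'   [runExperiment()]).
#' @return data.frame with one row per criteria set: minimum and mean pass
#'   rate and the mean of the per-field mean gamma.
#' @export
summarizeTestSplit <- function(report) {
  if (is.list(report) && !isS4(report)) report <- report$report
  stopifnot(is(report, "VerificationReport"))
  e <- report@entries[report@entries$split == "test", ]
  if (!nrow(e)) stop("report contains no test-split entries")
  keys <- unique(e[, c("dosePercent", "dtaMm")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    sel <- e$dosePercent == keys$dosePercent[k] & e$dtaMm == keys$dtaMm[k]
    data.frame(dosePercent = keys$dosePercent[k], dtaMm = keys$dtaMm[k],
               nFields = sum(sel),
               minPassRate = min(e$passRate[sel]),
               meanPassRate = mean(e$passRate[sel]),
               meanMeanGamma = mean(e$meanGamma[sel]))
  }))
  out
}
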