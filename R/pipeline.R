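# End-to-end orchestration: input -> descriptors -> split -> models ->
# reports, with a plain-file run directory and a parameter log.

#' Assemble a pipeline configuration
#'
#' @param input `"synthetic"` for a simulated study table, or the path
#'   of a SMILES/SDF molecule file.
#' @param format molecule file format (`"smiles"`/`"sdf"`), guessed
#'   from the extension when NULL.
#' @param targets for file input: path of a CSV with columns `id` and
#'   the target column, holding measured %F values.
#' @param targetColumn response column name (default `"F"`).
#' @param outputDir run directory (created if needed).
#' @param seed master seed for embedding and simulation.
#' @param n synthetic table size (default 217).
#' @param highBias,noiseSd synthetic response parameters.
#' @param trainFraction train share of the post-external table
#'   (default 159/209).
#' @param externalK external prediction set size (default 8).
#' @param probe,nPoints,grid descriptor engine settings.
#' @param wellThreshold %F cutoff separating well from poor absorption
#'   (default 50).
#' @param confidence ellipse confidence level (default 0.95).
#' @return A named list with class `"qsprPipelineConfig"`.
#' @export
pipelineConfig <- function(input = "synthetic", format = NULL, targets = NULL,
                           targetColumn = "F", outputDir = tempfile("qspr_run_"),
                           seed = 7L, n = 217L, highBias = 0.7, noiseSd = 5,
                           trainFraction = 159 / 209, externalK = 8L,
                           probe = 1.4, nPoints = 960L, grid = 0.1,
                           wellThreshold = 50, confidence = 0.95) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  structure(
    list(
      input = input, format = format, targets = targets,
      targetColumn = targetColumn, outputDir = outputDir, seed = seed,
      n = n, highBias = highBias, noiseSd = noiseSd,
      trainFraction = trainFraction, externalK = externalK,
      probe = probe, nPoints = nPoints, grid = grid,
      wellThreshold = wellThreshold, confidence = confidence
    ),
    class = "qsprPipelineConfig"
  )
}

.stage <- function(log, name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full QSPR pipeline
#'
#' Builds (or loads) the descriptor table, writes `desc.csv`, selects
#' the external prediction set across the %F range, tunes the
#' sphere-exclusion radius to the target training fraction, splits the
#' remaining compounds, fits the GRNN with bandwidth monitored on the
#' test set, and writes `split.json`, `model.json`, `pred.csv`,
#' `report.json` (one evaluation block per split) and `corr.csv`. When
#' the table carries `alogp` and `psa` columns the two absorption-plane
#' classifiers are fitted as well and their misclassification rates are
#' added to the report. A `run.log` records every parameter, the seed,
#' the package version and the input checksum; a rerun with the same
#' configuration reproduces every output file.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with the run directory, the file paths and
#'   the in-memory report.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "qsprPipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c(
    sprintf("BioavailQSPR %s", as.character(utils::packageVersion("BioavailQSPR"))),
    sprintf("seed: %d", as.integer(config$seed))
  )
  for (nm in setdiff(names(config), c("outputDir"))) {
    logLines <- c(logLines, sprintf("param %s: %s", nm,
                                    paste(format(config[[nm]]), collapse = " ")))
  }

  tcol <- config$targetColumn
  tab <- .stage(log, "input", {
    if (identical(config$input, "synthetic")) {
      t <- simulateDescriptorTable(
        n = config$n, seed = config$seed,
        highBias = config$highBias, noiseSd = config$noiseSd
      )
      names(t)[names(t) == "F"] <- tcol
      t
    } else {
      mols <- readMolecules(config$input, config$format)
      mols <- prepareMolecules(mols, seed = config$seed)
      desc <- computeDescriptorTable(
        mols, probe = config$probe, nPoints = config$nPoints, grid = config$grid
      )
      if (is.null(config$targets)) {
        stop("file input needs a 'targets' CSV with id and ", tcol)
      }
      tg <- utils::read.csv(config$targets, stringsAsFactors = FALSE)
      if (!all(c("id", tcol) %in% names(tg))) {
        stop("targets CSV must have columns 'id' and '", tcol, "'")
      }
      merge(desc, tg[, c("id", tcol)], by = "id", sort = FALSE)
    }
  })
  if (!tcol %in% names(tab)) {
    stop("pipeline stage 'input' failed: missing target column '", tcol, "'")
  }
  if (!identical(config$input, "synthetic")) {
    logLines <- c(logLines, sprintf(
      "input checksum: %s", unname(tools::md5sum(config$input))
    ))
  }

  paths <- list(desc = file.path(config$outputDir, "desc.csv"))
  writeDescriptorTable(tab, paths$desc)

  # external set first, spanning the %F range; never seen again until
  # final validation
  extIds <- .stage(log, "external", {
    selectExternalSet(tab, tab[[tcol]], k = config$externalK)
  })
  rest <- tab[!tab$id %in% extIds, , drop = FALSE]

  tuned <- .stage(log, "split", {
    tuneRadius(rest, targetTrainFraction = config$trainFraction, tolerance = 3L)
  })
  split <- tuned$split
  split@externalIds <- extIds
  validObject(split)
  logLines <- c(logLines, sprintf(
    "split: %d train / %d test / %d external, radius %.6g",
    length(trainIds(split)), length(testIds(split)), length(extIds),
    split@radius
  ))

  paths$split <- file.path(config$outputDir, "split.json")
  jsonlite::write_json(
    list(
      train_ids = trainIds(split), test_ids = testIds(split),
      external_ids = externalIds(split), radius = split@radius,
      scaling = split@scaling
    ),
    paths$split, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )

  trainTab <- tab[tab$id %in% trainIds(split), , drop = FALSE]
  testTab <- tab[tab$id %in% testIds(split), , drop = FALSE]
  extTab <- tab[tab$id %in% extIds, , drop = FALSE]

  model <- .stage(log, "grnn", {
    fitGRNN(trainTab, testTab, targetColumn = tcol)
  })
  logLines <- c(logLines, sprintf("grnn sigma: %.6g", model@sigma))

  paths$model <- file.path(config$outputDir, "model.json")
  jsonlite::write_json(
    list(
      sigma = model@sigma, columns = model@columns,
      center = as.list(model@center), scale = as.list(model@scale),
      clip = model@clip,
      train_x = model@trainX, train_y = model@trainY,
      selection_trace = model@trace
    ),
    paths$model, auto_unbox = TRUE, digits = NA
  )

  splits <- list(train = trainTab, test = testTab, external = extTab)
  preds <- list()
  report <- list()
  for (nm in names(splits)) {
    st <- splits[[nm]]
    st$F <- st[[tcol]]
    p <- grnnPredictBatch(model, st)
    p$split <- nm
    preds[[nm]] <- p
    ev <- evaluatePredictions(p$actual, p$predicted, nm)
    report[[nm]] <- as.list(ev)
  }
  predTab <- do.call(rbind, preds)
  rownames(predTab) <- NULL
  paths$pred <- file.path(config$outputDir, "pred.csv")
  utils::write.csv(predTab, paths$pred, row.names = FALSE)

  # absorption-plane classifiers, when the plane is available
  if (all(c("alogp", "psa") %in% names(tab))) {
    lab <- ifelse(tab[[tcol]] >= config$wellThreshold, "well", "poor")
    pts <- tab[, c("alogp", "psa")]
    if (sum(lab == "well") >= 3) {
      ell <- fitEllipse(pts[lab == "well", ], confidence = config$confidence)
      report$ellipse <- list(
        misclassification = misclassificationRate(ell, pts, lab),
        mean = ell@mean, covariance = ell@covariance,
        threshold = ell@threshold
      )
    }
    if (length(unique(lab)) == 2) {
      tree <- fitTree(pts, lab)
      report$tree <- list(
        misclassification = misclassificationRate(tree, pts, lab),
        depth = .treeDepth(tree@nodes)
      )
    }
  } else {
    logLines <- c(logLines,
      "absorption models skipped: no alogp/psa columns in the table")
  }

  paths$report <- file.path(config$outputDir, "report.json")
  jsonlite::write_json(report, paths$report,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  paths$corr <- file.path(config$outputDir, "corr.csv")
  cm <- correlationMatrix(tab)
  utils::write.csv(
    data.frame(descriptor = rownames(cm), cm, check.names = FALSE),
    paths$corr, row.names = FALSE
  )

  paths$log <- file.path(config$outputDir, "run.log")
  writeLines(logLines, paths$log)

  invisible(list(
    dir = config$outputDir, paths = paths, report = report,
    split = split, model = model
  ))
}
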