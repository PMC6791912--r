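# shared input reader: CSV with a smiles column, or plain one-SMILES-per-line
.readSmilesInput <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl(",", first) && grepl("smiles", tolower(first))) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("input CSV needs a 'smiles' column")
    if (!"id" %in% names(df)) df$id <- paste0("cmpd", seq_len(nrow(df)))
    df
  } else {
    sm <- readLines(path, warn = FALSE)
    sm <- sm[nzchar(trimws(sm))]
    data.frame(id = paste0("cmpd", seq_along(sm)), smiles = sm,
               stringsAsFactors = FALSE)
  }
}

.runManifest <- function(outDir, command, config, seed, nRows, outputs) {
  man <- list(command = command, configDigest = .configDigest(config),
              config = config, seed = seed, inputRows = nRows,
              outputs = outputs,
              versions = list(R = R.version.string,
                              chloroMS = as.character(utils::packageVersion("chloroMS"))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outDir, paste0(command, "-manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  .log("%s: config %s, seed %s, %d input rows -> %s",
       command, man$configDigest, as.character(seed), nRows,
       paste(outputs, collapse = ", "))
  invisible(path)
}

#' Command: compute descriptors for a SMILES input
#'
#' Reads SMILES (CSV with a `smiles` column, or one per line) and writes a
#' PaDEL-style descriptor CSV (first column `Name`).
#'
#' @param input input file path
#' @param output output CSV path
#' @return invisible output path
#' @export
cmdDescriptors <- function(input, output) {
  df <- .readSmilesInput(input)
  dm <- computeDescriptorMatrix(df$smiles, df$id)
  exportDescriptorCsv(dm, output)
  .log("descriptors: %d compounds x %d descriptors -> %s",
       nrow(dm@values), ncol(dm@values), output)
  invisible(output)
}

#' Command: label spectra by intensity criterion
#'
#' Reads a record CSV (`id`, `smiles`, `m_intensity`, `m35_intensity`) and
#' appends the class column for the chosen criterion.
#'
#' @param input input CSV path
#' @param criterion "I" ([M] > 800) or "II" ([M-35] > 100)
#' @param output output CSV path
#' @return invisible data.frame with the class column added
#' @export
cmdLabel <- function(input, criterion = "I", output = NULL) {
  df <- read.csv(input, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  col <- if (criterion == "I") "m_intensity" else "m35_intensity"
  if (!col %in% names(df)) stop("input CSV needs column ", col)
  df[[paste0("class_", criterion)]] <- assignClass(df[[col]], criterion)
  if (!is.null(output)) write.csv(df, output, row.names = FALSE)
  .log("label: %d records under criterion %s", nrow(df), criterion)
  invisible(df)
}

#' Command: train the classification ensemble
#'
#' Runs the full pipeline on a labelled record CSV and writes, under
#' `outDir`: the final model JSON files (`model1.json`...), the selection
#' result (JSON + ranked CSV), an evaluation summary JSON, and a run
#' manifest.
#'
#' @param input record CSV (`id`, `smiles`, `m_intensity`, `m35_intensity`)
#' @param outDir output directory
#' @param config list from [runConfig()] (or path to a YAML config)
#' @param seed RNG seed
#' @return invisible pipeline result list
#' @export
cmdTrain <- function(input, outDir, config = runConfig(), seed = 1L) {
  if (is.character(config)) config <- readRunConfig(config)
  records <- read.csv(input, stringsAsFactors = FALSE)
  names(records) <- tolower(names(records))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  res <- runPipeline(records, config, seed)
  outputs <- character(0)
  for (k in seq_along(res$models)) {
    p <- file.path(outDir, sprintf("model%d.json", k))
    saveMLP(res$models[[k]], p)
    outputs <- c(outputs, p)
  }
  saveSelection(res$selection, file.path(outDir, "selection.json"))
  selectionToCsv(res$selection, file.path(outDir, "selection.csv"))
  summ <- lapply(res$report$subsets, function(s)
    list(consensusAccuracy = s$consensus$accuracy,
         classAccuracy = as.list(s$consensus$classAccuracy),
         auc = s$roc$auc))
  jsonlite::write_json(summ, file.path(outDir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  # ROC / gain point lists for plotting, one CSV per subset
  for (nm in names(res$report$subsets)) {
    s <- res$report$subsets[[nm]]
    write.csv(s$roc$points, file.path(outDir, paste0("roc_", nm, ".csv")),
              row.names = FALSE)
    write.csv(s$gain, file.path(outDir, paste0("gain_", nm, ".csv")),
              row.names = FALSE)
  }
  .runManifest(outDir, "train", config, seed, nrow(records),
               c(outputs, "selection.json", "selection.csv", "evaluation.json",
                 "roc_*.csv", "gain_*.csv"))
  invisible(res)
}

#' Command: classify new spectra with a trained ensemble
#'
#' Loads the model JSON files from a training output directory, computes the
#' models' input descriptors for the given SMILES, and writes per-model and
#' majority-consensus class calls (the worked-example report layout: one row
#' per compound, one column per model).
#'
#' @param modelsDir directory containing `model*.json`
#' @param input SMILES input (CSV with `smiles` column or one per line)
#' @param output output CSV path
#' @return invisible data.frame of calls
#' @export
cmdPredict <- function(modelsDir, input, output = NULL) {
  paths <- sort(list.files(modelsDir, "^model[0-9]+\\.json$", full.names = TRUE))
  if (!length(paths)) stop("no model*.json files in ", modelsDir)
  models <- lapply(paths, loadMLP)
  df <- .readSmilesInput(input)
  fn <- models[[1]]@featureNames
  unknown <- setdiff(fn, defaultDescriptorSet())
  if (length(unknown))
    stop("models use descriptor(s) not natively computable: ",
         paste(unknown, collapse = ", "),
         "; supply them via importDescriptorCsv/mergeDescriptors")
  dm <- computeDescriptorMatrix(df$smiles, df$id, descriptors = fn)
  rep <- ensembleReport(models, dm@values)
  out <- data.frame(id = df$id, smiles = df$smiles,
                    rep$calls,
                    consensus = rep$consensus,
                    disagreement = rep$disagreement,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[2 + seq_along(models)] <- paste0("model", seq_along(models))
  if (!is.null(output)) write.csv(out, output, row.names = FALSE)
  .log("predict: %d compounds, %d models, %d disagreement(s)",
       nrow(out), length(models), sum(out$disagreement))
  invisible(out)
}

#' Command: generate a synthetic dataset (+ MSP fixtures)
#'
#' Writes the labelled synthetic record CSV and, optionally, one MSP
#' spectrum file per record.
#'
#' @param outDir output directory
#' @param config list from [generatorConfig()]
#' @param msp also write MSP fixtures under `outDir/msp/`
#' @return invisible records data.frame
#' @export
cmdSynth <- function(outDir, config = generatorConfig(), msp = FALSE) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rec <- genLabelledDataset(config)
  csv <- file.path(outDir, "synthetic.csv")
  write.csv(rec, csv, row.names = FALSE)
  outputs <- csv
  if (msp) {
    genMspFixtures(rec, file.path(outDir, "msp"), seed = config$seed)
    outputs <- c(outputs, file.path(outDir, "msp"))
  }
  .runManifest(outDir, "synth", config, config$seed, nrow(rec), outputs)
  invisible(rec)
}
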