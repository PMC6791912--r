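#' Run configuration with the standard defaults
#'
#' All pipeline parameters in one validated list: classification thresholds
#' (criterion I: [M] > 800; criterion II: [M-35] > 100; NIST base scale
#' 9999), the descriptor variance threshold 0.001, 70/15/15 split fractions,
#' selection size K = 100 from 5 preliminary nets, 5 final nets, and the
#' BFGS iteration caps.
#'
#' @param ... overrides of any default field
#' @return validated config list
#' @export
runConfig <- function(...) {
  cfg <- list(
    criterion = "I",
    thresholdI = 800, thresholdII = 100, baseScale = 9999,
    varianceThreshold = 0.001,
    fractions = c(0.70, 0.15, 0.15),
    K = 100L, nNets = 5L, nFinalNets = 5L,
    maxIter = 200L, maxIterPreliminary = 100L,
    stratify = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validateRunConfig(cfg)
  cfg
}

#' @rdname runConfig
#' @param cfg a config list to validate
#' @export
validateRunConfig <- function(cfg) {
  fail <- function(field, why) stop("config error at '", field, "': ", why)
  if (!cfg$criterion %in% c("I", "II")) fail("criterion", "must be 'I' or 'II'")
  if (cfg$thresholdI < 0 || cfg$thresholdI > cfg$baseScale)
    fail("thresholdI", "outside intensity scale")
  if (cfg$thresholdII < 0 || cfg$thresholdII > cfg$baseScale)
    fail("thresholdII", "outside intensity scale")
  if (length(cfg$fractions) != 3 || any(cfg$fractions <= 0) ||
      abs(sum(cfg$fractions) - 1) > 1e-9)
    fail("fractions", "must be 3 positive numbers summing to 1")
  if (cfg$varianceThreshold < 0) fail("varianceThreshold", "must be >= 0")
  for (f in c("K", "nNets", "nFinalNets", "maxIter", "maxIterPreliminary"))
    if (cfg[[f]] < 1) fail(f, "must be >= 1")
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Any field present overrides the default from [runConfig()];
#' unknown fields are rejected with their path.
#'
#' @param path YAML file path
#' @export
readRunConfig <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(runConfig, over)
}

# short digest of an arbitrary object, for run logging
.configDigest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% .Machine$integer.max)
}

.log <- function(...) message("[chloroMS] ", sprintf(...))

#' Full training pipeline on a labelled spectrum dataset
#'
#' Runs, in order: class labeling by the configured criterion, native
#' descriptor computation, the completeness/variance filter, the 70/15/15
#' split, the preliminary-ensemble sensitivity selection of K descriptors on
#' the training part, training of the final MLP ensemble on the selected
#' descriptors, and evaluation on all three subsets.
#'
#' @param records data.frame with columns `id`, `smiles`, `m_intensity`,
#'   `m35_intensity` (intensities in NIST units)
#' @param config list from [runConfig()]
#' @param seed seed controlling split, selection and training
#' @param descriptors optional precomputed [DescriptorMatrix-class] whose
#'   row ids match `records$id` (e.g. native merged with imported columns)
#' @return list with `labels`, `descriptors` (filtered), `split`,
#'   `selection`, `models`, `report`
#' @export
runPipeline <- function(records, config = runConfig(), seed = 1L,
                        descriptors = NULL) {
  validateRunConfig(config)
  need <- c("id", "smiles")
  if (!all(need %in% names(records))) stop("records need columns id and smiles")
  intensity <- if (config$criterion == "I") records$m_intensity else records$m35_intensity
  thr <- if (config$criterion == "I") config$thresholdI else config$thresholdII
  labels <- assignClass(intensity, config$criterion, threshold = thr)
  .log("labeled %d records under criterion %s (class 1: %d, class 2: %d)",
       length(labels), config$criterion, sum(labels == 1), sum(labels == 2))

  dm <- if (is.null(descriptors))
    computeDescriptorMatrix(records$smiles, records$id) else descriptors
  ok <- rowSums(is.na(dm@values)) < ncol(dm@values)
  if (!all(ok)) {
    .log("dropping %d record(s) with failed descriptor computation", sum(!ok))
    dm <- new("DescriptorMatrix", values = dm@values[ok, , drop = FALSE],
              provenance = dm@provenance)
  }
  ids <- rownames(dm@values)
  labels <- labels[match(ids, records$id)]

  keep <- varianceFilter(dm, config$varianceThreshold)
  dm <- subsetDescriptors(dm, keep)
  .log("variance filter kept %d descriptors", length(keep))

  split <- splitDataset(ids, config$fractions, seed = .deriveSeed(seed, 11L),
                        stratifyOn = if (config$stratify) labels else NULL)
  tr <- match(split$train, ids)
  sel <- preliminarySelect(subsetRows(dm, split$train), labels[tr],
                           nNets = config$nNets, K = config$K,
                           seed = .deriveSeed(seed, 23L),
                           maxIter = config$maxIterPreliminary)
  .log("selected %d descriptors from the preliminary ensemble", length(sel@selected))

  dmSel <- subsetDescriptors(dm, sel@selected)
  X <- dmSel@values
  va <- match(split$validation, ids)
  models <- lapply(seq_len(config$nFinalNets), function(k) {
    net <- .autoNetOn(X[tr, , drop = FALSE], labels[tr],
                      X[va, , drop = FALSE], labels[va],
                      seed = .deriveSeed(seed, 100L + k),
                      maxIter = config$maxIter)
    .log("final net %d: %d-%d-2 %s/%s (%s), best validation error %.4f", k,
         ncol(net@W1), nrow(net@W1), net@hiddenActivation,
         net@outputActivation, net@errorFn,
         min(net@meta$history$validation))
    net
  })
  report <- ensembleReport(models, X, labels, split)
  list(labels = stats::setNames(labels, ids), descriptors = dm, split = split,
       selection = sel, models = models, report = report)
}

# like .autoNet but with an external validation set (the pipeline's 15%)
.autoNetOn <- function(Xtr, ytr, Xval, yval, seed, maxIter,
                       hiddenRange = NULL, menu = .NET_MENU) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nIn <- ncol(Xtr)
  if (is.null(hiddenRange)) hiddenRange <- .hiddenRange(nIn)
  nh <- sample(seq(hiddenRange[1], hiddenRange[2]), 1)
  combo <- menu[[sample(length(menu), 1)]]
  m <- initMLP(nIn, nh, combo[1], combo[2], combo[3], seed = seed,
               featureNames = colnames(Xtr))
  trainMLP(m, Xtr, ytr, Xval, yval, maxIter = maxIter)
}

#' Row subset of a DescriptorMatrix
#'
#' @param dm a [DescriptorMatrix-class]
#' @param ids row ids to keep, in the given order
#' @export
subsetRows <- function(dm, ids) {
  missing <- setdiff(ids, rownames(dm@values))
  if (length(missing)) stop("unknown compound id(s): ", paste(head(missing, 5), collapse = ", "))
  new("DescriptorMatrix", values = dm@values[ids, , drop = FALSE],
      provenance = dm@provenance)
}
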