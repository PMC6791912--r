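# activation/error menu mirroring the variety of the trained ensembles
.NET_MENU <- list(
  c("exponential", "exponential", "sse"),
  c("tanh", "softmax", "entropy"),
  c("exponential", "linear", "sse"),
  c("tanh", "logistic", "sse"),
  c("tanh", "linear", "sse"))

# hidden-layer size range for automatically generated nets
.hiddenRange <- function(nIn) {
  lo <- max(2L, floor(nIn / 8))
  hi <- max(lo + 1L, ceiling(nIn / 4))
  c(lo, hi)
}

# derived seeds must stay below 2^31 (double arithmetic avoids integer overflow)
.deriveSeed <- function(seed, k)
  as.integer((as.numeric(seed) * 2654435 + as.numeric(k) * 97) %% 2147483647)

# train one automatically configured net on (X, labels): internal 85/15
# train/validation split, menu-drawn activations, range-drawn hidden size
.autoNet <- function(X, labels, seed, maxIter, hiddenRange = NULL,
                     menu = .NET_MENU) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nIn <- ncol(X)
  if (is.null(hiddenRange)) hiddenRange <- .hiddenRange(nIn)
  nh <- sample(seq(hiddenRange[1], hiddenRange[2]), 1)
  combo <- menu[[sample(length(menu), 1)]]
  idx <- sample(nrow(X))
  nVal <- max(1L, floor(0.15 * nrow(X)))
  vIdx <- idx[seq_len(nVal)]
  tIdx <- idx[-seq_len(nVal)]
  m <- initMLP(nIn, nh, combo[1], combo[2], combo[3], seed = seed,
               featureNames = colnames(X))
  trainMLP(m, X[tIdx, , drop = FALSE], labels[tIdx],
           X[vIdx, , drop = FALSE], labels[vIdx], maxIter = maxIter)
}

#' Preliminary-ensemble sensitivity selection of descriptors
#'
#' The two-stage selection's first stage: trains `nNets` automatically
#' configured networks (distinct derived seeds, hidden sizes drawn from
#' \[n_in/8, n_in/4\], activations and error function drawn from the same
#' menu as the final nets) on all filtered descriptors, computes each
#' network's mean-substitution sensitivity, aggregates by mean ratio across
#' nets (or mean rank with `aggregate = "rank"`), and keeps the top K
#' descriptors, ties broken lexically for determinism.
#'
#' @param dm a [DescriptorMatrix-class] that already passed
#'   [varianceFilter()] (no missing values)
#' @param labels classes in {1, 2}, aligned with the rows of `dm`
#' @param nNets number of preliminary networks (default 5)
#' @param K number of descriptors to keep (default 100); if K exceeds the
#'   number of columns, all columns are returned with a warning
#' @param seed base RNG seed; each net uses a distinct derived seed
#' @param maxIter BFGS iteration cap per preliminary net
#' @param aggregate "ratio" (mean sensitivity ratio) or "rank" (mean rank)
#' @return a [SelectionResult-class]
#' @export
preliminarySelect <- function(dm, labels, nNets = 5L, K = 100L, seed = 1L,
                              maxIter = 100L, aggregate = c("ratio", "rank")) {
  aggregate <- match.arg(aggregate)
  X <- if (is(dm, "DescriptorMatrix")) dm@values else dm
  if (anyNA(X)) stop("descriptor matrix has missing values; apply varianceFilter first")
  stopifnot(all(labels %in% c(1, 2)), length(labels) == nrow(X))
  nm <- colnames(X)
  perNet <- matrix(NA_real_, ncol(X), nNets,
                   dimnames = list(nm, paste0("net", seq_len(nNets))))
  for (t in seq_len(nNets)) {
    net <- .autoNet(X, labels, .deriveSeed(seed, t), maxIter)
    perNet[, t] <- mlpSensitivity(net, X, labels)$ratio[nm]
  }
  agg <- if (aggregate == "ratio") rowMeans(perNet)
         else -rowMeans(apply(-perNet, 2, rank, ties.method = "average"))
  ord <- order(-agg, nm)
  ranking <- data.frame(descriptor = nm[ord], sensitivity = agg[ord],
                        rank = seq_along(nm), row.names = NULL)
  if (K > length(nm)) {
    warning(sprintf("K = %d exceeds the %d available descriptors; keeping all",
                    K, length(nm)))
  }
  keep <- head(ranking$descriptor, min(K, length(nm)))
  new("SelectionResult", ranking = ranking, selected = keep,
      perNet = perNet, K = as.numeric(min(K, length(nm))), nNets = as.numeric(nNets))
}

#' Serialize a SelectionResult
#'
#' Writes the ranking, selected set and per-net sensitivity table as JSON;
#' `selectionToCsv` exports the ranked table as CSV.
#'
#' @param sel a [SelectionResult-class]
#' @param path output path
#' @export
saveSelection <- function(sel, path) {
  jsonlite::write_json(
    list(schema = "chloroMS-selection/1",
         ranking = sel@ranking, selected = sel@selected,
         perNet = as.data.frame(sel@perNet),
         K = sel@K, nNets = sel@nNets),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSelection
#' @export
selectionToCsv <- function(sel, path) {
  write.csv(sel@ranking, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn preliminarySelect selected descriptor names
#' @export
selectedDescriptors <- function(sel) sel@selected

#' @describeIn preliminarySelect full sensitivity ranking
#' @export
selectionRanking <- function(sel) sel@ranking
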