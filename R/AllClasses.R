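#' MolecularGraph: hydrogen-suppressed molecular graph
#'
#' Heavy-atom graph parsed from SMILES. Atoms carry element symbol, formal
#' charge, implicit hydrogen count and an aromaticity flag; bonds carry a
#' conventional order (1, 2, 3, or 1.5 for aromatic). Hydrogens are
#' suppressed and stored as per-atom counts; stereochemistry is discarded
#' (all in-scope descriptors are 2D).
#'
#' @slot atoms data.frame with columns `element`, `charge`, `hcount`,
#'   `aromatic` (one row per heavy atom)
#' @slot bonds data.frame with columns `i`, `j`, `order`; `order` is 1, 2, 3
#'   or 1.5 (aromatic)
#' @slot smiles the SMILES string the graph was parsed from
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 smiles = "character"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character(0)
  need <- c("element", "charge", "hcount", "aromatic")
  if (!all(need %in% names(a))) return("atoms must have element/charge/hcount/aromatic")
  if (nrow(b)) {
    if (!all(c("i", "j", "order") %in% names(b))) return("bonds must have i/j/order")
    if (any(b$i == b$j)) msg <- c(msg, "self-loop bond")
    if (any(b$i < 1 | b$j < 1 | b$i > nrow(a) | b$j > nrow(a)))
      msg <- c(msg, "bond index out of range")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate bond")
    if (!all(b$order %in% c(1, 1.5, 2, 3))) msg <- c(msg, "bond order not in {1, 1.5, 2, 3}")
  }
  if (any(a$hcount < 0)) msg <- c(msg, "negative hydrogen count")
  if (length(msg)) msg else TRUE
})

#' DescriptorMatrix: compounds x descriptors
#'
#' Rectangular numeric matrix of descriptor values with a per-column
#' provenance flag (`native` = computed by this package, `imported` = read
#' from an external CSV). Missing values are NA.
#'
#' @slot values numeric matrix, rownames = compound ids, colnames = descriptor names
#' @slot provenance character vector, one of "native"/"imported" per column
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
  representation(values = "matrix", provenance = "character"))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "row ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "column names must be present and unique")
  if (length(object@provenance) != ncol(v))
    msg <- c(msg, "provenance length must equal column count")
  else if (!all(object@provenance %in% c("native", "imported")))
    msg <- c(msg, "provenance must be 'native' or 'imported'")
  if (length(msg)) msg else TRUE
})

#' MLPModel: one-hidden-layer perceptron for 2-class output
#'
#' Weights, activation names, error-function name, the z-score input
#' standardization fitted on the training set, and training metadata.
#'
#' @slot W1,b1 hidden-layer weights (n_hidden x n_in) and biases
#' @slot W2,b2 output-layer weights (2 x n_hidden) and biases
#' @slot hiddenActivation one of "tanh", "exponential", "logistic", "linear"
#' @slot outputActivation one of "exponential", "linear", "softmax", "logistic", "tanh"
#' @slot errorFn "sse" (sum of squares) or "entropy" (cross-entropy)
#' @slot xMean,xSd per-feature training-set mean and sd applied internally
#' @slot featureNames input descriptor names, in weight-column order
#' @slot meta list: seed, iterations run, best iteration, training history
#' @exportClass MLPModel
setClass("MLPModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 hiddenActivation = "character", outputActivation = "character",
                 errorFn = "character", xMean = "numeric", xSd = "numeric",
                 featureNames = "character", meta = "list"))

setValidity("MLPModel", function(object) {
  msg <- character(0)
  nh <- nrow(object@W1); ni <- ncol(object@W1)
  if (length(object@b1) != nh) msg <- c(msg, "b1 length != n_hidden")
  if (!all(dim(object@W2) == c(2L, nh))) msg <- c(msg, "W2 must be 2 x n_hidden")
  if (length(object@b2) != 2L) msg <- c(msg, "b2 length != 2")
  if (length(object@xMean) != ni || length(object@xSd) != ni)
    msg <- c(msg, "standardization parameters must match n_in")
  if (any(object@xSd <= 0)) msg <- c(msg, "standardization sd must be > 0")
  if (!object@hiddenActivation %in% c("tanh", "exponential", "logistic", "linear"))
    msg <- c(msg, "unsupported hidden activation")
  if (!object@outputActivation %in% c("exponential", "linear", "softmax", "logistic", "tanh"))
    msg <- c(msg, "unsupported output activation")
  if (!object@errorFn %in% c("sse", "entropy")) msg <- c(msg, "unsupported error function")
  if (object@errorFn == "entropy" &&
      object@outputActivation %in% c("linear", "tanh"))
    msg <- c(msg, "entropy error requires a non-negative output activation")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: sensitivity-ranked descriptor selection
#'
#' Output of the preliminary-ensemble feature selection: the full ranking by
#' aggregate sensitivity ratio, the retained top-K set, and the per-network
#' sensitivity table.
#'
#' @slot ranking data.frame: descriptor, aggregate sensitivity, rank
#' @slot selected character vector of retained descriptor names (top K)
#' @slot perNet numeric matrix of sensitivity ratios, descriptors x networks
#' @slot K requested number of descriptors to keep
#' @slot nNets number of preliminary networks trained
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(ranking = "data.frame", selected = "character",
                 perNet = "matrix", K = "numeric", nNets = "numeric"))

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  if (!all(object@selected %in% object@ranking$descriptor))
    msg <- c(msg, "selected set must be a subset of the ranking")
  if (length(object@selected) != min(object@K, nrow(object@ranking)))
    msg <- c(msg, "|selected| must equal min(K, available)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d heavy atoms, %d bonds (%d aromatic atoms)\n",
              nrow(object@atoms), nrow(object@bonds), sum(object@atoms$aromatic)))
  cat("  SMILES: ", object@smiles, "\n", sep = "")
  comp <- table(object@atoms$element)
  cat("  composition:", paste(names(comp), comp, sep = ":", collapse = " "), "\n")
})

setMethod("show", "DescriptorMatrix", function(object) {
  v <- object@values
  cat(sprintf("DescriptorMatrix: %d compounds x %d descriptors (%d native, %d imported)\n",
              nrow(v), ncol(v), sum(object@provenance == "native"),
              sum(object@provenance == "imported")))
  cat(sprintf("  missing cells: %d\n", sum(is.na(v))))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel %d-%d-2 (%s/%s, %s error)\n",
              ncol(object@W1), nrow(object@W1),
              object@hiddenActivation, object@outputActivation, object@errorFn))
  if (!is.null(object@meta$bestIteration))
    cat(sprintf("  trained: best validation error at iteration %d of %d\n",
                object@meta$bestIteration, object@meta$iterations))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d of %d descriptors selected (K = %d, %d preliminary nets)\n",
              length(object@selected), nrow(object@ranking),
              as.integer(object@K), as.integer(object@nNets)))
  cat("  top of ranking:", paste(head(object@ranking$descriptor, 5), collapse = ", "), "\n")
})
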