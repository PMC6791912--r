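#' Confusion matrix and accuracies
#'
#' 2x2 confusion matrix (rows = actual class, columns = predicted) with
#' overall and per-class accuracy in percent -- the format in which model
#' quality is reported for each data subset.
#'
#' @param predictions predicted classes in {1, 2}
#' @param labels actual classes in {1, 2}
#' @return list with `confusion`, `accuracy` (percent), `classAccuracy`
#'   (percent, named "1" and "2")
#' @export
confusionAccuracy <- function(predictions, labels) {
  if (!length(labels)) stop("empty input")
  if (length(predictions) != length(labels)) stop("length mismatch")
  stopifnot(all(predictions %in% c(1, 2)), all(labels %in% c(1, 2)))
  cm <- matrix(0L, 2, 2, dimnames = list(actual = c("1", "2"),
                                         predicted = c("1", "2")))
  for (k in seq_along(labels))
    cm[labels[k], predictions[k]] <- cm[labels[k], predictions[k]] + 1L
  classAcc <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  classAcc[rowSums(cm) == 0] <- NA_real_
  list(confusion = cm,
       accuracy = 100 * sum(diag(cm)) / length(labels),
       classAccuracy = classAcc)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), giving monotone
#' (FPR, TPR) points from (0,0) to (1,1); AUC by the trapezoid rule. Class 1
#' is the positive class and scores are its posteriors.
#'
#' @param scores class-1 posterior per case
#' @param labels actual classes in {1, 2}
#' @return list with `points` (data.frame fpr/tpr/threshold) and `auc`
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("ROC needs at least one case of each class")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n2, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Cumulative gain curve
#'
#' Cases are ranked by descending score; each point gives (fraction of cases
#' selected, fraction of all positives captured). Starts at (0,0), ends at
#' (1,1), non-decreasing.
#'
#' @param scores class-1 posterior per case
#' @param labels actual classes in {1, 2}
#' @return data.frame with `selected` and `captured` fractions
#' @export
gainCurve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (!npos) stop("gain curve needs at least one positive (class-1) case")
  ord <- order(-scores)
  cap <- cumsum(labels[ord] == 1) / npos
  data.frame(selected = c(0, seq_along(scores) / length(scores)),
             captured = c(0, cap))
}

#' Class-separation tests for one descriptor
#'
#' Welch two-sample t test, Mann-Whitney U (normal approximation with tie
#' correction) and two-sample Kolmogorov-Smirnov test of the descriptor's
#' distribution in class 1 versus class 2 -- the statistics used to judge
#' whether a descriptor separates stable from fragmenting molecular ions.
#'
#' @param x descriptor column
#' @param labels classes in {1, 2}, at least 2 cases per class
#' @return data.frame with columns `test`, `statistic`, `p`; the t row is NA
#'   with a warning when both groups have zero variance
#' @export
classSeparationTests <- function(x, labels) {
  g1 <- x[labels == 1]; g2 <- x[labels == 2]
  if (length(g1) < 2 || length(g2) < 2)
    stop("need at least 2 cases per class")
  tt <- if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    warning("zero variance in both groups: t statistic undefined")
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    r <- stats::t.test(g1, g2)                     # Welch
    list(statistic = unname(r$statistic), p.value = r$p.value)
  }
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE))
  kt <- suppressWarnings(stats::ks.test(g1, g2))
  data.frame(test = c("t", "U", "KS"),
             statistic = c(tt$statistic, unname(wt$statistic), unname(kt$statistic)),
             p = c(tt$p.value, wt$p.value, kt$p.value))
}

#' Evaluate an ensemble of trained networks
#'
#' Applies each network to the dataset, reports per-model class calls and
#' class-1 posteriors, the majority-vote consensus of the (odd-sized)
#' ensemble, and flags the cases on which the networks disagree. When a
#' train/validation/test split is supplied, per-subset accuracy, ROC/AUC
#' and gain curves are computed for every model and for the ensemble-mean
#' posterior.
#'
#' @param models list of trained [MLPModel-class] objects sharing a feature
#'   set
#' @param X case matrix (raw descriptor scale), rownames = ids
#' @param labels actual classes in {1, 2} (optional for prediction-only use)
#' @param split optional list with `train`/`validation`/`test` id vectors
#'   (as from [splitDataset()])
#' @return list with `calls` (cases x models), `posterior` (cases x models),
#'   `consensus`, `disagreement`, and -- with labels -- `subsets`, a
#'   per-subset list of per-model accuracy and ROC plus ensemble-level
#'   metrics
#' @export
ensembleReport <- function(models, X, labels = NULL, split = NULL) {
  fn <- models[[1]]@featureNames
  for (m in models)
    if (!identical(m@featureNames, fn))
      stop("models do not share an input feature set")
  if (!identical(colnames(X), fn)) {
    missing <- setdiff(fn, colnames(X))
    if (length(missing))
      stop("input lacks model feature(s): ", paste(missing, collapse = ", "))
    X <- X[, fn, drop = FALSE]
  }
  nm <- length(models)
  calls <- vapply(models, function(m) mlpPredict(m, X), integer(nrow(X)))
  post <- vapply(models, function(m) mlpForward(m, X)$posterior, numeric(nrow(X)))
  if (nrow(X) == 1) { calls <- matrix(calls, 1); post <- matrix(post, 1) }
  rownames(calls) <- rownames(post) <- rownames(X)
  votes1 <- rowSums(calls == 1L)
  consensus <- ifelse(votes1 > nm / 2, 1L, 2L)
  disagreement <- votes1 > 0 & votes1 < nm
  out <- list(calls = calls, posterior = post, consensus = consensus,
              disagreement = disagreement)
  if (!is.null(labels)) {
    meanPost <- rowMeans(post)
    subsetEval <- function(idx) {
      list(
        perModel = lapply(seq_len(nm), function(k) {
          c(confusionAccuracy(calls[idx, k], labels[idx]),
            list(roc = rocAuc(post[idx, k], labels[idx])))
        }),
        consensus = confusionAccuracy(consensus[idx], labels[idx]),
        roc = rocAuc(meanPost[idx], labels[idx]),
        gain = gainCurve(meanPost[idx], labels[idx]))
    }
    if (is.null(split)) {
      out$subsets <- list(all = subsetEval(seq_len(nrow(X))))
    } else {
      ids <- rownames(X)
      out$subsets <- lapply(split[c("train", "validation", "test")],
                            function(s) subsetEval(match(s, ids)))
    }
  }
  out
}
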