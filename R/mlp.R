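#' One-hidden-layer perceptron for 2-class spectra classification
#'
#' Creates an untrained MLP n_in-n_hidden-2 with weights drawn uniformly in
#' \[-r, r\], r = sqrt(6/(fan_in + fan_out)) (Glorot range), reproducibly
#' for a given seed. Input standardization parameters are fitted later by
#' [trainMLP()].
#'
#' @param nIn number of input descriptors
#' @param nHidden hidden units (>= 1)
#' @param hiddenActivation "tanh", "exponential", "logistic" or "linear"
#' @param outputActivation "exponential", "linear", "softmax", "logistic" or
#'   "tanh"
#' @param errorFn "sse" (sum of squares) or "entropy" (cross-entropy;
#'   requires an output activation that cannot emit negatives)
#' @param seed RNG seed for the weight draw
#' @param featureNames optional input descriptor names
#' @return an [MLPModel-class]
#' @export
initMLP <- function(nIn, nHidden, hiddenActivation = "tanh",
                    outputActivation = "softmax", errorFn = "entropy",
                    seed = 1L, featureNames = paste0("x", seq_len(nIn))) {
  if (nHidden < 1) stop("nHidden must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r1 <- sqrt(6 / (nIn + nHidden))
  r2 <- sqrt(6 / (nHidden + 2))
  m <- new("MLPModel",
           W1 = matrix(runif(nHidden * nIn, -r1, r1), nHidden, nIn),
           b1 = runif(nHidden, -r1, r1),
           W2 = matrix(runif(2 * nHidden, -r2, r2), 2, nHidden),
           b2 = runif(2, -r2, r2),
           hiddenActivation = hiddenActivation,
           outputActivation = outputActivation,
           errorFn = errorFn,
           xMean = rep(0, nIn), xSd = rep(1, nIn),
           featureNames = featureNames,
           meta = list(seed = seed, iterations = 0L, bestIteration = NULL))
  validObject(m)
  m
}

.act <- function(z, name) {
  switch(name,
         tanh = tanh(z),
         exponential = exp(z),
         logistic = 1 / (1 + exp(-z)),
         linear = z,
         softmax = {
           e <- exp(z - apply(z, 1, max))
           e / rowSums(e)
         })
}

# derivative of the activation w.r.t. its pre-activation, as a function of
# the activation value (softmax handled separately through its Jacobian)
.actDeriv <- function(a, name) {
  switch(name,
         tanh = 1 - a^2,
         exponential = a,
         logistic = a * (1 - a),
         linear = array(1, dim(a)))
}

# flatten / unflatten model weights for the optimizer
.flatten <- function(m) c(m@W1, m@b1, m@W2, m@b2)
.unflatten <- function(m, theta) {
  nh <- nrow(m@W1); ni <- ncol(m@W1)
  p <- 0L
  m@W1 <- matrix(theta[p + seq_len(nh * ni)], nh, ni); p <- p + nh * ni
  m@b1 <- theta[p + seq_len(nh)]; p <- p + nh
  m@W2 <- matrix(theta[p + seq_len(2 * nh)], 2, nh); p <- p + 2 * nh
  m@b2 <- theta[p + seq_len(2)]
  m
}

.standardize <- function(m, X) sweep(sweep(X, 2, m@xMean), 2, m@xSd, "/")

#' Forward pass
#'
#' Standardizes the input internally, applies both layers, and reports the
#' raw outputs plus the class-1 posterior (softmax-normalized when the
#' output activation is not already softmax).
#'
#' @param model an [MLPModel-class]
#' @param x numeric vector of length n_in, or a matrix with one case per row
#' @return list with `outputs` (n x 2 matrix) and `posterior` (class-1
#'   probability per case)
#' @export
mlpForward <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model@W1))
    stop(sprintf("dimension mismatch: model expects %d inputs, got %d",
                 ncol(model@W1), ncol(X)))
  Xs <- .standardize(model, X)
  A1 <- .act(Xs %*% t(model@W1) + rep(1, nrow(Xs)) %o% model@b1,
             model@hiddenActivation)
  Z2 <- A1 %*% t(model@W2) + rep(1, nrow(Xs)) %o% model@b2
  Y <- if (model@outputActivation == "softmax") .act(Z2, "softmax")
       else .act(Z2, model@outputActivation)
  post <- if (model@outputActivation == "softmax") Y[, 1]
          else {
            e <- exp(Y - apply(Y, 1, max))
            (e / rowSums(e))[, 1]
          }
  list(outputs = Y, posterior = post)
}

# one-hot targets from labels in {1, 2}
.oneHot <- function(labels) {
  stopifnot(all(labels %in% c(1, 2)))
  cbind(as.numeric(labels == 1), as.numeric(labels == 2))
}

#' Error-function value on a dataset
#'
#' Sum of squares \eqn{\sum (y - t)^2} over cases and outputs, or
#' cross-entropy \eqn{-\sum t \ln y} with y clipped to
#' \[1e-12, 1 - 1e-12\]. Targets are the one-hot encoding of labels 1/2.
#'
#' @param model an [MLPModel-class]
#' @param X case matrix (raw descriptor scale)
#' @param labels class labels in {1, 2}
#' @return a single numeric error value
#' @export
mlpLoss <- function(model, X, labels) {
  Y <- mlpForward(model, X)$outputs
  Tm <- .oneHot(labels)
  if (model@errorFn == "sse") sum((Y - Tm)^2)
  else {
    Yc <- pmin(pmax(Y, 1e-12), 1 - 1e-12)
    -sum(Tm * log(Yc))
  }
}

# loss and analytic gradient at flattened weights theta, on pre-standardized
# inputs Xs; returns list(loss, grad)
.mlpLossGrad <- function(model, theta, Xs, Tm) {
  m <- .unflatten(model, theta)
  n <- nrow(Xs)
  ones <- rep(1, n)
  Z1 <- Xs %*% t(m@W1) + ones %o% m@b1
  A1 <- .act(Z1, m@hiddenActivation)
  Z2 <- A1 %*% t(m@W2) + ones %o% m@b2
  Y <- .act(Z2, m@outputActivation)
  if (m@errorFn == "sse") {
    loss <- sum((Y - Tm)^2)
    dY <- 2 * (Y - Tm)
  } else {
    Yc <- pmin(pmax(Y, 1e-12), 1 - 1e-12)
    loss <- -sum(Tm * log(Yc))
    dY <- -Tm / Yc
    dY[Y <= 1e-12 | Y >= 1 - 1e-12] <- 0   # clipped region is flat
  }
  if (m@outputActivation == "softmax") {
    if (m@errorFn == "entropy") {
      dZ2 <- Y - Tm                       # rowSums(Tm) == 1
    } else {
      s <- rowSums(dY * Y)
      dZ2 <- Y * (dY - s)                 # softmax Jacobian
    }
  } else {
    dZ2 <- dY * .actDeriv(Y, m@outputActivation)
  }
  gW2 <- t(dZ2) %*% A1
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% m@W2
  dZ1 <- dA1 * .actDeriv(A1, m@hiddenActivation)
  gW1 <- t(dZ1) %*% Xs
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

#' Train an MLP with BFGS and validation-based model selection
#'
#' Fits z-score standardization on the training set, then minimizes the
#' model's error function over the flattened weights with the BFGS
#' quasi-Newton update and a backtracking (Armijo) line search. The
#' validation error is tracked at every iteration and the returned model
#' carries the weights of the iteration with the smallest validation error.
#' Non-finite losses during the line search reject the step and retry a
#' smaller one. Training stops when the gradient infinity-norm drops below
#' `gradTol` or after `maxIter` iterations.
#'
#' @param model an [MLPModel-class] from [initMLP()]
#' @param X,labels training cases (raw descriptor scale) and labels in
#'   {1, 2}
#' @param Xval,labelsVal validation cases and labels
#' @param maxIter iteration cap (default 200)
#' @param gradTol gradient infinity-norm stopping tolerance (default 1e-6)
#' @param l2 optional L2 penalty coefficient on the weights (default 0)
#' @return the trained [MLPModel-class]; `meta` gains `iterations`,
#'   `bestIteration` and a `history` data.frame of train/validation error
#' @export
trainMLP <- function(model, X, labels, Xval, labelsVal,
                     maxIter = 200L, gradTol = 1e-6, l2 = 0) {
  if (!nrow(X) || !nrow(Xval)) stop("train and validation sets must be non-empty")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1    # guarded; filtered inputs have sd > 0
  model@xMean <- as.numeric(mu)
  model@xSd <- as.numeric(sdv)
  Xs <- .standardize(model, X)
  Xvs <- .standardize(model, Xval)
  Tm <- .oneHot(labels)
  Tv <- .oneHot(labelsVal)

  fg <- function(th) {
    r <- .mlpLossGrad(model, th, Xs, Tm)
    if (l2 > 0) {
      r$loss <- r$loss + l2 * sum(th^2)
      r$grad <- r$grad + 2 * l2 * th
    }
    r
  }
  valErr <- function(th) .mlpLossGrad(model, th, Xvs, Tv)$loss

  theta <- .flatten(model)
  np <- length(theta)
  H <- diag(np)
  # exponential activations can overflow (or blow the loss out of line-search
  # range) at the drawn weights; shrink the initial weights deterministically
  # until the starting point is workable
  for (shrink in 1:60) {
    r <- fg(theta)
    if (is.finite(r$loss) && all(is.finite(r$grad)) && r$loss <= 1e8) break
    theta <- theta / 2
  }
  f <- r$loss; g <- r$grad
  if (!is.finite(f) || !all(is.finite(g)))
    stop("training error: non-finite loss or gradient at the initial weights")
  hist <- data.frame(iteration = 0L, train = f, validation = valErr(theta))
  best <- list(theta = theta, val = hist$validation[1], iter = 0L)
  iter <- 0L
  while (iter < maxIter && all(is.finite(g)) && max(abs(g)) > gradTol) {
    iter <- iter + 1L
    p <- -as.numeric(H %*% g)
    gp <- sum(g * p)
    if (!is.finite(gp) || gp >= 0) { H <- diag(np); p <- -g; gp <- sum(g * p) }
    alpha <- 1
    ok <- FALSE
    for (ls in 1:40) {
      thNew <- theta + alpha * p
      rNew <- tryCatch(fg(thNew), error = function(e) NULL)
      if (!is.null(rNew) && is.finite(rNew$loss) && all(is.finite(rNew$grad)) &&
          rNew$loss <= f + 1e-4 * alpha * gp) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) break                               # persistent line-search failure
    s <- thNew - theta
    yk <- rNew$grad - g
    sy <- sum(s * yk)
    if (is.finite(sy) && sy > 1e-10) {           # curvature condition
      rho <- 1 / sy
      Hy <- H %*% yk
      H <- H - rho * (s %*% t(Hy) + Hy %*% t(s)) +
        (rho^2 * sum(yk * Hy) + rho) * (s %*% t(s))
    }
    theta <- thNew; f <- rNew$loss; g <- rNew$grad
    ve <- valErr(theta)
    hist <- rbind(hist, data.frame(iteration = iter, train = f, validation = ve))
    if (is.finite(ve) && ve < best$val) best <- list(theta = theta, val = ve, iter = iter)
  }
  out <- .unflatten(model, best$theta)
  out@meta <- c(model@meta[setdiff(names(model@meta),
                                   c("iterations", "bestIteration", "history"))],
                list(iterations = iter, bestIteration = best$iter, history = hist))
  out
}

#' Predict classes
#'
#' Argmax of the two outputs; exact ties go to class 2, the
#' majority-risk "fragmenting" class.
#'
#' @param model an [MLPModel-class]
#' @param X case matrix
#' @return integer vector of predicted classes in {1, 2}
#' @export
mlpPredict <- function(model, X) {
  Y <- mlpForward(model, X)$outputs
  ifelse(Y[, 1] > Y[, 2], 1L, 2L)
}

#' Sensitivity analysis by mean substitution
#'
#' For each input descriptor, replaces its column by the reference-set mean
#' and recomputes the model error; the sensitivity ratio is substituted
#' error divided by baseline error. Ratios near 1 mark uninformative
#' inputs; large ratios mark descriptors the network relies on. If the
#' baseline error is (numerically) zero the substituted errors themselves
#' are reported, flagged by `baselineZero`.
#'
#' @param model a trained [MLPModel-class]
#' @param X reference cases (normally the training set)
#' @param labels reference labels in {1, 2}
#' @return list with `ratio` (named per descriptor), `ranking` (descriptor
#'   names, descending sensitivity, ties broken by name), `baseline`, and
#'   `baselineZero`
#' @export
mlpSensitivity <- function(model, X, labels) {
  base <- mlpLoss(model, X, labels)
  nm <- model@featureNames
  sub <- vapply(seq_len(ncol(X)), function(j) {
    Xj <- X
    Xj[, j] <- mean(X[, j])
    mlpLoss(model, Xj, labels)
  }, 0)
  zero <- base <= 1e-300
  ratio <- if (zero) sub else sub / base
  names(ratio) <- nm
  ord <- order(-ratio, nm)
  list(ratio = ratio, ranking = nm[ord], baseline = base, baselineZero = zero)
}

#' Save / load an MLP model as JSON
#'
#' Serializes weights at full precision (IEEE doubles survive the
#' round-trip), together with activations, error function, standardization
#' and metadata, under a schema version.
#'
#' @param model an [MLPModel-class]
#' @param path output/input file path
#' @return `loadMLP` returns the restored [MLPModel-class]
#' @export
saveMLP <- function(model, path) {
  # %.17g decimal strings round-trip IEEE doubles exactly
  num <- function(x) sprintf("%.17g", as.numeric(x))
  doc <- list(schema = "chloroMS-mlp/1",
              nIn = ncol(model@W1), nHidden = nrow(model@W1),
              W1 = num(model@W1), b1 = num(model@b1),
              W2 = num(model@W2), b2 = num(model@b2),
              hiddenActivation = model@hiddenActivation,
              outputActivation = model@outputActivation,
              errorFn = model@errorFn,
              xMean = num(model@xMean), xSd = num(model@xSd),
              featureNames = model@featureNames,
              meta = model@meta[setdiff(names(model@meta), "history")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveMLP
#' @export
loadMLP <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot read model file ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$schema) || !identical(doc$schema, "chloroMS-mlp/1"))
    stop("model schema-version mismatch in ", path)
  m <- new("MLPModel",
           W1 = matrix(as.numeric(doc$W1), doc$nHidden, doc$nIn),
           b1 = as.numeric(doc$b1),
           W2 = matrix(as.numeric(doc$W2), 2, doc$nHidden),
           b2 = as.numeric(doc$b2),
           hiddenActivation = doc$hiddenActivation,
           outputActivation = doc$outputActivation,
           errorFn = doc$errorFn,
           xMean = as.numeric(doc$xMean), xSd = as.numeric(doc$xSd),
           featureNames = as.character(doc$featureNames),
           meta = as.list(doc$meta))
  validObject(m)
  m
}
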