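# Small dense feed-forward classifier mapping feature windows to vessel
# scores.  tanh hidden layers, sigmoid output, binary cross-entropy loss,
# full-batch Adam with early stopping on a seeded validation split.  All
# randomness (initialization, split) is controlled by explicit seeds so
# trained models are bit-reproducible.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a classifier network
#'
#' Architecture \code{inputDim -> layerSizes ... -> 1}; weights drawn from a
#' seeded Xavier-uniform distribution, biases zero.
#'
#' @param inputDim flattened feature length (e.g. 32 * 32 = 1024).
#' @param layerSizes hidden-layer widths (default \code{c(10, 8, 6)}).
#' @param seed RNG seed for the initial weights.
#' @return An untrained \code{\link{ClassifierModel-class}}.
#' @export
initNetwork <- function(inputDim, layerSizes = c(10, 8, 6), seed = 1) {
  if (length(layerSizes) == 0) stop("at least one hidden layer required")
  if (any(layerSizes < 1)) stop("hidden-layer widths must be >= 1")
  dims <- c(inputDim, layerSizes, 1)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  weights <- list()
  biases <- list()
  for (l in seq_len(length(dims) - 1)) {
    s <- sqrt(6 / (dims[l] + dims[l + 1]))
    weights[[l]] <- matrix(stats::runif(dims[l + 1] * dims[l], -s, s),
                           nrow = dims[l + 1])
    biases[[l]] <- numeric(dims[l + 1])
  }
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  new("ClassifierModel", inputDim = inputDim, layerSizes = layerSizes,
      weights = weights, biases = biases, activation = "tanh",
      trainingMeta = list(initSeed = seed))
}

# Forward pass for an n x inputDim matrix; returns activations per layer
# (for backprop) and the sigmoid scores.
forwardPass <- function(model, x) {
  acts <- list(x)
  nl <- length(model@weights)
  a <- x
  for (l in seq_len(nl - 1)) {
    a <- tanh(a %*% t(model@weights[[l]]) +
                rep(model@biases[[l]], each = nrow(a)))
    acts[[l + 1]] <- a
  }
  z <- a %*% t(model@weights[[nl]]) + rep(model@biases[[nl]], each = nrow(a))
  list(acts = acts, scores = as.vector(sigmoid(z)))
}

bceLoss <- function(p, y, w = 1) {
  eps <- 1e-12
  -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

#' Train a classifier
#'
#' Full-batch Adam on binary cross-entropy.  A seeded fraction of the data
#' is held out for validation; training keeps the weights with the best
#' validation performance and stops early after \code{patience} epochs
#' without improvement.  "Best" means lowest class-weighted validation
#' error rate, with the validation loss as tie-break: on separable,
#' imbalanced feature sets the raw loss bottoms out long before the
#' decision boundary is in place, so stopping on loss returns an under-fit
#' model.  With \code{validationFraction = 0} the training loss is
#' monitored instead.  With \code{balanceClasses = TRUE} (the default)
#' samples are inverse-frequency weighted in the loss: curated vessel
#' training sets run roughly 15 non-vessel windows per vessel window, and
#' an unweighted loss lets the majority class drown out the positives.
#'
#' @param model an initialized \code{\link{ClassifierModel-class}}.
#' @param data a \code{\link{TrainingSet-class}} containing both classes.
#' @param epochs maximum epochs (default 1500).
#' @param learningRate Adam step size (default 0.01).
#' @param validationFraction held-out fraction (default 0.2).
#' @param seed RNG seed for the split.
#' @param patience early-stopping patience in epochs.
#' @param balanceClasses weight classes inversely to their frequency.
#' @return The trained model; \code{trainingMeta} records the seed, epochs
#'   run, hyperparameters and the loss histories.
#' @export
trainNetwork <- function(model, data, epochs = 1500, learningRate = 0.01,
                         validationFraction = 0.2, seed = 1, patience = 300,
                         balanceClasses = TRUE) {
  stopifnot(is(model, "ClassifierModel"), is(data, "TrainingSet"))
  dm <- trainingMatrix(data)
  x <- dm$x
  y <- dm$y
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite features")
  if (ncol(x) != model@inputDim) stop("feature shape does not match model input")

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  n <- nrow(x)
  nVal <- floor(n * validationFraction)
  perm <- sample.int(n)
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  valIdx <- perm[seq_len(nVal)]
  trIdx <- if (nVal > 0) perm[-seq_len(nVal)] else perm
  if (length(unique(y[trIdx])) < 2) {
    # degenerate split; fall back to training on everything
    trIdx <- perm
    valIdx <- integer()
    nVal <- 0
  }
  xt <- x[trIdx, , drop = FALSE]; yt <- y[trIdx]
  xv <- x[valIdx, , drop = FALSE]; yv <- y[valIdx]

  classWeight <- function(yy) {
    if (!balanceClasses) return(rep(1, length(yy)))
    n1 <- sum(yy == 1); n0 <- sum(yy == 0)
    ifelse(yy == 1, length(yy) / (2 * max(n1, 1)),
           length(yy) / (2 * max(n0, 1)))
  }
  wt <- classWeight(yt)
  wv <- if (nVal > 0) classWeight(yv) else numeric()

  W <- model@weights
  b <- model@biases
  nl <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(v) v * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8

  lossHist <- numeric(0)
  valHist <- numeric(0)
  best <- list(W = W, b = b, err = Inf, loss = Inf, epoch = 0L)
  work <- model

  for (ep in seq_len(epochs)) {
    work@weights <- W; work@biases <- b
    fp <- forwardPass(work, xt)
    p <- fp$scores
    lossHist[ep] <- bceLoss(p, yt, wt)

    # backprop (weighted BCE + sigmoid gives delta = w (p - y) / n)
    delta <- matrix(wt * (p - yt) / length(yt), ncol = 1)
    gW <- vector("list", nl); gB <- vector("list", nl)
    for (l in rev(seq_len(nl))) {
      gW[[l]] <- t(delta) %*% fp$acts[[l]]
      gB[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% W[[l]]) * (1 - fp$acts[[l]]^2)
    }
    for (l in seq_len(nl)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhB <- mB[[l]] / (1 - beta1^ep); vhB <- vB[[l]] / (1 - beta2^ep)
      W[[l]] <- W[[l]] - learningRate * mhW / (sqrt(vhW) + adamEps)
      b[[l]] <- b[[l]] - learningRate * mhB / (sqrt(vhB) + adamEps)
    }

    if (nVal > 0) {
      work@weights <- W; work@biases <- b
      pv <- forwardPass(work, xv)$scores
      valHist[ep] <- bceLoss(pv, yv, wv)
      err <- sum(wv * ((pv >= 0.5) != (yv == 1))) / length(yv)
      loss <- valHist[ep]
    } else {
      err <- 0
      loss <- lossHist[ep]
    }
    if (err < best$err - 1e-12 ||
        (err <= best$err + 1e-12 && loss < best$loss - 1e-9)) {
      best <- list(W = W, b = b, err = err, loss = loss, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }

  model@weights <- best$W
  model@biases <- best$b
  model@trainingMeta <- c(model@trainingMeta[setdiff(names(model@trainingMeta),
    c("splitSeed", "epochsRun", "lossHistory", "valLossHistory"))],
    list(splitSeed = seed, epochs = epochs, learningRate = learningRate,
         validationFraction = validationFraction, patience = patience,
         balanceClasses = balanceClasses,
         epochsRun = length(lossHist), bestEpoch = best$epoch,
         lossHistory = lossHist, valLossHistory = valHist))
  model
}

#' @describeIn ClassifierModel-class vessel score(s) in \[0, 1\] for a
#'   \code{FeatureWindow}, a flattened numeric vector, or an n x inputDim
#'   matrix of flattened windows.  Deterministic.
#' @param model a \code{ClassifierModel}.
#' @param newdata feature input.
#' @param ... unused.
#' @export
setMethod("predictScore", "ClassifierModel", function(model, newdata, ...) {
  x <- if (is(newdata, "FeatureWindow")) matrix(as.vector(newdata@values),
                                                nrow = 1)
       else if (is.matrix(newdata)) newdata
       else matrix(as.numeric(newdata), nrow = 1)
  if (ncol(x) != model@inputDim)
    stop("feature shape (", ncol(x), ") does not match model input (",
         model@inputDim, ")")
  forwardPass(model, x)$scores
})

#' Serialize a classifier model to JSON
#'
#' Stores layer sizes, weights, biases and training metadata at full
#' numeric precision so a reloaded model reproduces its scores.
#'
#' @param model a \code{\link{ClassifierModel-class}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  obj <- list(inputDim = model@inputDim, layerSizes = model@layerSizes,
              activation = model@activation,
              weights = lapply(model@weights, function(w)
                list(dim = dim(w), values = as.vector(w))),
              biases = model@biases,
              trainingMeta = model@trainingMeta[
                setdiff(names(model@trainingMeta),
                        c("lossHistory", "valLossHistory"))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_along(obj$weights$dim), function(l)
    matrix(obj$weights$values[[l]], nrow = obj$weights$dim[[l]][1]))
  biases <- if (is.list(obj$biases)) obj$biases else list(obj$biases)
  new("ClassifierModel", inputDim = obj$inputDim,
      layerSizes = obj$layerSizes, weights = weights,
      biases = lapply(biases, as.numeric), activation = obj$activation,
      trainingMeta = as.list(obj$trainingMeta))
}
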