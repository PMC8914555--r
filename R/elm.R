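#' Hidden-layer activation functions
#'
#' The three activations used for the hidden layer: `sig` (logistic,
#' `1/(1+exp(-x))`), `sin`, and `hardlim` (1 for `x > 0`, else 0;
#' the boundary `x = 0`, a measure-zero case, maps to 0).
#'
#' @param name `"sig"`, `"sin"` or `"hardlim"`.
#' @param x Numeric vector or matrix of pre-activations.
#' @return Transformed values, same shape as `x`.
#' @export
activate <- function(name = c("sig", "sin", "hardlim"), x) {
  name <- match.arg(name)
  switch(name,
         sig = 1 / (1 + exp(-x)),
         sin = sin(x),
         hardlim = (x > 0) * 1)
}

#' Extreme learning machine configuration
#'
#' @param n_hidden Number of hidden neurons `L` (the reference search
#'   range is 1..100).
#' @param activation Hidden activation name (see [activate()]).
#' @param seed Seed for the random input weights and biases.
#' @param output_encoding `"onehot"` (one output neuron per class,
#'   argmax decoding — the default) or `"label"` (a single output neuron
#'   trained on the numeric class index, decoded by rounding and
#'   clamping).
#' @return An `elm_config` list.
#' @export
elm_config <- function(n_hidden, activation = c("sig", "sin", "hardlim"),
                       seed = 1L, output_encoding = c("onehot", "label")) {
  stopifnot(n_hidden >= 1L)
  structure(list(n_hidden = as.integer(n_hidden),
                 activation = match.arg(activation),
                 seed = as.integer(seed),
                 output_encoding = match.arg(output_encoding)),
            class = "elm_config")
}

# Random input weights/biases, uniform on [-1, 1], drawn as one stream:
# first the d x L weight matrix (column-major), then the L biases.
elm_random_layer <- function(d, L, seed) {
  set.seed(seed)
  list(W = matrix(stats::runif(d * L, -1, 1), nrow = d, ncol = L),
       b = stats::runif(L, -1, 1))
}

elm_targets <- function(y, classes, encoding) {
  idx <- match(y, classes)
  if (encoding == "onehot") {
    T <- matrix(0, length(y), length(classes))
    T[cbind(seq_along(idx), idx)] <- 1
    T
  } else {
    matrix(as.numeric(idx), ncol = 1L)
  }
}

# Minimum-norm least squares via SVD with relative cutoff 1e-10;
# tolerates rank-deficient H (e.g. all-zero hardlim columns).
minnorm_lsq <- function(H, T) {
  sv <- svd(H)
  d <- sv$d
  keep <- d > 1e-10 * max(d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(H), ncol(T)))
  }
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% T) / d[keep])
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer feedforward network: input weights and biases are
#' drawn uniformly on `[-1, 1]` and frozen; the hidden layer output
#' `H = S(X W + b)` is computed with the configured activation `S`; the
#' output weights are the minimum-norm least-squares solution of
#' `H beta = T` (SVD with relative singular-value cutoff 1e-10), where
#' `T` encodes the class labels per `output_encoding`.
#'
#' @param X Numeric matrix of training features (samples x d).
#' @param y Training labels.
#' @param config An [elm_config()].
#' @param classes Optional fixed class-level ordering (default: factor
#'   levels of `y`).
#' @return An `elm_model` with input weights, biases, output weights and
#'   the class levels.
#' @export
train_elm <- function(X, y, config, classes = NULL) {
  stopifnot(inherits(config, "elm_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  if (is.null(classes)) classes <- levels(factor(y))
  layer <- elm_random_layer(ncol(X), config$n_hidden, config$seed)
  H <- activate(config$activation,
                X %*% layer$W + matrix(layer$b, nrow(X), config$n_hidden,
                                       byrow = TRUE))
  T <- elm_targets(y, classes, config$output_encoding)
  beta <- minnorm_lsq(H, T)
  structure(list(W = layer$W, b = layer$b, beta = beta,
                 classes = classes, config = config),
            class = "elm_model")
}

#' Predict class labels with a trained ELM
#'
#' One-hot models decode by argmax over class scores (score ties break
#' toward the lowest class index); label-coded models round the single
#' output to the nearest class index, clamped into range.
#'
#' @param object An `elm_model`.
#' @param newdata Numeric matrix of features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$W)) {
    stop("feature dimension mismatch: model expects ", nrow(object$W),
         ", got ", ncol(X), call. = FALSE)
  }
  H <- activate(object$config$activation,
                X %*% object$W + matrix(object$b, nrow(X),
                                        ncol(object$W), byrow = TRUE))
  scores <- H %*% object$beta
  if (object$config$output_encoding == "onehot") {
    idx <- apply(scores, 1L, which.max)  # first max = lowest class index
  } else {
    idx <- pmin(pmax(round(scores[, 1L]), 1L), length(object$classes))
  }
  object$classes[idx]
}

#' Classification accuracy in percent
#'
#' `100 * (number correct) / (total)`.
#'
#' @param pred,truth Equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
elm_accuracy <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop("pred and truth must be nonempty and of equal length",
         call. = FALSE)
  }
  100 * mean(as.character(pred) == as.character(truth))
}

#' Search the hidden-layer size by cut-and-trial
#'
#' Trains one ELM per hidden-layer size `L` over `l_range` and returns
#' the `L` maximizing test-set accuracy (ties break toward the smallest
#' `L`). All sizes share one seed-derived weight stream: the weights and
#' biases for the largest `L` are drawn once and each smaller network
#' uses their leading columns, so the search is deterministic given the
#' seed and the hidden layer `H` is computed once.
#'
#' @param Xtr,ytr Training features and labels.
#' @param Xte,yte Test (prediction-set) features and labels.
#' @param activation Hidden activation name.
#' @param l_range Length-2 integer range of hidden sizes (default
#'   `c(1, 100)`).
#' @param seed Seed for the shared weight stream.
#' @param output_encoding See [elm_config()].
#' @return A list: `best_l`, `model` (refit at `best_l`), `train_accuracy`
#'   and `test_accuracy` at the optimum, and `curve` (accuracy vs `L`).
#' @export
tune_hidden <- function(Xtr, ytr, Xte, yte,
                        activation = c("sig", "sin", "hardlim"),
                        l_range = c(1L, 100L), seed = 1L,
                        output_encoding = c("onehot", "label")) {
  activation <- match.arg(activation)
  output_encoding <- match.arg(output_encoding)
  if (length(l_range) != 2L || l_range[2L] < l_range[1L] || l_range[1L] < 1L) {
    stop("l_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  classes <- levels(factor(c(as.character(ytr), as.character(yte))))
  Lmax <- as.integer(l_range[2L])
  Ls <- seq.int(l_range[1L], Lmax)
  layer <- elm_random_layer(ncol(Xtr), Lmax, seed)
  Htr <- activate(activation,
                  Xtr %*% layer$W + matrix(layer$b, nrow(Xtr), Lmax,
                                           byrow = TRUE))
  Hte <- activate(activation,
                  Xte %*% layer$W + matrix(layer$b, nrow(Xte), Lmax,
                                           byrow = TRUE))
  T <- elm_targets(ytr, classes, output_encoding)
  decode <- function(scores) {
    if (output_encoding == "onehot") {
      classes[apply(scores, 1L, which.max)]
    } else {
      classes[pmin(pmax(round(scores[, 1L]), 1L), length(classes))]
    }
  }
  curve <- data.frame(L = Ls, train_accuracy = NA_real_,
                      test_accuracy = NA_real_)
  for (i in seq_along(Ls)) {
    cols <- seq_len(Ls[i])
    beta <- minnorm_lsq(Htr[, cols, drop = FALSE], T)
    curve$train_accuracy[i] <-
      elm_accuracy(decode(Htr[, cols, drop = FALSE] %*% beta), ytr)
    curve$test_accuracy[i] <-
      elm_accuracy(decode(Hte[, cols, drop = FALSE] %*% beta), yte)
  }
  best <- which.max(curve$test_accuracy)  # smallest L on ties
  best_l <- Ls[best]
  cfg <- elm_config(best_l, activation, seed = seed,
                    output_encoding = output_encoding)
  model <- structure(list(W = layer$W[, seq_len(best_l), drop = FALSE],
                          b = layer$b[seq_len(best_l)],
                          beta = minnorm_lsq(Htr[, seq_len(best_l),
                                                 drop = FALSE], T),
                          classes = classes, config = cfg),
                     class = "elm_model")
  list(best_l = best_l, model = model,
       train_accuracy = curve$train_accuracy[best],
       test_accuracy = curve$test_accuracy[best],
       curve = curve)
}
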