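#' Base classifier configuration
#'
#' The three heterogeneous base learners share one probabilistic contract:
#' given a feature matrix they return an `n x K` matrix of class
#' probabilities. The three kinds are deliberately different model families
#' ("views" of the same task):
#'
#' * `softmax` — multinomial logistic regression with an L2 penalty
#'   (`nnet::multinom`, `decay = regularization`).
#' * `svm` — radial-kernel support vector machine; margins are mapped to
#'   probabilities by cross-validated Platt sigmoid calibration
#'   (`e1071::svm(probability = TRUE)`), so probability averaging across
#'   members is well defined.
#' * `dnn` — single-hidden-layer perceptron of width `max(16, 2d)` with
#'   softmax output (`nnet::nnet`), weight decay and an iteration cap.
#'
#' @param kind one of `"softmax"`, `"svm"`, `"dnn"`.
#' @param regularization L2 penalty (softmax decay / 1 over SVM cost / dnn
#'   weight decay scale), must be positive.
#' @param svm_gamma RBF kernel width; `NULL` uses `1/d`.
#' @param hidden_size dnn hidden width; `NULL` uses `max(16, 2d)`.
#' @param max_epochs dnn optimizer iteration cap.
#' @param seed integer seed consumed by the stochastic fits.
#' @return A `base_config` object.
#' @export
base_config <- function(kind = c("softmax", "svm", "dnn"),
                        regularization = 1.0, svm_gamma = NULL,
                        hidden_size = NULL, max_epochs = 200L, seed = 1L) {
  kind <- match.arg(kind)
  if (regularization <= 0) abort("regularization must be > 0")
  if (!is.null(hidden_size) && hidden_size < 1) abort("hidden_size must be >= 1")
  structure(list(kind = kind, regularization = regularization,
                 svm_gamma = svm_gamma, hidden_size = hidden_size,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "base_config")
}

#' Default configuration triple
#'
#' One config of each kind, with child seeds derived from `seed` by fixed
#' offsets.
#'
#' @param seed master seed.
#' @return List of three `base_config` objects (softmax, svm, dnn).
#' @export
default_configs <- function(seed = 1L) {
  list(base_config("softmax", seed = child_seed(seed, 1L)),
       base_config("svm",     seed = child_seed(seed, 2L)),
       base_config("dnn",     seed = child_seed(seed, 3L)))
}

fit_member <- function(config, X, y_codes, classes) {
  # y_codes: integer 0..K-1; classes: character code levels "0".."K-1"
  y <- factor(as.character(y_codes), levels = classes)
  fit <- with_seed(config$seed, switch(
    config$kind,
    softmax = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, decay = config$regularization,
                     maxit = 200, trace = FALSE)
    },
    svm = e1071::svm(X, y, kernel = "radial",
                     gamma = config$svm_gamma %||% (1 / ncol(X)),
                     cost = 1 / config$regularization, probability = TRUE),
    dnn = {
      size <- config$hidden_size %||% max(16L, 2L * ncol(X))
      nnet::nnet(x = X, y = nnet::class.ind(y), size = size, softmax = TRUE,
                 decay = 1e-3 * config$regularization,
                 maxit = config$max_epochs, MaxNWts = 100000, trace = FALSE)
    }))
  structure(list(kind = config$kind, fit = fit, classes = classes,
                 d = ncol(X), feature_names = colnames(X)),
            class = "metl_member")
}

predict_member <- function(member, X) {
  K <- length(member$classes)
  if (nrow(X) == 0L)
    return(matrix(numeric(0), 0L, K, dimnames = list(NULL, member$classes)))
  colnames(X) <- member$feature_names
  P <- switch(
    member$kind,
    mock = {   # fixed-response member used in unit tests of the ensembles
      pr <- member$proba_fn(X)
      colnames(pr) <- member$classes
      pr
    },
    softmax = {
      pr <- predict(member$fit, newdata = data.frame(X, check.names = FALSE),
                    type = "probs")
      if (is.null(dim(pr))) {
        if (K == 2L) pr <- cbind(1 - pr, pr) else pr <- matrix(pr, nrow = 1L)
      }
      colnames(pr) <- if (ncol(pr) == K) member$classes else colnames(pr)
      pr
    },
    svm = {
      raw <- predict(member$fit, X, probability = TRUE)
      pr <- attr(raw, "probabilities")
      if (is.null(pr)) {
        # degenerate tiny fit without a calibration model: smoothed one-hot
        pr <- 0.1 + 0.9 * nnet::class.ind(factor(raw, levels = member$classes))
        pr <- pr / rowSums(pr)
        colnames(pr) <- member$classes
      }
      pr
    },
    dnn = {
      pr <- predict(member$fit, X)
      colnames(pr) <- colnames(member$fit$fitted.values) %||% member$classes
      pr
    })
  P <- P[, member$classes, drop = FALSE]   # enforce class-code column order
  P <- P / rowSums(P)
  dimnames(P) <- list(NULL, member$classes)
  P
}

#' Fit the three heterogeneous base classifiers
#'
#' Trains one classifier of each kind on the identical training table. The
#' training features are standardized (zero mean, unit variance over this
#' training pool) and the statistics are stored in the returned object, so
#' prediction applies the same transform.
#'
#' @param train a `labeled_table` (or data frame with `label_col`) with at
#'   least two classes present.
#' @param configs list of exactly three `base_config`s, one of each kind.
#' @param seed master seed used when `configs` is `NULL`.
#' @param scale standardize features on this training pool (default `TRUE`).
#' @param label_col label column when `train` is a data frame.
#' @return A `triple_classifier` object.
#' @export
fit_triple <- function(train, configs = NULL, seed = 1L, scale = TRUE,
                       label_col = "label") {
  train <- as_table(train, label_col)
  configs <- configs %||% default_configs(seed)
  kinds <- vapply(configs, `[[`, character(1), "kind")
  if (length(configs) != 3L || !setequal(kinds, c("softmax", "svm", "dnn")))
    abort("configs must contain exactly one softmax, one svm and one dnn",
          class = "metl_validation_error")
  if (length(unique(train$labels)) < 2L)
    abort("training data must contain at least two classes",
          class = "metl_validation_error")
  K <- length(train$label_names)
  classes <- as.character(seq_len(K) - 1L)
  X <- train$features
  scaler <- NULL
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaler <- list(center = ctr, scale = scl)
    X <- scale_features(X, scaler)
  }
  members <- lapply(configs[order(match(kinds, c("softmax", "svm", "dnn")))],
                    function(cfg) fit_member(cfg, X, train$labels, classes))
  structure(list(members = members, classes = classes, K = K,
                 d = ncol(X), feature_names = train$feature_names,
                 label_names = train$label_names, scaler = scaler),
            class = "triple_classifier")
}

scale_features <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

check_X <- function(triple, X) {
  X <- as.matrix(X)
  if (ncol(X) != triple$d)
    abort(sprintf("expected %d feature columns, got %d", triple$d, ncol(X)),
          class = "metl_shape_error")
  storage.mode(X) <- "double"
  X
}

#' Per-member class probabilities
#'
#' @param triple a fitted `triple_classifier`.
#' @param X numeric matrix with the training dimensionality.
#' @return List of three `n x K` probability matrices (softmax, svm, dnn
#'   order); every row sums to 1.
#' @export
predict_proba <- function(triple, X) {
  Xs <- scale_features(check_X(triple, X), triple$scaler)
  lapply(triple$members, function(mem) predict_member(mem, Xs))
}

#' Per-member predicted labels
#'
#' Argmax of each member's probabilities; ties break toward the smallest
#' class code.
#'
#' @inheritParams predict_proba
#' @return List of three integer vectors of class codes `0..K-1`.
#' @export
predict_label <- function(triple, X) {
  lapply(predict_proba(triple, X), prob_argmax)
}

# first-maximum argmax => ties go to the smallest class code
prob_argmax <- function(P) {
  if (nrow(P) == 0L) return(integer(0))
  max.col(P, ties.method = "first") - 1L
}

#' @export
print.triple_classifier <- function(x, ...) {
  cat(sprintf("<triple_classifier> members: %s | %d classes, %d features\n",
              paste(vapply(x$members, `[[`, character(1), "kind"),
                    collapse = " + "), x$K, x$d))
  invisible(x)
}
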