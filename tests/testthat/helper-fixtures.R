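# Fixtures are generated in code; nothing is read from disk.

# Two-class Gaussian blobs in d dimensions, classes separated along the
# first axis by `sep` within-class sds. `flip` inverts that share of labels.
make_blobs <- function(n = 200, d = 4, sep = 4, seed = 1, flip = 0,
                       shift = 0) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    X[, 1] <- X[, 1] + ifelse(y == 1, sep / 2, -sep / 2) + shift
    if (flip > 0) {
      k <- round(flip * n)
      pos <- sample(n, k)
      y[pos] <- 1L - y[pos]
    }
    colnames(X) <- paste0("x", seq_len(d))
    labeled_table(X, y, c("neg", "pos"))
  })
}

# A triple_classifier whose three members return fixed probabilities.
# `proba_fns` is one function (shared by all members) or a list of three,
# each mapping an n x d matrix to an n x K probability matrix.
make_mock_triple <- function(proba_fns, K = 2, d = 2,
                             label_names = paste0("c", seq_len(K) - 1L)) {
  if (is.function(proba_fns)) proba_fns <- list(proba_fns, proba_fns, proba_fns)
  classes <- as.character(seq_len(K) - 1L)
  members <- lapply(proba_fns, function(f)
    structure(list(kind = "mock", proba_fn = f, classes = classes, d = d,
                   feature_names = paste0("x", seq_len(d))),
              class = "metl_member"))
  structure(list(members = members, classes = classes, K = K, d = d,
                 feature_names = paste0("x", seq_len(d)),
                 label_names = label_names, scaler = NULL),
            class = "triple_classifier")
}

# constant-probability member function
const_proba <- function(row) function(X) {
  matrix(rep(row, each = nrow(X)), nrow(X), length(row))
}

# Wrap mock triples into a metl_model with given normalized weights.
make_mock_model <- function(triples, weights, d = 2, K = 2,
                            label_names = paste0("c", seq_len(K) - 1L)) {
  sms <- lapply(triples, function(tr)
    structure(list(triple = tr, sampled_idx = 1L, sampled_source = NULL,
                   iterations_run = 1L, converged = TRUE,
                   size_history = 1L,
                   agreement_mode = "classifiers_and_label"),
              class = "source_model"))
  structure(list(source_models = sms,
                 weights = structure(list(raw = weights,
                                          normalized = weights /
                                            ifelse(sum(weights) > 0,
                                                   sum(weights), 1)),
                                     class = "weight_vector"),
                 label_names = label_names,
                 feature_names = paste0("x", seq_len(d)),
                 K = K, d = d, weighting = "mock",
                 config = metl_config()),
            class = "metl_model")
}

# Exhaustive double-sum MI oracle, independent of mi_discrete(): builds the
# full joint probability table and sums term by term.
mi_oracle <- function(a, b, log_base = 2) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  n <- length(a)
  total <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      px <- sum(a == x) / n
      py <- sum(b == y) / n
      total <- total + pxy * log(pxy / (px * py)) / log(log_base)
    }
  }
  total
}

# plug-in entropy in the given base
entropy_oracle <- function(a, log_base = 2) {
  p <- table(a) / length(a)
  -sum(p * log(p)) / log(log_base)
}
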