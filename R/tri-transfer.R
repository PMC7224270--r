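#' Tri-transfer configuration
#'
#' @param max_iterations cap `N` on sampling iterations (default 20).
#' @param agreement_mode `"classifiers_and_label"` (default): a source row is
#'   kept only if the three members unanimously predict its own given label;
#'   `"classifiers_only"`: unanimity among the members suffices.
#' @param configs optional list of three `base_config`s; `NULL` derives
#'   defaults from `seed`.
#' @param seed master seed for the iterative fits.
#' @return A `tri_config` object.
#' @export
tri_config <- function(max_iterations = 20L,
                       agreement_mode = c("classifiers_and_label",
                                          "classifiers_only"),
                       configs = NULL, seed = 1L) {
  if (max_iterations < 1L) abort("max_iterations must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 agreement_mode = match.arg(agreement_mode),
                 configs = configs, seed = as.integer(seed)),
            class = "tri_config")
}

#' Unanimous-agreement mask over source rows
#'
#' Row `i` is `TRUE` iff the three members predict the same label for source
#' row `i` (`classifiers_only`), additionally equal to the source's own label
#' (`classifiers_and_label`).
#'
#' @param triple a fitted `triple_classifier`.
#' @param source a `labeled_table` of source rows.
#' @param mode agreement mode, see [tri_config()].
#' @return Logical vector, one entry per source row.
#' @export
agreement_mask <- function(triple, source,
                           mode = c("classifiers_and_label",
                                    "classifiers_only")) {
  mode <- match.arg(mode)
  labs <- predict_label(triple, source$features)
  stopifnot(length(labs) == 3L)
  un <- labs[[1L]] == labs[[2L]] & labs[[2L]] == labs[[3L]]
  if (mode == "classifiers_and_label") un <- un & labs[[1L]] == source$labels
  un
}

# derive the configs for iteration n from a tri_config
iteration_configs <- function(config, n) {
  if (!is.null(config$configs)) {
    lapply(seq_along(config$configs), function(j) {
      cfg <- config$configs[[j]]
      cfg$seed <- child_seed(cfg$seed, 100L + n)
      cfg
    })
  } else {
    default_configs(child_seed(config$seed, 100L + n))
  }
}

#' Tri-transfer fit for one source domain
#'
#' Iterative transferable-instance sampling: starting from the full source,
#' each iteration fits the three heterogeneous classifiers from scratch on
#' the current sampled source set pooled with the labeled target data, then
#' keeps only the source rows passing the unanimous-agreement mask. The
#' sampling pool of each iteration is the previous sampled set, so the sets
#' are non-increasing and the loop terminates as soon as the set stops
#' changing (or after `max_iterations` fits). If the set empties, the triple
#' is refit on the target data alone.
#'
#' @param source source-domain data: a `domain_set`, `labeled_table` or data
#'   frame.
#' @param target_train labeled target training data (same schema).
#' @param config a [tri_config()].
#' @param label_col label column for data-frame inputs.
#' @return A `source_model`: the final `triple_classifier`, the converged
#'   sampled source (`sampled_source`, with `sampled_idx` giving row indices
#'   into the original source), `iterations_run`, `converged`, and
#'   `size_history` (sampled-set size before and after every iteration).
#' @export
tri_transfer_fit <- function(source, target_train, config = tri_config(),
                             label_col = "label") {
  source <- as_table(source, label_col)
  target_train <- as_table(target_train, label_col)
  check_compatible(source, target_train)
  N <- config$max_iterations
  idx <- seq_len(n_samples(source))
  converged <- FALSE
  iter <- 0L
  triple <- NULL
  size_history <- length(idx)
  repeat {
    iter <- iter + 1L
    pool <- bind_tables(subset_table(source, idx), target_train)
    triple <- fit_triple(pool, configs = iteration_configs(config, iter))
    keep <- agreement_mask(triple, subset_table(source, idx),
                           mode = config$agreement_mode)
    new_idx <- idx[keep]
    size_history <- c(size_history, length(new_idx))
    log_info("tri-transfer iteration %d: sampled %d/%d source rows",
             iter, length(new_idx), length(idx))
    if (length(new_idx) == 0L) {
      warn("sampled source set became empty; refitting on target data alone")
      triple <- fit_triple(target_train,
                           configs = iteration_configs(config, iter + 1L))
      idx <- integer(0)
      converged <- TRUE
      break
    }
    if (identical(new_idx, idx)) {
      converged <- TRUE
      break
    }
    idx <- new_idx
    if (iter == N) break
  }
  structure(list(triple = triple, sampled_idx = idx,
                 sampled_source = if (length(idx)) subset_table(source, idx),
                 iterations_run = iter, converged = converged,
                 size_history = size_history,
                 agreement_mode = config$agreement_mode),
            class = "source_model")
}

#' Per-source ensemble prediction
#'
#' The per-source classifier is the equal-weight multi-view ensemble of the
#' three members: the arithmetic mean of their probability outputs.
#'
#' @param model a `source_model` (or bare `triple_classifier`).
#' @param X numeric feature matrix.
#' @return `n x K` probability matrix; rows sum to 1.
#' @export
source_model_predict <- function(model, X) {
  triple <- if (inherits(model, "triple_classifier")) model else model$triple
  Ps <- predict_proba(triple, X)
  # offset form of the mean: exact when the members coincide
  Ps[[1L]] + ((Ps[[2L]] - Ps[[1L]]) + (Ps[[3L]] - Ps[[1L]])) / 3
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf(
    "<source_model> %d sampled source rows, %d iterations, converged=%s\n",
    length(x$sampled_idx), x$iterations_run, x$converged))
  invisible(x)
}

# product-Gaussian kernel density with per-dimension Scott bandwidths,
# evaluated in the triple's standardized feature space
kde_gauss <- function(train, eval_points) {
  n <- nrow(train); d <- ncol(train)
  h <- n^(-1 / (d + 4)) * apply(train, 2L, sd)
  h[h == 0 | !is.finite(h)] <- 1
  vapply(seq_len(nrow(eval_points)), function(i) {
    z <- sweep(sweep(train, 2L, eval_points[i, ]), 2L, h, "/")
    mean(exp(rowSums(dnorm(z, log = TRUE))) / prod(h))
  }, numeric(1))
}

#' Per-sample transferability diagnostic
#'
#' For each source row, `alpha` is +1 when the three members agree on its
#' predicted label and -1 otherwise; the target density at the row is
#' estimated by a Gaussian product-kernel density (Scott-type per-dimension
#' bandwidth) over the standardized target training features; and the
#' transferability score is `beta = exp(alpha * density)`. The score is a
#' diagnostic — it does not gate the sampling loop.
#'
#' @param model a fitted `source_model`.
#' @param source the original source `labeled_table` (or data frame).
#' @param target_train labeled target training data with at least 2 rows.
#' @param label_col label column for data-frame inputs.
#' @return A tibble with one row per source sample: `alpha`,
#'   `density_at_sample`, `beta`.
#' @export
transferability <- function(model, source, target_train, label_col = "label") {
  source <- as_table(source, label_col)
  target_train <- as_table(target_train, label_col)
  if (n_samples(target_train) < 2L)
    abort("density estimation needs at least 2 target samples",
          class = "metl_density_error")
  triple <- model$triple
  agree <- agreement_mask(triple, source, mode = "classifiers_only")
  alpha <- ifelse(agree, 1, -1)
  Zt <- scale_features(target_train$features, triple$scaler)
  Zs <- scale_features(check_X(triple, source$features), triple$scaler)
  dens <- kde_gauss(Zt, Zs)
  tibble::tibble(alpha = alpha, density_at_sample = dens,
                 beta = exp(alpha * dens))
}
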