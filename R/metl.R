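#' METL configuration
#'
#' Bundles the Phase 1 (tri-transfer) and Phase 2 (MI weighting)
#' configurations; all child seeds are derived deterministically from
#' `master_seed`.
#'
#' @param tri a [tri_config()]; `NULL` for defaults.
#' @param mi an [mi_config()]; `NULL` for defaults.
#' @param master_seed integer master seed.
#' @return A `metl_config` object.
#' @export
metl_config <- function(tri = NULL, mi = NULL, master_seed = 1L) {
  structure(list(tri = tri %||% tri_config(seed = child_seed(master_seed, 11L)),
                 mi = mi %||% mi_config(seed = child_seed(master_seed, 12L)),
                 master_seed = as.integer(master_seed)),
            class = "metl_config")
}

#' Fit a multi-source ensemble transfer model
#'
#' Runs the full two-phase procedure: per source domain, the tri-transfer
#' loop samples transferable instances and yields a three-member ensemble
#' classifier; then each source receives a raw weight equal to the mutual
#' information between its converged sampled set and the labeled target
#' training data, and the weights are normalized onto the simplex. Sources
#' whose sampled set empties get raw weight 0; if every sampled set empties,
#' the model degrades to uniformly weighted target-only ensembles with a
#' warning.
#'
#' @param target_train labeled target training data: data frame,
#'   `labeled_table` or `domain_set`.
#' @param sources list of source domains (same types); `m >= 1`.
#' @param config a [metl_config()].
#' @param label_col label column for data-frame inputs.
#' @param weighting `"mi"` (default) or `"equal"` (the equal-weight
#'   baseline: every source gets raw weight 1).
#' @return A `metl_model` with elements `source_models`, `weights`
#'   (a `weight_vector`), `label_names`, `feature_names`.
#' @export
metl_fit <- function(target_train, sources, config = metl_config(),
                     label_col = "label", weighting = c("mi", "equal")) {
  weighting <- match.arg(weighting)
  target_train <- as_table(target_train, label_col)
  if (inherits(sources, "domain_set") || inherits(sources, "labeled_table") ||
      is.data.frame(sources))
    sources <- list(sources)
  if (length(sources) < 1L)
    abort("need at least one source domain", class = "metl_validation_error")
  sources <- lapply(sources, function(s)
    as_labeled_table_like(s, label_col, target_train$label_names))
  for (s in sources) check_compatible(s, target_train)
  m <- length(sources)
  # the same tri seed is used for every source: weights are then exactly
  # permutation-equivariant and twin sources get identical models
  source_models <- purrr::imap(sources, function(src, i) {
    log_info("fitting source domain %d/%d (n=%d)", i, m, n_samples(src))
    tri_transfer_fit(src, target_train, config = config$tri)
  })
  raw <- if (weighting == "equal") {
    rep(1, m)
  } else {
    purrr::map_dbl(source_models, function(sm) {
      if (length(sm$sampled_idx) == 0L) return(0)
      cfg <- config$mi
      domain_mi(sm$sampled_source, target_train, config = cfg)
    })
  }
  if (all(vapply(source_models, function(sm) length(sm$sampled_idx) == 0L,
                 logical(1))))
    warn(paste("every sampled source set is empty: model degrades to",
               "uniformly weighted target-only ensembles"))
  weights <- suppressWarnings(normalize_weights(raw))
  if (sum(raw) == 0) weights <- normalize_weights(rep(1, m))
  log_info("normalized source weights: %s",
           paste(signif(weights$normalized, 4), collapse = " "))
  structure(list(source_models = source_models, weights = weights,
                 label_names = target_train$label_names,
                 feature_names = target_train$feature_names,
                 K = length(target_train$label_names),
                 d = length(target_train$feature_names),
                 weighting = weighting, config = config),
            class = "metl_model")
}

# coerce to labeled_table with a forced shared label encoding
as_labeled_table_like <- function(x, label_col, label_names) {
  if (is.data.frame(x)) return(as_labeled_table(x, label_col, label_names))
  as_table(x, label_col)
}

#' Predict from a fitted METL model
#'
#' The final classifier is the weighted probability mixture of the
#' per-source ensembles, `f*(x) = sum_i w_i* f_i(x)`; predicted labels are
#' the argmax with ties broken toward the smallest class code.
#'
#' @param model a fitted `metl_model`.
#' @param X numeric feature matrix (or data frame of the feature columns).
#' @return List with `labels` (integer codes `0..K-1`) and `proba`
#'   (`n x K` matrix; rows sum to 1).
#' @export
metl_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    abort(sprintf("expected %d feature columns, got %d", model$d, ncol(X)),
          class = "metl_shape_error")
  w <- model$weights$normalized
  proba <- matrix(0, nrow(X), model$K)
  for (i in seq_along(model$source_models)) {
    if (w[i] == 0) next
    proba <- proba + w[i] * source_model_predict(model$source_models[[i]], X)
  }
  colnames(proba) <- model$label_names
  list(labels = prob_argmax(proba), proba = proba)
}

#' @export
#' @rdname metl_predict
#' @param object a fitted `metl_model`.
#' @param new_data data frame or matrix of feature columns (any label column
#'   is ignored).
#' @param ... unused.
predict.metl_model <- function(object, new_data, ...) {
  if (is.data.frame(new_data))
    new_data <- new_data[intersect(names(new_data), object$feature_names)]
  pr <- metl_predict(object, as.matrix(new_data))
  out <- tibble::as_tibble(as.data.frame(pr$proba, check.names = FALSE))
  names(out) <- paste0(".pred_", object$label_names)
  dplyr::bind_cols(
    tibble::tibble(.pred_class = object$label_names[pr$labels + 1L]), out)
}

#' @export
print.metl_model <- function(x, ...) {
  cat(sprintf("<metl_model> %d source domain(s), %d classes, %d features\n",
              length(x$source_models), x$K, x$d))
  cat("  weighting:", x$weighting, "\n  normalized weights:",
      paste(signif(x$weights$normalized, 4), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-source summary of a fitted METL model
#'
#' @param x a `metl_model`.
#' @param ... unused.
#' @return A tibble with one row per source domain: raw and normalized
#'   weight, sampled-set size, iterations and convergence flag.
#' @exportS3Method generics::tidy
tidy.metl_model <- function(x, ...) {
  tibble::tibble(
    source = seq_along(x$source_models),
    raw_weight = x$weights$raw,
    weight = x$weights$normalized,
    n_sampled = vapply(x$source_models, function(s) length(s$sampled_idx),
                       integer(1)),
    iterations = vapply(x$source_models, `[[`, integer(1), "iterations_run"),
    converged = vapply(x$source_models, `[[`, logical(1), "converged"))
}

#' One-row summary of a fitted METL model
#'
#' @param x a `metl_model`.
#' @param ... unused.
#' @return A one-row tibble: number of sources, classes, features, total
#'   sampled rows, weighting scheme.
#' @exportS3Method generics::glance
glance.metl_model <- function(x, ...) {
  tibble::tibble(
    n_sources = length(x$source_models),
    n_classes = x$K, n_features = x$d,
    n_sampled_total = sum(vapply(x$source_models,
                                 function(s) length(s$sampled_idx),
                                 integer(1))),
    weighting = x$weighting)
}

#' Save a fitted METL model archive
#'
#' Writes a directory with a JSON manifest (label encoding, per-source
#' weights, sampled-row indices, per-triple standardization statistics) plus
#' the serialized classifier objects.
#'
#' @param model a `metl_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_metl <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "metl", format = 1L,
    label_names = model$label_names, feature_names = model$feature_names,
    weighting = model$weighting,
    weights = list(raw = model$weights$raw,
                   normalized = model$weights$normalized),
    sources = lapply(model$source_models, function(s) list(
      n_sampled = length(s$sampled_idx),
      sampled_idx = s$sampled_idx,
      iterations_run = s$iterations_run, converged = s$converged,
      member_kinds = vapply(s$triple$members, `[[`, character(1), "kind"),
      scaler = s$triple$scaler)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"), version = 2)
  invisible(dir)
}

#' Load a METL model archive
#'
#' @param dir directory written by [save_metl()].
#' @return The `metl_model`.
#' @export
load_metl <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("no manifest.json under %s", dir))
  manifest <- jsonlite::read_json(mf)
  model <- readRDS(file.path(dir, "model.rds"))
  if (!identical(unlist(manifest$label_names), model$label_names))
    abort("manifest/model label encoding mismatch")
  model
}
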