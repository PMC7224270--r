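#' Synthetic domain-shift specification
#'
#' Defines a family of domains over a shared label space: class-conditional
#' Gaussians with identity within-class covariance (so all distances are in
#' within-class-sd units), where each domain's class means are translated by
#' its shift magnitude along a seeded random direction. This emulates the
#' structure of multi-domain tabular clinical data — related sources are
#' mildly shifted versions of the target, unrelated sources are strongly
#' shifted and/or label-noised.
#'
#' Defaults describe the canonical test family: 300 samples per domain, 6
#' features, 2 classes separated by 3 sd, three sources at mild shifts
#' (0.5, 1, 1.5 sd) plus the target (last, shift 0), no label noise, no
#' imbalance.
#'
#' @param n_per_domain samples per domain.
#' @param d feature dimension (must be `>= K`).
#' @param K number of classes.
#' @param class_separation distance between class mean vectors, in
#'   within-class-sd units.
#' @param domain_shifts per-domain mean-shift magnitudes (sd units); the
#'   target is listed last and must have shift 0.
#' @param label_flip_fractions per-domain fraction of rows relabeled
#'   uniformly to another class.
#' @param imbalance_ratio majority:minority class-count ratio `>= 1`,
#'   applied by downsampling the non-majority classes.
#' @param seed integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_per_domain = 300L, d = 6L, K = 2L,
                           class_separation = 3,
                           domain_shifts = c(0.5, 1, 1.5, 0),
                           label_flip_fractions = rep(0, length(domain_shifts)),
                           imbalance_ratio = 1, seed = 1L) {
  if (d < 2L) abort("d must be >= 2")
  if (d < K) abort("d must be >= K (class means live on distinct axes)")
  if (length(label_flip_fractions) != length(domain_shifts))
    abort("label_flip_fractions and domain_shifts must have equal length")
  if (utils::tail(domain_shifts, 1L) != 0)
    abort("the target domain (listed last) must have shift 0")
  if (imbalance_ratio < 1) abort("imbalance_ratio must be >= 1")
  structure(list(n_per_domain = as.integer(n_per_domain), d = as.integer(d),
                 K = as.integer(K), class_separation = class_separation,
                 domain_shifts = domain_shifts,
                 label_flip_fractions = label_flip_fractions,
                 imbalance_ratio = imbalance_ratio, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic domains
#'
#' Draws every domain of the spec. Class `k`'s mean is
#' `class_separation/sqrt(2)` along coordinate axis `k` (pairwise mean
#' distance = `class_separation`); domain `j` adds `shift_j` times a seeded
#' random unit vector to all its class means; label flips relabel a seeded
#' subset of rows uniformly to another class; imbalance downsamples the
#' non-majority classes (class 0 is the majority).
#'
#' @param spec a [synthetic_spec()].
#' @return List of `domain_set`s: sources first, the target last.
#' @export
generate_domains <- function(spec) {
  m1 <- length(spec$domain_shifts)
  label_names <- paste0("c", seq_len(spec$K) - 1L)
  mu <- matrix(0, spec$K, spec$d)
  for (k in seq_len(spec$K))
    mu[k, k] <- spec$class_separation / sqrt(2)
  # class counts: class 0 is the majority; counts are allocated so that
  # majority:minority = imbalance_ratio while the domain keeps n samples
  class_w <- c(spec$imbalance_ratio, rep(1, spec$K - 1L))
  exact <- spec$n_per_domain * class_w / sum(class_w)
  counts0 <- floor(exact)
  rem_ord <- order(exact - counts0, decreasing = TRUE)
  short <- spec$n_per_domain - sum(counts0)
  if (short > 0)
    counts0[rem_ord[seq_len(short)]] <- counts0[rem_ord[seq_len(short)]] + 1L
  if (any(counts0 < 1))
    abort("imbalance_ratio too large: minority class would be empty",
          class = "metl_validation_error")
  with_seed(spec$seed, {
    domains <- lapply(seq_len(m1), function(j) {
      u <- rnorm(spec$d); u <- u / sqrt(sum(u^2))
      counts <- counts0
      y <- rep(seq_len(spec$K) - 1L, counts)
      n <- length(y)
      X <- mu[y + 1L, , drop = FALSE] +
        matrix(spec$domain_shifts[j] * u, n, spec$d, byrow = TRUE) +
        matrix(rnorm(n * spec$d), n, spec$d)
      fl <- spec$label_flip_fractions[j]
      if (fl > 0) {
        flip <- sample_from(seq_len(n), round(fl * n))
        # shift by 1..K-1 mod K: uniform over the other classes
        y[flip] <- (y[flip] + sample(spec$K - 1L, length(flip),
                                     replace = TRUE)) %% spec$K
      }
      colnames(X) <- paste0("x", seq_len(spec$d))
      tab <- labeled_table(X, y, label_names)
      domain_set(tab, role = if (j == m1) "target" else "source", index = j)
    })
  })
  domains
}

#' Split one table into domains by K-means on a single attribute
#'
#' One-dimensional K-means on the chosen numeric column partitions the rows
#' into `k` clusters with different distributions of that attribute; each
#' cluster becomes one domain. Initial centers sit at the attribute's
#' evenly spaced quantiles, and clusters are ordered by ascending center.
#'
#' @param table a `labeled_table` or data frame.
#' @param attribute name of a numeric feature column with at least `k`
#'   distinct values.
#' @param k number of clusters/domains (default 4).
#' @param seed integer seed.
#' @param target_domain which cluster (1-based, in ascending-center order)
#'   becomes the target; the rest are sources.
#' @param label_col label column for data-frame input.
#' @return List of `domain_set`s, sources first, the target last.
#' @export
kmeans_split <- function(table, attribute, k = 4L, seed = 1L,
                         target_domain = 1L, label_col = "label") {
  table <- as_table(table, label_col)
  if (!attribute %in% table$feature_names)
    abort(sprintf("attribute '%s' is not a feature column", attribute),
          class = "metl_validation_error")
  x <- table$features[, attribute]
  if (length(unique(x)) < k)
    abort(sprintf("attribute '%s' has fewer than %d distinct values",
                  attribute, k),
          class = "metl_validation_error")
  if (k == 1L)   # degenerate split: the whole table is the target domain
    return(list(domain_set(table, "target", 1L)))
  fit <- with_seed(seed, {
    centers <- quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE)
    if (anyDuplicated(centers)) {   # heavy ties: spread over distinct values
      uq <- sort(unique(x))
      centers <- uq[round(seq(1, length(uq), length.out = k))]
    }
    kmeans(matrix(x, ncol = 1L), centers = matrix(centers, ncol = 1L),
           iter.max = 300L)
  })
  ord <- order(fit$centers[, 1L])
  cluster_rank <- match(fit$cluster, ord)
  if (target_domain < 1L || target_domain > k)
    abort("target_domain out of range")
  parts <- lapply(seq_len(k), function(r)
    subset_table(table, which(cluster_rank == r)))
  src_ranks <- setdiff(seq_len(k), target_domain)
  out <- c(lapply(seq_along(src_ranks), function(i)
    domain_set(parts[[src_ranks[i]]], "source", i)),
    list(domain_set(parts[[target_domain]], "target", k)))
  out
}

#' SMOTE class balancing
#'
#' Oversamples every minority class up to the majority count: each synthetic
#' row is a uniform-random point on the segment between a minority row and
#' one of its `k_neighbors` nearest minority neighbors (Euclidean, within
#' class). Majority rows are never changed; a single-sample minority class
#' is duplicated with a small jitter (with a warning). Apply only to
#' training pools.
#'
#' @param train a `labeled_table` or data frame.
#' @param k_neighbors neighborhood size (default 5).
#' @param seed integer seed.
#' @param label_col label column for data-frame input.
#' @return A `labeled_table` with equal class counts (original rows first).
#' @export
smote_balance <- function(train, k_neighbors = 5L, seed = 1L,
                          label_col = "label") {
  train <- as_table(train, label_col)
  K <- length(train$label_names)
  counts <- tabulate(train$labels + 1L, K)
  if (sum(counts > 0) < 2L)
    abort("need at least two classes", class = "metl_validation_error")
  n_max <- max(counts)
  if (all(counts == n_max)) return(train)
  new_feats <- list(); new_labs <- list()
  with_seed(seed, {
    for (k in which(counts < n_max & counts > 0)) {
      M <- train$features[train$labels == k - 1L, , drop = FALSE]
      nm <- nrow(M)
      need <- n_max - nm
      if (nm == 1L) {
        warn(sprintf("class '%s' has a single sample: duplicating with jitter",
                     train$label_names[k]))
        syn <- matrix(rep(M[1L, ], need), need, ncol(M), byrow = TRUE) +
          matrix(rnorm(need * ncol(M), sd = 1e-6), need)
      } else {
        kk <- min(k_neighbors, nm - 1L)
        D <- as.matrix(dist(M))
        diag(D) <- Inf
        ord <- apply(D, 1L, function(r) order(r)[seq_len(kk)])
        nn <- if (kk == 1L) matrix(ord, ncol = 1L) else t(ord)
        base <- sample(nm, need, replace = TRUE)
        nbr <- nn[cbind(base, sample(kk, need, replace = TRUE))]
        lam <- runif(need)
        syn <- M[base, , drop = FALSE] +
          lam * (M[nbr, , drop = FALSE] - M[base, , drop = FALSE])
      }
      new_feats[[length(new_feats) + 1L]] <- syn
      new_labs[[length(new_labs) + 1L]] <- rep(k - 1L, need)
    }
  })
  labeled_table(rbind(train$features, do.call(rbind, new_feats)),
                c(train$labels, unlist(new_labs)),
                train$label_names, train$feature_names)
}

#' Target-only baseline
#'
#' The zero-source reference: the three heterogeneous classifiers fitted on
#' the labeled target training data alone and averaged. Returned as a
#' `metl_model` so downstream code is uniform.
#'
#' @param target_train labeled target training data.
#' @param config a [metl_config()].
#' @param label_col label column for data-frame input.
#' @return A `metl_model` with one target-only member and weight 1.
#' @export
baseline_target_only <- function(target_train, config = metl_config(),
                                 label_col = "label") {
  target_train <- as_table(target_train, label_col)
  triple <- fit_triple(target_train,
                       configs = iteration_configs(config$tri, 1L))
  sm <- structure(list(triple = triple, sampled_idx = integer(0),
                       sampled_source = NULL, iterations_run = 0L,
                       converged = TRUE,
                       agreement_mode = config$tri$agreement_mode),
                  class = "source_model")
  structure(list(source_models = list(sm), weights = normalize_weights(1),
                 label_names = target_train$label_names,
                 feature_names = target_train$feature_names,
                 K = length(target_train$label_names),
                 d = length(target_train$feature_names),
                 weighting = "target_only", config = config),
            class = "metl_model")
}

#' Equal-weight ensemble baseline
#'
#' Identical to [metl_fit()] except that every source receives raw weight 1
#' (normalized `1/m`) instead of its mutual-information weight.
#'
#' @inheritParams metl_fit
#' @return A `metl_model`.
#' @export
baseline_equal_weight <- function(target_train, sources,
                                  config = metl_config(),
                                  label_col = "label") {
  metl_fit(target_train, sources, config = config, label_col = label_col,
           weighting = "equal")
}

fit_protocol_method <- function(method, srcs, train, config) {
  if (method == "target_only" || length(srcs) == 0L)
    baseline_target_only(train, config = config)
  else if (method == "equal")
    baseline_equal_weight(train, srcs, config = config)
  else
    metl_fit(train, srcs, config = config)
}

#' Repeated-evaluation benchmark protocol
#'
#' For every (method, label ratio, source count) cell: the target domain is
#' freshly re-split per repeat (a `test_fraction` stratified test set; a
#' `label_ratio` share of the remainder as labeled training data), the
#' method is fitted with the first `n` source domains, and accuracy is
#' scored on the held-out target test set. Cells whose fit fails are marked
#' missing and the run continues.
#'
#' @param domains list of `domain_set`s (the target is the element with role
#'   `"target"`, else the last).
#' @param methods subset of `"metl"`, `"equal"`, `"target_only"`.
#' @param label_ratios labeled fractions of the non-test target data.
#' @param n_sources_grid integer vector of source-domain counts (default:
#'   all available sources).
#' @param repeats repeats per cell, fresh stratified resplit each time
#'   (default 10).
#' @param test_fraction held-out target fraction (default 0.7).
#' @param seed master seed; every repeat consumes a derived child seed.
#' @param max_iterations Phase 1 iteration cap passed to [tri_config()].
#' @return A `protocol_result` tibble: `method`, `label_ratio`, `n_sources`,
#'   `mean_accuracy`, `sd`, `repeats`; per-repeat accuracies are kept in
#'   `attr(, "runs")`.
#' @export
run_protocol <- function(domains, methods = c("metl", "equal", "target_only"),
                         label_ratios = c(0.03, 0.1, 0.3),
                         n_sources_grid = NULL, repeats = 10L,
                         test_fraction = 0.7, seed = 1L,
                         max_iterations = 20L) {
  methods <- match.arg(methods, several.ok = TRUE)
  roles <- vapply(domains, function(d)
    if (inherits(d, "domain_set")) d$role else "source", character(1))
  t_idx <- if (any(roles == "target")) which(roles == "target")[1L]
           else length(domains)
  target <- as_table(domains[[t_idx]])
  sources <- lapply(domains[-t_idx], as_table)
  n_sources_grid <- n_sources_grid %||% length(sources)
  if (max(n_sources_grid) > length(sources))
    abort("not enough source domains for n_sources_grid")
  grid <- tidyr::expand_grid(method = methods, label_ratio = label_ratios,
                             n_sources = as.integer(n_sources_grid))
  cell_runs <- purrr::pmap(grid, function(method, label_ratio, n_sources) {
    acc <- vapply(seq_len(repeats), function(r) {
      cell_seed <- child_seed(seed, r * 131L +
                                match(method, c("metl", "equal", "target_only")))
      tryCatch({
        sp <- split_target(target, test_fraction = test_fraction,
                           label_ratio = label_ratio, seed = cell_seed)
        cfg <- metl_config(
          tri = tri_config(max_iterations = max_iterations,
                           seed = child_seed(cell_seed, 21L)),
          mi = mi_config(seed = child_seed(cell_seed, 22L)),
          master_seed = cell_seed)
        fit <- fit_protocol_method(method, sources[seq_len(n_sources)],
                                   sp$train, cfg)
        pr <- metl_predict(fit, sp$test$features)
        mean(pr$labels == sp$test$labels)
      }, error = function(e) {
        warn(sprintf("protocol cell failed (%s, %.2f, %d, repeat %d): %s",
                     method, label_ratio, n_sources, r,
                     conditionMessage(e)))
        NA_real_
      })
    }, numeric(1))
    acc
  })
  runs <- dplyr::mutate(grid[rep(seq_len(nrow(grid)), each = repeats), ],
                        repeat_id = rep(seq_len(repeats), nrow(grid)),
                        accuracy = unlist(cell_runs))
  out <- dplyr::summarise(
    dplyr::group_by(runs, .data$method, .data$label_ratio, .data$n_sources),
    mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
    sd = stats::sd(.data$accuracy, na.rm = TRUE),
    repeats = sum(!is.na(.data$accuracy)), .groups = "drop")
  structure(out, runs = tibble::as_tibble(runs),
            class = c("protocol_result", class(out)))
}

#' Plot a protocol result
#'
#' Mean accuracy (with one-sd error bars) against the number of source
#' domains, one panel per label ratio, colored by method.
#'
#' @param object a `protocol_result` from [run_protocol()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.protocol_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_sources,
                                   y = .data$mean_accuracy,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd,
      ymax = .data$mean_accuracy + .data$sd)) +
    ggplot2::facet_wrap(~label_ratio, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "number of source domains", y = "target-test accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
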