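#' Mutual-information estimation configuration
#'
#' Mutual information between domains is estimated on discretized features:
#' per-column bin edges are computed on a reference matrix (the pooled
#' sampled source and target data) and applied everywhere, so source and
#' target share one code book.
#'
#' @param bins number of bins per feature column (default 8).
#' @param binning `"equal_frequency"` (quantile edges, default) or
#'   `"equal_width"`.
#' @param log_base 2 (bits, default) or `exp(1)` (nats).
#' @param max_pairs cap on sample pairs per domain-MI evaluation; beyond it,
#'   pairs are subsampled uniformly under `seed`.
#' @param seed integer seed for pair subsampling.
#' @return An `mi_config` object.
#' @export
mi_config <- function(bins = 8L, binning = c("equal_frequency", "equal_width"),
                      log_base = 2, max_pairs = 10000L, seed = 1L) {
  if (bins < 2L) abort("bins must be >= 2")
  if (max_pairs < 1L) abort("max_pairs must be >= 1")
  structure(list(bins = as.integer(bins), binning = match.arg(binning),
                 log_base = log_base, max_pairs = as.integer(max_pairs),
                 seed = as.integer(seed)),
            class = "mi_config")
}

#' Discretize features against a reference
#'
#' Bin edges are computed per column on `reference` and applied to `values`;
#' values outside the reference range clamp to the outer bins. Columns that
#' are constant in the reference collapse to a single bin.
#'
#' @param values numeric matrix to encode.
#' @param config an [mi_config()].
#' @param reference numeric matrix the edges are computed on (defaults to
#'   `values`).
#' @return Integer code matrix with entries in `0..bins-1`.
#' @export
discretize <- function(values, config = mi_config(), reference = values) {
  values <- as.matrix(values); reference <- as.matrix(reference)
  if (nrow(reference) == 0L) abort("reference must be nonempty")
  if (ncol(values) != ncol(reference))
    abort("values and reference must have the same column count",
          class = "metl_shape_error")
  B <- config$bins
  codes <- vapply(seq_len(ncol(values)), function(j) {
    ref <- reference[, j]
    if (length(unique(ref)) == 1L) {
      log_info("column %d constant in reference: single bin", j)
      return(rep(0L, nrow(values)))
    }
    edges <- if (config$binning == "equal_frequency") {
      unique(quantile(ref, probs = seq_len(B - 1L) / B, names = FALSE))
    } else {
      seq(min(ref), max(ref), length.out = B + 1L)[-c(1L, B + 1L)]
    }
    findInterval(values[, j], unique(edges))
  }, integer(nrow(values)))
  matrix(as.integer(codes), nrow = nrow(values))
}

#' Mutual information of two discrete code vectors
#'
#' The plug-in estimate `sum_xy p(x,y) log[p(x,y)/(p(x)p(y))]` with empirical
#' frequencies and the convention `0 log 0 = 0`.
#'
#' @param a,b equal-length integer code vectors.
#' @param log_base 2 for bits (default), `exp(1)` for nats.
#' @return Nonnegative scalar.
#' @export
mi_discrete <- function(a, b, log_base = 2) {
  if (length(a) != length(b))
    abort("code vectors must have equal length", class = "metl_shape_error")
  if (length(a) == 0L) abort("code vectors must be nonempty")
  joint <- table(a, b) / length(a)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  sum(terms[joint > 0]) / log(log_base)
}

#' Mutual information between two individual samples
#'
#' The two samples' `d` discretized feature codes are treated as `d` paired
#' draws of two discrete variables and fed to [mi_discrete()].
#'
#' @param x_source,x_target integer code vectors of length `d >= 2`.
#' @param config an [mi_config()] (supplies the log base).
#' @return Nonnegative scalar.
#' @export
pair_mi <- function(x_source, x_target, config = mi_config()) {
  if (length(x_source) < 2L)
    abort("per-sample MI needs at least 2 features",
          class = "metl_validation_error")
  mi_discrete(x_source, x_target, log_base = config$log_base)
}

#' Mutual information between a sampled source domain and the target
#'
#' The mean of [pair_mi()] over all source x target sample pairs, or over
#' `max_pairs` uniformly subsampled pairs when the full product exceeds the
#' cap. Only labeled target *training* rows may be passed here — never test
#' rows.
#'
#' With `reference = "target"` (default) the bin edges are computed on the
#' target training features alone, so the code book is anchored on the
#' target distribution: samples from far-shifted sources clamp into the
#' outer bins, their code entropy collapses, and their pair MI is capped
#' low — which is what makes the MI weight favor related sources.
#' `reference = "pooled"` computes edges on the pooled source and target
#' features; it is symmetric in the two domains but insensitive to
#' covariate shift.
#'
#' @param sampled_source converged sampled source `labeled_table` (or data
#'   frame); may be `NULL`/empty, giving MI 0 with a warning.
#' @param target_train labeled target training `labeled_table`.
#' @param config an [mi_config()].
#' @param reference `"target"` (default) or `"pooled"`; see Details.
#' @param label_col label column for data-frame inputs.
#' @return Nonnegative scalar.
#' @export
domain_mi <- function(sampled_source, target_train, config = mi_config(),
                      reference = c("target", "pooled"),
                      label_col = "label") {
  reference <- match.arg(reference)
  if (is.null(sampled_source)) {
    warn("empty sampled source: domain MI is 0")
    return(0)
  }
  sampled_source <- as_table(sampled_source, label_col)
  target_train <- as_table(target_train, label_col)
  ns <- n_samples(sampled_source); nt <- n_samples(target_train)
  ref <- if (reference == "target") target_train$features
         else rbind(sampled_source$features, target_train$features)
  cs <- discretize(sampled_source$features, config, reference = ref)
  ct <- discretize(target_train$features, config, reference = ref)
  total <- as.double(ns) * nt
  if (total <= config$max_pairs) {
    si <- rep(seq_len(ns), times = nt)
    ti <- rep(seq_len(nt), each = ns)
  } else {
    pick <- with_seed(config$seed, sample.int(total, config$max_pairs))
    si <- ((pick - 1) %% ns) + 1
    ti <- ((pick - 1) %/% ns) + 1
  }
  vals <- vapply(seq_along(si), function(k)
    mi_discrete(cs[si[k], ], ct[ti[k], ], log_base = config$log_base),
    numeric(1))
  mean(vals)
}

#' Normalize source weights onto the simplex
#'
#' `w_i* = w_i / sum_k w_k`; all-zero input falls back to uniform weights
#' with a warning.
#'
#' @param raw nonnegative numeric vector of raw weights.
#' @return A `weight_vector`: list with `raw` and `normalized` (sums to 1).
#' @export
normalize_weights <- function(raw) {
  if (length(raw) < 1L) abort("need at least one weight")
  if (any(raw < 0)) abort("raw weights must be nonnegative")
  s <- sum(raw)
  normalized <- if (s == 0) {
    warn("all raw weights are zero: falling back to uniform weights")
    rep(1 / length(raw), length(raw))
  } else raw / s
  structure(list(raw = raw, normalized = normalized),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n  raw:       ",
      paste(signif(x$raw, 4), collapse = " "), "\n  normalized:",
      paste(signif(x$normalized, 4), collapse = " "), "\n")
  invisible(x)
}
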