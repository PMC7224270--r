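test_that("unshifted domains are statistically indistinguishable", {
  spec <- synthetic_spec(n_per_domain = 300, domain_shifts = c(0, 0),
                         seed = 31)
  doms <- generate_domains(spec)
  a <- doms[[1]]$data$features
  b <- doms[[2]]$data$features
  # per-feature z statistic for the difference of means; with shift 0 every
  # |z| should stay below the 4-sigma band
  z <- (colMeans(a) - colMeans(b)) / sqrt(2 / nrow(a))
  expect_true(all(abs(z) < 4))
})

test_that("shifted domains are separated and flips invert the concept", {
  spec <- synthetic_spec(domain_shifts = c(3, 0), seed = 32)
  doms <- generate_domains(spec)
  gap <- sqrt(sum((colMeans(doms[[1]]$data$features) -
                   colMeans(doms[[2]]$data$features))^2))
  expect_gt(gap, 2)
  expect_lt(gap, 4)

  spec_f <- synthetic_spec(class_separation = 6, domain_shifts = c(0, 0),
                           label_flip_fractions = c(1, 0), seed = 33)
  df <- generate_domains(spec_f)
  clean <- df[[2]]$data
  flipped <- df[[1]]$data
  centro <- sapply(0:1, function(k)
    colMeans(clean$features[clean$labels == k, , drop = FALSE]))
  pred <- apply(flipped$features, 1, function(r)
    which.min(colSums((centro - r)^2)) - 1L)
  expect_lte(mean(pred == flipped$labels), 0.05)
})

test_that("imbalance allocates majority:minority at the stated ratio", {
  spec <- synthetic_spec(n_per_domain = 500, domain_shifts = c(0, 0),
                         imbalance_ratio = 4, seed = 34)
  doms <- generate_domains(spec)
  counts <- tabulate(doms[[1]]$data$labels + 1L, 2)
  expect_equal(counts, c(400L, 100L))
  expect_error(synthetic_spec(imbalance_ratio = 0.5))
  expect_error(generate_domains(
    synthetic_spec(n_per_domain = 10, domain_shifts = c(0, 0),
                   imbalance_ratio = 50)),
    class = "metl_validation_error")
})

test_that("generation is seed-reproducible", {
  s <- synthetic_spec(seed = 35)
  expect_identical(generate_domains(s), generate_domains(s))
})

test_that("kmeans_split partitions well-separated attribute values", {
  X <- cbind(a = c(1, 1, 2, 2, 10, 10, 20, 20), b = rnorm(8))
  lt <- labeled_table(X, rep(0:1, 4), c("n", "y"))
  doms <- kmeans_split(lt, "a", k = 4, seed = 2, target_domain = 1)
  expect_length(doms, 4)
  vals <- lapply(doms, function(d) sort(unique(d$data$features[, "a"])))
  expect_true(all(lengths(vals) == 1))
  expect_equal(vapply(doms, function(d) d$role, character(1)),
               c(rep("source", 3), "target"))

  single <- kmeans_split(lt, "a", k = 1, seed = 2)
  expect_length(single, 1)
  expect_equal(nrow(single[[1]]$data$features), 8)

  const <- labeled_table(cbind(a = rep(1, 8), b = rnorm(8)),
                         rep(0:1, 4), c("n", "y"))
  expect_error(kmeans_split(const, "a", k = 4),
               class = "metl_validation_error")
})

test_that("smote balances classes by convex interpolation", {
  withr::with_seed(36, {
    X <- matrix(rnorm(50), 25, 2)
    y <- rep(c(0L, 1L), c(20L, 5L))
    colnames(X) <- c("x1", "x2")
  })
  lt <- labeled_table(X, y, c("maj", "min"))
  out <- smote_balance(lt, seed = 4)
  expect_equal(tabulate(out$labels + 1L, 2), c(20L, 20L))
  # original rows first and untouched
  expect_identical(out$features[1:25, ], lt$features)
  # synthetic rows stay inside the minority bounding box
  minority <- lt$features[lt$labels == 1L, ]
  syn <- out$features[26:40, ]
  for (j in 1:2) {
    expect_true(all(syn[, j] >= min(minority[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(minority[, j]) + 1e-12))
  }
  # balanced input passes through unchanged
  bal <- make_blobs(n = 40, seed = 37)
  expect_identical(smote_balance(bal, seed = 5), bal)
  # single-sample minority duplicates with jitter
  lt1 <- labeled_table(X[1:21, ], rep(c(0L, 1L), c(20L, 1L)), c("maj", "min"))
  expect_warning(out1 <- smote_balance(lt1, seed = 6), "single sample")
  expect_equal(tabulate(out1$labels + 1L, 2), c(20L, 20L))
})

test_that("equal-weight baseline differs from METL only in the weights", {
  target <- make_blobs(n = 50, d = 3, sep = 3, seed = 38)
  sources <- list(make_blobs(n = 60, d = 3, sep = 3, seed = 39),
                  make_blobs(n = 60, d = 3, sep = 3, seed = 40, shift = 2),
                  make_blobs(n = 60, d = 3, sep = 3, seed = 41, shift = 1))
  eq <- suppressMessages(baseline_equal_weight(target, sources,
                                               metl_config(master_seed = 3)))
  expect_equal(eq$weights$normalized, rep(1 / 3, 3))
  mi <- suppressMessages(metl_fit(target, sources,
                                  metl_config(master_seed = 3)))
  for (i in 1:3)
    expect_identical(eq$source_models[[i]]$sampled_idx,
                     mi$source_models[[i]]$sampled_idx)
})

test_that("target-only baseline is a one-member model", {
  target <- make_blobs(n = 50, d = 3, sep = 4, seed = 42)
  b <- baseline_target_only(target, metl_config(master_seed = 4))
  expect_s3_class(b, "metl_model")
  expect_equal(b$weights$normalized, 1)
  expect_length(b$source_models[[1]]$sampled_idx, 0)
  X <- make_blobs(n = 100, d = 3, sep = 4, seed = 43)$features
  pr <- metl_predict(b, X)
  expect_gte(mean(pr$labels == make_blobs(n = 100, d = 3, sep = 4,
                                          seed = 43)$labels), 0.9)
})

test_that("run_protocol is deterministic and well-formed", {
  doms <- generate_domains(synthetic_spec(n_per_domain = 80, d = 3,
                                          domain_shifts = c(0.5, 0),
                                          seed = 44))
  r1 <- suppressMessages(suppressWarnings(
    run_protocol(doms, methods = c("metl", "target_only"),
                 label_ratios = 0.3, repeats = 2, seed = 45,
                 max_iterations = 2)))
  r2 <- suppressMessages(suppressWarnings(
    run_protocol(doms, methods = c("metl", "target_only"),
                 label_ratios = 0.3, repeats = 2, seed = 45,
                 max_iterations = 2)))
  expect_equal(r1, r2)
  expect_named(r1, c("method", "label_ratio", "n_sources", "mean_accuracy",
                     "sd", "repeats"))
  expect_true(all(r1$mean_accuracy >= 0 & r1$mean_accuracy <= 1))
  expect_true(all(r1$sd >= 0 | is.na(r1$sd)))
  expect_true(all(attr(r1, "runs")$accuracy >= 0))
  p <- ggplot2::autoplot(r1)
  expect_s3_class(p, "ggplot")
})
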