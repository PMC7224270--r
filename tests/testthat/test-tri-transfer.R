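test_that("agreement mask implements both mode semantics", {
  src <- labeled_table(matrix(0, 3, 2), c(0L, 0L, 0L), c("a", "b"))
  all0 <- make_mock_triple(const_proba(c(1, 0)))
  expect_equal(agreement_mask(all0, src, "classifiers_only"), rep(TRUE, 3))
  expect_equal(agreement_mask(all0, src, "classifiers_and_label"),
               rep(TRUE, 3))

  split_members <- make_mock_triple(list(const_proba(c(1, 0)),
                                         const_proba(c(1, 0)),
                                         const_proba(c(0, 1))))
  expect_equal(agreement_mask(split_members, src, "classifiers_only"),
               rep(FALSE, 3))

  all1 <- make_mock_triple(const_proba(c(0, 1)))
  expect_equal(agreement_mask(all1, src, "classifiers_only"), rep(TRUE, 3))
  expect_equal(agreement_mask(all1, src, "classifiers_and_label"),
               rep(FALSE, 3))
})

test_that("a source matching the target concept is mostly retained", {
  target <- make_blobs(n = 200, d = 3, sep = 4, seed = 21)
  source <- make_blobs(n = 200, d = 3, sep = 4, seed = 22)
  # oracle: unanimous correct classification by a triple fitted once on the
  # pooled data — establishes that the fixture itself is retainable
  pooled <- metl:::bind_tables(source, target)
  oracle_triple <- fit_triple(pooled, seed = 30)
  oracle_frac <- mean(agreement_mask(oracle_triple, source,
                                     "classifiers_and_label"))
  expect_gte(oracle_frac, 0.9)

  sm <- suppressMessages(
    tri_transfer_fit(source, target, tri_config(seed = 30)))
  expect_gte(length(sm$sampled_idx) / 200, 0.9)
  expect_true(sm$converged)
})

test_that("a label-flipped source is almost entirely rejected", {
  target <- make_blobs(n = 200, d = 3, sep = 4, seed = 23)
  flipped <- make_blobs(n = 200, d = 3, sep = 4, seed = 24, flip = 1)
  # full rejection may empty the set entirely, which itself warns
  sm <- suppressWarnings(suppressMessages(
    tri_transfer_fit(flipped, target, tri_config(seed = 31))))
  expect_lte(length(sm$sampled_idx) / 200, 0.1)
})

test_that("sampling shrinks monotonically and respects the iteration cap", {
  target <- make_blobs(n = 60, d = 3, sep = 3, seed = 25)
  source <- make_blobs(n = 80, d = 3, sep = 3, seed = 26, flip = 0.3)
  sm <- suppressMessages(
    tri_transfer_fit(source, target, tri_config(max_iterations = 4,
                                                seed = 32)))
  expect_true(all(diff(sm$size_history) <= 0))
  expect_lte(sm$iterations_run, 4L)
  expect_true(all(sm$sampled_idx %in% seq_len(80)))

  sm1 <- suppressMessages(
    tri_transfer_fit(source, target, tri_config(max_iterations = 1,
                                                seed = 32)))
  expect_equal(sm1$iterations_run, 1L)
  kept_all <- length(sm1$sampled_idx) == 80L
  expect_equal(sm1$converged, kept_all)
})

test_that("converged sampling is a fixpoint under an extra iteration", {
  target <- make_blobs(n = 60, d = 3, sep = 4, seed = 27)
  source <- make_blobs(n = 60, d = 3, sep = 4, seed = 28)
  a <- suppressMessages(
    tri_transfer_fit(source, target, tri_config(max_iterations = 8,
                                                seed = 33)))
  expect_true(a$converged)
  b <- suppressMessages(
    tri_transfer_fit(source, target,
                     tri_config(max_iterations = a$iterations_run + 1L,
                                seed = 33)))
  expect_identical(a$sampled_idx, b$sampled_idx)
})

test_that("per-source ensemble is the arithmetic mean of the members", {
  mix <- make_mock_triple(list(const_proba(c(1, 0)), const_proba(c(1, 0)),
                               const_proba(c(0, 1))))
  P <- source_model_predict(mix, matrix(0, 4, 2))
  expect_equal(P, matrix(rep(c(2 / 3, 1 / 3), each = 4), 4, 2,
                         dimnames = list(NULL, c("0", "1"))))

  same <- make_mock_triple(const_proba(c(0.3, 0.7)))
  Ps <- source_model_predict(same, matrix(0, 5, 2))
  expect_identical(Ps, predict_proba(same, matrix(0, 5, 2))[[1]])
  expect_equal(rowSums(Ps), rep(1, 5), tolerance = 1e-6)
})

test_that("transferability scores follow beta = exp(alpha * density)", {
  target <- make_blobs(n = 50, d = 3, sep = 3, seed = 41)
  source <- make_blobs(n = 40, d = 3, sep = 3, seed = 42, flip = 0.5)
  sm <- suppressMessages(
    tri_transfer_fit(source, target, tri_config(max_iterations = 2,
                                                seed = 43)))
  diag <- transferability(sm, source, target)
  expect_setequal(unique(diag$alpha), c(-1, 1))
  expect_true(all(diag$density_at_sample >= 0))
  expect_equal(diag$beta, exp(diag$alpha * diag$density_at_sample))
  expect_true(all(diag$beta[diag$alpha == -1] <= 1))
  expect_true(all(diag$beta[diag$alpha == 1] >= 1))

  # independent product-kernel density oracle on the standardized scale
  scaler <- sm$triple$scaler
  Zt <- scale(target$features, scaler$center, scaler$scale)
  Zs <- scale(source$features, scaler$center, scaler$scale)
  h <- nrow(Zt)^(-1 / (3 + 4)) * apply(Zt, 2, sd)
  dens_oracle <- vapply(seq_len(nrow(Zs)), function(i) {
    mean(vapply(seq_len(nrow(Zt)), function(j)
      prod(dnorm((Zs[i, ] - Zt[j, ]) / h) / h), numeric(1)))
  }, numeric(1))
  expect_equal(diag$density_at_sample, dens_oracle, tolerance = 1e-10)

  tiny <- labeled_table(matrix(0, 1, 3), 0L, c("neg", "pos"))
  expect_error(transferability(sm, source, tiny),
               class = "metl_density_error")
})

test_that("flipped rows score lower transferability than consistent rows", {
  ok <- 0L
  for (s in 1:5) {
    target <- make_blobs(n = 80, d = 3, sep = 4, seed = 100 + s)
    source <- make_blobs(n = 80, d = 3, sep = 4, seed = 200 + s)
    flip_pos <- withr::with_seed(300 + s, sample(80, 40))
    y <- source$labels
    y[flip_pos] <- 1L - y[flip_pos]
    flipped <- labeled_table(source$features, y, source$label_names)
    sm <- suppressMessages(suppressWarnings(
      tri_transfer_fit(flipped, target, tri_config(max_iterations = 1,
                                                   seed = s))))
    diag <- transferability(sm, flipped, target)
    if (mean(diag$beta[flip_pos]) < mean(diag$beta[-flip_pos])) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("an emptied sampled set falls back to a target-only triple", {
  target <- make_blobs(n = 120, d = 3, sep = 5, seed = 51)
  bad <- make_blobs(n = 4, d = 3, sep = 5, seed = 52, flip = 1)
  expect_warning(
    sm <- suppressMessages(
      tri_transfer_fit(bad, target, tri_config(seed = 53))),
    "empty")
  expect_length(sm$sampled_idx, 0)
  expect_null(sm$sampled_source)
  expect_true(sm$converged)
  P <- source_model_predict(sm, target$features[1:5, ])
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
})
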