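test_that("accuracy_on_condition: oracle and chance decoders", {
  alone <- test_condition("vernier_alone", character(), "alone")
  # oracle decoder that reads the true label -> 100%
  oracle <- mock_model(function(frames, iterations) {
    t(vapply(frames, function(f) {
      s <- c(left = -10, right = -10, none = -10)
      s[f$vernier_offset] <- 10
      s
    }, numeric(3)))
  })
  r <- accuracy_on_condition(oracle, alone, small_stim, n_trials = 200)
  expect_equal(r$percent_correct, 100)
  expect_equal(r$n_trials, 200)
  # uniformly random left/right decoder -> ~50% (binomial tolerance)
  set.seed(2)
  coin <- mock_model(function(frames, iterations)
    cbind(rnorm(length(frames)), rnorm(length(frames)), -10))
  r2 <- accuracy_on_condition(coin, alone, small_stim, n_trials = 2000)
  expect_gt(r2$percent_correct, 45)
  expect_lt(r2$percent_correct, 55)
  # "no vernier" predictions count as incorrect
  naysayer <- mock_model(function(frames, iterations)
    cbind(-10, -10, 10)[rep(1, length(frames)), , drop = FALSE])
  expect_equal(accuracy_on_condition(naysayer, alone, small_stim,
                                     n_trials = 50)$percent_correct, 0)
  # untrained models are rejected
  expect_error(accuracy_on_condition(init_caps_model(small_caps, 1), alone,
                                     small_stim, 10), "untrained")
})

test_that("uncrowding score identity and baseline matching", {
  cond <- test_condition("square_5same", rep("square", 5), "inside", "square_1")
  base <- test_condition("square_1", "square", "inside", "square_1")
  wrong <- test_condition("circle_1", "circle", "inside", "circle_1")
  # a decoder that is good inside 5 squares and at chance with 1 square
  biased <- mock_model(function(frames, iterations) {
    t(vapply(frames, function(f) {
      good <- f$n_repetitions == 5
      s <- c(left = 0, right = 0, none = -10)
      if (good) s[f$vernier_offset] <- 10 else s[sample(1:2, 1)] <- 1
      s
    }, numeric(3)))
  })
  set.seed(3)
  sc <- uncrowding_score(biased, cond, base, small_stim, n_trials = 400)
  expect_equal(sc$delta,
               sc$percent_correct - sc$baseline_percent_correct)
  expect_gt(sc$delta, 30)
  expect_error(uncrowding_score(biased, cond, wrong, small_stim, 10),
               "baseline mismatch")
})

test_that("evaluate_battery emits a tidy table with deltas", {
  oracle <- mock_model(function(frames, iterations) {
    t(vapply(frames, function(f) {
      s <- c(left = -1, right = -1, none = -1); s[f$vernier_offset] <- 5; s
    }, numeric(3)))
  })
  bat <- build_test_battery(1, shapes = c("square", "circle"),
                            alternating_pairs = cbind("square", "circle"))
  df <- evaluate_battery(oracle, bat, small_stim, n_trials = 30)
  expect_true(all(c("condition", "percent_correct", "delta", "baseline") %in%
                    names(df)))
  expect_equal(nrow(df), length(bat))
  # delta identity recomputed from the table itself
  for (i in seq_len(nrow(df))) {
    bl <- df$baseline[i]
    if (is.na(bl) || bl == df$condition[i]) next
    expect_equal(df$delta[i],
                 df$percent_correct[i] -
                   df$percent_correct[df$condition == bl])
  }
})

test_that("iteration_sweep shape and capsule-only restriction", {
  oracle <- mock_model(function(frames, iterations) {
    # error rate decreases with iterations: 30% at 1 iter to 2% at 8
    p_err <- 0.32 - 0.04 * iterations
    t(vapply(frames, function(f) {
      s <- c(left = 0, right = 0, none = -10)
      lab <- if (runif(1) < p_err) setdiff(c("left", "right"), f$vernier_offset)
             else f$vernier_offset
      s[lab] <- 5; s
    }, numeric(3)))
  })
  conds <- build_test_battery(2)[2:3]
  set.seed(4)
  sw <- iteration_sweep(oracle, conds, iterations = 1:8, stim = small_stim2,
                        n_trials = 150)
  expect_equal(nrow(sw), 8 * 2)           # one value per iteration per condition
  expect_equal(sort(unique(sw$iterations)), 1:8)
  fit <- fit_line(sw$iterations[sw$condition == "lines"],
                  sw$error_rate[sw$condition == "lines"])
  expect_lt(fit$slope, 0)
  am <- init_alt_model(alt_config(small_caps, "ffcnn"), seed = 1)
  am$trained <- TRUE
  expect_error(iteration_sweep(am, conds, 1:2, small_stim2, 5),
               "not supported for the alternative")
})

test_that("top_reconstructions: ordering and k bound", {
  res <- tiny_train(steps = 12, seed = 71)
  f <- render_vernier("left", small_stim)
  tr <- top_reconstructions(res$model, f, k = 3)
  expect_length(tr$images, 3)
  expect_equal(tr$norms, sort(tr$norms, decreasing = TRUE))
  expect_true(all(dim(tr$images[[1]]) == c(small_stim$height, small_stim$width)))
  expect_error(top_reconstructions(res$model, f, k = 99), "exceeds")
})

test_that("fit_line: exact, constant, noisy vs normal equations", {
  f <- fit_line(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(fit_line(1:5, rep(3.3, 5))$slope, 0, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(40); y <- 1.7 * x - 0.4 + rnorm(40, sd = 0.3)
  f2 <- fit_line(x, y)
  # independent normal-equations oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  expect_error(fit_line(rep(2, 5), 1:5), "identical")
})

test_that("t tests match hand-computed formula oracles", {
  a <- c(3.1, 2.7, 3.5, 2.9, 3.3)
  b <- c(2.2, 2.5, 1.9, 2.8)
  got <- compare_slopes(a, b)
  # pooled-variance Student t by hand
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(got$t, t_hand, tolerance = 1e-8)
  expect_equal(got$p, 2 * pt(-abs(t_hand), length(a) + length(b) - 2),
               tolerance = 1e-8)
  # identical groups -> t = 0, p = 1
  same <- compare_slopes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # one-sample against a reference
  v <- c(10.2, 11.0, 9.8)
  got1 <- one_sample_test(v, 9)
  t1 <- (mean(v) - 9) / (sd(v) / sqrt(3))
  expect_equal(got1$t, t1, tolerance = 1e-8)
  expect_equal(got1$p, 2 * pt(-abs(t1), 2), tolerance = 1e-8)
  expect_equal(one_sample_test(c(5, 5, 5), 5)$p, 1)
  expect_error(one_sample_test(c(5, 5, 5), 6), "zero variance")
})
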