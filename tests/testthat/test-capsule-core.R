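test_that("squash: closed-form values and bound", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- c(1, 0, 0)
  expect_equal(squash(v), 0.5 * v, tolerance = 1e-10)
  w <- c(0, 10, 0)
  expect_equal(sqrt(sum(squash(w)^2)), 100 / 101, tolerance = 1e-10)
  set.seed(1)
  m <- matrix(rnorm(200, sd = 3), 50, 4)
  s <- squash(m)
  norms <- sqrt(rowSums(s^2))
  expect_true(all(norms < 1 & norms >= 0))
  # direction preserved
  expect_equal(s / sqrt(rowSums(s^2)), m / sqrt(rowSums(m^2)), tolerance = 1e-12)
})

test_that("conv_features: valid-convolution arithmetic, ELU bound, two stages", {
  p <- small_caps$plans
  # H_out = (H - k) %/% s + 1 against direct arithmetic
  expect_equal(p[[1]]$h_out,
               (small_stim$height - small_caps$conv1$k) %/% small_caps$conv1$s + 1)
  expect_equal(p[[1]]$w_out,
               (small_stim$width - small_caps$conv1$k) %/% small_caps$conv1$s + 1)
  # stride-1 special case: H - k + 1
  p1 <- crowdcaps:::.plan_conv(30, 40, 5, 1)
  expect_equal(c(p1$h_out, p1$w_out), c(30 - 5 + 1, 40 - 5 + 1))
  m <- init_caps_model(small_caps, seed = 1)
  fr <- build_training_set(1, 3, small_stim, seed = 2)
  ft <- conv_features(crowdcaps:::.stack_images(fr), m$weights, small_caps, 3)
  expect_true(all(ft$out >= -1))                      # ELU codomain
  expect_length(small_caps$plans, 3)                  # two conv + caps conv
  # image too small -> error naming the layer
  tiny <- stim_config_small(1); tiny$height <- 2
  expect_error(caps_config_small(tiny), "conv1")
})

test_that("primary capsules: element conservation, m = 7, squash bound", {
  m <- init_caps_model(small_caps, seed = 1)
  fr <- build_training_set(1, 2, small_stim, seed = 3)
  ft <- conv_features(crowdcaps:::.stack_images(fr), m$weights, small_caps, 2)
  pc <- form_primary_capsules(ft$out, m$weights, small_caps, 2)
  expect_equal(length(pc$u), small_caps$npos3 * 2 * small_caps$m * small_caps$n)
  expect_equal(small_caps$m, 7)
  norms <- sqrt(apply(pc$u^2, c(1, 3), sum))
  expect_true(all(norms < 1))
  bad <- small_caps; bad$weights <- NULL
  w <- m$weights; w$W3 <- w$W3[, 1:(ncol(w$W3) - 1)]
  expect_error(form_primary_capsules(ft$out, w, small_caps, 2), "divisible")
})

test_that("predict_votes: identity/zero transforms and vote count", {
  n <- 4; d <- 4; m <- 3; pb <- 5
  u <- array(rnorm(pb * n * m), c(pb, n, m))
  Wv <- array(0, c(n, d, m, m))
  for (i in 1:m) for (j in 1:m) Wv[, , i, j] <- diag(n)
  V <- predict_votes(u, Wv)
  expect_equal(dim(V), c(pb * m, d, m))      # n_children x dim x n_parents
  for (i in 1:m) for (j in 1:m)
    expect_equal(V[((i - 1) * pb + 1):(i * pb), , j], u[, , i])
  expect_true(all(predict_votes(u, Wv * 0) == 0))
})

test_that("routing matches the brute-force oracle", {
  set.seed(4)
  # single parent: couplings 1, output = squash(sum of votes), any iterations
  votes1 <- array(rnorm(6 * 3 * 1), c(6, 3, 1))
  for (it in c(1, 3, 5)) {
    r <- route_capsules(votes1, it)
    expect_true(all(r$couplings == 1))
    expect_equal(r$v[1, , 1], squash(colSums(votes1[, , 1])), tolerance = 1e-12)
  }
  # 2 children x 2 parents, 1 iteration: uniform couplings, squash(mean)
  votes2 <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  r1 <- route_capsules(votes2, 1)
  expect_true(all(abs(r1$couplings - 0.5) < 1e-15))
  for (j in 1:2)
    expect_equal(r1$v[1, , j], squash(colMeans(votes2[, , j])), tolerance = 1e-12)
  # random instances vs the naive-loop oracle, iterations 1..4
  for (rep in 1:5) {
    nc <- sample(2:6, 1); d <- sample(2:5, 1); mp <- sample(2:4, 1)
    votes <- array(rnorm(nc * d * mp), c(nc, d, mp))
    for (it in 1:4) {
      mine <- route_capsules(votes, it)
      ora <- oracle_route(votes, it)
      expect_equal(matrix(mine$v[1, , ], d, mp), t(ora$v), tolerance = 1e-6)
      expect_equal(mine$couplings, ora$couplings, tolerance = 1e-6)
    }
  }
  expect_error(route_capsules(votes2, 0), ">= 1")
})

test_that("coupling normalisation and agreement monotonicity", {
  set.seed(5)
  # couplings sum to 1 across parents at every iteration
  for (it in 1:4) {
    votes <- array(rnorm(8 * 4 * 3), c(8, 4, 3))
    r <- route_capsules(votes, it)
    expect_equal(rowSums(r$couplings), rep(1, 8), tolerance = 1e-12)
  }
  # 3 children voting identically for parent A, 1 voting orthogonally:
  # coupling of the agreeing children to A strictly increases over iterations
  d <- 4
  va <- c(2, 0, 0, 0)
  vo <- c(0, 2, 0, 0)
  votes <- array(0, c(4, d, 2))
  for (i in 1:3) votes[i, , 1] <- va
  votes[4, , 1] <- vo
  votes[1:3, , 2] <- matrix(rnorm(3 * d, sd = 0.01), 3)
  votes[4, , 2] <- vo
  c1 <- route_capsules(votes, 1)$couplings[1, 1]
  c2 <- route_capsules(votes, 2)$couplings[1, 1]
  c3 <- route_capsules(votes, 3)$couplings[1, 1]
  expect_gt(c2, c1)
  expect_gt(c3, c2)
})

test_that("caps_forward: determinism, type count, feedforward equivalence", {
  m <- init_caps_model(small_caps, seed = 9)
  fr <- build_training_set(1, 4, small_stim, seed = 10)
  f1 <- caps_forward(m, fr, 3)
  f2 <- caps_forward(m, fr, 3)
  expect_identical(f1$v, f2$v)
  expect_equal(dim(f1$v), c(4, small_caps$d, length(small_caps$classes)))
  expect_true(all(f1$norms < 1))
  # iterations = 1 equals the uniform-coupling closed form computed by hand
  fw <- caps_forward(m, fr[1], 1, keep_cache = TRUE)
  V <- fw$cache$V
  for (j in seq_len(small_caps$m)) {
    s <- colSums(V[, , j]) / small_caps$m
    expect_equal(fw$v[1, , j], squash(s), tolerance = 1e-6)
  }
  expect_warning(caps_forward(m, fr, 9), "exceeds")
})

test_that("hand-derived gradients match numerical differentiation", {
  set.seed(31)
  fr <- build_training_set(1, 2, small_stim, seed = 32)
  m <- init_caps_model(small_caps_e2e, seed = 33)
  st <- crowdcaps:::.caps_step(m, fr, 1)   # 1 iteration: gradients exact
  for (nm in c("W1", "W2", "W3", "Wv", "Vw1", "Vw2", "Rw1", "Xw", "Dw1",
               "Dw3", "b2")) {
    w <- m$weights[[nm]]
    for (ii in sample(length(w), 3)) {
      eps <- 1e-5
      mp <- m; mp$weights[[nm]][ii] <- w[ii] + eps
      mm <- m; mm$weights[[nm]][ii] <- w[ii] - eps
      num <- (crowdcaps:::.caps_step(mp, fr, 1)$losses[["total"]] -
                crowdcaps:::.caps_step(mm, fr, 1)$losses[["total"]]) / (2 * eps)
      ana <- st$grads[[nm]][ii]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})
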