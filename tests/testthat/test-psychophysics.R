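test_that("simulated observer: exact 75% at threshold, chance floor, monotone", {
  for (lapse in c(0, 0.05, 0.1)) {
    obs <- make_simulated_observer(true_threshold = 8, spread = 4, lapse = lapse)
    expect_equal(obs(8), 0.75, tolerance = 1e-12)
    expect_lt(obs(0.01), 0.56)                    # near the 0.5 chance floor
    off <- seq(0, 20, by = 0.5)                   # below numeric saturation
    expect_true(all(diff(obs(off)) > 0))          # monotone increasing
    expect_lte(max(obs(seq(0, 40, 0.5))), 1 - lapse + 1e-12)
  }
  expect_error(make_simulated_observer(8, spread = 0))
  expect_error(make_simulated_observer(8, 4, lapse = 0.2))
})

test_that("staircase config invariants from the experimental design", {
  cfg <- staircase_config()
  expect_equal(cfg$max_offset, 2 * cfg$start_offset)  # cap = twice the start
  expect_equal(cfg$start_offset, 16.66)
  expect_equal(cfg$total, 160)                        # 2 blocks of 80
  expect_equal(cfg$target, 0.75)
})

test_that("run_pest: offset cap, trial count, adaptation toward threshold", {
  cfg <- staircase_config()
  obs <- make_simulated_observer(8, spread = 2)
  for (seed in 1:6) {
    tr <- run_pest(obs, cfg, seed = seed)
    expect_equal(nrow(tr), cfg$total)
    expect_true(all(tr$offset_arcmin <= cfg$max_offset + 1e-12))
    expect_true(all(tr$offset_arcmin >= cfg$min_offset - 1e-12))
    expect_true(all(tr$correct == (tr$response == tr$direction)))
  }
  # steep observer at 8': late-block offsets concentrate near 8'
  set.seed(42)
  late <- replicate(12, {
    tr <- run_pest(make_simulated_observer(8, spread = 1.5), cfg)
    mean(tail(tr$offset_arcmin[tr$block == 2], 20))
  })
  expect_lt(abs(mean(late) - 8), 2.5)
  # omissions are recorded and scored incorrect
  cfg_om <- staircase_config(omission_rate = 0.3)
  tr <- run_pest(obs, cfg_om, seed = 2)
  expect_gt(sum(tr$response == "omitted"), 0)
  expect_true(all(!tr$correct[tr$response == "omitted"]))
  expect_warning(run_pest(function(x) 0.9 - 0.01 * x, staircase_config(), 1),
                 "decreases")
})

test_that("fit_psychometric: parameter recovery and threshold identities", {
  set.seed(8)
  mu <- 10; sigma <- 4
  # unbiased within Monte-Carlo error on 2000-trial synthetic datasets:
  # the mean recovered parameters over replicates land within 5% of truth
  fits <- lapply(1:8, function(i) {
    x <- runif(2000, 0.5, 25)
    p <- 0.5 + 0.5 * pnorm((x - mu) / sigma)
    fit_psychometric(data.frame(offset_arcmin = x, correct = runif(2000) < p))
  })
  expect_lt(abs(mean(vapply(fits, `[[`, 0, "mu")) - mu) / mu, 0.05)
  expect_lt(abs(mean(vapply(fits, `[[`, 0, "sigma")) - sigma) / sigma, 0.05)
  fit <- fits[[1]]
  # 2AFC parameterisation: the 75% point is mu itself
  expect_equal(fit$threshold, fit$mu, tolerance = 1e-9)
  x <- runif(2000, 0.5, 25)
  # plain cumulative Gaussian (guess 0): threshold = mu + z(0.75) sigma
  p0 <- pnorm((x - mu) / sigma)
  trials0 <- data.frame(offset_arcmin = x, correct = runif(2000) < p0)
  fit0 <- fit_psychometric(trials0, guess = 0, target = 0.75)
  expect_equal(fit0$threshold, fit0$mu + fit0$sigma * qnorm(0.75),
               tolerance = 1e-9)
  expect_equal(qnorm(0.75), 0.6745, tolerance = 1e-4)
  # degenerate inputs fail loudly
  allc <- data.frame(offset_arcmin = c(1, 2, 3), correct = c(TRUE, TRUE, TRUE))
  expect_error(fit_psychometric(allc), "perfect separation")
  one_level <- data.frame(offset_arcmin = rep(5, 10),
                          correct = rep(c(TRUE, FALSE), 5))
  expect_error(fit_psychometric(one_level), "two offset levels")
})

test_that("staircase + fit recovers the true threshold on average", {
  set.seed(9)
  obs <- make_simulated_observer(8, spread = 4)
  est <- vapply(1:25, function(i) estimate_threshold(obs, staircase_config()), 0)
  expect_lt(abs(mean(est) - 8), 1.5)
})

test_that("duration series analysis: slopes, group test, flat null", {
  set.seed(10)
  durations <- c(20, 40, 80, 160, 320, 640)
  rows <- list()
  for (s in 1:5) for (cc in c("lines", "cuboids")) {
    slope <- if (cc == "cuboids") -0.02 else -0.001
    thr <- 17 + slope * durations + rnorm(length(durations), sd = 0.4)
    rows[[length(rows) + 1]] <- data.frame(subject = s, condition = cc,
                                           duration = durations, threshold = thr)
  }
  dd <- do.call(rbind, rows)
  an <- duration_series_analysis(dd, c("lines", "cuboids"), reference = 3)
  expect_equal(nrow(an$slopes), 10)
  # known steeper cuboid slopes: large, significant difference
  expect_lt(an$slope_test$p, 0.05)
  expect_lt(mean(an$slopes$slope[an$slopes$condition == "cuboids"]),
            mean(an$slopes$slope[an$slopes$condition == "lines"]))
  # crowding at the shortest duration relative to the reference
  expect_lt(an$crowding_tests$lines$p, 0.05)
  # flat thresholds: slope ~ 0 and a non-significant difference
  flat <- dd; flat$threshold <- 12 + rnorm(nrow(dd), sd = 0.2)
  an2 <- duration_series_analysis(flat, c("lines", "cuboids"))
  expect_lt(abs(mean(an2$slopes$slope)), 0.005)
  expect_gt(an2$slope_test$p, 0.05)
})

test_that("geometry spec holds the published visual-angle values", {
  g <- geometry_spec()
  expect_equal(g$vernier_length_arcmin, 40)
  expect_equal(g$vernier_gap_arcmin, 4)
  expect_equal(g$eccentricity_deg, 5)
  expect_equal(g$flanker_length_arcmin, 84)
  expect_equal(g$flanker_dist_arcmin, 40)
  expect_equal(g$cuboid_width_arcmin, 58)
  expect_equal(g$oblique_length_arcmin, 23.33)
  expect_equal(arcmin_to_deg(60), 1)
})
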