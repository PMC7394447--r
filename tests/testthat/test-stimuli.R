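test_that("vernier rendering: mirror symmetry, pixel count, geometry errors", {
  for (off in c(1, 2, 3, 4)) {
    vr <- render_vernier("right", small_stim, offset_px = off)
    vl <- render_vernier("left", small_stim, offset_px = off)
    # exact horizontal mirror about the central column of the odd-width canvas
    expect_identical(vl$image[, ncol(vl$image):1], vr$image)
  }
  vr <- render_vernier("right", small_stim)
  expect_equal(px_count(vr), 2 * small_stim$vernier_length)
  expect_identical(vr$shape_class, "vernier")
  expect_identical(vr$vernier_offset, "right")
  # decoder target space has exactly three labels (left, right, no vernier)
  expect_length(crowdcaps:::.offset_levels, 3)
  expect_error(render_vernier("up", small_stim), "left.*right")
  expect_error(render_vernier("left", small_stim, at = c(1, 1)), "canvas")
})

test_that("shape groups: centering, count scaling, monotone width", {
  ctr <- c((small_stim$width + 1) %/% 2, (small_stim$height + 1) %/% 2)
  for (s in small_stim$shapes) {
    g1 <- render_shape_group(s, 1, config = small_stim)
    pix <- which(g1$image > 0, arr.ind = TRUE)
    centroid <- c(mean(pix[, 2]), mean(pix[, 1]))
    expect_lt(max(abs(centroid - ctr)), 1.01) # roughly centered
    g5 <- render_shape_group(s, 5, config = small_stim)
    expect_equal(px_count(g5), 5 * px_count(g1)) # no outline overlap
    widths <- vapply(c(1, 3, 5), function(n) {
      p <- which(render_shape_group(s, n, config = small_stim)$image > 0,
                 arr.ind = TRUE)
      diff(range(p[, 2]))
    }, 0)
    expect_true(all(diff(widths) > 0))
  }
  expect_error(render_shape_group("square", 2, config = small_stim), "1, 3 or 5")
  expect_error(render_shape_group("blob", 1, config = small_stim), "unknown")
  wide <- stim_config_small(1); wide$width <- 31
  expect_error(render_shape_group("square", 5, config = wide), "wider than canvas")
})

test_that("experiment-2 stimuli: cuboid/scramble pixel identity, line alignment", {
  set.seed(42)
  for (sp in c(1, 3, 6)) {
    cp <- render_exp2_stimulus(exp2_shape_spec("cuboid_pair", pair_spacing = sp),
                               small_stim2)
    sc <- render_exp2_stimulus(exp2_shape_spec("scrambled_cuboid_pair",
                                               pair_spacing = sp), small_stim2)
    # the scramble permutes segments, never deletes them
    expect_equal(px_count(sc), px_count(cp))
    expect_identical(cp$shape_class, "cuboids")
    expect_identical(sc$shape_class, "scrambled_cuboids")
  }
  # innermost cuboid edges coincide with the corresponding line pair
  gap <- 4L
  cp <- render_exp2_stimulus(exp2_shape_spec("cuboid_pair", pair_spacing = gap),
                             small_stim2)
  ctr_x <- (small_stim2$width + 1) %/% 2
  inner_l <- ctr_x - ((gap + 1) %/% 2)
  inner_r <- inner_l + gap + 1
  ll <- small_stim2$line_length
  cy <- (small_stim2$height + 1) %/% 2
  hh <- (ll - 1) %/% 2
  for (x in c(inner_l, inner_r))
    expect_true(all(cp$image[(cy - hh):(cy - hh + ll - 1), x] > 0))
  lg <- render_exp2_stimulus(exp2_shape_spec("line_group", line_count = 4,
                                             pair_spacing = 2), small_stim2)
  expect_equal(px_count(lg), 4 * small_stim2$line_length)
  expect_error(exp2_shape_spec("cuboid_pair", pair_spacing = 0), "\\[1, 6\\]")
  expect_error(exp2_shape_spec("cuboid_pair", pair_spacing = 7), "\\[1, 6\\]")
  expect_error(exp2_shape_spec("pyramid"), "invalid kind")
})

test_that("compose_test_stimulus: identity, centroids, overlap error", {
  v <- render_vernier("right", small_stim) # even offset: symmetric centroid
  alone <- test_condition("vernier_alone", character(), "alone")
  out <- compose_test_stimulus(v, alone, small_stim)
  expect_identical(out$image, v$image)
  # inside one square: vernier centroid equals square centroid
  sq1 <- test_condition("square_1", "square", "inside", "square_1")
  comp <- compose_test_stimulus(v, sq1, small_stim)
  sq_only <- render_shape_group("square", 1, config = small_stim)
  vern_pix <- which(comp$image > 0 & sq_only$image == 0, arr.ind = TRUE)
  sq_pix <- which(sq_only$image > 0, arr.ind = TRUE)
  expect_equal(c(mean(vern_pix[, 2]), mean(vern_pix[, 1])),
               c(mean(sq_pix[, 2]), mean(sq_pix[, 1])))
  # a flanker drawn over the vernier is an error
  tight <- stim_config_small(1)
  tight$vernier_length <- 5L # tall vernier collides with the square outline
  vt <- render_vernier("right", tight)
  expect_error(compose_test_stimulus(vt, sq1, tight), "overlap")
  # composition is label-preserving
  expect_identical(comp$vernier_offset, "right")
  expect_identical(comp$condition, "square_1")
})

test_that("test battery contents", {
  bat <- build_test_battery(1, shapes = small_stim$shapes)
  nm <- vapply(bat, `[[`, "", "name")
  expect_true("vernier_alone" %in% nm)
  for (s in small_stim$shapes) {
    expect_true(paste0(s, "_1") %in% nm)        # central flanker alone
    expect_true(paste0(s, "_5same") %in% nm)    # 5 identical
    expect_true(paste0(s, "_5same_outside") %in% nm)
  }
  # every crowding condition has a matched central-flanker-alone baseline
  for (cd in bat) {
    if (cd$name == "vernier_alone" || cd$vernier_placement == "outside") next
    expect_true(cd$baseline %in% nm)
  }
  # every inside configuration has an outside control
  inside <- nm[vapply(bat, function(c) c$vernier_placement == "inside", TRUE)]
  for (n in inside) expect_true(paste0(n, "_outside") %in% nm)
  # alternating configurations present, 5 elements, alternating pattern
  alt <- bat[grepl("5alt$", nm)]
  expect_gt(length(alt), 0)
  for (cd in alt) {
    expect_length(cd$flanker_layout, 5)
    expect_length(unique(cd$flanker_layout), 2)
    expect_identical(cd$flanker_layout[1], cd$flanker_layout[3])
  }
  bat2 <- build_test_battery(2)
  expect_setequal(vapply(bat2, `[[`, "", "name"),
                  c("vernier_alone", "lines", "cuboids"))
  # all compositions render on the small canvases
  for (cd in bat) expect_s3_class(
    compose_test_stimulus(render_vernier("left", small_stim), cd, small_stim),
    "stimulus_frame")
  for (cd in bat2) expect_s3_class(
    compose_test_stimulus(render_vernier("left", small_stim2), cd, small_stim2),
    "stimulus_frame")
  # outside placement clears the flanker bounding region
  sqo <- bat[[which(nm == "square_5same_outside")]]
  comp <- compose_test_stimulus(render_vernier("left", small_stim), sqo, small_stim)
  flank <- compose_test_stimulus(render_vernier("left", small_stim),
                                 bat[[which(nm == "square_5same")]], small_stim)
  sq_rows <- range(which(rowSums(render_shape_group("square", 5,
                     config = small_stim)$image) > 0))
  vern_rows <- which(rowSums(comp$image) > 0 &
                       rowSums(render_shape_group("square", 5,
                         config = small_stim)$image) == 0)
  expect_true(all(vern_rows < sq_rows[1]))
})

test_that("augmentation: identity, clipping, determinism, label invariance", {
  f <- render_shape_group("circle", 3, config = small_stim)
  ident <- aug_config(noise_sd_range = c(0, 0), brightness_shift_range = c(0, 0),
                      contrast_factor_range = c(1, 1))
  expect_equal(augment_frame(f, ident)$image, f$image)
  cfg <- aug_config()
  set.seed(1)
  for (i in 1:20) {
    a <- augment_frame(f, cfg)
    expect_true(all(a$image >= 0 & a$image <= 1))
    expect_identical(a$shape_class, f$shape_class)
    expect_identical(a$vernier_offset, f$vernier_offset)
  }
  set.seed(7); a1 <- augment_frame(f, cfg)
  set.seed(7); a2 <- augment_frame(f, cfg)
  expect_identical(a1$image, a2$image)
  expect_error(aug_config(noise_sd_range = c(-0.1, 0.1)))
})

test_that("training sets: purity, balance, class sets, determinism", {
  ds <- build_training_set(1, 300, small_stim, seed = 5)
  for (f in ds) {
    expect_true(all(f$image >= 0 & f$image <= 1))
    # verniers and shapes never combined
    if (f$shape_class != "vernier") expect_identical(f$vernier_offset, "none")
    if (f$vernier_offset != "none") expect_identical(f$shape_class, "vernier")
  }
  cls <- vapply(ds, `[[`, "", "shape_class")
  expect_setequal(unique(cls), training_classes(1, small_stim))
  expect_length(training_classes(1, small_stim), 7)  # 6 shapes + vernier
  expect_setequal(training_classes(2, small_stim2),
                  c("vernier", "lines", "cuboids", "scrambled_cuboids"))
  tab <- table(cls)
  expect_lt(max(tab) / min(tab), 2.5) # approximately balanced
  # byte-identical under a fixed seed
  d1 <- build_training_set(2, 25, small_stim2, seed = 11)
  d2 <- build_training_set(2, 25, small_stim2, seed = 11)
  expect_identical(d1, d2)
})

test_that("stimulus archive roundtrip (plain-text PGM + CSV)", {
  dir <- withr::local_tempdir()
  frames <- build_training_set(1, 4, small_stim, aug = NULL, seed = 3)
  write_stimulus_set(frames, dir)
  labels <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labels), 4)
  expect_true(all(c("frame_id", "shape_class", "vernier_offset", "x", "y") %in%
                    names(labels)))
  img <- read_pgm(file.path(dir, paste0(labels$frame_id[1], ".pgm")))
  expect_equal(dim(img), dim(frames[[1]]$image))
  expect_lt(max(abs(img - frames[[1]]$image)), 1 / 254)
})
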