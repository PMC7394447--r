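# The (un)crowding test protocol: per-condition vernier accuracy with fresh
# augmentation draws, uncrowding deltas against the central-flanker-alone
# baseline, routing-iteration sweeps, capsule reconstruction analysis, and
# the line-fit / t-test statistics used to compare conditions.

# vernier scores only (skips unneeded decoder heads for speed).
# "mock_model" objects (testing) supply score_fn(frames, iterations) directly.
.vernier_scores <- function(model, frames, iterations) {
  if (inherits(model, "mock_model")) {
    model$score_fn(frames, iterations)
  } else if (inherits(model, "caps_model")) {
    fw <- caps_forward(model, frames, iterations)
    vid <- match("vernier", model$config$classes)
    xv <- fw$v[, , vid, drop = FALSE]; dim(xv) <- c(length(frames), model$config$d)
    decode_vernier(xv, model$weights)
  } else {
    fwd <- .alt_forward(model, frames, iterations)
    decode_vernier(fwd$h, model$weights)
  }
}

#' Vernier discrimination accuracy on one test condition
#'
#' Generates `n_trials` stimuli of the condition (fresh random offset
#' directions and augmentation draws per trial), decodes the vernier offset,
#' and scores a trial correct iff the predicted label equals the true
#' direction; predicting "no vernier" counts as incorrect.
#'
#' @param model Trained `caps_model` or `alt_model`.
#' @param condition A [test_condition()].
#' @param stim The [stim_config()] used to compose test stimuli.
#' @param n_trials Trials (default 1000, making binomial noise small relative
#'   to the effects of interest).
#' @param iterations Routing / recurrent iterations.
#' @param aug An [aug_config()] or NULL for clean stimuli.
#' @param batch Forward-pass batch size.
#' @return Object of class `condition_result`: list with `condition`,
#'   `percent_correct`, `n_trials`, `iterations`.
#' @export
accuracy_on_condition <- function(model, condition, stim = model$config$stim,
                                  n_trials = 1000,
                                  iterations = model$config$routing_iterations,
                                  aug = aug_config(), batch = 250L) {
  if (!isTRUE(model$trained)) stop("model is untrained; train it before testing")
  stopifnot(n_trials >= 1)
  # composition is deterministic: build the two clean frames once, then draw
  # fresh augmentation per trial
  clean <- list(left = compose_test_stimulus(render_vernier("left", stim),
                                             condition, stim),
                right = compose_test_stimulus(render_vernier("right", stim),
                                              condition, stim))
  correct <- 0L
  done <- 0L
  while (done < n_trials) {
    nb <- min(batch, n_trials - done)
    dirs <- sample(c("left", "right"), nb, replace = TRUE)
    frames <- lapply(dirs, function(dd) {
      f <- clean[[dd]]
      if (!is.null(aug)) f <- augment_frame(f, aug)
      f
    })
    sc <- .vernier_scores(model, frames, iterations)
    pred <- .offset_levels[max.col(sc, ties.method = "first")]
    correct <- correct + sum(pred == dirs)
    done <- done + nb
  }
  structure(list(condition = condition$name,
                 percent_correct = 100 * correct / n_trials,
                 n_trials = n_trials, iterations = iterations),
            class = "condition_result")
}

#' Uncrowding score of a configuration
#'
#' `percent_correct(full configuration) - percent_correct(central flanker
#' alone)`. Values above 0 indicate uncrowding (expected for groups of
#' identical flankers); values at or below 0 indicate crowding (expected for
#' alternating flankers).
#'
#' @param model Trained model.
#' @param condition The full-configuration [test_condition()].
#' @param baseline The matched central-flanker-alone condition; its name must
#'   equal `condition$baseline`.
#' @param stim,n_trials,iterations,aug As in [accuracy_on_condition()].
#' @return Object of class `uncrowding_score`: list with `configuration`,
#'   `delta`, and both accuracies.
#' @export
uncrowding_score <- function(model, condition, baseline,
                             stim = model$config$stim, n_trials = 1000,
                             iterations = model$config$routing_iterations,
                             aug = aug_config()) {
  if (!identical(baseline$name, condition$baseline))
    stop(sprintf("baseline mismatch: condition '%s' expects baseline '%s', got '%s'",
                 condition$name, condition$baseline, baseline$name))
  a <- accuracy_on_condition(model, condition, stim, n_trials, iterations, aug)
  b <- accuracy_on_condition(model, baseline, stim, n_trials, iterations, aug)
  structure(list(configuration = condition$name,
                 delta = a$percent_correct - b$percent_correct,
                 percent_correct = a$percent_correct,
                 baseline_percent_correct = b$percent_correct,
                 n_trials = n_trials),
            class = "uncrowding_score")
}

#' Evaluate a whole test battery
#'
#' @param model Trained model.
#' @param conditions List of [test_condition()]s (see
#'   [build_test_battery()]).
#' @param stim,n_trials,iterations,aug As in [accuracy_on_condition()].
#' @return Tidy data frame: condition, placement, baseline, n_trials,
#'   iterations, percent_correct, delta (vs the named baseline, NA for
#'   baselines themselves).
#' @export
evaluate_battery <- function(model, conditions, stim = model$config$stim,
                             n_trials = 1000,
                             iterations = model$config$routing_iterations,
                             aug = aug_config()) {
  acc <- vapply(conditions, function(cd)
    accuracy_on_condition(model, cd, stim, n_trials, iterations, aug)$percent_correct, 0)
  names(acc) <- vapply(conditions, `[[`, "", "name")
  delta <- vapply(seq_along(conditions), function(i) {
    bl <- conditions[[i]]$baseline
    if (is.na(bl) || bl == conditions[[i]]$name) NA_real_ else acc[i] - acc[[bl]]
  }, 0)
  data.frame(condition = names(acc),
             placement = vapply(conditions, `[[`, "", "vernier_placement"),
             baseline = vapply(conditions, `[[`, "", "baseline"),
             n_trials = n_trials, iterations = iterations,
             percent_correct = as.vector(acc), delta = delta,
             row.names = NULL)
}

#' Error rate as a function of routing iterations
#'
#' Sweeps the recurrent routing iterations (1 = purely feedforward regime)
#' and reports the vernier discrimination error rate per condition. Only
#' capsule models are swept: the alternative architectures produced no
#' uncrowding, so the comparison is not defined for them.
#'
#' @param model Trained `caps_model`.
#' @param conditions List of [test_condition()]s.
#' @param iterations Integer vector, default 1:8.
#' @param stim,n_trials,aug As in [accuracy_on_condition()].
#' @return Data frame: condition, iterations, error_rate (100 - %correct).
#' @export
iteration_sweep <- function(model, conditions, iterations = 1:8,
                            stim = model$config$stim, n_trials = 1000,
                            aug = aug_config()) {
  if (inherits(model, "alt_model"))
    stop("iteration sweeps are not supported for the alternative ",
         "architectures (they produced no uncrowding at all)")
  rows <- list()
  for (cd in conditions) for (it in iterations) {
    r <- accuracy_on_condition(model, cd, stim, n_trials, it, aug)
    rows[[length(rows) + 1]] <- data.frame(condition = cd$name, iterations = it,
                                           error_rate = 100 - r$percent_correct,
                                           n_trials = n_trials)
  }
  do.call(rbind, rows)
}

#' Reconstructions from the k most active secondary capsules
#'
#' Orders secondary capsule types by norm (descending) and decodes the input
#' reconstruction from each of the top k capsules alone, visualising which
#' objects each capsule has segmented.
#'
#' @param model Trained `caps_model`.
#' @param frame One [stimulus_frame()].
#' @param k Number of capsules (default 3).
#' @param iterations Routing iterations.
#' @return List with `capsules` (class names, by descending norm), `norms`,
#'   and `images` (list of H x W matrices).
#' @export
top_reconstructions <- function(model, frame, k = 3,
                                iterations = model$config$routing_iterations) {
  cf <- model$config
  if (k > cf$m) stop("k exceeds the number of secondary capsule types")
  fw <- caps_forward(model, list(frame), iterations)
  ord <- order(fw$norms[1, ], decreasing = TRUE)[seq_len(k)]
  imgs <- lapply(ord, function(j) {
    mask <- rep(0, cf$m); mask[j] <- 1
    rec <- reconstruct_from_capsules(fw$v, matrix(mask, 1), model$weights,
                                     c(cf$stim$height, cf$stim$width))
    matrix(rec[1, , ], cf$stim$height, cf$stim$width)
  })
  list(capsules = cf$classes[ord], norms = fw$norms[1, ord], images = imgs)
}

# ---- statistics ------------------------------------------------------------

#' Ordinary least-squares line fit y = a x + b
#'
#' @param x,y Numeric vectors of equal length with at least two distinct x.
#' @return Object of class `line_fit`: list with `slope` (a) and `intercept`
#'   (b).
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("all x values identical; slope undefined")
  co <- stats::coef(stats::lm(y ~ x))
  structure(list(slope = unname(co[2]), intercept = unname(co[1])),
            class = "line_fit")
}

#' Two-sided two-sample t test on slopes (or any values)
#'
#' Classic Student t test (pooled variance), as used to compare per-subject
#' (or per-network) duration/iteration slopes between flanker conditions.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`.
#' @export
compare_slopes <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate (zero) variance in both groups")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Two-sided one-sample t test against a reference value
#'
#' Used to test crowding: are flanked thresholds larger than the
#' vernier-alone threshold?
#' @param values Numeric vector (>= 2 values).
#' @param reference Reference mean.
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_test <- function(values, reference) {
  stopifnot(length(values) >= 2)
  if (stats::var(values) == 0) {
    if (isTRUE(all.equal(mean(values), reference)))
      return(list(t = 0, df = length(values) - 1, p = 1))
    stop("zero variance in values; t statistic undefined")
  }
  tt <- stats::t.test(values, mu = reference)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
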