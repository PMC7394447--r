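# Human-experiment machinery on simulated observers: stimulus geometry in
# visual angle, the PEST adaptive staircase driving the vernier offset toward
# the 75%-correct point, maximum-likelihood cumulative-Gaussian threshold
# estimation, and the duration-series slope analysis.

#' Stimulus geometry of the psychophysical experiment (visual angle)
#'
#' The displayed geometry: vernier lines 40 arcmin long with a 4 arcmin
#' vertical gap at 5 degrees eccentricity, 6 arcmin fixation cross, flanker
#' lines 84 arcmin at 40 arcmin from the vernier, cuboids 58 arcmin wide with
#' 23.33 arcmin oblique edges at 135 degrees, viewed from 75 cm.
#'
#' @param vernier_length_arcmin,vernier_gap_arcmin,eccentricity_deg,
#'   fixation_arcmin,flanker_length_arcmin,flanker_dist_arcmin,
#'   cuboid_width_arcmin,oblique_angle_deg,oblique_length_arcmin,
#'   viewing_distance_cm Geometry values.
#' @return Object of class `geometry_spec`.
#' @export
geometry_spec <- function(vernier_length_arcmin = 40,
                          vernier_gap_arcmin = 4,
                          eccentricity_deg = 5,
                          fixation_arcmin = 6,
                          flanker_length_arcmin = 84,
                          flanker_dist_arcmin = 40,
                          cuboid_width_arcmin = 58,
                          oblique_angle_deg = 135,
                          oblique_length_arcmin = 23.33,
                          viewing_distance_cm = 75) {
  g <- list(vernier_length_arcmin = vernier_length_arcmin,
            vernier_gap_arcmin = vernier_gap_arcmin,
            eccentricity_deg = eccentricity_deg,
            fixation_arcmin = fixation_arcmin,
            flanker_length_arcmin = flanker_length_arcmin,
            flanker_dist_arcmin = flanker_dist_arcmin,
            cuboid_width_arcmin = cuboid_width_arcmin,
            oblique_angle_deg = oblique_angle_deg,
            oblique_length_arcmin = oblique_length_arcmin,
            viewing_distance_cm = viewing_distance_cm)
  stopifnot(all(unlist(g) > 0))
  structure(g, class = "geometry_spec")
}

#' Convert arcmin to degrees (1 degree = 60 arcmin)
#' @param arcmin Numeric.
#' @return Degrees.
#' @export
arcmin_to_deg <- function(arcmin) arcmin / 60

#' PEST staircase configuration
#'
#' Start offset 16.66 arcmin; offsets are capped at 33.3 arcmin (twice the
#' starting value); blocks of 80 trials, each condition measured twice (160
#' trials). Step rules (initial step, halving on reversals, doubling after
#' repeated same-direction steps, Wald deviation limit) follow the classic
#' PEST prescription; only target, start and cap are fixed by the
#' experimental design.
#'
#' @param target Target proportion correct (0.75).
#' @param start_offset Starting offset (arcmin).
#' @param max_offset Offset cap; defaults to twice the start.
#' @param block_length Trials per block.
#' @param n_blocks Blocks per condition (staircase restarts each block).
#' @param initial_step Initial step size (arcmin).
#' @param min_step Smallest step (arcmin).
#' @param max_step Largest step (arcmin).
#' @param min_offset Smallest presentable offset (arcmin).
#' @param wald_w Wald sequential-test deviation limit (in trials).
#' @param omission_rate Probability a simulated observer omits the response
#'   (omissions are scored incorrect, as in the experiment).
#' @return Object of class `staircase_config`.
#' @export
staircase_config <- function(target = 0.75, start_offset = 16.66,
                             max_offset = 2 * start_offset,
                             block_length = 80, n_blocks = 2,
                             initial_step = 8, min_step = 0.25,
                             max_step = 16, min_offset = 0.25,
                             wald_w = 1, omission_rate = 0) {
  stopifnot(target > 0.5, target < 1, start_offset > 0,
            max_offset >= start_offset, block_length >= 1, n_blocks >= 1,
            initial_step > 0, min_step > 0, min_offset > 0,
            omission_rate >= 0, omission_rate < 1)
  structure(list(target = target, start_offset = start_offset,
                 max_offset = max_offset, block_length = block_length,
                 n_blocks = n_blocks, total = block_length * n_blocks,
                 initial_step = initial_step, min_step = min_step,
                 max_step = max_step, min_offset = min_offset,
                 wald_w = wald_w, omission_rate = omission_rate),
            class = "staircase_config")
}

#' Simulated 2AFC observer
#'
#' Returns a response function mapping vernier offset (arcmin) to the
#' probability of a correct direction report:
#' `p(o) = 0.5 + (0.5 - lapse) * Phi((o - shift) / spread)`, with `shift`
#' chosen so that accuracy is exactly 0.75 at `true_threshold`. Accuracy
#' tends to the 0.5 chance floor for vanishing offsets and is monotone
#' increasing in the offset.
#'
#' @param true_threshold Offset (arcmin) at which true accuracy is 75%.
#' @param spread Psychometric spread (arcmin), > 0.
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @return Function `function(offset) p_correct`, with attributes
#'   `true_threshold`, `spread`, `lapse`.
#' @export
make_simulated_observer <- function(true_threshold, spread, lapse = 0) {
  stopifnot(spread > 0, lapse >= 0, lapse <= 0.1)
  shift <- true_threshold - spread * stats::qnorm(0.25 / (0.5 - lapse))
  f <- function(offset)
    0.5 + (0.5 - lapse) * stats::pnorm((offset - shift) / spread)
  attr(f, "true_threshold") <- true_threshold
  attr(f, "spread") <- spread
  attr(f, "lapse") <- lapse
  f
}

#' Run the PEST adaptive staircase on an observer
#'
#' Implements the classic PEST rules: trials are run at the current offset
#' until a Wald sequential test decides performance is above or below the
#' target proportion (deviation limit `wald_w` trials); the offset then moves
#' down or up. Step sizes halve on every reversal, stay constant on the
#' second step in the same direction, and double from the third step onward
#' (unless the preceding reversal followed a doubled step). Offsets never
#' exceed the cap. Each block restarts the staircase; the trial count is
#' exactly `config$total`.
#'
#' @param observer Response function (offset -> probability correct),
#'   monotone increasing (a warning is issued if a decreasing trend is
#'   detected).
#' @param config A [staircase_config()].
#' @param seed Optional seed.
#' @return Data frame of trial records: block, trial, offset_arcmin,
#'   direction, response, correct.
#' @export
run_pest <- function(observer, config = staircase_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (observer(config$max_offset) < observer(config$min_offset))
    warning("observer accuracy decreases with offset; psychometric fit may fail")
  recs <- vector("list", config$n_blocks)
  for (blk in seq_len(config$n_blocks)) {
    level <- config$start_offset
    step <- config$initial_step
    dir_prev <- 0L       # -1 down, +1 up, 0 none yet
    run_len <- 0L        # consecutive steps in the same direction
    doubled_last <- FALSE
    post_double_reversal <- FALSE
    n_here <- 0L; c_here <- 0L
    offset <- numeric(config$block_length)
    direction <- character(config$block_length)
    response <- character(config$block_length)
    correct <- logical(config$block_length)
    for (t in seq_len(config$block_length)) {
      offset[t] <- level
      direction[t] <- sample(c("left", "right"), 1)
      omitted <- stats::runif(1) < config$omission_rate
      if (omitted) {
        response[t] <- "omitted"; correct[t] <- FALSE
      } else {
        ok <- stats::runif(1) < observer(level)
        response[t] <- if (ok) direction[t] else
          setdiff(c("left", "right"), direction[t])
        correct[t] <- ok
      }
      n_here <- n_here + 1L; c_here <- c_here + correct[t]
      # Wald sequential test at the current level
      exp_c <- config$target * n_here
      move <- 0L
      if (c_here >= exp_c + config$wald_w) move <- -1L   # too good: decrease
      if (c_here <= exp_c - config$wald_w) move <- +1L   # too poor: increase
      if (move != 0L) {
        if (dir_prev == 0L) {                  # first step
          run_len <- 1L
        } else if (move == dir_prev) {         # same direction
          run_len <- run_len + 1L
          if (run_len == 2L) {
            # same size
          } else if (run_len == 3L && post_double_reversal) {
            post_double_reversal <- FALSE      # wait one extra step
          } else {
            step <- min(step * 2, config$max_step)
            doubled_last <- TRUE
          }
        } else {                               # reversal: halve
          post_double_reversal <- doubled_last
          doubled_last <- FALSE
          step <- max(step / 2, config$min_step)
          run_len <- 1L
        }
        dir_prev <- move
        level <- min(max(level + move * step, config$min_offset),
                     config$max_offset)
        n_here <- 0L; c_here <- 0L
      }
    }
    recs[[blk]] <- data.frame(block = blk, trial = seq_len(config$block_length),
                              offset_arcmin = offset, direction = direction,
                              response = response, correct = correct)
  }
  do.call(rbind, recs)
}

#' Psychometric fit result
#' @param mu,sigma Cumulative-Gaussian parameters.
#' @param threshold Offset at the target proportion correct.
#' @param guess Guess rate used in the parameterisation.
#' @param target Target proportion.
#' @param loglik Maximised log likelihood.
#' @return Object of class `psychometric_fit`.
#' @keywords internal
.psychometric_fit <- function(mu, sigma, threshold, guess, target, loglik) {
  structure(list(mu = mu, sigma = sigma, threshold = threshold,
                 guess = guess, target = target, loglik = loglik),
            class = "psychometric_fit")
}

#' Fit a cumulative Gaussian to staircase trial records
#'
#' Maximum-likelihood probit fit of
#' `p(correct | x) = guess + (1 - guess) * Phi((x - mu) / sigma)` to binary
#' outcomes; the threshold is the offset at which the fitted proportion
#' correct equals `target`:
#' `threshold = mu + sigma * qnorm((target - guess) / (1 - guess))`
#' (for the 2AFC guess rate 0.5 and target 0.75 this reduces to `mu`; for a
#' plain cumulative Gaussian, `guess = 0`, it is `mu + 0.6745 sigma`).
#'
#' @param trials Data frame with columns `offset_arcmin` and `correct` (as
#'   from [run_pest()]), or vectors via `offset`/`correct`.
#' @param guess Guess rate (0.5 for 2AFC).
#' @param target Target proportion (0.75).
#' @param lapse Fixed lapse rate (0 by default).
#' @return A `psychometric_fit` with fields `mu`, `sigma`, `threshold`.
#' @export
fit_psychometric <- function(trials, guess = 0.5, target = 0.75, lapse = 0) {
  x <- trials$offset_arcmin; k <- as.numeric(trials$correct)
  stopifnot(length(x) == length(k), all(k %in% c(0, 1)))
  if (length(unique(x)) < 2)
    stop("trials must span at least two offset levels")
  if (all(k == 1) || all(k == 0))
    stop("perfect separation (all responses ",
         if (all(k == 1)) "correct" else "incorrect",
         "); cumulative-Gaussian fit does not converge")
  upper <- 1 - lapse
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- guess + (upper - guess) * stats::pnorm((x - mu) / sigma)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(k * log(p) + (1 - k) * log(1 - p))
  }
  init <- c(stats::median(x), log(max(stats::sd(x), 1)))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 500))  # polish
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  thr <- mu + sigma * stats::qnorm((target - guess) / (upper - guess))
  .psychometric_fit(mu, sigma, thr, guess, target, -opt$value)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit mu=%.3f sigma=%.3f threshold(%.0f%%)=%.3f>\n",
              x$mu, x$sigma, 100 * x$target, x$threshold))
  invisible(x)
}

#' Estimate a threshold for one condition: staircase + fit
#'
#' Convenience wrapper: runs the PEST staircase on an observer and returns
#' the fitted threshold.
#' @param observer Response function.
#' @param config A [staircase_config()].
#' @param seed Optional seed.
#' @return The fitted threshold (arcmin).
#' @export
estimate_threshold <- function(observer, config = staircase_config(),
                               seed = NULL) {
  trials <- run_pest(observer, config, seed)
  fit_psychometric(trials, guess = 0.5, target = config$target)$threshold
}

#' Duration-series slope analysis
#'
#' For each subject and condition, fits a line `threshold = a * duration + b`
#' and compares the slopes `a` between two flanker conditions with a
#' two-sample t test; additionally tests, per condition, whether thresholds
#' at the shortest duration exceed the vernier-alone reference (crowding).
#'
#' @param thresholds Data frame with columns `subject`, `condition`,
#'   `duration`, `threshold`.
#' @param conditions Length-2 character vector of conditions whose slopes are
#'   compared (default lines vs cuboids).
#' @param reference Vernier-alone reference threshold (scalar), or NULL to
#'   skip the crowding tests.
#' @return List with `slopes` (data frame subject x condition), `slope_test`
#'   (from [compare_slopes()]), and `crowding_tests` (one
#'   [one_sample_test()] per condition at the shortest duration).
#' @export
duration_series_analysis <- function(thresholds,
                                     conditions = c("lines", "cuboids"),
                                     reference = NULL) {
  stopifnot(all(c("subject", "condition", "duration", "threshold") %in%
                  names(thresholds)))
  sub <- thresholds[thresholds$condition %in% conditions, ]
  sl <- do.call(rbind, lapply(split(sub, list(sub$subject, sub$condition),
                                    drop = TRUE), function(dd) {
    if (length(unique(dd$duration)) < 2) stop("need >= 2 durations per subject")
    f <- fit_line(dd$duration, dd$threshold)
    data.frame(subject = dd$subject[1], condition = dd$condition[1],
               slope = f$slope, intercept = f$intercept)
  }))
  rownames(sl) <- NULL
  a <- sl$slope[sl$condition == conditions[1]]
  b <- sl$slope[sl$condition == conditions[2]]
  out <- list(slopes = sl, slope_test = compare_slopes(a, b))
  if (!is.null(reference)) {
    dmin <- min(sub$duration)
    out$crowding_tests <- lapply(stats::setNames(conditions, conditions),
      function(cc) {
        v <- sub$threshold[sub$condition == cc & sub$duration == dmin]
        one_sample_test(v, reference)
      })
  }
  out
}
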