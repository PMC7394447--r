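# End-to-end training: Adam with cosine-decay warm restarts, ensemble
# training with per-network seeds, and the experiment-2 exclusion rule.

#' Training configuration
#'
#' Batch size 48 and learning rate 0.0004 are the published values; the
#' cosine-restart period, step count and dataset size are package choices
#' (the originals are in unpublished supplementary tables) and are exposed
#' here. Scaled-down runs shrink `steps` and `dataset_size`, never the
#' optimiser constants.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Base Adam learning rate.
#' @param steps Number of optimisation steps.
#' @param restart_period Steps in the first cosine period.
#' @param restart_mult Period multiplier after each warm restart.
#' @param dataset_size Training frames generated per network.
#' @param seed Base seed.
#' @param routing_iterations_train Routing iterations during training
#'   (experiment 2 uses 8).
#' @param aug An [aug_config()] applied afresh to every sampled frame each
#'   step (so the network never sees the same noise twice), or NULL if the
#'   dataset is already augmented.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 48, learning_rate = 4e-4,
                         steps = 2000, restart_period = 500,
                         restart_mult = 2, dataset_size = 4000,
                         seed = 1L, routing_iterations_train = NULL,
                         aug = aug_config()) {
  stopifnot(batch_size >= 1, learning_rate > 0, steps >= 1,
            restart_period >= 1, restart_mult >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, steps = as.integer(steps),
                 restart_period = restart_period, restart_mult = restart_mult,
                 dataset_size = as.integer(dataset_size), seed = as.integer(seed),
                 routing_iterations_train = routing_iterations_train,
                 aug = aug),
            class = "train_config")
}

#' Cosine-decay learning-rate schedule with warm restarts
#'
#' Within each restart period the rate decays from the base rate along a
#' half cosine; at every restart boundary it returns to the base rate.
#' Periods grow by `restart_mult` after each restart.
#'
#' @param step 0-based step index.
#' @param config A [train_config()].
#' @return Learning rate at `step`.
#' @export
lr_schedule <- function(step, config = train_config()) {
  stopifnot(all(step >= 0))
  vapply(step, function(s) {
    t_cur <- s; period <- config$restart_period
    while (t_cur >= period) {
      t_cur <- t_cur - period
      period <- period * config$restart_mult
    }
    config$learning_rate * 0.5 * (1 + cos(pi * t_cur / period))
  }, 0)
}

#' Train one network
#'
#' Runs Adam over minibatches sampled from `dataset` (a list of training
#' frames, or a generator `function(n)` returning `n` fresh frames). The
#' dataset must come from [build_training_set()]: it never contains
#' (un)crowding compositions, which is asserted here.
#'
#' @param model A `caps_model` or `alt_model`.
#' @param dataset List of [stimulus_frame()]s or generator function.
#' @param config A [train_config()].
#' @param verbose Print progress every 100 steps.
#' @return List with `model` (trained) and `history` (data frame with one row
#'   per step: step, lr, L_shape, L_vernier, L_reps, L_recon, L_loc,
#'   L_total).
#' @export
train_one <- function(model, dataset, config = train_config(), verbose = FALSE) {
  is_gen <- is.function(dataset)
  if (!is_gen) {
    stopifnot(length(dataset) >= 1)
    bad <- vapply(dataset, function(f)
      f$vernier_offset != "none" && f$shape_class != "vernier", TRUE)
    if (any(bad))
      stop("training dataset contains vernier+flanker compositions")
  }
  step_fn <- if (inherits(model, "caps_model")) .caps_step else .alt_step
  iters <- config$routing_iterations_train
  if (is.null(iters))
    iters <- if (inherits(model, "caps_model")) model$config$routing_iterations
             else model$config$recurrent_iterations
  adam <- .adam_init(model$weights)
  hist <- matrix(NA_real_, config$steps, 8,
                 dimnames = list(NULL, c("step", "lr", "L_shape", "L_vernier",
                                         "L_reps", "L_recon", "L_loc", "L_total")))
  for (s in seq_len(config$steps)) {
    batch <- if (is_gen) dataset(config$batch_size)
             else dataset[sample.int(length(dataset), config$batch_size, replace = TRUE)]
    if (!is.null(config$aug))
      batch <- lapply(batch, augment_frame, config = config$aug)
    st <- step_fn(model, batch, iters)
    if (!is.finite(st$losses[["total"]]))
      stop(sprintf("training diverged at step %d (total loss %s)", s,
                   format(st$losses[["total"]])))
    lr <- lr_schedule(s - 1L, config)
    upd <- .adam_step(model$weights, st$grads, adam, lr)
    model$weights <- upd$weights; adam <- upd$state
    hist[s, ] <- c(s, lr,
                   st$losses[["shape_type"]], st$losses[["vernier_offset"]],
                   st$losses[["shape_repetitions"]], st$losses[["reconstruction"]],
                   st$losses[["location"]], st$losses[["total"]])
    if (verbose && s %% 100 == 0)
      message(sprintf("step %4d  lr %.2e  total %.4f  vernier %.4f",
                      s, lr, hist[s, "L_total"], hist[s, "L_vernier"]))
  }
  model$trained <- TRUE
  list(model = model, history = as.data.frame(hist))
}

#' Train an ensemble of networks
#'
#' Independent initialisations and training runs, one per seed (matching the
#' paper's practice of training N networks to mimic N observers: 10 in
#' experiment 1, 50 in experiment 2). Failed runs are logged and skipped so
#' surviving networks are still reported.
#'
#' @param model_factory `function(seed)` returning a fresh model.
#' @param dataset_factory `function(seed)` returning a dataset or generator
#'   for [train_one()].
#' @param config A [train_config()].
#' @param n_networks Ensemble size.
#' @param seeds Distinct integer seeds, default `config$seed + 0:(n-1)`.
#' @param verbose Forwarded to [train_one()].
#' @return Object of class `ensemble_result`: lists `models`, `histories`,
#'   vectors `seeds`, `failed`, and `excluded` (all FALSE until
#'   [exclusion_filter()] is applied).
#' @export
train_ensemble <- function(model_factory, dataset_factory,
                           config = train_config(), n_networks,
                           seeds = config$seed + seq_len(n_networks) - 1L,
                           verbose = FALSE) {
  stopifnot(length(seeds) == n_networks, !anyDuplicated(seeds))
  models <- vector("list", n_networks)
  histories <- vector("list", n_networks)
  failed <- logical(n_networks)
  for (i in seq_len(n_networks)) {
    res <- tryCatch({
      m <- model_factory(seeds[i])
      ds <- dataset_factory(seeds[i])
      train_one(m, ds, config, verbose = verbose)
    }, error = function(e) {
      warning(sprintf("network %d (seed %d) failed: %s", i, seeds[i],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed[i] <- TRUE
    else { models[[i]] <- res$model; histories[[i]] <- res$history }
  }
  structure(list(models = models, histories = histories, seeds = seeds,
                 failed = failed, excluded = rep(FALSE, n_networks)),
            class = "ensemble_result")
}

#' Experiment-2 network exclusion rule
#'
#' A network is excluded if and only if its vernier discrimination accuracy
#' is at ceiling (>= 95%) for BOTH the line and cuboid flanker conditions, or
#' at floor (<= 55%) for both.
#'
#' @param ensemble An `ensemble_result`, or `NULL` to just compute flags.
#' @param accuracies Data frame (or matrix) with columns `lines` and
#'   `cuboids`: percent correct per network.
#' @return The ensemble with its `excluded` flags set (and the flags as
#'   attribute `flags`), or the logical flag vector when `ensemble` is NULL.
#' @export
exclusion_filter <- function(ensemble = NULL, accuracies) {
  if (is.null(accuracies) || !all(c("lines", "cuboids") %in% colnames(accuracies)))
    stop("accuracies must contain 'lines' and 'cuboids' columns")
  li <- accuracies[, "lines"]; cu <- accuracies[, "cuboids"]
  if (anyNA(li) || anyNA(cu)) stop("missing condition accuracy")
  flags <- (li >= 95 & cu >= 95) | (li <= 55 & cu <= 55)
  if (is.null(ensemble)) return(flags)
  stopifnot(inherits(ensemble, "ensemble_result"),
            length(flags) == length(ensemble$models))
  ensemble$excluded <- as.vector(flags)
  attr(ensemble, "flags") <- flags
  ensemble
}

#' Save / load a trained model
#'
#' Weights go into an RDS checkpoint; the architecture is echoed into a JSON
#' sidecar for reproducibility.
#' @param model A model object.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model`: invisibly, the sidecar path. `load_model`: the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  cf <- model$config
  jsonlite::write_json(list(arch = model$arch, experiment = cf$experiment,
                            classes = cf$classes, m = cf$m, n = cf$n, d = cf$d,
                            routing_iterations = cf$routing_iterations,
                            canvas = c(cf$stim$height, cf$stim$width),
                            trained = model$trained),
                       side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
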