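# Shared fixtures and independent oracles used across the test files.

small_stim <- stim_config_small(1)
small_stim2 <- stim_config_small(2)
small_caps <- caps_config_small(small_stim)
small_caps2 <- caps_config_small(small_stim2)
# fully end-to-end variant (no stop-gradient): exact-gradient contract for
# the numerical gradient checks
small_caps_e2e <- caps_config_small(small_stim, vernier_ce_stopgrad = FALSE)

# --- independent routing oracle: naive scalar loops, no shared code paths ---
# votes: array (n_children, d, n_parents) for ONE sample
oracle_route <- function(votes, iterations) {
  nc <- dim(votes)[1]; d <- dim(votes)[2]; mp <- dim(votes)[3]
  squash1 <- function(s) {
    r <- sqrt(sum(s^2))
    if (r == 0) return(s)
    s * (r / (1 + r^2))
  }
  b <- matrix(0, nc, mp)
  v <- matrix(0, mp, d)
  cpl <- NULL
  for (it in seq_len(iterations)) {
    cpl <- matrix(0, nc, mp)
    for (i in seq_len(nc)) cpl[i, ] <- exp(b[i, ]) / sum(exp(b[i, ]))
    for (j in seq_len(mp)) {
      s <- rep(0, d)
      for (i in seq_len(nc)) s <- s + cpl[i, j] * votes[i, , j]
      v[j, ] <- squash1(s)
    }
    if (it < iterations)
      for (i in seq_len(nc)) for (j in seq_len(mp))
        b[i, j] <- b[i, j] + sum(votes[i, , j] * v[j, ])
  }
  list(v = v, couplings = cpl)
}

# --- independent cross-entropy oracle (log-sum-exp form) ---
oracle_xent <- function(scores, target_idx) {
  m <- max(scores)
  -(scores[target_idx] - m - log(sum(exp(scores - m))))
}

# mock model whose vernier decoder is an arbitrary score function
mock_model <- function(score_fn, stim = small_stim) {
  structure(list(score_fn = score_fn, trained = TRUE,
                 config = list(stim = stim, routing_iterations = 1L)),
            class = "mock_model")
}

# count of non-background pixels in a frame
px_count <- function(frame) sum(frame$image > 0)

# fast, tiny training run used by several tests
tiny_train <- function(arch = "capsnet", steps = 30, seed = 7, experiment = 1) {
  stim <- if (experiment == 1) small_stim else small_stim2
  cfgc <- if (experiment == 1) small_caps else small_caps2
  model <- if (arch == "capsnet") init_caps_model(cfgc, seed = seed)
           else init_alt_model(alt_config(cfgc, head_kind = arch), seed = seed)
  ds <- build_training_set(experiment, 120, stim, seed = seed + 1)
  train_one(model, ds,
            train_config(batch_size = 8, steps = steps, restart_period = steps,
                         dataset_size = 120, seed = seed))
}
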