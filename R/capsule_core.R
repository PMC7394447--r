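# Capsule network forward computation: two ELU convolutions, a third
# convolution reshaped into m primary capsule types of dimension n, and
# recurrent routing-by-agreement into m secondary capsules of dimension d.
#
# Feature-map layout follows nn_ops.R: matrices (npos * batch, channels).
# Primary capsules are held as arrays (npos3 * batch, n, m); the routing
# child index runs over (position, batch, type) with position fastest.

#' Capsule network configuration
#'
#' Architecture hyperparameters. The number of capsule types `m` equals the
#' number of stimulus classes (7 in experiment 1: six shapes plus the
#' vernier; 4 in experiment 2), and the secondary capsule type count equals
#' the class count. Primary-capsule receptive fields are sized to roughly
#' match one shape. Kernel sizes, channel counts and capsule dimensions are
#' not fixed by the scientific design and are all exposed here.
#'
#' @param stim A [stim_config()]; supplies canvas size and class set.
#' @param conv1,conv2 Lists `list(k =, c =, s =)`: kernel, channels, stride
#'   of the two feature-extraction convolutions (ELU nonlinearity, no
#'   padding).
#' @param caps_kernel,caps_stride Geometry of the third convolution that is
#'   reshaped into primary capsules.
#' @param n Primary capsule dimension.
#' @param d Secondary capsule dimension.
#' @param routing_iterations Routing iterations used during training (also
#'   the default at test time); 8 for experiment 2, 3 for experiment 1.
#' @param vernier_hidden Hidden units of the vernier-offset decoder.
#' @param rep_hidden Hidden units of the shape-repetition decoder.
#' @param recon_hidden Two hidden-layer sizes of the reconstruction decoder.
#' @param vernier_ce_stopgrad If TRUE (default), "no vernier" frames train
#'   the offset decoder readout but their cross-entropy gradient is stopped
#'   at the capsule layer (trunk). At the package's CPU training scale a
#'   fully end-to-end "none" gradient drives the vernier capsule into a
#'   saturated always-on state that defeats the margin loss; see the methods
#'   vignette.
#' @return Object of class `caps_config`.
#' @export
caps_config <- function(stim = stim_config(),
                        conv1 = list(k = 5, c = 16, s = 2),
                        conv2 = list(k = 5, c = 16, s = 2),
                        caps_kernel = 3, caps_stride = 1,
                        n = 8, d = 16,
                        routing_iterations = if (stim$experiment == 2) 8L else 3L,
                        vernier_hidden = 64,
                        rep_hidden = 64,
                        recon_hidden = c(512, 1024),
                        vernier_ce_stopgrad = TRUE) {
  classes <- training_classes(stim$experiment, stim)
  m <- length(classes)
  p1 <- .plan_conv(stim$height, stim$width, conv1$k, conv1$s, "conv1")
  p2 <- .plan_conv(p1$h_out, p1$w_out, conv2$k, conv2$s, "conv2")
  p3 <- .plan_conv(p2$h_out, p2$w_out, caps_kernel, caps_stride, "primary-capsule conv")
  stopifnot(routing_iterations >= 1)
  structure(list(stim = stim, experiment = stim$experiment,
                 classes = classes, m = m, n = n, d = d,
                 conv1 = conv1, conv2 = conv2,
                 caps_kernel = caps_kernel, caps_stride = caps_stride,
                 routing_iterations = as.integer(routing_iterations),
                 vernier_hidden = vernier_hidden, rep_hidden = rep_hidden,
                 recon_hidden = recon_hidden,
                 vernier_ce_stopgrad = isTRUE(vernier_ce_stopgrad),
                 plans = list(p1, p2, p3),
                 npos3 = p3$npos_out,
                 n_children = p3$npos_out * m),
            class = "caps_config")
}

#' Small capsule configuration paired with [stim_config_small()]
#'
#' Scaled down so that one network trains in well under a minute on one CPU;
#' used by the test suite and the scaled-down acceptance runs.
#' @param stim A small `stim_config`.
#' @param ... Overrides passed to [caps_config()].
#' @return A `caps_config`.
#' @export
caps_config_small <- function(stim = stim_config_small(), ...) {
  caps_config(stim = stim,
              conv1 = list(k = 3, c = 12, s = 2),
              conv2 = list(k = 3, c = 16, s = 2),
              caps_kernel = 3, caps_stride = 1,
              n = 6, d = 8,
              vernier_hidden = 32, rep_hidden = 32,
              recon_hidden = c(96, 192), ...)
}

# ---- squash ----------------------------------------------------------------

#' Squash nonlinearity
#'
#' Scales a vector (or each row of a matrix) to norm
#' `||s||^2 / (1 + ||s||^2)` while preserving direction, bounding every
#' capsule norm in `[0, 1)`. The zero vector is a fixed point; a unit vector
#' maps to half itself.
#'
#' @param s Numeric vector, or matrix with one capsule vector per row.
#' @return Same shape as `s`.
#' @export
squash <- function(s) {
  if (is.matrix(s)) {
    r <- sqrt(rowSums(s * s))
    s * (r / (1 + r^2))   # column-major recycling scales each row
  } else {
    r <- sqrt(sum(s * s))
    s * (r / (1 + r^2))
  }
}

# backward through squash for row-wise matrices: given s (rows = capsules)
# and upstream gradient g wrt squash(s), return gradient wrt s.
.squash_backward <- function(s, g) {
  r2 <- rowSums(s * s); r <- sqrt(r2)
  w <- r / (1 + r2)
  wp <- (1 - r2) / (1 + r2)^2                    # dw/dr
  coef <- (r > 1e-12) * wp / pmax(r, 1e-12)      # (s.g) s term vanishes as r -> 0
  g * w + s * (coef * rowSums(s * g))
}

# ---- layers ----------------------------------------------------------------

#' Convolutional feature extraction
#'
#' Two valid (no padding) convolutions, each followed by an ELU.
#'
#' @param x Image matrix in canonical layout `(H*W*batch, 1)` (see
#'   [.stack_images()] users) or a single image matrix `(H, W)`.
#' @param weights Model weight list containing `W1, b1, W2, b2`.
#' @param config A [caps_config()].
#' @param batch Batch size.
#' @return List with `out` (feature maps after conv2+ELU) and `cache`.
#' @keywords internal
#' @export
conv_features <- function(x, weights, config, batch = 1L) {
  if (is.matrix(x) && ncol(x) > 1) { # a raw single image (H, W)
    stopifnot(batch == 1L)
    x <- matrix(as.vector(x), ncol = 1)
  }
  p <- config$plans
  c1 <- .conv_forward(x, weights$W1, weights$b1, p[[1]], batch)
  a1 <- .elu(c1$out)
  c2 <- .conv_forward(a1, weights$W2, weights$b2, p[[2]], batch)
  a2 <- .elu(c2$out)
  list(out = a2,
       cache = list(x = x, c1 = c1, a1 = a1, c2 = c2, batch = batch))
}

#' Form primary capsules from the third convolution
#'
#' Applies the primary-capsule convolution (m*n output channels), reshapes
#' its output into m capsule types of dimension n per spatial position, and
#' squashes each capsule vector.
#'
#' @param feat Feature maps from [conv_features()].
#' @param weights Model weights (`W3`, `b3`).
#' @param config A [caps_config()].
#' @param batch Batch size.
#' @return List with `u` (squashed primary capsules, array
#'   `(npos3*batch, n, m)`) and `cache`.
#' @keywords internal
#' @export
form_primary_capsules <- function(feat, weights, config, batch = 1L) {
  if (ncol(weights$W3) %% (config$m * config$n) != 0)
    stop("primary-capsule convolution channels not divisible by m * n")
  c3 <- .conv_forward(feat, weights$W3, weights$b3, config$plans[[3]], batch)
  pre <- c3$out                              # (npos3*B, m*n), n fastest
  u_raw <- pre
  dim(u_raw) <- c(nrow(pre), config$n, config$m)
  u <- u_raw
  for (i in seq_len(config$m)) u[, , i] <- squash(u_raw[, , i])
  list(u = u, cache = list(c3 = c3, u_raw = u_raw))
}

#' Predict secondary-capsule votes
#'
#' One learned linear map per (child capsule type, parent type) pair, shared
#' across spatial positions, sends each n-dimensional primary capsule to a
#' d-dimensional vote for every parent.
#'
#' @param u Primary capsules, array `(npos3*batch, n, m)`.
#' @param Wv Vote weights, array `(n, d, m_child, m_parent)`.
#' @return Votes as array `(K, d, m_parent)` with child rows ordered
#'   (position, batch, type), K = npos3 * batch * m_child.
#' @keywords internal
#' @export
predict_votes <- function(u, Wv) {
  pb <- dim(u)[1]; n <- dim(u)[2]; m <- dim(u)[3]
  stopifnot(dim(Wv)[1] == n)
  d <- dim(Wv)[2]; mp <- dim(Wv)[4]
  V <- array(0, c(pb * m, d * mp))
  for (i in seq_len(m)) {
    rows <- ((i - 1) * pb + 1):(i * pb)
    V[rows, ] <- u[, , i] %*% matrix(Wv[, , i, ], n, d * mp)
  }
  dim(V) <- c(pb * m, d, mp)
  V
}

# ---- routing ---------------------------------------------------------------

# batched routing core. V: (K, d, mp); b_index: batch id per child row.
.route <- function(V, iterations, b_index, n_batch) {
  if (iterations < 1) stop("routing iterations must be >= 1")
  K <- dim(V)[1]; d <- dim(V)[2]; mp <- dim(V)[3]
  # 0/1 aggregation matrix: child row -> batch sample (BLAS-friendly rowsum)
  G <- matrix(0, K, n_batch)
  G[cbind(seq_len(K), b_index)] <- 1
  Dsum <- matrix(0, d * mp, mp)       # block column sums over d within parent
  for (j in seq_len(mp)) Dsum[((j - 1) * d + 1):(j * d), j] <- 1
  Vm <- V; dim(Vm) <- c(K, d * mp)
  jexp <- rep(seq_len(mp), each = d)
  logits <- matrix(0, K, mp)
  cpl <- NULL; s <- NULL; v <- NULL
  for (it in seq_len(iterations)) {
    mx <- logits[, 1]
    if (mp > 1) for (j in 2:mp) mx <- pmax(mx, logits[, j])
    e <- exp(logits - mx)
    cpl <- e / rowSums(e)
    s <- crossprod(G, Vm * cpl[, jexp])          # (B, d*mp)
    v <- s
    dim(s) <- c(n_batch, d, mp); dim(v) <- c(n_batch, d, mp)
    for (j in seq_len(mp)) v[, , j] <- squash(s[, , j])
    if (it < iterations) {
      vm <- v; dim(vm) <- c(n_batch, d * mp)
      logits <- logits + (Vm * (G %*% vm)) %*% Dsum
    }
  }
  list(v = v, s = s, couplings = cpl, logits = logits)
}

#' Route votes into secondary capsules by agreement
#'
#' Implements the published routing algorithm: coupling coefficients are the
#' softmax (over parents) of routing logits initialised at zero; each
#' parent's pre-activation is the coupling-weighted sum of votes, squashed to
#' give its output; logits are incremented by the scalar product between each
#' vote and the parent output on every iteration after the first.
#'
#' @param votes Array `(n_children, d, n_parents)` for one sample, or the
#'   batched `(K, d, n_parents)` layout of [predict_votes()] together with
#'   `b_index`.
#' @param iterations Number of routing iterations (>= 1); 1 is the purely
#'   feedforward regime with uniform couplings.
#' @param b_index Optional batch index per child row (defaults to a single
#'   sample).
#' @param n_batch Number of samples.
#' @return List with `v` (secondary capsules, array `(n_batch, d,
#'   n_parents)`), `s` (pre-squash sums), and `couplings` (rows sum to 1
#'   across parents).
#' @export
route_capsules <- function(votes, iterations, b_index = NULL, n_batch = 1L) {
  stopifnot(length(dim(votes)) == 3)
  if (is.null(b_index)) b_index <- rep(1L, dim(votes)[1])
  .route(votes, iterations, b_index, n_batch)
}

# ---- full capsule-network forward -----------------------------------------

# forward pass through convs, primary capsules, votes and routing.
# Returns secondary capsules plus caches for backprop when keep_cache = TRUE.
.caps_trunk_forward <- function(weights, x, config, batch, iterations,
                                keep_cache = FALSE) {
  feat <- conv_features(x, weights, config, batch)
  prim <- form_primary_capsules(feat$out, weights, config, batch)
  V <- predict_votes(prim$u, weights$Wv)
  pb <- config$npos3 * batch
  b_index <- rep(rep(seq_len(batch), each = config$npos3), times = config$m)
  rt <- .route(V, iterations, b_index, batch)
  out <- list(v = rt$v,                              # (B, d, m)
              norms = sqrt(apply(rt$v^2, c(1, 3), sum)),
              couplings = rt$couplings)
  if (is.matrix(out$norms) == FALSE) out$norms <- matrix(out$norms, batch, config$m)
  if (keep_cache)
    out$cache <- list(feat = feat$cache, prim = prim$cache, u = prim$u,
                      V = V, rt = rt, b_index = b_index, batch = batch)
  out
}

# backward from gradient on secondary capsules (B, d, m) down to all weights.
# Couplings are treated as constants (stop-gradient through the routing
# logits); exact for 1 iteration, an approximation otherwise.
.caps_trunk_backward <- function(weights, config, cache, grad_v) {
  batch <- cache$batch
  m <- config$m; n <- config$n; d <- config$d
  pb <- config$npos3 * batch
  V <- cache$V; rt <- cache$rt; b_index <- cache$b_index
  # through squash of each parent, then couplings * votes
  gV <- array(0, dim(V))
  for (j in seq_len(m)) {
    ds <- .squash_backward(matrix(rt$s[, , j], ncol = d),
                           matrix(grad_v[, , j], ncol = d))  # (B, d)
    gV[, , j] <- ds[b_index, , drop = FALSE] * rt$couplings[, j]
  }
  # votes -> primary capsules and vote weights (one GEMM per child type)
  gu <- array(0, c(pb, n, m))
  gWv <- array(0, dim(weights$Wv))
  u <- cache$u
  for (i in seq_len(m)) {
    rows <- ((i - 1) * pb + 1):(i * pb)
    gi <- gV[rows, , ]; dim(gi) <- c(pb, d * m)
    Wi <- matrix(weights$Wv[, , i, ], n, d * m)
    gu[, , i] <- gi %*% t(Wi)
    gWv[, , i, ] <- crossprod(u[, , i], gi)
  }
  # through primary squash
  u_raw <- cache$prim$u_raw
  g3 <- array(0, c(pb, n, m))
  for (i in seq_len(m)) g3[, , i] <- .squash_backward(u_raw[, , i], gu[, , i])
  dim(g3) <- c(pb, n * m)
  # conv3
  p <- config$plans
  bk3 <- .conv_backward(g3, cache$prim$c3$col, config$conv2$c, weights$W3,
                        p[[3]], batch)
  # conv2 + ELU
  g2 <- bk3$gx * .elu_grad(cache$feat$c2$out)
  bk2 <- .conv_backward(g2, cache$feat$c2$col, config$conv1$c, weights$W2,
                        p[[2]], batch)
  g1 <- bk2$gx * .elu_grad(cache$feat$c1$out)
  bk1 <- .conv_backward(g1, cache$feat$c1$col, 1L, weights$W1, p[[1]], batch)
  list(W1 = bk1$gW, b1 = bk1$gb, W2 = bk2$gW, b2 = bk2$gb,
       W3 = bk3$gW, b3 = bk3$gb, Wv = gWv)
}

# ---- weight initialisation -------------------------------------------------

.init_caps_weights <- function(config) {
  c1 <- config$conv1; c2 <- config$conv2
  m <- config$m; n <- config$n; d <- config$d
  k3 <- config$caps_kernel
  hw <- config$stim$height * config$stim$width
  flat <- m * d
  w <- list(
    W1 = .glorot(c1$k^2, c1$c), b1 = rep(0, c1$c),
    W2 = .glorot(c2$k^2 * c1$c, c2$c), b2 = rep(0, c2$c),
    W3 = .glorot(k3^2 * c2$c, m * n), b3 = rep(0, m * n),
    Wv = array(stats::rnorm(n * d * m * m, 0, sqrt(2 / (n + d))), c(n, d, m, m)),
    Vw1 = .glorot(d, config$vernier_hidden), Vb1 = rep(0, config$vernier_hidden),
    Vw2 = .glorot(config$vernier_hidden, 3), Vb2 = rep(0, 3),
    Dw1 = .glorot(flat, config$recon_hidden[1]), Db1 = rep(0, config$recon_hidden[1]),
    Dw2 = .glorot(config$recon_hidden[1], config$recon_hidden[2]),
    Db2 = rep(0, config$recon_hidden[2]),
    Dw3 = .glorot(config$recon_hidden[2], hw), Db3 = rep(0, hw)
  )
  if (config$experiment == 1) {
    w$Rw1 <- .glorot(flat, config$rep_hidden); w$Rb1 <- rep(0, config$rep_hidden)
    w$Rw2 <- .glorot(config$rep_hidden, 3); w$Rb2 <- rep(0, 3)
    w$Xw <- .glorot(flat, config$stim$width); w$Xb <- rep(0, config$stim$width)
    w$Yw <- .glorot(flat, config$stim$height); w$Yb <- rep(0, config$stim$height)
  }
  w
}

#' Initialise a capsule network
#'
#' @param config A [caps_config()].
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `caps_model` with fields `config`, `weights`,
#'   `arch = "capsnet"` and `trained`.
#' @export
init_caps_model <- function(config = caps_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = config, weights = .init_caps_weights(config),
                 arch = "capsnet", trained = FALSE),
            class = "caps_model")
}

#' Capsule network forward pass
#'
#' Deterministic given weights, input and iteration count. Secondary capsule
#' norms are strictly below 1 (squash bound). Requesting more iterations than
#' the configured training value raises a warning, not an error (iteration
#' sweeps deliberately exceed it).
#'
#' @param model A `caps_model`.
#' @param frames List of [stimulus_frame()] objects (a batch).
#' @param iterations Routing iterations (default: the configured value).
#' @param keep_cache Keep intermediate activations (needed for training).
#' @return List with `v` (secondary capsules `(B, d, m)`), `norms` `(B, m)`,
#'   `couplings`, and optionally `cache`.
#' @export
caps_forward <- function(model, frames, iterations = model$config$routing_iterations,
                         keep_cache = FALSE) {
  stopifnot(inherits(model, "caps_model"))
  if (iterations > 8)
    warning("iteration count ", iterations, " exceeds the evaluated sweep range [1, 8]")
  x <- .stack_images(frames)
  .caps_trunk_forward(model$weights, x, model$config, length(frames),
                      iterations, keep_cache)
}
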