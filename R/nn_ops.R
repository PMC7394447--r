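# Internal neural-network primitives. Feature maps are stored as matrices of
# shape (npos * batch, channels), conceptually arrays (npos, batch, channels)
# in column-major order with npos = Hout * Wout spatial positions (y fastest).
# Convolutions are "valid" (no padding) and implemented as im2col + GEMM with
# an index-based col2im for the backward pass; all gradients are hand-derived
# and verified against numerical differentiation in the test suite.

.elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
.elu_grad <- function(x) exp(pmin(x, 0))
.relu <- function(x) pmax(x, 0)
.relu_grad <- function(x) (x > 0) * 1
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-normal initialisation
.glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

# ---- convolution -----------------------------------------------------------

# Precompute valid-convolution geometry and the im2col gather indices.
.plan_conv <- function(h_in, w_in, k, stride, name = "conv") {
  if (h_in < k || w_in < k)
    stop(sprintf("input %dx%d too small for %s kernel %d", h_in, w_in, name, k))
  h_out <- (h_in - k) %/% stride + 1L
  w_out <- (w_in - k) %/% stride + 1L
  npos_out <- h_out * w_out
  oy <- rep(seq_len(h_out), times = w_out)
  ox <- rep(seq_len(w_out), each = h_out)
  iy0 <- (oy - 1L) * stride; ix0 <- (ox - 1L) * stride
  ip <- matrix(0L, npos_out, k * k)
  q <- 1L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    ip[, q] <- (iy0 + dy + 1L) + (ix0 + dx) * h_in
    q <- q + 1L
  }
  list(h_in = h_in, w_in = w_in, h_out = h_out, w_out = w_out,
       npos_in = h_in * w_in, npos_out = npos_out,
       k = k, stride = stride, ipvec = as.vector(ip))
}

# x: (npos_in * B, C_in) matrix. Returns list(out, col) with out of shape
# (npos_out * B, C_out); col retained for the backward pass.
.conv_forward <- function(x, W, b, plan, batch) {
  cin <- ncol(x); k2 <- plan$k^2
  xg <- x; dim(xg) <- c(plan$npos_in, batch * cin)
  g <- xg[plan$ipvec, , drop = FALSE]
  dim(g) <- c(plan$npos_out, k2, batch, cin)
  g <- aperm(g, c(1, 3, 2, 4))
  dim(g) <- c(plan$npos_out * batch, k2 * cin)
  out <- g %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, col = g)
}

.conv_backward <- function(grad_out, col, x_dim_cin, W, plan, batch) {
  gW <- crossprod(col, grad_out)
  gb <- colSums(grad_out)
  gcol <- grad_out %*% t(W)
  k2 <- plan$k^2; cin <- x_dim_cin
  dim(gcol) <- c(plan$npos_out, batch, k2, cin)
  gcol <- aperm(gcol, c(1, 3, 2, 4))
  dim(gcol) <- c(plan$npos_out * k2, batch * cin)
  rs <- rowsum(gcol, plan$ipvec)
  gx <- matrix(0, plan$npos_in, batch * cin)
  gx[as.integer(rownames(rs)), ] <- rs
  dim(gx) <- c(plan$npos_in * batch, cin)
  list(gx = gx, gW = gW, gb = gb)
}

# ---- dense -----------------------------------------------------------------

.dense_forward <- function(x, W, b) sweep(x %*% W, 2, b, "+")

.dense_backward <- function(grad_out, x, W) {
  list(gx = grad_out %*% t(W), gW = crossprod(x, grad_out), gb = colSums(grad_out))
}

# ---- softmax cross entropy -------------------------------------------------

# scores: (B, K); targets: integer class indices in 1..K.
# Returns mean loss and gradient wrt scores (already divided by B).
.softmax_ce <- function(scores, targets) {
  m <- scores[cbind(seq_len(nrow(scores)), max.col(scores, ties.method = "first"))]
  e <- exp(scores - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(nrow(scores)), targets)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / nrow(scores), p = p)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

.adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# stack a list of stimulus frames into the canonical (npos * B, 1) matrix
.stack_images <- function(frames) {
  b <- length(frames)
  h <- nrow(frames[[1]]$image); w <- ncol(frames[[1]]$image)
  x <- vapply(frames, function(f) as.vector(f$image), numeric(h * w))
  dim(x) <- c(h * w * b, 1L)
  x
}
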