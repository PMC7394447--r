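# Assembled capsule-network training step: trunk forward, decoder heads,
# loss components (margin, cross entropies, reconstruction) and the full
# hand-derived backward pass producing gradients for every weight.

# labels shared by all architectures
.frame_labels <- function(frames, config) {
  b <- length(frames)
  cls <- vapply(frames, `[[`, "", "shape_class")
  cls_idx <- match(cls, config$classes)
  if (any(is.na(cls_idx)))
    stop("frame class not in model class set: ",
         paste(unique(cls[is.na(cls_idx)]), collapse = ", "))
  off_idx <- match(vapply(frames, `[[`, "", "vernier_offset"), .offset_levels)
  tk <- matrix(0, b, config$m)
  tk[cbind(seq_len(b), cls_idx)] <- 1
  labs <- list(cls_idx = cls_idx, off_idx = off_idx, tk = tk,
               x = vapply(frames, `[[`, 1L, "x"),
               y = vapply(frames, `[[`, 1L, "y"))
  if (config$experiment == 1)
    labs$rep_idx <- match(vapply(frames, `[[`, 1L, "n_repetitions"), .rep_levels)
  labs
}

# one loss (+ gradient) evaluation of the capsule model on a batch of frames.
.caps_step <- function(model, frames, iterations = model$config$routing_iterations,
                       mp = margin_params(), lw = loss_weights(),
                       compute_grads = TRUE) {
  cf <- model$config; w <- model$weights
  b <- length(frames)
  labs <- .frame_labels(frames, cf)
  x <- .stack_images(frames)
  fw <- .caps_trunk_forward(w, x, cf, b, iterations, keep_cache = compute_grads)
  v <- fw$v; norms <- fw$norms
  d <- cf$d; m <- cf$m
  grads <- list()
  gv <- array(0, c(b, d, m))

  # shape type: margin loss on secondary norms
  L_shape <- margin_loss(norms, labs$tk, mp)
  if (compute_grads) {
    gn <- .margin_loss_grad(norms, labs$tk, mp) * lw$shape_type  # (B, m)
    rs <- pmax(norms, 1e-12)
    for (k in seq_len(m)) gv[, , k] <- gv[, , k] + (gn[, k] / rs[, k]) * v[, , k]
  }

  # vernier offset: decoder on the secondary vernier capsule only
  vid <- match("vernier", cf$classes)
  xv <- v[, , vid, drop = FALSE]; dim(xv) <- c(b, d)
  pre1 <- .dense_forward(xv, w$Vw1, w$Vb1); h <- .relu(pre1)
  scores <- .dense_forward(h, w$Vw2, w$Vb2)
  ce_v <- .softmax_ce(scores, labs$off_idx)
  L_vern <- ce_v$loss
  if (compute_grads) {
    gs <- ce_v$grad * lw$vernier_offset
    bk2 <- .dense_backward(gs, h, w$Vw2)
    gpre1 <- bk2$gx * .relu_grad(pre1)
    bk1 <- .dense_backward(gpre1, xv, w$Vw1)
    grads$Vw2 <- bk2$gW; grads$Vb2 <- bk2$gb
    grads$Vw1 <- bk1$gW; grads$Vb1 <- bk1$gb
    # the offset loss shapes the capsules only on frames that contain a
    # vernier: "no vernier" frames train the decoder readout but their CE
    # gradient is stopped at the capsule layer (at this training scale a
    # fully end-to-end "none" gradient locks the vernier capsule into an
    # always-on state that defeats the margin loss; see the methods
    # vignette). Disable with vernier_ce_stopgrad = FALSE in caps_config.
    gx_tr <- bk1$gx
    if (isTRUE(cf$vernier_ce_stopgrad)) gx_tr[labs$off_idx == 3L, ] <- 0
    gv[, , vid] <- gv[, , vid] + gx_tr
  }

  flat <- v; dim(flat) <- c(b, d * m)
  gflat <- matrix(0, b, d * m)

  L_rep <- NA_real_; L_loc <- NA_real_
  if (cf$experiment == 1) {
    # shape repetitions: hidden ReLU decoder on all secondary capsules
    rp1 <- .dense_forward(flat, w$Rw1, w$Rb1); rh <- .relu(rp1)
    rsc <- .dense_forward(rh, w$Rw2, w$Rb2)
    ce_r <- .softmax_ce(rsc, labs$rep_idx)
    L_rep <- ce_r$loss
    # location: one linear softmax head per axis (pixel-index bins)
    sx <- .dense_forward(flat, w$Xw, w$Xb)
    sy <- .dense_forward(flat, w$Yw, w$Yb)
    ce_x <- .softmax_ce(sx, labs$x); ce_y <- .softmax_ce(sy, labs$y)
    L_loc <- ce_x$loss + ce_y$loss
    if (compute_grads) {
      gr <- ce_r$grad * lw$shape_repetitions
      rbk2 <- .dense_backward(gr, rh, w$Rw2)
      grp1 <- rbk2$gx * .relu_grad(rp1)
      rbk1 <- .dense_backward(grp1, flat, w$Rw1)
      grads$Rw2 <- rbk2$gW; grads$Rb2 <- rbk2$gb
      grads$Rw1 <- rbk1$gW; grads$Rb1 <- rbk1$gb
      gflat <- gflat + rbk1$gx
      xbk <- .dense_backward(ce_x$grad * lw$location, flat, w$Xw)
      ybk <- .dense_backward(ce_y$grad * lw$location, flat, w$Yw)
      grads$Xw <- xbk$gW; grads$Xb <- xbk$gb
      grads$Yw <- ybk$gW; grads$Yb <- ybk$gb
      gflat <- gflat + xbk$gx + ybk$gx
    }
  }

  # reconstruction from the ground-truth class capsule
  mask <- labs$tk
  vm <- v * aperm(array(mask, c(b, m, d)), c(1, 3, 2))
  xr <- vm; dim(xr) <- c(b, d * m)
  dp1 <- .dense_forward(xr, w$Dw1, w$Db1); dh1 <- .elu(dp1)
  dp2 <- .dense_forward(dh1, w$Dw2, w$Db2); dh2 <- .elu(dp2)
  dp3 <- .dense_forward(dh2, w$Dw3, w$Db3); recon <- .sigmoid(dp3)
  target <- t(matrix(x, cf$stim$height * cf$stim$width, b))
  L_recon <- mean(rowSums((recon - target)^2))
  if (compute_grads) {
    gout <- 2 * (recon - target) / b * lw$reconstruction
    gdp3 <- gout * recon * (1 - recon)
    dbk3 <- .dense_backward(gdp3, dh2, w$Dw3)
    gdp2 <- dbk3$gx * .elu_grad(dp2)
    dbk2 <- .dense_backward(gdp2, dh1, w$Dw2)
    gdp1 <- dbk2$gx * .elu_grad(dp1)
    dbk1 <- .dense_backward(gdp1, xr, w$Dw1)
    grads$Dw3 <- dbk3$gW; grads$Db3 <- dbk3$gb
    grads$Dw2 <- dbk2$gW; grads$Db2 <- dbk2$gb
    grads$Dw1 <- dbk1$gW; grads$Db1 <- dbk1$gb
    gxr <- dbk1$gx; dim(gxr) <- c(b, d, m)
    gv <- gv + gxr * aperm(array(mask, c(b, m, d)), c(1, 3, 2))
  }

  comps <- list(shape_type = L_shape, vernier_offset = L_vern,
                shape_repetitions = L_rep, reconstruction = L_recon,
                location = L_loc)
  total <- total_loss(comps[!is.na(unlist(comps))], lw, cf$experiment)
  if (compute_grads) {
    gv <- gv + array(gflat, c(b, d, m))
    trunk <- .caps_trunk_backward(w, cf, fw$cache, gv)
    grads <- c(grads, trunk)
  }
  list(losses = c(unlist(lapply(comps, function(z) if (is.na(z)) NA_real_ else z)),
                  total = total),
       grads = if (compute_grads) grads else NULL,
       vernier_scores = scores, norms = norms, v = v)
}

#' Decode all network outputs for a batch of frames
#'
#' Runs the forward pass and every decoder head: vernier offset scores,
#' shape-type norms, and (experiment 1) repetition and location scores, plus
#' the reconstruction from the most active capsule.
#'
#' @param model A `caps_model` or `alt_model`.
#' @param frames List of [stimulus_frame()] objects.
#' @param iterations Routing / recurrent iterations.
#' @return List with `vernier_scores` `(B, 3)`, `norms` `(B, m)` (capsule
#'   norms, or sigmoid class scores for alternative heads), `secondary` /
#'   `last_layer` activations, and `reconstruction` `(B, H, W)`.
#' @export
network_outputs <- function(model, frames,
                            iterations = model$config$routing_iterations) {
  if (inherits(model, "caps_model")) {
    st <- .caps_step(model, frames, iterations, compute_grads = FALSE)
    cf <- model$config
    top <- max.col(st$norms, ties.method = "first")
    mask <- matrix(0, length(frames), cf$m)
    mask[cbind(seq_along(frames), top)] <- 1
    rec <- reconstruct_from_capsules(st$v, mask, model$weights,
                                     c(cf$stim$height, cf$stim$width))
    list(vernier_scores = st$vernier_scores, norms = st$norms,
         secondary = st$v, reconstruction = rec)
  } else {
    st <- .alt_step(model, frames, iterations, compute_grads = FALSE)
    list(vernier_scores = st$vernier_scores, norms = st$norms,
         last_layer = st$h, reconstruction = st$reconstruction)
  }
}
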