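# The three comparison architectures: the two capsule layers replaced by
# (a) a feedforward fully connected layer (classic ffCNN), (b) a fully
# connected layer with lateral recurrent connections, (c) a fully connected
# layer with top-down recurrent connections to the layer below (the retained
# third convolution). All decoders read the entire last layer rather than
# specific capsules; neuron counts match the capsule model by construction,
# and the recurrent iteration count matches the routing iterations.

#' Alternative-head configuration
#'
#' @param caps A [caps_config()]; the alternative network copies its
#'   convolutional stack, class set and iteration count, and sizes its fully
#'   connected layer to the capsule model's secondary-layer neuron count
#'   (m * d), asserting parity.
#' @param head_kind "ffcnn", "lateral" or "topdown".
#' @param hidden_units Fully connected layer size; must equal `m * d`.
#' @param recurrent_iterations Defaults to the capsule model's routing
#'   iterations.
#' @return Object of class `alt_config`.
#' @export
alt_config <- function(caps = caps_config(),
                       head_kind = c("ffcnn", "lateral", "topdown"),
                       hidden_units = caps$m * caps$d,
                       recurrent_iterations = caps$routing_iterations) {
  head_kind <- match.arg(head_kind)
  if (hidden_units != caps$m * caps$d)
    stop(sprintf(paste("neuron-count parity violated: fully connected layer has %d",
                       "units but the capsule model's secondary layer has %d"),
                 hidden_units, caps$m * caps$d))
  out <- caps
  out$head_kind <- head_kind
  out$hidden_units <- hidden_units
  out$recurrent_iterations <- as.integer(recurrent_iterations)
  class(out) <- c("alt_config", "caps_config")
  out
}

#' Initialise an alternative-architecture network
#'
#' @param config An [alt_config()].
#' @param seed Integer seed.
#' @return Object of class `alt_model`.
#' @export
init_alt_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "alt_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  zdim <- cf$npos3 * cf$m * cf$n          # flattened conv3 (parity with primary caps)
  hd <- cf$hidden_units
  w <- list(
    W1 = .glorot(cf$conv1$k^2, cf$conv1$c), b1 = rep(0, cf$conv1$c),
    W2 = .glorot(cf$conv2$k^2 * cf$conv1$c, cf$conv2$c), b2 = rep(0, cf$conv2$c),
    W3 = .glorot(cf$caps_kernel^2 * cf$conv2$c, cf$m * cf$n), b3 = rep(0, cf$m * cf$n),
    Wf = .glorot(zdim, hd), bf = rep(0, hd),
    Sw = .glorot(hd, cf$m), Sb = rep(0, cf$m),
    Vw1 = .glorot(hd, cf$vernier_hidden), Vb1 = rep(0, cf$vernier_hidden),
    Vw2 = .glorot(cf$vernier_hidden, 3), Vb2 = rep(0, 3),
    Dw1 = .glorot(hd, cf$recon_hidden[1]), Db1 = rep(0, cf$recon_hidden[1]),
    Dw2 = .glorot(cf$recon_hidden[1], cf$recon_hidden[2]), Db2 = rep(0, cf$recon_hidden[2]),
    Dw3 = .glorot(cf$recon_hidden[2], cf$stim$height * cf$stim$width),
    Db3 = rep(0, cf$stim$height * cf$stim$width)
  )
  if (cf$head_kind == "lateral") w$Lw <- .glorot(hd, hd) * 0.1
  if (cf$head_kind == "topdown") w$Fw <- .glorot(hd, zdim) * 0.1
  if (cf$experiment == 1) {
    w$Rw1 <- .glorot(hd, cf$rep_hidden); w$Rb1 <- rep(0, cf$rep_hidden)
    w$Rw2 <- .glorot(cf$rep_hidden, 3); w$Rb2 <- rep(0, 3)
    w$Xw <- .glorot(hd, cf$stim$width); w$Xb <- rep(0, cf$stim$width)
    w$Yw <- .glorot(hd, cf$stim$height); w$Yb <- rep(0, cf$stim$height)
  }
  structure(list(config = cf, weights = w, arch = cf$head_kind, trained = FALSE),
            class = "alt_model")
}

# shared conv trunk: conv1-ELU-conv2-ELU-conv3 (preactivation returned)
.alt_conv_forward <- function(w, x, cf, batch) {
  p <- cf$plans
  c1 <- .conv_forward(x, w$W1, w$b1, p[[1]], batch); a1 <- .elu(c1$out)
  c2 <- .conv_forward(a1, w$W2, w$b2, p[[2]], batch); a2 <- .elu(c2$out)
  c3 <- .conv_forward(a2, w$W3, w$b3, p[[3]], batch)
  # flatten (npos3*B, C3) -> (B, npos3*C3)
  pf <- c3$out
  dim(pf) <- c(cf$npos3, batch, cf$m * cf$n)
  pf <- aperm(pf, c(2, 1, 3)); dim(pf) <- c(batch, cf$npos3 * cf$m * cf$n)
  list(p3 = pf, cache = list(c1 = c1, a1 = a1, c2 = c2, c3 = c3, batch = batch))
}

.alt_conv_backward <- function(w, cf, cache, gp3flat) {
  batch <- cache$batch
  g3 <- gp3flat
  dim(g3) <- c(batch, cf$npos3, cf$m * cf$n)
  g3 <- aperm(g3, c(2, 1, 3)); dim(g3) <- c(cf$npos3 * batch, cf$m * cf$n)
  p <- cf$plans
  bk3 <- .conv_backward(g3, cache$c3$col, cf$conv2$c, w$W3, p[[3]], batch)
  g2 <- bk3$gx * .elu_grad(cache$c2$out)
  bk2 <- .conv_backward(g2, cache$c2$col, cf$conv1$c, w$W2, p[[2]], batch)
  g1 <- bk2$gx * .elu_grad(cache$c1$out)
  bk1 <- .conv_backward(g1, cache$c1$col, 1L, w$W1, p[[1]], batch)
  list(W1 = bk1$gW, b1 = bk1$gb, W2 = bk2$gW, b2 = bk2$gb,
       W3 = bk3$gW, b3 = bk3$gb)
}

# head forward passes; return last layer h plus caches for BPTT
.alt_head_forward <- function(w, p3, kind, iterations) {
  z1 <- .elu(p3)
  if (kind == "ffcnn") {
    q <- .dense_forward(z1, w$Wf, w$bf)
    return(list(h = .elu(q), cache = list(z = z1, q = q)))
  }
  if (kind == "lateral") {
    a <- .dense_forward(z1, w$Wf, w$bf)
    h <- a * 0; pres <- vector("list", iterations); hs <- vector("list", iterations)
    for (t in seq_len(iterations)) {
      pre <- a + h %*% w$Lw
      h <- .elu(pre)
      pres[[t]] <- pre; hs[[t]] <- h
    }
    return(list(h = h, cache = list(z = z1, a = a, pres = pres, hs = hs)))
  }
  # topdown
  zs <- vector("list", iterations); qs <- vector("list", iterations)
  hs <- vector("list", iterations); zpres <- vector("list", iterations)
  z <- z1; zpres[[1]] <- p3
  h <- NULL
  for (t in seq_len(iterations)) {
    zs[[t]] <- z
    q <- .dense_forward(z, w$Wf, w$bf)
    qs[[t]] <- q
    h <- .elu(q)
    hs[[t]] <- h
    if (t < iterations) {
      zpres[[t + 1]] <- p3 + h %*% w$Fw
      z <- .elu(zpres[[t + 1]])
    }
  }
  list(h = h, cache = list(zs = zs, qs = qs, hs = hs, zpres = zpres))
}

# BPTT through the head; returns grads for head weights and gradient wrt p3
.alt_head_backward <- function(w, cache, kind, iterations, gh, p3) {
  if (kind == "ffcnn") {
    gq <- gh * .elu_grad(cache$q)
    bk <- .dense_backward(gq, cache$z, w$Wf)
    return(list(grads = list(Wf = bk$gW, bf = bk$gb),
                gp3 = bk$gx * .elu_grad(p3)))
  }
  if (kind == "lateral") {
    gWf <- 0; gbf <- 0; gLw <- 0; ga <- 0
    ght <- gh
    for (t in rev(seq_len(iterations))) {
      gpre <- ght * .elu_grad(cache$pres[[t]])
      ga <- ga + gpre
      hprev <- if (t > 1) cache$hs[[t - 1]] else cache$a * 0
      gLw <- gLw + crossprod(hprev, gpre)
      ght <- gpre %*% t(w$Lw)
    }
    bk <- .dense_backward(ga, cache$z, w$Wf)
    return(list(grads = list(Wf = bk$gW, bf = bk$gb, Lw = gLw),
                gp3 = bk$gx * .elu_grad(p3)))
  }
  # topdown
  gWf <- 0; gbf <- 0; gFw <- 0; gp3 <- 0
  gq <- gh * .elu_grad(cache$qs[[iterations]])
  gWf <- gWf + crossprod(cache$zs[[iterations]], gq); gbf <- gbf + colSums(gq)
  gz <- gq %*% t(w$Wf)
  for (t in rev(seq_len(iterations - 1))) {
    # z_{t+1} = elu(p3 + h_t Fw)
    gzpre <- gz * .elu_grad(cache$zpres[[t + 1]])
    gp3 <- gp3 + gzpre
    gFw <- gFw + crossprod(cache$hs[[t]], gzpre)
    ght <- gzpre %*% t(w$Fw)
    gq <- ght * .elu_grad(cache$qs[[t]])
    gWf <- gWf + crossprod(cache$zs[[t]], gq); gbf <- gbf + colSums(gq)
    gz <- gq %*% t(w$Wf)
  }
  gp3 <- gp3 + gz * .elu_grad(cache$zpres[[1]]) # z_1 = elu(p3)
  list(grads = list(Wf = gWf, bf = gbf, Fw = gFw), gp3 = gp3)
}

#' Forward pass of the feedforward fully connected head (classic ffCNN)
#'
#' @param model An `alt_model` with `head_kind = "ffcnn"` (the other heads
#'   reduce to it with zero recurrent weights).
#' @param frames List of stimulus frames.
#' @return Last-layer activation matrix `(B, hidden_units)`.
#' @export
forward_ffcnn <- function(model, frames) {
  .alt_forward(model, frames, iterations = 1L, force_kind = "ffcnn")$h
}

#' Forward pass of the laterally recurrent fully connected head
#'
#' @param model An `alt_model` with `head_kind = "lateral"`.
#' @param frames List of stimulus frames.
#' @param iterations Recurrent iterations (>= 1).
#' @return Last-layer activation matrix after `iterations` updates.
#' @export
forward_lateral <- function(model, frames,
                            iterations = model$config$recurrent_iterations) {
  if (iterations < 1) stop("iterations must be >= 1")
  .alt_forward(model, frames, iterations, force_kind = "lateral")$h
}

#' Forward pass of the top-down recurrent head
#'
#' The final fully connected layer feeds back into the flattened third
#' convolution each iteration.
#' @param model An `alt_model` with `head_kind = "topdown"`.
#' @param frames List of stimulus frames.
#' @param iterations Recurrent iterations (>= 1).
#' @return Last-layer activation matrix after `iterations` updates.
#' @export
forward_topdown <- function(model, frames,
                            iterations = model$config$recurrent_iterations) {
  if (iterations < 1) stop("iterations must be >= 1")
  .alt_forward(model, frames, iterations, force_kind = "topdown")$h
}

.alt_forward <- function(model, frames, iterations, force_kind = NULL) {
  stopifnot(inherits(model, "alt_model"))
  kind <- if (is.null(force_kind)) model$config$head_kind else force_kind
  x <- .stack_images(frames)
  tr <- .alt_conv_forward(model$weights, x, model$config, length(frames))
  hd <- .alt_head_forward(model$weights, tr$p3, kind, iterations)
  list(h = hd$h, p3 = tr$p3, conv_cache = tr$cache, head_cache = hd$cache,
       x = x)
}

#' Decode all outputs from the entire last layer of an alternative network
#'
#' The same decoder heads as the capsule model (vernier offset, shape type,
#' and for experiment 1 repetitions and location, plus reconstruction), but
#' reading the whole last layer rather than specific capsules. Shape-type
#' scores are sigmoid-bounded so the capsule margin loss applies unchanged.
#'
#' @param model An `alt_model`.
#' @param activations Last-layer matrix `(B, hidden_units)` from one of the
#'   forward functions.
#' @return List with `vernier_scores`, `norms` (sigmoid class scores),
#'   `reconstruction`.
#' @export
decode_all_from_last_layer <- function(model, activations) {
  w <- model$weights; cf <- model$config
  scores <- decode_vernier(activations, w)
  sig <- .sigmoid(.dense_forward(activations, w$Sw, w$Sb))
  dh1 <- .elu(.dense_forward(activations, w$Dw1, w$Db1))
  dh2 <- .elu(.dense_forward(dh1, w$Dw2, w$Db2))
  rec <- .sigmoid(.dense_forward(dh2, w$Dw3, w$Db3))
  list(vernier_scores = scores, norms = sig,
       reconstruction = array(rec, c(nrow(activations), cf$stim$height,
                                     cf$stim$width)))
}

# one loss/grad evaluation for an alternative model (mirrors .caps_step)
.alt_step <- function(model, frames, iterations = model$config$recurrent_iterations,
                      mp = margin_params(), lw = loss_weights(),
                      compute_grads = TRUE) {
  cf <- model$config; w <- model$weights
  b <- length(frames)
  labs <- .frame_labels(frames, cf)
  fwd <- .alt_forward(model, frames, iterations)
  h <- fwd$h
  grads <- list()
  gh <- matrix(0, b, ncol(h))

  # shape type: sigmoid class scores through the margin loss
  spre <- .dense_forward(h, w$Sw, w$Sb)
  sig <- .sigmoid(spre)
  sig <- pmin(sig, 1 - 1e-9)
  L_shape <- margin_loss(sig, labs$tk, mp)
  if (compute_grads) {
    gn <- .margin_loss_grad(sig, labs$tk, mp) * lw$shape_type
    gspre <- gn * sig * (1 - sig)
    sbk <- .dense_backward(gspre, h, w$Sw)
    grads$Sw <- sbk$gW; grads$Sb <- sbk$gb
    gh <- gh + sbk$gx
  }

  pre1 <- .dense_forward(h, w$Vw1, w$Vb1); vh <- .relu(pre1)
  scores <- .dense_forward(vh, w$Vw2, w$Vb2)
  ce_v <- .softmax_ce(scores, labs$off_idx)
  L_vern <- ce_v$loss
  if (compute_grads) {
    gs <- ce_v$grad * lw$vernier_offset
    bk2 <- .dense_backward(gs, vh, w$Vw2)
    gpre1 <- bk2$gx * .relu_grad(pre1)
    bk1 <- .dense_backward(gpre1, h, w$Vw1)
    grads$Vw2 <- bk2$gW; grads$Vb2 <- bk2$gb
    grads$Vw1 <- bk1$gW; grads$Vb1 <- bk1$gb
    # same stop-gradient rule as the capsule model ("trained the same way"):
    # no-vernier frames do not shape the trunk through the offset loss
    gx_tr <- bk1$gx
    if (isTRUE(cf$vernier_ce_stopgrad)) gx_tr[labs$off_idx == 3L, ] <- 0
    gh <- gh + gx_tr
  }

  L_rep <- NA_real_; L_loc <- NA_real_
  if (cf$experiment == 1) {
    rp1 <- .dense_forward(h, w$Rw1, w$Rb1); rh <- .relu(rp1)
    rsc <- .dense_forward(rh, w$Rw2, w$Rb2)
    ce_r <- .softmax_ce(rsc, labs$rep_idx)
    L_rep <- ce_r$loss
    sx <- .dense_forward(h, w$Xw, w$Xb); sy <- .dense_forward(h, w$Yw, w$Yb)
    ce_x <- .softmax_ce(sx, labs$x); ce_y <- .softmax_ce(sy, labs$y)
    L_loc <- ce_x$loss + ce_y$loss
    if (compute_grads) {
      gr <- ce_r$grad * lw$shape_repetitions
      rbk2 <- .dense_backward(gr, rh, w$Rw2)
      grp1 <- rbk2$gx * .relu_grad(rp1)
      rbk1 <- .dense_backward(grp1, h, w$Rw1)
      grads$Rw2 <- rbk2$gW; grads$Rb2 <- rbk2$gb
      grads$Rw1 <- rbk1$gW; grads$Rb1 <- rbk1$gb
      xbk <- .dense_backward(ce_x$grad * lw$location, h, w$Xw)
      ybk <- .dense_backward(ce_y$grad * lw$location, h, w$Yw)
      grads$Xw <- xbk$gW; grads$Xb <- xbk$gb
      grads$Yw <- ybk$gW; grads$Yb <- ybk$gb
      gh <- gh + rbk1$gx + xbk$gx + ybk$gx
    }
  }

  dp1 <- .dense_forward(h, w$Dw1, w$Db1); dh1 <- .elu(dp1)
  dp2 <- .dense_forward(dh1, w$Dw2, w$Db2); dh2 <- .elu(dp2)
  dp3 <- .dense_forward(dh2, w$Dw3, w$Db3); recon <- .sigmoid(dp3)
  target <- t(matrix(fwd$x, cf$stim$height * cf$stim$width, b))
  L_recon <- mean(rowSums((recon - target)^2))
  if (compute_grads) {
    gout <- 2 * (recon - target) / b * lw$reconstruction
    gdp3 <- gout * recon * (1 - recon)
    dbk3 <- .dense_backward(gdp3, dh2, w$Dw3)
    gdp2 <- dbk3$gx * .elu_grad(dp2)
    dbk2 <- .dense_backward(gdp2, dh1, w$Dw2)
    gdp1 <- dbk2$gx * .elu_grad(dp1)
    dbk1 <- .dense_backward(gdp1, h, w$Dw1)
    grads$Dw3 <- dbk3$gW; grads$Db3 <- dbk3$gb
    grads$Dw2 <- dbk2$gW; grads$Db2 <- dbk2$gb
    grads$Dw1 <- dbk1$gW; grads$Db1 <- dbk1$gb
    gh <- gh + dbk1$gx
  }

  comps <- list(shape_type = L_shape, vernier_offset = L_vern,
                shape_repetitions = L_rep, reconstruction = L_recon,
                location = L_loc)
  total <- total_loss(comps[!is.na(unlist(comps))], lw, cf$experiment)
  if (compute_grads) {
    hb <- .alt_head_backward(w, fwd$head_cache, cf$head_kind, iterations, gh,
                             fwd$p3)
    grads <- c(grads, hb$grads,
               .alt_conv_backward(w, cf, fwd$conv_cache, hb$gp3))
  }
  list(losses = c(unlist(lapply(comps, function(z) if (is.na(z)) NA_real_ else z)),
                  total = total),
       grads = if (compute_grads) grads else NULL,
       vernier_scores = scores, norms = sig, h = h,
       reconstruction = array(recon, c(b, cf$stim$height, cf$stim$width)))
}
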