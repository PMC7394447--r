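# Decoders reading out from the secondary capsules, and the loss terms
# combined into the experiment-specific total losses: margin loss on capsule
# norms for shape type, softmax cross entropies for vernier offset, shape
# repetitions and location, and a squared-error reconstruction loss.

#' Margin-loss parameters
#'
#' Defaults m+ = 0.9, m- = 0.1, lambda = 0.5 (the standard values of the
#' routing-by-agreement literature, which the model follows).
#' @param m_plus Present-class margin (0 < m_minus < m_plus < 1).
#' @param m_minus Absent-class margin.
#' @param lambda_down Down-weighting of absent-class terms (> 0).
#' @return Object of class `margin_params`.
#' @export
margin_params <- function(m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5) {
  stopifnot(0 < m_minus, m_minus < m_plus, m_plus < 1, lambda_down > 0)
  structure(list(m_plus = m_plus, m_minus = m_minus,
                 lambda_down = lambda_down), class = "margin_params")
}

#' Loss-term weights
#'
#' Defaults are the published scaling factors: alpha_shape_type = 0.5,
#' alpha_vernier_offset = 1, alpha_shape_repetitions = 0.4,
#' alpha_reconstruction = 0.0005, alpha_location = 0.1.
#' @param shape_type,vernier_offset,shape_repetitions,reconstruction,location
#'   Nonnegative reals.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(shape_type = 0.5, vernier_offset = 1,
                         shape_repetitions = 0.4, reconstruction = 0.0005,
                         location = 0.1) {
  w <- c(shape_type = shape_type, vernier_offset = vernier_offset,
         shape_repetitions = shape_repetitions,
         reconstruction = reconstruction, location = location)
  stopifnot(all(w >= 0))
  structure(as.list(w), class = "loss_weights")
}

#' Margin loss on capsule norms
#'
#' `sum_k T_k max(0, m+ - ||v_k||)^2 + lambda (1 - T_k) max(0, ||v_k|| - m-)^2`,
#' averaged over the batch if `norms` is a matrix. Supports several present
#' classes per sample (multi-object detection).
#'
#' @param norms Capsule norms in `[0, 1)`: vector (one sample) or matrix
#'   `(B, m)`.
#' @param targets 0/1 indicators `T_k`, same shape as `norms`.
#' @param params A [margin_params()].
#' @return Scalar loss.
#' @export
margin_loss <- function(norms, targets, params = margin_params()) {
  if (any(norms >= 1) || any(norms < 0))
    stop("capsule norms must lie in [0, 1) (squash invariant violated)")
  stopifnot(all(targets %in% c(0, 1)))
  pres <- pmax(0, params$m_plus - norms)^2
  abs_ <- pmax(0, norms - params$m_minus)^2
  per <- targets * pres + params$lambda_down * (1 - targets) * abs_
  if (is.matrix(norms)) mean(rowSums(per)) else sum(per)
}

# gradient of the (batch-mean) margin loss wrt the norms matrix (B, m)
.margin_loss_grad <- function(norms, targets, params) {
  gp <- -2 * pmax(0, params$m_plus - norms) * targets
  ga <- 2 * params$lambda_down * pmax(0, norms - params$m_minus) * (1 - targets)
  (gp + ga) / nrow(norms)
}

# ---- cross-entropy heads ---------------------------------------------------

.offset_levels <- c("left", "right", "none")
.rep_levels <- c(1L, 3L, 5L)

#' Decode vernier offset scores from a capsule vector
#'
#' A single dense hidden layer with ReLU followed by a dense readout of three
#' nodes (left, right, no vernier). For capsule networks the input is the
#' secondary vernier capsule only; alternative architectures pass their whole
#' last layer.
#'
#' @param x Input vector or matrix `(B, input_dim)`.
#' @param weights List with `Vw1, Vb1, Vw2, Vb2`.
#' @return Score matrix `(B, 3)` with columns left, right, none.
#' @export
decode_vernier <- function(x, weights) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  h <- .relu(.dense_forward(x, weights$Vw1, weights$Vb1))
  out <- .dense_forward(h, weights$Vw2, weights$Vb2)
  colnames(out) <- .offset_levels
  out
}

#' Vernier-offset loss
#'
#' Softmax cross entropy between decoder scores and the one-hot true offset.
#' @param scores Length-3 vector or `(B, 3)` matrix (left, right, none).
#' @param true_offset Character vector in `{left, right, none}`.
#' @return Scalar mean loss.
#' @export
vernier_offset_loss <- function(scores, true_offset) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  stopifnot(all(true_offset %in% .offset_levels))
  .softmax_ce(scores, match(true_offset, .offset_levels))$loss
}

#' Shape-repetition loss
#'
#' Softmax cross entropy over the three repetition labels 1, 3, 5.
#' @param scores Length-3 vector or `(B, 3)` matrix.
#' @param true_repetitions Integers in `{1, 3, 5}`.
#' @return Scalar mean loss.
#' @export
shape_repetition_loss <- function(scores, true_repetitions) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  idx <- match(true_repetitions, .rep_levels)
  if (any(is.na(idx)))
    stop("true_repetitions must be 1, 3 or 5; got ",
         paste(true_repetitions[is.na(idx)], collapse = ", "))
  .softmax_ce(scores, idx)$loss
}

#' Location loss
#'
#' Sum of two softmax cross entropies, one per axis, over discretised
#' coordinate bins (default one bin per pixel).
#' @param location_scores List with `x` (`(B, width)` scores) and `y`
#'   (`(B, height)` scores).
#' @param true_xy Matrix `(B, 2)` (columns x, y) or length-2 vector of pixel
#'   coordinates.
#' @return Scalar mean loss.
#' @export
location_loss <- function(location_scores, true_xy) {
  if (!is.matrix(true_xy)) true_xy <- matrix(true_xy, nrow = 1)
  sx <- location_scores$x; sy <- location_scores$y
  if (!is.matrix(sx)) sx <- matrix(sx, nrow = 1)
  if (!is.matrix(sy)) sy <- matrix(sy, nrow = 1)
  if (any(true_xy[, 1] < 1 | true_xy[, 1] > ncol(sx)) ||
      any(true_xy[, 2] < 1 | true_xy[, 2] > ncol(sy)))
    stop("true coordinates outside the canvas / coordinate bins")
  .softmax_ce(sx, true_xy[, 1])$loss + .softmax_ce(sy, true_xy[, 2])$loss
}

# ---- reconstruction --------------------------------------------------------

#' Reconstruct the input image from (masked) secondary capsules
#'
#' Unselected capsule types are zeroed, the rest are flattened and decoded
#' through two fully connected ELU hidden layers (defaults 512 then 1024
#' units) and a sigmoid readout of input-image size. During training the mask
#' selects the ground-truth class capsule; at analysis time single capsules
#' are decoded to visualise segmentation.
#'
#' @param v Secondary capsules, array `(B, d, m)` (or `(d, m)` for one
#'   sample).
#' @param mask Logical/0-1 matrix `(B, m)` (or vector of length m) selecting
#'   capsule types; must select at least one type.
#' @param weights List with `Dw1..Db3`.
#' @param dims Canvas `c(height, width)`.
#' @return Array `(B, height, width)` of reconstructed intensities in (0, 1).
#' @export
reconstruct_from_capsules <- function(v, mask, weights, dims) {
  if (length(dim(v)) == 2) v <- array(v, c(1, dim(v)))
  b <- dim(v)[1]; d <- dim(v)[2]; m <- dim(v)[3]
  if (!is.matrix(mask)) mask <- matrix(mask, b, m, byrow = TRUE)
  if (any(rowSums(mask != 0) < 1)) stop("reconstruction mask selects no capsule type")
  vm <- v * aperm(array(mask, c(b, m, d)), c(1, 3, 2))
  x <- vm; dim(x) <- c(b, d * m)
  h1 <- .elu(.dense_forward(x, weights$Dw1, weights$Db1))
  h2 <- .elu(.dense_forward(h1, weights$Dw2, weights$Db2))
  out <- .sigmoid(.dense_forward(h2, weights$Dw3, weights$Db3))
  array(out, c(b, dims[1], dims[2]))
}

#' Reconstruction loss
#'
#' Summed squared pixel difference between input and reconstruction
#' (batch-averaged when given image stacks).
#' @param input Image matrix, or array `(B, H, W)`.
#' @param reconstruction Same dimensions as `input`.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(input, reconstruction) {
  if (!identical(dim(input), dim(reconstruction)))
    stop("input and reconstruction dimensions differ")
  if (length(dim(input)) == 3) mean(apply((input - reconstruction)^2, 1, sum))
  else sum((input - reconstruction)^2)
}

# ---- total loss ------------------------------------------------------------

#' Combine loss components into the experiment total
#'
#' Experiment 1 uses all five weighted terms; experiment 2 uses shape type,
#' vernier offset and reconstruction only.
#' @param components Named list/vector with entries `shape_type`,
#'   `vernier_offset`, `shape_repetitions`, `reconstruction`, `location`
#'   (the last two optional for experiment 2).
#' @param weights A [loss_weights()].
#' @param experiment 1 or 2.
#' @return Scalar total loss.
#' @export
total_loss <- function(components, weights = loss_weights(), experiment = 1) {
  stopifnot(experiment %in% c(1, 2))
  comp <- unlist(components)
  if (any(comp < 0)) stop("loss components must be nonnegative")
  terms <- if (experiment == 1)
    c("shape_type", "vernier_offset", "shape_repetitions", "reconstruction",
      "location")
  else c("shape_type", "vernier_offset", "reconstruction")
  if (!all(terms %in% names(comp)))
    stop("missing loss components: ",
         paste(setdiff(terms, names(comp)), collapse = ", "))
  sum(vapply(terms, function(t) weights[[t]] * comp[[t]], 0))
}
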