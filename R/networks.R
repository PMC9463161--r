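# The two-head convolutional discriminator/regressor and the fully connected
# generator, written directly on BLAS matrix operations with explicit
# backward passes. The networks are small by design (two 1-D convolutional
# layers of 32 length-3 filters, one 512-unit dense layer, a 2-unit head;
# generator 100 -> 512 -> 512 -> 1152), so a framework-free implementation
# keeps the package dependency-light and every gradient auditable.
#
# Internal batch layout: a batch of B examples with C channels of T samples
# is a (C, T*B) matrix whose columns are grouped by example; the public API
# uses (B, C, T) arrays.

SEG_CHANNELS <- 3L
SEG_LEN <- 384L
NOISE_DIM <- 100L

batch_to_internal <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  d <- dim(x)
  m <- aperm(x, c(2, 3, 1))
  dim(m) <- c(d[2], d[3] * d[1])
  m
}

internal_to_batch <- function(m, C, T, B) {
  a <- m
  dim(a) <- c(C, T, B)
  aperm(a, c(3, 1, 2))
}

# ---- initializers -----------------------------------------------------------

# semi-orthogonal matrix along the smaller dimension (SVD of a Gaussian
# draw): rows orthonormal when n <= m, columns orthonormal when n >= m
init_orthogonal <- function(n, m) {
  a <- matrix(stats::rnorm(n * m), n, m)
  sv <- svd(a)
  if (n <= m) t(sv$v) else sv$u
}

# He-uniform: bounds +/- sqrt(6 / fan_in), fan_in = input width
init_he_uniform <- function(n, m) {
  b <- sqrt(6 / m)
  matrix(stats::runif(n * m, -b, b), n, m)
}

#' Initialize discriminator parameters
#'
#' Two 1-D convolutional layers (32 filters of length 3, stride 1, padding 1)
#' and a 512-unit dense layer, all weight-normalized with scales `g`
#' initialized to 1 and biases to 0; a plain 2-unit output layer (score and
#' real/fake logit). Convolutional directions are initialized
#' semi-orthogonally, dense directions He-uniform.
#'
#' @param seed integer seed (the draw is reproducible from it).
#' @param channels,seg_len input geometry (3 x 384 by default).
#' @return a parameter tree (nested list of numeric arrays).
#' @export
init_discriminator <- function(seed = 1L, channels = SEG_CHANNELS, seg_len = SEG_LEN) {
  with_seed(derive_seed(seed, "disc_init"), {
    list(
      conv1 = list(v = init_orthogonal(32L, channels * 3L),
                   g = rep(1, 32L), b = rep(0, 32L)),
      conv2 = list(v = init_orthogonal(32L, 32L * 3L),
                   g = rep(1, 32L), b = rep(0, 32L)),
      fc1 = list(v = init_he_uniform(512L, 32L * seg_len),
                 g = rep(1, 512L), b = rep(0, 512L)),
      out = list(W = init_he_uniform(2L, 512L), b = rep(0, 2L))
    )
  })
}

#' Initialize generator parameters
#'
#' Two weight-normalized 512-unit dense layers with ReLU and a linear
#' 1152-unit output layer (reshaped to 3 x 384, the discriminator's input).
#' All weights He-uniform, biases 0, norms `g` 1.
#'
#' @param seed integer seed.
#' @param noise_dim input noise width.
#' @param out_dim output width (channels x segment length).
#' @return a parameter tree.
#' @export
init_generator <- function(seed = 1L, noise_dim = NOISE_DIM,
                           out_dim = SEG_CHANNELS * SEG_LEN) {
  with_seed(derive_seed(seed, "gen_init"), {
    list(
      fc1 = list(v = init_he_uniform(512L, noise_dim),
                 g = rep(1, 512L), b = rep(0, 512L)),
      fc2 = list(v = init_he_uniform(512L, 512L),
                 g = rep(1, 512L), b = rep(0, 512L)),
      out = list(W = init_he_uniform(out_dim, 512L), b = rep(0, out_dim))
    )
  })
}

#' Count trainable parameters of a network
#' @param params a parameter tree.
#' @return integer total number of scalar parameters.
#' @export
n_params <- function(params) tree_count(params)

# ---- weight normalization ---------------------------------------------------
# w = g * v / ||v||_row ; scaling any row of v leaves the effective map
# unchanged, so optimization of direction and scale decouple. The algebra
# lives in C++ (see src/fastnn.cpp) together with the convolution kernels
# and the fused ReLU + inverted-dropout pass.

wn_weight <- function(layer) cpp_wn_weight(layer$v, layer$g)

# effective weights of all weight-normalized discriminator layers; computed
# once per training step and shared by the real/fake/generator forwards
disc_weights <- function(params) {
  list(w1 = wn_weight(params$conv1), w2 = wn_weight(params$conv2),
       w3 = wn_weight(params$fc1))
}

wn_backward <- function(layer, rn, dW) {
  g <- cpp_wn_backward(dW, layer$v, layer$g, rn)
  list(v = g$v, g = as.numeric(g$g), b = NULL)
}

# sigmoid clamped away from exact 0/1 so downstream least-squares terms and
# their (0,1) preconditions stay well defined when the logit saturates
sigmoid <- function(x) pmin(pmax(1 / (1 + exp(-x)), 1e-12), 1 - 1e-12)

# ---- discriminator ----------------------------------------------------------

#' Discriminator forward pass
#'
#' Maps a batch of 3 x 384 log-spectral examples to an unbounded severity
#' score (first output unit, no nonlinearity) and a real-example probability
#' (second unit through a sigmoid). In training mode, dropout with the given
#' probability is applied after each of the three hidden layers, consuming
#' the caller's RNG stream; in inference mode the pass is deterministic.
#'
#' @param params discriminator parameters from [init_discriminator()].
#' @param x numeric array (B, 3, 384), or a single 3 x 384 matrix.
#' @param training apply dropout?
#' @param dropout dropout probability.
#' @param keep_cache retain intermediate activations for a backward pass.
#' @param weights optionally, precomputed effective weights (internal reuse
#'   across the several forward passes of one training step).
#' @return list with `score` (length B), `prob` (length B, in (0,1)) and,
#'   if requested, `cache`.
#' @export
discriminator_forward <- function(params, x, training = FALSE, dropout = 0.5,
                                  keep_cache = FALSE, weights = NULL) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  abort_if(length(d) != 3L || d[2] != SEG_CHANNELS,
           "input must be a (batch, 3, T) array")
  abort_if(any(!is.finite(x)), "input contains non-finite values")
  B <- d[1]; T <- d[3]
  xm <- batch_to_internal(x)
  if (is.null(weights)) weights <- disc_weights(params)
  w1 <- weights$w1; w2 <- weights$w2; w3 <- weights$w3

  y1 <- cpp_conv1d_forward(xm, w1$W, params$conv1$b, T, B)
  rd1 <- cpp_relu_dropout(y1, dropout, training)

  y2 <- cpp_conv1d_forward(rd1$h, w2$W, params$conv2$b, T, B)
  rd2 <- cpp_relu_dropout(y2, dropout, training)

  fl <- rd2$h
  dim(fl) <- c(32L * T, B)

  z3 <- w3$W %*% fl + params$fc1$b
  rd3 <- cpp_relu_dropout(z3, dropout, training)

  o <- params$out$W %*% rd3$h + params$out$b
  out <- list(score = as.numeric(o[1, ]), prob = sigmoid(as.numeric(o[2, ])))
  if (keep_cache) {
    # the masks m* fold the ReLU derivative and the dropout keep/scale factor
    out$cache <- list(xm = xm, B = B, T = T, w1 = w1, m1 = rd1$m, h1 = rd1$h,
                      w2 = w2, m2 = rd2$m, fl = fl, w3 = w3, m3 = rd3$m,
                      h3 = rd3$h)
  }
  out
}

# backward through the discriminator given gradients w.r.t. the score unit
# and the real/fake logit (pre-sigmoid). With raw = TRUE the gradients are
# returned in effective-weight space (the weight-norm chain rule, which is
# linear in dW, can then be applied once after summing several branches);
# with need_param_grads = FALSE only the input gradient is computed (used
# for generator updates, where the discriminator is not being trained).
disc_backward_raw <- function(params, cache, d_score, d_logit,
                              need_dx = FALSE, need_param_grads = TRUE) {
  B <- cache$B; T <- cache$T
  do <- rbind(matrix(d_score, 1L), matrix(d_logit, 1L))
  g_out <- if (need_param_grads) {
    list(W = tcrossprod(do, cache$h3), b = rowSums(do))
  }
  dh3 <- crossprod(params$out$W, do)
  dz3 <- cpp_mask_mult(dh3, cache$m3)

  g_fc1 <- if (need_param_grads) {
    list(W = tcrossprod(dz3, cache$fl), b = rowSums(dz3))
  }
  dfl <- crossprod(cache$w3$W, dz3)
  dim(dfl) <- c(32L, T * B)

  dy2 <- cpp_mask_mult(dfl, cache$m2)
  bk2 <- cpp_conv1d_backward(cache$h1, cache$w2$W, dy2, T, B,
                             need_dx = TRUE, need_dw = need_param_grads)
  g_conv2 <- if (need_param_grads) list(W = bk2$dW, b = as.numeric(bk2$db))

  dy1 <- cpp_mask_mult(bk2$dx, cache$m1)
  bk1 <- cpp_conv1d_backward(cache$xm, cache$w1$W, dy1, T, B,
                             need_dx = need_dx, need_dw = need_param_grads)
  g_conv1 <- if (need_param_grads) list(W = bk1$dW, b = as.numeric(bk1$db))

  out <- list()
  if (need_param_grads) {
    out$raw <- list(conv1 = g_conv1, conv2 = g_conv2, fc1 = g_fc1, out = g_out)
  }
  if (need_dx) out$dx <- internal_to_batch(bk1$dx, SEG_CHANNELS, T, B)
  out
}

# map effective-weight-space gradients to (v, g, b) parameter space
disc_grads_from_raw <- function(params, cache, raw) {
  tr <- function(layer, w, gr) {
    out <- wn_backward(layer, w$rn, gr$W)
    out$b <- gr$b
    out
  }
  list(conv1 = tr(params$conv1, cache$w1, raw$conv1),
       conv2 = tr(params$conv2, cache$w2, raw$conv2),
       fc1 = tr(params$fc1, cache$w3, raw$fc1),
       out = list(W = raw$out$W, b = raw$out$b))
}

disc_backward <- function(params, cache, d_score, d_logit, need_dx = FALSE) {
  bk <- disc_backward_raw(params, cache, d_score, d_logit, need_dx = need_dx)
  out <- list(grads = disc_grads_from_raw(params, cache, bk$raw))
  if (need_dx) out$dx <- bk$dx
  out
}

# ---- generator --------------------------------------------------------------

#' Sample a uniform noise batch
#' @param n batch size.
#' @param noise_dim noise width.
#' @return an (n, noise_dim) matrix of draws uniform on `[0, 1]`.
#' @export
sample_noise <- function(n, noise_dim = NOISE_DIM) {
  matrix(stats::runif(n * noise_dim), n, noise_dim)
}

#' Generator forward pass
#'
#' Maps uniform noise to fake log-spectral examples shaped like the
#' discriminator's input. Deterministic given the noise.
#'
#' @param params generator parameters from [init_generator()].
#' @param noise an (B, 100) matrix with entries in `[0, 1]`.
#' @param keep_cache retain activations for a backward pass.
#' @return list with `x` (array B x 3 x 384) and, if requested, `cache`.
#' @export
generator_forward <- function(params, noise, keep_cache = FALSE) {
  abort_if(!is.matrix(noise) || ncol(noise) != ncol(params$fc1$v),
           "noise must be a (batch, ", ncol(params$fc1$v), ") matrix")
  abort_if(any(noise < 0 | noise > 1), "noise values must lie in [0, 1]")
  B <- nrow(noise)
  z <- t(noise)

  w1 <- wn_weight(params$fc1)
  y1 <- w1$W %*% z + params$fc1$b
  a1 <- pmax(y1, 0)
  w2 <- wn_weight(params$fc2)
  y2 <- w2$W %*% a1 + params$fc2$b
  a2 <- pmax(y2, 0)
  o <- params$out$W %*% a2 + params$out$b # (1152, B), linear

  xo <- o
  dim(xo) <- c(SEG_CHANNELS, SEG_LEN * B)
  out <- list(x = internal_to_batch(xo, SEG_CHANNELS, SEG_LEN, B))
  if (keep_cache) {
    out$cache <- list(z = z, B = B, w1 = w1, y1 = y1, a1 = a1,
                      w2 = w2, y2 = y2, a2 = a2)
  }
  out
}

# backward through the generator given the gradient w.r.t. its output batch
# (array B x 3 x 384); l2 is the L2-regularization coefficient applied to
# the output layer's weights
gen_backward <- function(params, cache, dx, l2 = 0) {
  B <- cache$B
  do <- batch_to_internal(dx)
  dim(do) <- c(SEG_CHANNELS * SEG_LEN, B)
  g_out <- list(W = tcrossprod(do, cache$a2) + 2 * l2 * params$out$W,
                b = rowSums(do))
  da2 <- crossprod(params$out$W, do)
  dy2 <- da2 * (cache$y2 > 0)
  g_fc2 <- wn_backward(params$fc2, cache$w2$rn, tcrossprod(dy2, cache$a1))
  g_fc2$b <- rowSums(dy2)
  da1 <- crossprod(cache$w2$W, dy2)
  dy1 <- da1 * (cache$y1 > 0)
  g_fc1 <- wn_backward(params$fc1, cache$w1$rn, tcrossprod(dy1, cache$z))
  g_fc1$b <- rowSums(dy1)
  list(fc1 = g_fc1, fc2 = g_fc2, out = g_out)
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a parameter checkpoint
#'
#' Writes the parameter tree with a JSON header carrying an architecture
#' hash, seed and epoch; loading verifies the hash.
#'
#' @param params parameter tree.
#' @param path file path.
#' @param seed,epoch provenance recorded in the header.
#' @export
save_checkpoint <- function(params, path, seed = NA, epoch = NA) {
  shape <- tree_map(function(a) paste(dim(a) %||% length(a), collapse = "x"), params)
  hash <- digest_shapes(shape)
  obj <- list(header = list(arch_hash = hash, seed = seed, epoch = epoch,
                            package = "pigdgan"),
              params = params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  shape <- tree_map(function(a) paste(dim(a) %||% length(a), collapse = "x"),
                    obj$params)
  abort_if(!identical(digest_shapes(shape), obj$header$arch_hash),
           "checkpoint architecture hash mismatch")
  obj
}

digest_shapes <- function(shape) {
  s <- paste(unlist(shape), names(unlist(shape)), collapse = ";")
  tmp <- tempfile()
  writeLines(s, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
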