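test_that("discriminator forward obeys its output contract", {
  p <- init_discriminator(4)
  x <- array(rnorm(6 * 3 * 384), c(6, 3, 384))
  fw <- discriminator_forward(p, x)
  expect_length(fw$score, 6)
  expect_length(fw$prob, 6)
  expect_true(all(fw$prob > 0 & fw$prob < 1))

  # inference mode is deterministic
  fw2 <- discriminator_forward(p, x)
  expect_identical(fw$score, fw2$score)

  # zeroed output layer: score 0, probability sigmoid(0) = 0.5
  pz <- p
  pz$out$W[] <- 0; pz$out$b[] <- 0
  fw0 <- discriminator_forward(pz, x)
  expect_equal(fw0$score, rep(0, 6))
  expect_equal(fw0$prob, rep(0.5, 6))

  expect_error(discriminator_forward(p, array(0, c(2, 4, 384))), "batch, 3")
  expect_error(discriminator_forward(p, array(NA_real_, c(1, 3, 384))), "finite")
})

test_that("generator maps noise to discriminator-shaped output deterministically", {
  g <- init_generator(4)
  noise <- sample_noise(5)
  expect_identical(dim(noise), c(5L, 100L))
  expect_true(all(noise >= 0 & noise <= 1))

  out <- generator_forward(g, noise)
  expect_identical(dim(out$x), c(5L, 3L, 384L))
  expect_identical(3L * 384L, 1152L) # output layer width matches input contract

  out2 <- generator_forward(g, noise)
  expect_identical(out$x, out2$x)

  # zero noise through zero-initialized biases keeps the linear chain at zero
  z0 <- generator_forward(g, matrix(0, 2, 100))
  expect_true(all(z0$x == 0))

  expect_error(generator_forward(g, matrix(0.5, 2, 7)), "matrix")
})

test_that("initializers give semi-orthogonal convolutions, He-uniform dense
           bounds, zero biases and unit norms", {
  p <- init_discriminator(11)
  # conv1 direction is 32 x 9: columns orthonormal (rows cannot be, 32 > 9)
  expect_lt(max(abs(crossprod(p$conv1$v) - diag(9))), 1e-8)
  # conv2 direction is 32 x 96: rows orthonormal
  expect_lt(max(abs(tcrossprod(p$conv2$v) - diag(32))), 1e-8)
  # dense layers: He-uniform bounds +/- sqrt(6 / fan_in)
  expect_lte(max(abs(p$fc1$v)), sqrt(6 / (32 * 384)))
  expect_lte(max(abs(p$out$W)), sqrt(6 / 512))
  g <- init_generator(11)
  expect_lte(max(abs(g$fc1$v)), sqrt(6 / 100))
  expect_lte(max(abs(g$fc2$v)), sqrt(6 / 512))
  # biases 0, weight-norm scales 1
  expect_true(all(p$conv1$b == 0) && all(p$fc1$b == 0) && all(p$out$b == 0))
  expect_true(all(p$conv1$g == 1) && all(p$conv2$g == 1) && all(p$fc1$g == 1))

  expect_identical(init_discriminator(11), p) # same seed, same draw
  expect_false(identical(init_discriminator(12), p))
})

test_that("trainable parameter counts are pinned", {
  # conv1: 32*9 + 32 + 32; conv2: 32*96 + 64; fc1: 512*12288 + 1024; out: 1026
  expect_identical(n_params(init_discriminator(1)), 6296994L)
  # fc1: 512*100 + 1024; fc2: 512*512 + 1024; out: 1152*512 + 1152
  expect_identical(n_params(init_generator(1)), 906368L)
})

test_that("weight normalization is invariant to rescaling a direction vector", {
  p <- init_discriminator(8)
  x <- array(rnorm(3 * 3 * 384), c(3, 3, 384))
  base <- discriminator_forward(p, x)
  p2 <- p
  p2$fc1$v <- p$fc1$v * 7.3 # same directions, g untouched
  scaled <- discriminator_forward(p2, x)
  expect_equal(scaled$score, base$score, tolerance = 1e-10)
  expect_equal(scaled$prob, base$prob, tolerance = 1e-10)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(5150)
  p <- init_discriminator(7)
  x <- array(rnorm(4 * 3 * 384), c(4, 3, 384))
  bt <- paired_batch(c(3, 5, 2, 8), c(2, 1, 4, 3), c(1, 2, 2, 1))
  loss_of <- function(params) {
    fw <- discriminator_forward(params, x)
    loss_train(fw$score, bt, 1, 1) + 0.5 * mean((fw$prob - 1)^2)
  }
  fw <- discriminator_forward(p, x, keep_cache = TRUE)
  d_score <- pigdgan:::loss_train_grad(fw$score, bt, 1, 1)
  d_logit <- 0.5 * 2 * (fw$prob - 1) * fw$prob * (1 - fw$prob) / 4
  bk <- pigdgan:::disc_backward(p, fw$cache, d_score, d_logit)
  rel_errs <- c()
  for (lay in names(p)) for (nm in names(p[[lay]])) {
    leaf <- p[[lay]][[nm]]
    for (i in sample(length(leaf), min(4, length(leaf)))) {
      eps <- 1e-5
      pp <- p; pp[[lay]][[nm]][i] <- leaf[i] + eps
      pm <- p; pm[[lay]][[nm]][i] <- leaf[i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      ana <- bk$grads[[lay]][[nm]][i]
      rel_errs <- c(rel_errs, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
    }
  }
  # almost all coordinates agree tightly; allow a stray ReLU-kink artifact of
  # the finite-difference probe (the kink makes the numeric quotient, not the
  # analytic gradient, inexact)
  expect_lt(stats::median(rel_errs), 1e-7)
  expect_gte(mean(rel_errs < 1e-4), 0.9)
  expect_lt(max(rel_errs), 1e-2)

  # generator chain, probed end to end through the discriminator
  g <- init_generator(7)
  noise <- sample_noise(3)
  gloss <- function(gp) {
    xo <- generator_forward(gp, noise)
    fwd <- discriminator_forward(p, xo$x)
    mean((fwd$prob - 1)^2) + 1e-4 * sum(gp$out$W^2)
  }
  gf <- generator_forward(g, noise, keep_cache = TRUE)
  fwd <- discriminator_forward(p, gf$x, keep_cache = TRUE)
  d_logit <- 2 * (fwd$prob - 1) * fwd$prob * (1 - fwd$prob) / 3
  bkd <- pigdgan:::disc_backward(p, fwd$cache, rep(0, 3), d_logit, need_dx = TRUE)
  gg <- pigdgan:::gen_backward(g, gf$cache, bkd$dx, l2 = 1e-4)
  rel_errs <- c()
  for (lay in names(g)) for (nm in names(g[[lay]])) {
    leaf <- g[[lay]][[nm]]
    for (i in sample(length(leaf), min(3, length(leaf)))) {
      eps <- 1e-6
      gp <- g; gp[[lay]][[nm]][i] <- leaf[i] + eps
      gm <- g; gm[[lay]][[nm]][i] <- leaf[i] - eps
      num <- (gloss(gp) - gloss(gm)) / (2 * eps)
      ana <- gg[[lay]][[nm]][i]
      rel_errs <- c(rel_errs, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
    }
  }
  expect_gte(mean(rel_errs < 1e-4), 0.9)
  expect_lt(max(rel_errs), 1e-2)
})

test_that("checkpoints round-trip and verify the architecture hash", {
  p <- init_discriminator(2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, path, seed = 2, epoch = 10)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, p)
  expect_identical(ck$header$epoch, 10)

  # corrupt the architecture -> hash mismatch
  obj <- readRDS(path)
  obj$params$fc1$v <- obj$params$fc1$v[, 1:100]
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "hash mismatch")
})
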