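test_that("paired-batch construction enforces its invariants", {
  expect_error(paired_batch(1:3, c(2, 1, 3), c(1, 2, 1)), "even")
  expect_error(paired_batch(1:4, c(2, 1, 3, 4), c(1, 2, 1, 2)), "involution")
  expect_error(paired_batch(1:4, c(1, 2, 4, 3), c(1, 2, 1, 2)), "involution")
  expect_error(paired_batch(1:4, c(2, 1, 4, 3), c(1, 2, 3, 2)), "1 or 2")
  expect_error(paired_batch(1:4, c(2, 1, 4, 3), c(1, 2, 1, 2),
                            subject_id = c("a", "b", "c", "c"),
                            visit_id = c("1", "2", "1", "2")),
               "share a subject")
  expect_error(paired_batch(1:4, c(2, 1, 4, 3), c(1, 2, 1, 2),
                            subject_id = c("a", "a", "c", "c"),
                            visit_id = c("1", "1", "1", "2")),
               "different visits")
  bt <- paired_batch(1:4, c(2, 1, 4, 3), c(1, 2, 2, 1))
  expect_s3_class(bt, "paired_batch")
})

test_that("paired-visit loss reproduces hand-computed values", {
  # alpha=1, beta=0, one pair, preds (2,1), truths (0,0): (4+1)/2
  bt <- paired_batch(c(0, 0), c(2, 1), c(1, 2))
  expect_equal(loss_train(c(2, 1), bt, alpha = 1, beta = 0), 2.5)

  # alpha=beta=1, preds (3,1), truths (2,2), visit order (1,2):
  # term1 = (1+1)/2 = 1; pred diff 2, truth diff 0 -> term2 = (4+4)/2 = 4
  bt2 <- paired_batch(c(2, 2), c(2, 1), c(1, 2))
  expect_equal(loss_train(c(3, 1), bt2, alpha = 1, beta = 1), 5)

  # exact fit is the zero of the loss for any weights
  expect_equal(loss_train(c(2, 2), bt2, alpha = 3, beta = 7), 0)

  expect_error(loss_train(c(1, 2, 3), bt2), "length")
})

test_that("discriminator and generator losses match their printed forms", {
  bt <- paired_batch(c(2, 2), c(2, 1), c(1, 2))
  pred <- c(3, 1)
  # gamma=1, delta=0 reduces exactly to the training loss
  expect_equal(loss_disc(pred, bt, d_real = c(0.7, 0.2), d_fake = c(0.4, 0.9),
                         gamma = 1, delta = 0),
               loss_train(pred, bt))
  # perfect discrimination zeroes the adversarial term
  expect_equal(loss_disc(bt$truth, bt, d_real = c(1 - 1e-12, 1 - 1e-12),
                         d_fake = c(1e-12, 1e-12), gamma = 1, delta = 1),
               0, tolerance = 1e-10)
  # gamma=0, delta=1, N=1, d_real=d_fake=0.5 -> 0.25 + 0.25
  expect_equal(loss_disc(pred, bt, d_real = 0.5, d_fake = 0.5,
                         gamma = 0, delta = 1), 0.5)

  expect_equal(loss_gen(c(1 - 1e-12, 1 - 1e-12)), 0, tolerance = 1e-10)
  expect_equal(loss_gen(c(1e-12, 1e-12)), 1, tolerance = 1e-10)
  expect_equal(loss_gen(c(0.5, 0.5)), 0.25)
  expect_error(loss_gen(numeric(0)), "non-empty")
  expect_error(loss_gen(c(0.5, 1.2)), "inside")
})

test_that("every loss matches an independent double-loop oracle on random
           batches", {
  set.seed(404)
  for (rep in 1:100) {
    n_pairs <- sample(1:32, 1)
    su <- random_paired_setup(n_pairs)
    n <- 2L * n_pairs
    pred <- runif(n, -5, 25)
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    bt <- paired_batch(su$truth, su$pair_index, su$visit_order)
    expect_equal(loss_train(pred, bt, a, b),
                 oracle_loss_train(pred, su$truth, su$pair_index,
                                   su$visit_order, a, b),
                 tolerance = 1e-10)
    d_real <- runif(n, 0.01, 0.99); d_fake <- runif(n, 0.01, 0.99)
    g <- runif(1, 0, 2); d <- runif(1, 0, 2)
    expect_equal(loss_disc(pred, bt, d_real, d_fake, a, b, g, d),
                 oracle_loss_disc(pred, su$truth, su$pair_index,
                                  su$visit_order, d_real, d_fake, a, b, g, d),
                 tolerance = 1e-10)
    expect_equal(loss_gen(d_fake), oracle_loss_gen(d_fake), tolerance = 1e-10)
  }
})

test_that("the paired term is symmetric under swapping pair members", {
  set.seed(77)
  for (rep in 1:20) {
    su <- random_paired_setup(8)
    pred <- runif(16, 0, 20)
    bt <- paired_batch(su$truth, su$pair_index, su$visit_order)
    # swap the members of every pair; the involution maps to itself, so the
    # pair bookkeeping is unchanged while values and visit flags travel
    perm <- su$pair_index
    bt_sw <- paired_batch(su$truth[perm], su$pair_index,
                          su$visit_order[perm])
    expect_equal(loss_train(pred, bt, 1, 1), loss_train(pred[perm], bt_sw, 1, 1))
  }
})

test_that("analytic prediction gradients vanish at the optimum and match
           numeric differentiation", {
  set.seed(99)
  su <- random_paired_setup(6)
  bt <- paired_batch(su$truth, su$pair_index, su$visit_order)
  # optimum: gradient identically zero
  expect_equal(pigdgan:::loss_train_grad(su$truth, bt, 1, 1), rep(0, 12))

  pred <- runif(12, 0, 20)
  gr <- pigdgan:::loss_train_grad(pred, bt, 1.3, 0.7)
  num <- vapply(seq_along(pred), function(i) {
    e <- 1e-6
    pp <- pred; pp[i] <- pred[i] + e
    pm <- pred; pm[i] <- pred[i] - e
    (loss_train(pp, bt, 1.3, 0.7) - loss_train(pm, bt, 1.3, 0.7)) / (2 * e)
  }, numeric(1))
  expect_equal(gr, num, tolerance = 1e-6)
})

test_that("historical-averaging penalty is a scaled squared drift", {
  cur <- list(a = matrix(1:4, 2), b = list(w = c(2, 0)))
  expect_equal(historical_average_penalty(cur, cur, 1), 0)

  avg <- list(a = matrix(0, 2, 2), b = list(w = c(0, 0)))
  expect_equal(historical_average_penalty(cur, avg, 1),
               sum((1:4)^2) + 4)
  expect_equal(historical_average_penalty(cur, avg, 0), 0)
  expect_equal(historical_average_penalty(cur, avg, 0.5),
               oracle_hist_penalty(cur, avg, 0.5))

  bad <- list(a = matrix(0, 2, 2), b = list(w = 0))
  expect_error(historical_average_penalty(cur, bad, 1), "congruent")

  set.seed(8)
  p <- init_generator(3)
  q <- rapply(p, function(x) x + rnorm(length(x), sd = 0.1), how = "replace")
  expect_equal(historical_average_penalty(p, q, 1e-3),
               oracle_hist_penalty(p, q, 1e-3), tolerance = 1e-10)
})
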