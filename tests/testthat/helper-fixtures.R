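# Shared fixtures and independent oracles for the test suite.

# small cohort used by several preprocessing/training tests
tiny_cohort <- function(n_subjects = 6, n_bouts = 2, seed = 101, ...) {
  simulate_cohort(sim_config(n_subjects = n_subjects,
                             n_bouts_per_session = n_bouts,
                             seed = seed, ...))
}

# memoized preprocessed examples (several test files reuse them)
.fixture_env <- new.env(parent = emptyenv())

tiny_examples <- function() {
  if (is.null(.fixture_env$tiny_ex)) {
    .fixture_env$tiny_ex <- preprocess_cohort(tiny_cohort())
  }
  .fixture_env$tiny_ex
}

# independent double-loop oracle for the paired-visit loss: literal sums,
# no vectorization shared with the implementation
oracle_loss_train <- function(pred, truth, pair_index, visit_order,
                              alpha, beta) {
  n <- length(pred)
  t1 <- 0
  for (i in seq_len(n)) t1 <- t1 + (pred[i] - truth[i])^2
  t1 <- t1 / n
  t2 <- 0
  for (i in seq_len(n)) {
    j <- pair_index[i]
    if (visit_order[i] == 1L) {
      dp <- pred[i] - pred[j]; dt <- truth[i] - truth[j]
    } else {
      dp <- pred[j] - pred[i]; dt <- truth[j] - truth[i]
    }
    t2 <- t2 + (dp - dt)^2
  }
  t2 <- t2 / n
  alpha * t1 + beta * t2
}

oracle_loss_disc <- function(pred, truth, pair_index, visit_order,
                             d_real, d_fake, alpha, beta, gamma, delta) {
  adv1 <- 0
  for (v in d_real) adv1 <- adv1 + (v - 1)^2
  adv2 <- 0
  for (v in d_fake) adv2 <- adv2 + v^2
  gamma * oracle_loss_train(pred, truth, pair_index, visit_order, alpha, beta) +
    delta * (adv1 / length(d_real) + adv2 / length(d_fake))
}

oracle_loss_gen <- function(d_fake) {
  s <- 0
  for (v in d_fake) s <- s + (v - 1)^2
  s / length(d_fake)
}

oracle_hist_penalty <- function(cur, avg, coef) {
  cv <- unlist(cur, use.names = FALSE)
  av <- unlist(avg, use.names = FALSE)
  s <- 0
  for (i in seq_along(cv)) s <- s + (cv[i] - av[i])^2
  coef * s
}

# random but valid paired batch of n/2 pairs (predictions drawn separately)
random_paired_setup <- function(n_pairs) {
  n <- 2L * n_pairs
  pair_index <- integer(n)
  visit_order <- integer(n)
  for (k in seq_len(n_pairs)) {
    i <- 2L * k - 1L; j <- 2L * k
    pair_index[i] <- j; pair_index[j] <- i
    o <- sample(1:2)
    visit_order[i] <- o[1]; visit_order[j] <- o[2]
  }
  list(truth = round(runif(n, 0, 20)), pair_index = pair_index,
       visit_order = visit_order)
}
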