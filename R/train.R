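# Mini-batch construction with visit pairing, Adam optimization of the CNN
# (paired-visit loss) or the GAN (alternating discriminator/generator
# updates), dev-set convergence monitoring, and historical averaging.

#' Training configuration
#'
#' @param batch_pairs examples selected per step; each gains an opposite-visit
#'   partner, so the mini-batch holds `2 * batch_pairs` examples (200 -> 400
#'   at the defaults).
#' @param learning_rate Adam step size.
#' @param epochs training epochs; one epoch is `ceil(n_train / batch)` steps.
#' @param alpha,beta,gamma,delta loss weights (see [loss_train()],
#'   [loss_disc()]).
#' @param dev_subject_count subjects held out to monitor convergence.
#' @param convergence_window,convergence_tol steadiness criterion: converged
#'   when (max - min) / max of the trailing window drops below the tolerance.
#' @param dropout dropout probability in training mode.
#' @param hist_decay,hist_coef historical-averaging EMA decay and penalty
#'   coefficient (applied to the discriminator/CNN only).
#' @param gen_l2 L2 coefficient on the generator output layer's weights.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param mode `"CNN"` or `"GAN"`.
#' @param seed master seed; every random stream is derived from it.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_pairs = 200L, learning_rate = 0.01,
                         epochs = 100L, alpha = 1, beta = 1,
                         gamma = 1, delta = 1,
                         dev_subject_count = 10L,
                         convergence_window = 20L, convergence_tol = 0.05,
                         dropout = 0.5,
                         hist_decay = 0.999, hist_coef = 1e-3,
                         gen_l2 = 1e-4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
                         mode = c("CNN", "GAN"), seed = 1L) {
  mode <- match.arg(mode)
  abort_if(batch_pairs < 1, "`batch_pairs` must be at least 1")
  abort_if(learning_rate < 0, "`learning_rate` must be non-negative")
  abort_if(epochs < 1, "`epochs` must be at least 1")
  abort_if(any(c(alpha, beta, gamma, delta) < 0),
           "loss weights must be non-negative")
  structure(list(batch_pairs = as.integer(batch_pairs),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 dev_subject_count = as.integer(dev_subject_count),
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol, dropout = dropout,
                 hist_decay = hist_decay, hist_coef = hist_coef,
                 gen_l2 = gen_l2, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 mode = mode, seed = as.integer(seed)),
            class = "train_config")
}

#' Split examples into train and development sets by subject
#'
#' The development subjects are drawn once before training and stay fixed;
#' no subject straddles both sides.
#'
#' @param examples a `spectral_examples` set.
#' @param dev_subject_count how many subjects to hold out.
#' @param seed integer seed for the draw.
#' @return list with `train` and `dev` (`spectral_examples`), plus
#'   `dev_subjects`.
#' @export
split_dev <- function(examples, dev_subject_count = 10L, seed = 1L) {
  subjects <- unique(examples$meta$subject_id)
  abort_if(length(subjects) < dev_subject_count + 1L,
           "need more than `dev_subject_count` distinct subjects")
  dev_subjects <- with_seed(derive_seed(seed, "split_dev"), {
    if (dev_subject_count > 0) sample(subjects, dev_subject_count) else character(0)
  })
  in_dev <- examples$meta$subject_id %in% dev_subjects
  # pairing requires every training subject to have examples from >= 2 visits
  tr_meta <- examples$meta[!in_dev, ]
  nv <- tapply(tr_meta$visit_id, tr_meta$subject_id,
               function(v) length(unique(v)))
  abort_if(any(nv < 2),
           "training subjects with a single visit cannot be paired: ",
           paste(names(nv)[nv < 2], collapse = ", "))
  list(train = subset_examples(examples, !in_dev),
       dev = subset_examples(examples, in_dev),
       dev_subjects = dev_subjects)
}

#' Sample a visit-paired mini-batch
#'
#' Selects `batch_pairs` examples uniformly (subjects may repeat) and joins
#' each with a uniformly drawn example from the same subject's opposite
#' visit, giving a batch of `2 * batch_pairs`. Consumes the caller's RNG
#' stream.
#'
#' @param examples training `spectral_examples`.
#' @param batch_pairs number of selections.
#' @return a [paired_batch()] carrying the example tensor.
#' @export
sample_paired_batch <- function(examples, batch_pairs) {
  meta <- examples$meta
  n <- nrow(meta)
  abort_if(n < 2L, "need at least two examples to pair")
  first <- sample.int(n, batch_pairs, replace = TRUE)
  partner <- vapply(first, function(i) {
    cand <- which(meta$subject_id == meta$subject_id[i] &
                    meta$visit_id != meta$visit_id[i])
    abort_if(length(cand) == 0L, "subject ", meta$subject_id[i],
             " has no opposite-visit example")
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  sel <- as.vector(rbind(first, partner)) # interleave: pair k -> rows 2k-1, 2k
  m <- meta[sel, ]
  npair <- length(sel)
  pair_index <- as.integer(as.vector(rbind(seq(2, npair, by = 2), seq(1, npair, by = 2))))
  # the member with the lexicographically earlier visit id is the visit-1 member
  visit_order <- integer(npair)
  for (k in seq(1, npair, by = 2)) {
    o <- order(c(m$visit_id[k], m$visit_id[k + 1]))
    visit_order[k] <- which(o == 1L)
    visit_order[k + 1] <- which(o == 2L)
  }
  paired_batch(truth = m$pigd_score, pair_index = pair_index,
               visit_order = visit_order,
               x = examples$logspec[sel, , , drop = FALSE],
               subject_id = m$subject_id, visit_id = m$visit_id)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# fused Adam + historical-averaging step over a parameter tree; moments and
# the running average are updated in place (they are private to the loop)
adam_hist_step <- function(params, grads, state, avg, lr, b1, b2, eps,
                           hist_coef, hist_decay) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v, a) {
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      for (k in seq_along(p)) out[[k]] <- walk(p[[k]], g[[k]], m[[k]], v[[k]], a[[k]])
      out
    } else {
      cpp_adam_hist_step(p, g, m, v, a, state$t, lr, b1, b2, eps,
                         hist_coef, hist_decay)
    }
  }
  list(params = walk(params, grads, state$m, state$v, avg), state = state)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# ---- shared training internals ---------------------------------------------

# one discriminator/CNN gradient evaluation on a paired batch; fake branch
# optional. Returns grads tree and the component losses.
disc_step_grads <- function(params, batch, cfg, fake_x = NULL,
                            dropout_seed, dropout_seed_fake = NULL,
                            weights = NULL) {
  if (is.null(weights)) weights <- disc_weights(params)
  fw <- with_seed(dropout_seed,
                  discriminator_forward(params, batch$x, training = TRUE,
                                        dropout = cfg$dropout, keep_cache = TRUE,
                                        weights = weights))
  pred <- fw$score
  n <- batch$n
  if (is.null(fake_x)) {
    l_train <- loss_train(pred, batch, cfg$alpha, cfg$beta)
    d_score <- loss_train_grad(pred, batch, cfg$alpha, cfg$beta)
    bk <- disc_backward(params, fw$cache, d_score, rep(0, n))
    list(grads = bk$grads, loss = l_train, loss_train = l_train,
         d_real = fw$prob, d_fake = NULL)
  } else {
    fwf <- with_seed(dropout_seed_fake,
                     discriminator_forward(params, fake_x, training = TRUE,
                                           dropout = cfg$dropout, keep_cache = TRUE,
                                           weights = weights))
    l_train <- loss_train(pred, batch, cfg$alpha, cfg$beta)
    l_disc <- cfg$gamma * l_train +
      cfg$delta * (mean((fw$prob - 1)^2) + mean(fwf$prob^2))
    d_score <- cfg$gamma * loss_train_grad(pred, batch, cfg$alpha, cfg$beta)
    # d/dlogit of delta * mean((sigmoid(u) - 1)^2): chain through the sigmoid
    d_logit_real <- cfg$delta * 2 * (fw$prob - 1) * fw$prob * (1 - fw$prob) / n
    bk_real <- disc_backward_raw(params, fw$cache, d_score, d_logit_real)
    nf <- length(fwf$prob)
    d_logit_fake <- cfg$delta * 2 * fwf$prob * fwf$prob * (1 - fwf$prob) / nf
    bk_fake <- disc_backward_raw(params, fwf$cache, rep(0, nf), d_logit_fake)
    # weight-norm chain rule is linear in dW: sum the raw branches, map once
    raw <- tree_map(`+`, bk_real$raw, bk_fake$raw)
    grads <- disc_grads_from_raw(params, fw$cache, raw)
    list(grads = grads, loss = l_disc, loss_train = l_train,
         d_real = fw$prob, d_fake = fwf$prob)
  }
}

#' Train the convolutional severity regressor (CNN mode)
#'
#' Runs `epochs` x `ceil(n_train / batch)` Adam steps of the paired-visit
#' loss on the score head (the real/fake head is ignored), with dropout,
#' weight normalization, and a historical-averaging penalty. The development
#' MSE is recorded at the end of every epoch.
#'
#' @param examples a `spectral_examples` set (all subjects; the dev split is
#'   made internally from `config$seed`).
#' @param config a [train_config()].
#' @return a `train_state`: list with `params`, per-epoch traces
#'   (`train_loss`: inference-mode loss on a fixed evaluation batch;
#'   `train_loss_batch`: mean mini-batch loss; `dev_mse`), the held-out
#'   subjects and the config.
#' @export
train_cnn <- function(examples, config = train_config(mode = "CNN")) {
  abort_if(config$mode != "CNN", "config$mode must be 'CNN'")
  run_training(examples, config)
}

#' Train the GAN (discriminator + generator)
#'
#' Per step: a paired real batch and a fresh uniform noise batch are drawn;
#' the discriminator takes one Adam step on [loss_disc()] (plus the
#' historical penalty), then the generator takes one Adam step on
#' [loss_gen()] against the updated discriminator. At the end of every epoch
#' the losses are evaluated in inference mode on a fixed evaluation batch and
#' noise draw (deterministic monitoring traces), alongside running batch
#' means (`*_batch`) and the development MSE.
#'
#' @inheritParams train_cnn
#' @return a `train_state` with `params` (discriminator), `gen_params`, and
#'   traces `disc_loss`, `gen_loss`, `train_loss`, `dev_mse`, `d_fake`.
#' @export
train_gan <- function(examples, config = train_config(mode = "GAN")) {
  abort_if(config$mode != "GAN", "config$mode must be 'GAN'")
  run_training(examples, config)
}

run_training <- function(examples, cfg) {
  split <- split_dev(examples, cfg$dev_subject_count, cfg$seed)
  train <- split$train
  n_train <- nrow(train$meta)
  batch_n <- 2L * cfg$batch_pairs
  steps_per_epoch <- max(1L, ceiling(n_train / batch_n))

  params <- init_discriminator(cfg$seed)
  opt <- adam_init(params)
  hist_avg <- tree_map(function(a) a + 0, params) # private deep copy (updated in place)
  gan <- cfg$mode == "GAN"
  if (gan) {
    gen_params <- init_generator(cfg$seed)
    gen_opt <- adam_init(gen_params)
  }

  traces <- list(train_loss = numeric(0), dev_mse = numeric(0),
                 train_loss_batch = numeric(0))
  if (gan) {
    traces$disc_loss <- numeric(0)
    traces$gen_loss <- numeric(0)
    traces$d_fake <- numeric(0)
    traces$disc_loss_batch <- numeric(0)
    traces$gen_loss_batch <- numeric(0)
  }

  # fixed evaluation batch and noise: the per-epoch loss traces are computed
  # on these in inference mode, so they are deterministic functions of the
  # parameters and measure parameter settling rather than mini-batch noise
  eval_pairs <- min(50L, max(1L, n_train %/% 2L))
  eval_batch <- with_seed(derive_seed(cfg$seed, "eval_batch"),
                          sample_paired_batch(train, eval_pairs))
  eval_noise <- if (gan) {
    with_seed(derive_seed(cfg$seed, "eval_noise"),
              sample_noise(2L * eval_pairs, ncol(gen_params$fc1$v)))
  }

  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ep_train <- ep_disc <- ep_gen <- 0
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      batch <- with_seed(derive_seed(cfg$seed, "batch", step),
                         sample_paired_batch(train, cfg$batch_pairs))
      fake_x <- NULL
      if (gan) {
        noise <- with_seed(derive_seed(cfg$seed, "noise", step),
                           sample_noise(batch_n, ncol(gen_params$fc1$v)))
        gfw <- generator_forward(gen_params, noise, keep_cache = TRUE)
        fake_x <- gfw$x
      }
      sg <- disc_step_grads(params, batch, cfg, fake_x,
                            dropout_seed = derive_seed(cfg$seed, "drop_real", step),
                            dropout_seed_fake = derive_seed(cfg$seed, "drop_fake", step))
      abort_if(!is.finite(sg$loss), "training diverged: non-finite loss at step ", step)
      up <- adam_hist_step(params, sg$grads, opt, hist_avg, cfg$learning_rate,
                           cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps,
                           cfg$hist_coef, cfg$hist_decay)
      params <- up$params
      opt <- up$state

      ep_train <- ep_train + sg$loss_train
      if (gan) {
        ep_disc <- ep_disc + sg$loss
        # generator update against the freshly updated discriminator
        fwg <- with_seed(derive_seed(cfg$seed, "drop_gen", step),
                         discriminator_forward(params, fake_x, training = TRUE,
                                               dropout = cfg$dropout,
                                               keep_cache = TRUE))  # fresh weights: params just updated
        lg <- loss_gen(fwg$prob)
        nf <- length(fwg$prob)
        d_logit <- 2 * (fwg$prob - 1) * fwg$prob * (1 - fwg$prob) / nf
        bkd <- disc_backward_raw(params, fwg$cache, rep(0, nf), d_logit,
                                 need_dx = TRUE, need_param_grads = FALSE)
        ggr <- gen_backward(gen_params, gfw$cache, bkd$dx, l2 = cfg$gen_l2)
        gup <- adam_hist_step(gen_params, ggr, gen_opt, gen_params,
                              cfg$learning_rate, cfg$adam_beta1,
                              cfg$adam_beta2, cfg$adam_eps, 0, -1)
        gen_params <- gup$params
        gen_opt <- gup$state
        ep_gen <- ep_gen + lg
      }
    }
    # epoch-end evaluation: inference mode on the fixed batch/noise
    ws <- disc_weights(params)
    fw_ev <- discriminator_forward(params, eval_batch$x, weights = ws)
    lt_ev <- loss_train(fw_ev$score, eval_batch, cfg$alpha, cfg$beta)
    traces$train_loss <- c(traces$train_loss, lt_ev)
    traces$train_loss_batch <- c(traces$train_loss_batch,
                                 ep_train / steps_per_epoch)
    if (nrow(split$dev$meta) > 0L) {
      fw_dev <- discriminator_forward(params, split$dev$logspec, weights = ws)
      traces$dev_mse <- c(traces$dev_mse,
                          mean((fw_dev$score - split$dev$meta$pigd_score)^2))
    } else {
      traces$dev_mse <- c(traces$dev_mse, NA_real_)
    }
    if (gan) {
      fake_ev <- generator_forward(gen_params, eval_noise)$x
      fw_fk <- discriminator_forward(params, fake_ev, weights = ws)
      traces$disc_loss <- c(traces$disc_loss,
                            cfg$gamma * lt_ev +
                              cfg$delta * (mean((fw_ev$prob - 1)^2) +
                                             mean(fw_fk$prob^2)))
      traces$gen_loss <- c(traces$gen_loss, mean((fw_fk$prob - 1)^2))
      traces$d_fake <- c(traces$d_fake, mean(fw_fk$prob))
      traces$disc_loss_batch <- c(traces$disc_loss_batch,
                                  ep_disc / steps_per_epoch)
      traces$gen_loss_batch <- c(traces$gen_loss_batch, ep_gen / steps_per_epoch)
    }
  }

  out <- list(params = params, traces = traces, config = cfg,
              dev_subjects = split$dev_subjects,
              n_train = n_train, steps_per_epoch = steps_per_epoch,
              mode = cfg$mode)
  if (gan) out$gen_params <- gen_params
  structure(out, class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> mode=%s  epochs=%d  n_train=%d  final dev MSE=%.3f\n",
              x$mode, length(x$traces$dev_mse), x$n_train,
              utils::tail(x$traces$dev_mse, 1)))
  invisible(x)
}

#' Steady-state convergence check on a loss trace
#'
#' A trace has converged when, over its trailing window, the relative
#' fluctuation `(max - min) / max` falls below the tolerance.
#'
#' @param trace numeric loss trace (one value per epoch).
#' @param window trailing window length, epochs.
#' @param tol relative fluctuation tolerance.
#' @return logical flag.
#' @export
check_convergence <- function(trace, window = 20L, tol = 0.05) {
  abort_if(length(trace) < window, "trace shorter than the window")
  w <- utils::tail(trace, window)
  hi <- max(w); lo <- min(w)
  if (hi == 0) return(lo == 0)
  (hi - lo) / hi < tol
}
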