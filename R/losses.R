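# Training objectives.
#
# The regression loss couples the usual per-example squared error with a
# paired-visit term: every example is paired with an example from the same
# subject's opposite visit, and the model is penalized when the predicted
# within-subject visit difference departs from the clinician-scored one.
# This rewards learning medication-state contrast rather than just
# between-subject differences. The adversarial game adds a least-squares
# real/fake term for the discriminator and the mirror-image term for the
# generator, stabilized by historical averaging of parameters.

#' Construct a paired batch
#'
#' Bundles predictions' targets and the pairing bookkeeping. `pair_index`
#' must be an involution (the partner of the partner of `i` is `i`) and
#' `visit_order` flags whether each example belongs to the subject's first
#' or second visit of the pair.
#'
#' @param truth numeric vector of clinician scores, one per example.
#' @param pair_index integer vector: index of each example's opposite-visit
#'   partner.
#' @param visit_order integer vector in `{1, 2}`.
#' @param x optional example tensor (N x 3 x 384).
#' @param subject_id,visit_id optional id vectors; when given, pairing is
#'   checked to join the same subject across different visits.
#' @return a `paired_batch` list.
#' @export
paired_batch <- function(truth, pair_index, visit_order, x = NULL,
                         subject_id = NULL, visit_id = NULL) {
  n <- length(truth)
  abort_if(n %% 2L != 0L, "paired batch size must be even")
  abort_if(length(pair_index) != n || length(visit_order) != n,
           "pairing vectors must match batch size")
  abort_if(any(pair_index < 1L) || any(pair_index > n) ||
             any(pair_index == seq_len(n)) ||
             any(pair_index[pair_index] != seq_len(n)),
           "`pair_index` must be a fixed-point-free involution")
  abort_if(!all(visit_order %in% c(1L, 2L)), "`visit_order` must be 1 or 2")
  if (!is.null(subject_id)) {
    abort_if(any(subject_id != subject_id[pair_index]),
             "paired examples must share a subject")
    if (!is.null(visit_id)) {
      abort_if(any(visit_id == visit_id[pair_index]),
               "paired examples must come from different visits")
    }
  }
  structure(list(truth = as.numeric(truth), pair_index = as.integer(pair_index),
                 visit_order = as.integer(visit_order), x = x,
                 subject_id = subject_id, visit_id = visit_id, n = n),
            class = "paired_batch")
}

# signed within-pair differences, ordered visit-1 minus visit-2; each member
# of a pair carries the same difference value
pair_diff <- function(values, batch) {
  sgn <- ifelse(batch$visit_order == 1L, 1, -1)
  sgn * (values - values[batch$pair_index])
}

#' Paired-visit regression loss
#'
#' `alpha` x mean squared error of predictions against clinician scores,
#' plus `beta` x mean squared error of predicted within-subject visit
#' differences against clinician-scored differences. Both means run over all
#' N examples, so each pair contributes its difference term twice (once per
#' member), keeping per-example weighting uniform.
#'
#' @param pred numeric predictions, one per example.
#' @param batch a [paired_batch()].
#' @param alpha,beta non-negative term weights.
#' @return non-negative scalar; zero exactly when predictions match scores.
#' @export
loss_train <- function(pred, batch, alpha = 1, beta = 1) {
  abort_if(!inherits(batch, "paired_batch"), "`batch` must be a paired_batch")
  abort_if(length(pred) != batch$n, "prediction length must match batch size")
  abort_if(alpha < 0 || beta < 0, "loss weights must be non-negative")
  term1 <- mean((pred - batch$truth)^2)
  e <- pair_diff(pred, batch) - pair_diff(batch$truth, batch)
  term2 <- mean(e^2)
  alpha * term1 + beta * term2
}

# gradient of loss_train w.r.t. the predictions
loss_train_grad <- function(pred, batch, alpha = 1, beta = 1) {
  n <- batch$n
  g1 <- 2 * (pred - batch$truth) / n
  sgn <- ifelse(batch$visit_order == 1L, 1, -1)
  e <- pair_diff(pred, batch) - pair_diff(batch$truth, batch)
  # e_i = e_{pair(i)}; d/dpred_i of (e_i^2 + e_pair^2)/n = 4 e_i sgn_i / n
  g2 <- 4 * e * sgn / n
  alpha * g1 + beta * g2
}

#' Discriminator loss
#'
#' `gamma` x [loss_train()] plus `delta` x the least-squares adversarial
#' term: mean (D(real) - 1)^2 + mean D(fake)^2. Minimizing it pushes the
#' real-example probability towards 1 and the fake-example probability
#' towards 0 while still regressing severity on the real examples.
#'
#' @param pred score-head predictions on the real examples.
#' @param batch a [paired_batch()] of real examples.
#' @param d_real sigmoid outputs on the real examples, in (0,1).
#' @param d_fake sigmoid outputs on the generated examples, in (0,1).
#' @param alpha,beta,gamma,delta non-negative weights.
#' @return non-negative scalar.
#' @export
loss_disc <- function(pred, batch, d_real, d_fake,
                      alpha = 1, beta = 1, gamma = 1, delta = 1) {
  abort_if(length(d_real) == 0 || length(d_fake) == 0,
           "adversarial terms need non-empty probability vectors")
  abort_if(any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1),
           "discriminator probabilities must lie strictly inside (0, 1)")
  abort_if(gamma < 0 || delta < 0, "loss weights must be non-negative")
  gamma * loss_train(pred, batch, alpha, beta) +
    delta * (mean((d_real - 1)^2) + mean(d_fake^2))
}

#' Generator loss
#'
#' Mean of (D(fake) - 1)^2: the generator is rewarded for pushing the
#' discriminator's real-probability of its samples towards 1.
#'
#' @param d_fake sigmoid outputs on generated examples, in (0,1).
#' @return non-negative scalar.
#' @export
loss_gen <- function(d_fake) {
  abort_if(length(d_fake) == 0, "`d_fake` must be non-empty")
  abort_if(any(d_fake <= 0 | d_fake >= 1),
           "discriminator probabilities must lie strictly inside (0, 1)")
  mean((d_fake - 1)^2)
}

#' Historical-averaging penalty
#'
#' L2 cost on the drift of the current parameters from a running
#' (exponential moving) average of recent parameters; discourages updates
#' that jump far from the trajectory's recent history, which stabilizes the
#' adversarial game.
#'
#' @param current,running_average congruent parameter trees.
#' @param coefficient non-negative penalty weight.
#' @return `coefficient` x sum of squared elementwise differences.
#' @export
historical_average_penalty <- function(current, running_average, coefficient) {
  abort_if(coefficient < 0, "`coefficient` must be non-negative")
  abort_if(!tree_congruent(current, running_average),
           "parameter trees are not congruent")
  coefficient * tree_reduce_sum(function(a, b) (a - b)^2, current, running_average)
}

# gradient contribution of the historical penalty: 2 c (theta - avg)
historical_average_grad <- function(current, running_average, coefficient) {
  tree_map(function(a, b) 2 * coefficient * (a - b), current, running_average)
}

# EMA update of the running average after a step
historical_average_update <- function(running_average, current, decay) {
  tree_map(function(a, b) decay * a + (1 - decay) * b, running_average, current)
}
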