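# Per-visit scoring and ON/OFF discrimination analysis.
#
# Per-walk predictions are averaged within a visit; for every subject with
# at least one ON and one OFF visit, the mean predicted score across OFF
# visits should exceed the mean across ON visits. Accuracy counts strict
# inequalities; agreement with clinician scores is summarized by the
# coefficient of determination.

#' Score every visit with a trained model
#'
#' Evaluates the score head in inference mode (dropout off) on every walk
#' example and averages predictions within each (subject, visit).
#'
#' @param params trained discriminator parameters.
#' @param examples a `spectral_examples` set.
#' @return data frame of visit scores: `subject_id`, `visit_id`, `state`,
#'   `mean_pred`, `clinician_score`, `n_walks`.
#' @export
score_visits <- function(params, examples) {
  meta <- examples$meta
  abort_if(nrow(meta) == 0L, "no examples to score")
  fw <- discriminator_forward(params, examples$logspec, training = FALSE)
  key <- paste(meta$subject_id, meta$visit_id, sep = "\r")
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  ord <- !duplicated(key)
  out <- data.frame(
    subject_id = meta$subject_id[ord],
    visit_id = meta$visit_id[ord],
    state = meta$state[ord],
    clinician_score = meta$pigd_score[ord]
  )
  # tapply sorts by key; realign to first-occurrence order
  skey <- sort(unique(key))
  mp <- tapply(fw$score, key, mean)[skey]
  nw <- tapply(fw$score, key, length)[skey]
  pos <- match(paste(out$subject_id, out$visit_id, sep = "\r"), skey)
  out$mean_pred <- as.numeric(mp[pos])
  out$n_walks <- as.integer(nw[pos])
  out
}

# aggregate visit scores into one row per subject having both states;
# TRANSITIONING visits are excluded from both averages
subject_on_off <- function(visit_scores) {
  vs <- visit_scores[visit_scores$state %in% c("ON", "OFF"), , drop = FALSE]
  rows <- lapply(split(vs, vs$subject_id), function(d) {
    on <- d[d$state == "ON", , drop = FALSE]
    off <- d[d$state == "OFF", , drop = FALSE]
    if (nrow(on) == 0L || nrow(off) == 0L) return(NULL)
    data.frame(subject_id = d$subject_id[1],
               mu_on = mean(on$mean_pred), mu_off = mean(off$mean_pred),
               mu_hat_on = mean(on$clinician_score),
               mu_hat_off = mean(off$clinician_score))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(subject_id = character(0), mu_on = numeric(0),
                      mu_off = numeric(0), mu_hat_on = numeric(0),
                      mu_hat_off = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' ON/OFF discrimination accuracy
#'
#' Fraction of subjects whose OFF-state mean score strictly exceeds their
#' ON-state mean score. Ties count as incorrect.
#'
#' @param subject_rows per-subject table from [build_report()] (columns
#'   `mu_on`, `mu_off`, `mu_hat_on`, `mu_hat_off`).
#' @param use_predictions compare model means (`mu_*`); otherwise clinician
#'   means (`mu_hat_*`).
#' @return fraction in `[0, 1]`.
#' @export
on_off_accuracy <- function(subject_rows, use_predictions = TRUE) {
  abort_if(nrow(subject_rows) == 0L,
           "accuracy undefined: no subjects with both ON and OFF visits")
  if (use_predictions) {
    mean(subject_rows$mu_off > subject_rows$mu_on)
  } else {
    mean(subject_rows$mu_hat_off > subject_rows$mu_hat_on)
  }
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` about the mean of the truth; may be negative for
#' predictors worse than the truth mean. `method = "pearson"` returns the
#' squared Pearson correlation instead.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @param method `"ss"` (residual sum of squares) or `"pearson"`.
#' @return a real number, at most 1 for `method = "ss"`.
#' @export
r_squared <- function(pred, truth, method = c("ss", "pearson")) {
  method <- match.arg(method)
  abort_if(length(pred) != length(truth) || length(truth) < 2L,
           "`pred` and `truth` must have equal length >= 2")
  abort_if(stats::var(truth) == 0, "R^2 undefined for constant truth")
  if (method == "ss") {
    1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  } else {
    stats::cor(pred, truth)^2
  }
}

#' Build the ON/OFF evaluation report
#'
#' `protocol = "multi_visit_on_off"` drops TRANSITIONING visits and keeps
#' every subject with at least one ON and one OFF visit;
#' `protocol = "paired_two_visit"` additionally requires exactly one visit
#' of each state per subject (others are excluded). The report combines the
#' model's and the clinician's ON/OFF accuracy and the coefficient of
#' determination between the 2-per-subject state means.
#'
#' @param visit_scores data frame from [score_visits()].
#' @param protocol evaluation protocol.
#' @param r2_method passed to [r_squared()].
#' @return an `evaluation_report`: list with `on_off_accuracy`,
#'   `clinician_accuracy`, `r_squared`, `n_subjects_counted`, `subjects`
#'   (per-subject table) and `excluded` subject ids.
#' @export
build_report <- function(visit_scores,
                         protocol = c("multi_visit_on_off", "paired_two_visit"),
                         r2_method = "ss") {
  protocol <- match.arg(protocol)
  rows <- subject_on_off(visit_scores)
  excluded <- setdiff(unique(visit_scores$subject_id), rows$subject_id)
  if (protocol == "paired_two_visit" && nrow(rows) > 0L) {
    vs <- visit_scores[visit_scores$state %in% c("ON", "OFF"), , drop = FALSE]
    cnt <- table(vs$subject_id, vs$state)
    good <- rownames(cnt)[cnt[, "ON"] == 1 & cnt[, "OFF"] == 1]
    excluded <- union(excluded, setdiff(rows$subject_id, good))
    rows <- rows[rows$subject_id %in% good, , drop = FALSE]
  }
  abort_if(nrow(rows) == 0L,
           "no subjects satisfy the ", protocol, " protocol")
  preds <- c(rows$mu_on, rows$mu_off)
  truths <- c(rows$mu_hat_on, rows$mu_hat_off)
  structure(list(
    on_off_accuracy = on_off_accuracy(rows, use_predictions = TRUE),
    clinician_accuracy = on_off_accuracy(rows, use_predictions = FALSE),
    r_squared = r_squared(preds, truths, r2_method),
    n_subjects_counted = nrow(rows),
    subjects = rows,
    excluded = excluded,
    protocol = protocol
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> protocol=%s  subjects=%d\n",
              x$protocol, x$n_subjects_counted))
  cat(sprintf("  model ON/OFF accuracy:     %.0f%%\n", 100 * x$on_off_accuracy))
  cat(sprintf("  clinician ON/OFF accuracy: %.0f%%\n", 100 * x$clinician_accuracy))
  cat(sprintf("  R^2 vs clinician scores:   %.3f\n", x$r_squared))
  invisible(x)
}
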