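# Raw session -> fixed-size log-spectral examples.
#
# Turns are located from cumulative rotation on the first gyroscope axis and
# excised; the remaining straight-walk snippets are truncated to 3 s
# (384 samples at 128 Hz), high-pass filtered to remove gravity and drift,
# and converted to 384-bin log-magnitude spectra per acceleration channel.

#' Detect turns from gyroscope angular rate
#'
#' A turn is a period over which the cumulative rotation about the sensor's
#' first axis, integrated over a sliding window, exceeds a threshold
#' (default 120 degrees). Angular rate is integrated by the trapezoidal rule;
#' whenever the windowed rotation magnitude crosses the threshold, the whole
#' contributing window is marked, and marked stretches separated by less than
#' `merge_gap` seconds are merged.
#'
#' @param gyro_x angular-rate series, degrees/second.
#' @param sample_rate sampling rate, Hz.
#' @param angle_threshold rotation threshold, degrees.
#' @param window integration window, seconds.
#' @param merge_gap merge detections closer than this, seconds.
#' @return data frame with columns `start`, `end`: sorted, non-overlapping
#'   half-open sample intervals `[start, end)`, 1-based.
#' @export
detect_turns <- function(gyro_x, sample_rate, angle_threshold = 120,
                         window = 2, merge_gap = 0.5) {
  abort_if(angle_threshold <= 0, "`angle_threshold` must be positive")
  n <- length(gyro_x)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
  abort_if(any(!is.finite(gyro_x)), "`gyro_x` contains non-finite samples")

  # cumulative trapezoidal integral of angular rate (degrees)
  cum <- c(0, cumsum((gyro_x[-n] + gyro_x[-1]) / 2)) / sample_rate
  w <- max(1L, round(window * sample_rate))
  lag <- pmax(seq_len(n) - w, 1L)
  rot <- abs(cum - cum[lag]) # rotation over the trailing window at each sample

  hit <- which(rot > angle_threshold)
  if (length(hit) == 0) return(data.frame(start = integer(0), end = integer(0)))

  # expand each crossing to its full contributing window, then merge
  starts <- pmax(hit - w, 1L)
  ends <- hit + 1L # half-open
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  gap <- max(0L, round(merge_gap * sample_rate))
  out_s <- starts[1]; out_e <- ends[1]
  res_s <- integer(0); res_e <- integer(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= out_e + gap) {
      out_e <- max(out_e, ends[k])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- starts[k]; out_e <- ends[k]
    }
  }
  res_s <- c(res_s, out_s); res_e <- c(res_e, min(out_e, n + 1L))
  data.frame(start = as.integer(res_s), end = as.integer(pmin(res_e, n + 1L)))
}

#' Cut a session into straight-walk snippets
#'
#' Returns the complement of the turn intervals along the time axis. Snippets
#' shorter than `min_samples` cannot yield a full example and are dropped;
#' the number dropped is attached as attribute `n_dropped`.
#'
#' @param session a `raw_session`.
#' @param turn_intervals data frame of half-open sample intervals, as from
#'   [detect_turns()].
#' @param min_samples minimum snippet length kept.
#' @return list of walk snippets: each a list with `accel` (3 x L) and the
#'   session metadata.
#' @export
segment_walks <- function(session, turn_intervals, min_samples = 384L) {
  n <- ncol(session$accel)
  keep <- rep(TRUE, n)
  if (nrow(turn_intervals) > 0) {
    abort_if(any(turn_intervals$start < 1) || any(turn_intervals$end > n + 1L),
             "turn intervals outside session bounds")
    for (k in seq_len(nrow(turn_intervals))) {
      s <- turn_intervals$start[k]; e <- turn_intervals$end[k] - 1L
      if (e >= s) keep[s:e] <- FALSE
    }
  }
  r <- rle(keep)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  walk <- which(r$values)
  snippets <- list()
  dropped <- 0L
  for (k in walk) {
    len <- r$lengths[k]
    if (len < min_samples) {
      dropped <- dropped + 1L
      next
    }
    idx <- starts[k]:stops[k]
    snippets[[length(snippets) + 1L]] <- list(
      accel = session$accel[, idx, drop = FALSE],
      subject_id = session$subject_id,
      visit_id = session$visit_id,
      state = session$state,
      pigd_score = session$pigd_score,
      sample_rate = session$sample_rate
    )
  }
  attr(snippets, "n_dropped") <- dropped
  snippets
}

#' Truncate a walk snippet to a fixed-length segment
#'
#' Keeps the first `duration * sample_rate` samples of each channel
#' (384 at the defaults), so every example has identical dimensions.
#'
#' @param snippet a walk snippet from [segment_walks()].
#' @param duration seconds kept.
#' @param sample_rate Hz.
#' @return the snippet with `accel` cut to 3 x (duration * sample_rate).
#' @export
truncate_segment <- function(snippet, duration = 3, sample_rate = 128) {
  n_keep <- round(duration * sample_rate)
  abort_if(ncol(snippet$accel) < n_keep,
           "snippet shorter than ", n_keep, " samples")
  snippet$accel <- snippet$accel[, seq_len(n_keep), drop = FALSE]
  snippet
}

# steady-state initial filter conditions (the classic lfilter_zi construction:
# the internal state for which a unit-step input produces the steady-state
# response from the first sample, removing start-up transients)
iir_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  # companion matrix of the denominator polynomial
  comp <- rbind(-a[-1] / a[1],
                cbind(diag(1, n - 2), rep(0, n - 2)))
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# zero-phase IIR filtering: odd-reflection edge extension, then a forward and
# a backward pass each started from steady-state initial conditions scaled to
# the first processed sample (so constant inputs filter to an exact constant
# response with no edge transient)
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  # long extension: for sub-Hz corners the impulse response outlasts a 3-s
  # segment, so edge transients must be pushed well away from the payload
  ext <- min(n - 1L, 48L * (max(length(a), length(b)) - 1L))
  abort_if(n <= 8L, "segment too short to filter (", n, " samples)")
  pre <- 2 * x[1] - x[seq(ext + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - ext)]
  xx <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- cpp_iir_filter(b, a, xx, zi * xx[1])
  y <- rev(y)
  y <- cpp_iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(ext + 1L):(ext + n)]
}

#' High-pass filter a walk segment
#'
#' Removes gravity offset and slow drift with a Butterworth high-pass filter
#' applied forward-backward (zero phase). The cutoff is interpreted in Hz by
#' default; `interpret = "normalized"` reads it as a fraction of the Nyquist
#' frequency instead.
#'
#' @param segment a walk segment (list with 3 x n `accel`).
#' @param cutoff filter cutoff (0.25 Hz default).
#' @param order filter order (per pass).
#' @param sample_rate Hz.
#' @param interpret `"hz"` or `"normalized"`.
#' @return the segment with filtered `accel`; per-channel means of constant
#'   inputs are reduced to below 1 percent of channel RMS.
#' @export
highpass_segment <- function(segment, cutoff = 0.25, order = 4,
                             sample_rate = 128,
                             interpret = c("hz", "normalized")) {
  interpret <- match.arg(interpret)
  wc <- if (interpret == "hz") cutoff / (sample_rate / 2) else cutoff
  abort_if(wc <= 0 || wc >= 1, "cutoff must fall inside (0, Nyquist)")
  bf <- signal::butter(order, wc, type = "high")
  segment$accel <- t(apply(segment$accel, 1, function(ch) filtfilt_pad(bf$b, bf$a, ch)))
  segment
}

#' Log-magnitude spectrum of a walk segment
#'
#' Per channel, the natural log of the magnitude of the full 384-point
#' discrete Fourier transform plus a small floor, keeping all 384
#' (conjugate-symmetric) bins so the feature tensor is 3 x 384 — matching the
#' input contract of the discriminator and the 1152-unit generator output.
#'
#' @param segment a 384-sample walk segment.
#' @param floor additive floor before the log, keeps the output finite.
#' @param half_spectrum if `TRUE`, the positive-frequency half spectrum is
#'   zero-padded back to 384 bins instead of keeping the full symmetric DFT.
#' @return a `spectral_example`: list with `logspec` (3 x 384) and metadata.
#' @export
log_spectrum <- function(segment, floor = 1e-8, half_spectrum = FALSE) {
  x <- segment$accel
  abort_if(any(!is.finite(x)), "segment contains non-finite samples")
  n <- ncol(x)
  spec <- t(apply(x, 1, function(ch) {
    m <- Mod(stats::fft(ch))
    if (half_spectrum) m <- c(m[seq_len(n %/% 2 + 1L)], rep(0, n - n %/% 2 - 1L))
    log(m + floor)
  }))
  structure(list(
    logspec = spec,
    subject_id = segment$subject_id,
    visit_id = segment$visit_id,
    state = segment$state,
    pigd_score = segment$pigd_score
  ), class = "spectral_example")
}

#' Preprocess a cohort into spectral examples
#'
#' Runs [detect_turns()], [segment_walks()], [truncate_segment()],
#' [highpass_segment()] and [log_spectrum()] over every session and stacks
#' the results. Each example inherits its session's subject, visit, state and
#' clinician PIGD label.
#'
#' @param cohort a `gait_cohort` or list of `raw_session`.
#' @param angle_threshold,window turn-detection parameters, see [detect_turns()].
#' @param duration,cutoff,order,floor,half_spectrum pipeline parameters.
#' @return a `spectral_examples` set: list with `logspec` (n x 3 x 384 array),
#'   `meta` (data frame: subject_id, visit_id, state, pigd_score) and
#'   `n_dropped` (snippets too short to keep).
#' @export
preprocess_cohort <- function(cohort, angle_threshold = 120, window = 2,
                              duration = 3, cutoff = 0.25, order = 4,
                              floor = 1e-8, half_spectrum = FALSE) {
  sessions <- if (inherits(cohort, "gait_cohort")) cohort$sessions else cohort
  specs <- list()
  dropped <- 0L
  for (s in sessions) {
    fs <- s$sample_rate
    turns <- detect_turns(s$gyro[1, ], fs, angle_threshold, window)
    n_keep <- round(duration * fs)
    snippets <- segment_walks(s, turns, min_samples = n_keep)
    dropped <- dropped + attr(snippets, "n_dropped")
    for (sn in snippets) {
      seg <- truncate_segment(sn, duration, fs)
      seg <- highpass_segment(seg, cutoff, order, fs)
      specs[[length(specs) + 1L]] <- log_spectrum(seg, floor, half_spectrum)
    }
  }
  n <- length(specs)
  d <- if (n > 0) dim(specs[[1]]$logspec) else c(3L, round(duration * 128))
  logspec <- array(0, dim = c(n, d[1], d[2]))
  meta <- data.frame(subject_id = character(n), visit_id = character(n),
                     state = character(n), pigd_score = integer(n))
  for (k in seq_len(n)) {
    logspec[k, , ] <- specs[[k]]$logspec
    meta$subject_id[k] <- specs[[k]]$subject_id
    meta$visit_id[k] <- specs[[k]]$visit_id
    meta$state[k] <- specs[[k]]$state
    meta$pigd_score[k] <- specs[[k]]$pigd_score
  }
  structure(list(logspec = logspec, meta = meta, n_dropped = dropped),
            class = "spectral_examples")
}

#' @export
print.spectral_examples <- function(x, ...) {
  cat(sprintf("<spectral_examples> %d examples (%d x %d), %d subjects, %d dropped snippets\n",
              nrow(x$meta), dim(x$logspec)[2], dim(x$logspec)[3],
              length(unique(x$meta$subject_id)), x$n_dropped))
  invisible(x)
}

#' Subset a spectral example set
#' @param examples a `spectral_examples` set.
#' @param idx integer or logical index over examples.
#' @return the subsetted `spectral_examples`.
#' @export
subset_examples <- function(examples, idx) {
  structure(list(logspec = examples$logspec[idx, , , drop = FALSE],
                 meta = examples$meta[idx, , drop = FALSE],
                 n_dropped = examples$n_dropped),
            class = "spectral_examples")
}

#' Write / read a spectral example set as a single file
#'
#' Stores the example tensor and metadata in one RDS container.
#' @param examples a `spectral_examples` set.
#' @param path file path.
#' @export
write_examples <- function(examples, path) {
  saveRDS(examples, path)
  invisible(path)
}

#' @rdname write_examples
#' @export
read_examples <- function(path) {
  x <- readRDS(path)
  abort_if(!inherits(x, "spectral_examples"), path, " is not an examples file")
  x
}
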