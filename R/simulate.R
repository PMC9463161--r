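# Synthetic gait-cohort simulator.
#
# Emulates lumbar-IMU walk sessions from a levodopa-treated Parkinson's
# cohort: quasi-periodic vertical acceleration at a cadence fundamental,
# severity-dependent amplitude and cadence variability, band-limited tremor,
# gravity plus slow drift, and interleaved turns visible as large cumulative
# rotation on the first gyroscope axis. Subjects carry a latent gait-severity
# trait on the PIGD scale (0-20); OFF-state visits are strictly more severe
# than ON-state visits by a configurable medication gap.

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_session()] and
#' [simulate_cohort()]. Defaults describe a paired-visit study: each subject
#' is recorded once ON and once OFF medication, walking straight bouts
#' separated by about-turns, with a lumbar IMU sampling at 128 Hz.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject visits per subject (2 for the paired ON/OFF
#'   design; up to 5 for an ON/OFF-cycle design).
#' @param sample_rate sampling rate in Hz.
#' @param walk_bout_duration duration of one straight-walk bout, seconds.
#' @param n_bouts_per_session straight-walk bouts per recording; bouts are
#'   separated by turns.
#' @param cadence_base step cadence in Hz of an unimpaired (PIGD 0) walk.
#' @param severity_to_cadence_slope cadence change per PIGD point (Hz/point,
#'   negative: more severe subjects walk slower).
#' @param severity_to_amplitude_slope vertical acceleration amplitude change
#'   per PIGD point (g/point, negative).
#' @param amplitude_base vertical acceleration amplitude at PIGD 0, in g.
#' @param tremor_band frequency interval (Hz) of the tremor component.
#' @param noise_sd white measurement noise, g.
#' @param on_off_gap mean severity difference OFF minus ON, PIGD points (> 0).
#' @param score_skew gamma shape parameter of the latent-trait draw; small
#'   values give the right-skewed score distributions typical of such cohorts.
#' @param severity_scale gamma scale of the latent-trait draw (PIGD points).
#' @param turn_duration duration of one turn, seconds.
#' @param turn_angle_range degrees turned during one turn (sampled uniformly).
#' @param design `"paired_on_off"` assigns each subject exactly one ON and one
#'   OFF visit in random order; `"on_off_cycle"` samples each visit's state
#'   from ON/OFF/TRANSITIONING states, as in a multi-visit medication-cycle
#'   protocol.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 35L,
                       visits_per_subject = 2L,
                       sample_rate = 128,
                       walk_bout_duration = 6,
                       n_bouts_per_session = 4L,
                       cadence_base = 2.0,
                       severity_to_cadence_slope = -0.025,
                       severity_to_amplitude_slope = -0.012,
                       amplitude_base = 0.35,
                       tremor_band = c(4, 6),
                       noise_sd = 0.02,
                       on_off_gap = 6,
                       score_skew = 2,
                       severity_scale = 2,
                       turn_duration = 2,
                       turn_angle_range = c(150, 200),
                       design = c("paired_on_off", "on_off_cycle"),
                       seed = 1L) {
  design <- match.arg(design)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    visits_per_subject = as.integer(visits_per_subject),
    sample_rate = sample_rate,
    walk_bout_duration = walk_bout_duration,
    n_bouts_per_session = as.integer(n_bouts_per_session),
    cadence_base = cadence_base,
    severity_to_cadence_slope = severity_to_cadence_slope,
    severity_to_amplitude_slope = severity_to_amplitude_slope,
    amplitude_base = amplitude_base,
    tremor_band = tremor_band,
    noise_sd = noise_sd,
    on_off_gap = on_off_gap,
    score_skew = score_skew,
    severity_scale = severity_scale,
    turn_duration = turn_duration,
    turn_angle_range = turn_angle_range,
    design = design,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  abort_if(cfg$n_subjects < 0, "`n_subjects` must be non-negative")
  abort_if(cfg$visits_per_subject < 1, "`visits_per_subject` must be positive")
  abort_if(cfg$sample_rate <= 0, "`sample_rate` must be positive")
  abort_if(cfg$walk_bout_duration <= 0, "`walk_bout_duration` must be positive")
  abort_if(cfg$n_bouts_per_session < 1, "`n_bouts_per_session` must be positive")
  abort_if(cfg$on_off_gap <= 0, "`on_off_gap` must be > 0 (OFF strictly more severe)")
  abort_if(cfg$noise_sd < 0, "`noise_sd` must be non-negative")
  abort_if(cfg$score_skew <= 0, "`score_skew` must be positive")
  invisible(cfg)
}

#' Medication states
#' @export
PIGD_STATES <- c("ON", "OFF", "TRANSITIONING_TO_ON", "TRANSITIONING_TO_OFF")

# severity actually expressed during a visit: the latent (ON-state) trait,
# raised by the full medication gap when OFF and half of it when transitioning
effective_severity <- function(severity, state, on_off_gap) {
  severity + switch(state,
    ON = 0,
    OFF = on_off_gap,
    TRANSITIONING_TO_ON = on_off_gap / 2,
    TRANSITIONING_TO_OFF = on_off_gap / 2
  )
}

# one straight-walk bout of triaxial acceleration (3 x n matrix, g units).
# Vertical channel (az): three harmonics of a jittered cadence fundamental;
# lateral sway (ax) at the stride rate (half cadence); antero-posterior (ay)
# at the cadence. Amplitude shrinks and cadence jitter grows with severity;
# a band-limited tremor component grows with severity.
walk_bout_accel <- function(n, eff_sev, cfg) {
  fs <- cfg$sample_rate
  cadence <- max(cfg$cadence_base + cfg$severity_to_cadence_slope * eff_sev, 0.8)
  amp <- max(cfg$amplitude_base + cfg$severity_to_amplitude_slope * eff_sev, 0.05)
  cv <- 0.03 + 0.0035 * eff_sev # step-time variability grows with severity

  # per-step cadence jitter: piecewise-constant instantaneous frequency
  n_steps <- ceiling(n / fs * cadence) + 2L
  f_step <- cadence * pmax(1 + cv * stats::rnorm(n_steps), 0.3)
  step_len <- pmax(round(fs / f_step), 2L)
  inst_f <- rep(f_step, times = step_len)[seq_len(n)]
  phase <- 2 * pi * cumsum(inst_f) / fs

  harm <- function(ph) {
    sin(ph + stats::runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * ph + stats::runif(1, 0, 2 * pi)) +
      0.25 * sin(3 * ph + stats::runif(1, 0, 2 * pi))
  }
  az <- amp * harm(phase)
  ay <- 0.6 * amp * harm(phase)
  ax <- 0.35 * amp * harm(phase / 2) # stride-rate lateral sway

  # tremor: narrowband component in tremor_band, energy growing with severity
  f_tr <- stats::runif(1, cfg$tremor_band[1], cfg$tremor_band[2])
  tremor_amp <- 0.004 * eff_sev
  tt <- seq_len(n) / fs
  tremor <- tremor_amp * sin(2 * pi * f_tr * tt + stats::runif(1, 0, 2 * pi))

  noise <- matrix(stats::rnorm(3 * n, sd = cfg$noise_sd), nrow = 3)
  rbind(ax, ay, az + tremor) + rbind(tremor * 0.3, tremor * 0.5, 0 * tt) + noise
}

#' Simulate one walk session
#'
#' Generates a raw six-channel recording: `n_bouts_per_session` straight-walk
#' bouts separated by about-turns. During turns, the first gyroscope channel
#' carries a raised-cosine angular-rate pulse whose integral lies in
#' `turn_angle_range` (well above the 120 degree detection threshold); during
#' walks the gyroscope carries only noise. The vertical accelerometer channel
#' includes a 1 g gravity offset and slow drift, which downstream high-pass
#' filtering removes. Consumes the caller's random-number stream; seed it for
#' reproducibility.
#'
#' @param subject_severity latent (ON-state) severity on the PIGD scale, in
#'   `[0, 20]`.
#' @param state one of `r paste(PIGD_STATES, collapse = ", ")`.
#' @param config a [sim_config()].
#' @param subject_id,visit_id identifiers attached to the session.
#' @return a `raw_session`: list with `accel` and `gyro` (3 x T matrices, g
#'   and deg/s), `turn_truth` (data frame of injected turn sample intervals,
#'   half-open), `state`, `pigd_score`, ids and `sample_rate`.
#' @export
simulate_session <- function(subject_severity, state, config = sim_config(),
                             subject_id = "S01", visit_id = "V1") {
  abort_if(!is.numeric(subject_severity) || length(subject_severity) != 1L ||
             !is.finite(subject_severity) ||
             subject_severity < 0 || subject_severity > 20,
           "`subject_severity` must lie in [0, 20]")
  state <- match.arg(state, PIGD_STATES)
  cfg <- config
  fs <- cfg$sample_rate
  eff <- effective_severity(subject_severity, state, cfg$on_off_gap)

  n_bout <- round(cfg$walk_bout_duration * fs)
  n_turn <- round(cfg$turn_duration * fs)
  n_bouts <- cfg$n_bouts_per_session
  total <- n_bouts * n_bout + (n_bouts - 1L) * n_turn

  accel <- matrix(0, nrow = 3, ncol = total,
                  dimnames = list(c("ax", "ay", "az"), NULL))
  gyro <- matrix(stats::rnorm(3 * total, sd = 3), nrow = 3,
                 dimnames = list(c("gx", "gy", "gz"), NULL))
  turn_truth <- data.frame(start = integer(0), end = integer(0))

  pos <- 1L
  turn_sign <- 1
  for (b in seq_len(n_bouts)) {
    idx <- pos:(pos + n_bout - 1L)
    accel[, idx] <- walk_bout_accel(n_bout, eff, cfg)
    pos <- pos + n_bout
    if (b < n_bouts) {
      idx <- pos:(pos + n_turn - 1L)
      angle <- stats::runif(1, cfg$turn_angle_range[1], cfg$turn_angle_range[2])
      # raised-cosine pulse integrating to `angle` degrees over the turn
      u <- (seq_len(n_turn) - 0.5) / n_turn
      pulse <- turn_sign * (angle / cfg$turn_duration) * (1 - cos(2 * pi * u))
      gyro["gx", idx] <- gyro["gx", idx] + pulse
      # slow shuffling accelerations while turning
      accel[, idx] <- matrix(stats::rnorm(3 * n_turn, sd = cfg$noise_sd * 2), nrow = 3)
      turn_truth <- rbind(turn_truth,
                          data.frame(start = idx[1], end = idx[n_turn] + 1L))
      turn_sign <- -turn_sign
      pos <- pos + n_turn
    }
  }
  # gravity on the vertical channel plus slow drift (removed by filtering)
  tt <- seq_len(total) / fs
  accel["az", ] <- accel["az", ] + 1 +
    0.05 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi))

  structure(list(
    accel = accel,
    gyro = gyro,
    subject_id = subject_id,
    visit_id = visit_id,
    state = state,
    pigd_score = as.integer(min(max(round(eff), 0), 20)),
    severity = subject_severity,
    sample_rate = fs,
    turn_truth = turn_truth
  ), class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %s/%s  state=%s  PIGD=%d  %.1f s @ %g Hz\n",
              x$subject_id, x$visit_id, x$state, x$pigd_score,
              ncol(x$accel) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Draws one latent severity trait per subject from a right-skewed gamma
#' distribution, assigns visit states per the configured design, and
#' generates every session. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `gait_cohort`: list with `sessions` (list of `raw_session`),
#'   `subjects` (data frame of latent traits) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$seed, "cohort"), {
    traits <- stats::rgamma(cfg$n_subjects, shape = cfg$score_skew,
                            scale = cfg$severity_scale)
    traits <- pmin(traits, 20 - cfg$on_off_gap) # keep OFF scores on scale
    sessions <- list()
    subj_ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
    for (s in seq_len(cfg$n_subjects)) {
      states <- if (cfg$design == "paired_on_off") {
        abort_if(cfg$visits_per_subject != 2L,
                 "paired_on_off design requires visits_per_subject = 2")
        sample(c("ON", "OFF"))
      } else {
        sample(PIGD_STATES, cfg$visits_per_subject, replace = TRUE,
               prob = c(0.35, 0.25, 0.2, 0.2))
      }
      for (v in seq_along(states)) {
        sessions[[length(sessions) + 1L]] <-
          simulate_session(traits[s], states[v], cfg,
                           subject_id = subj_ids[s],
                           visit_id = sprintf("V%d", v))
      }
    }
    structure(list(
      sessions = sessions,
      subjects = data.frame(subject_id = subj_ids, severity = traits),
      config = cfg
    ), class = "gait_cohort")
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects, %d sessions (design: %s)\n",
              nrow(x$subjects), length(x$sessions), x$config$design))
  invisible(x)
}

# ---- on-disk session format -------------------------------------------------

#' Write / read a cohort as CSV sessions with JSON sidecars
#'
#' Each session becomes `<subject>_<visit>.csv` with columns
#' `time_s, ax, ay, az, gx, gy, gz` plus a JSON sidecar holding the metadata;
#' `manifest.json` lists all sessions.
#'
#' @param cohort a `gait_cohort` or list of `raw_session`.
#' @param dir output directory (created if missing).
#' @return `write_cohort` returns the manifest path invisibly; `read_cohort`
#'   returns a list of `raw_session`.
#' @export
write_cohort <- function(cohort, dir) {
  sessions <- if (inherits(cohort, "gait_cohort")) cohort$sessions else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(sessions, function(s) {
    stem <- sprintf("%s_%s", s$subject_id, s$visit_id)
    tab <- data.frame(
      time_s = seq_len(ncol(s$accel)) / s$sample_rate,
      ax = s$accel[1, ], ay = s$accel[2, ], az = s$accel[3, ],
      gx = s$gyro[1, ], gy = s$gyro[2, ], gz = s$gyro[3, ]
    )
    utils::write.csv(tab, file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    meta <- list(subject_id = s$subject_id, visit_id = s$visit_id,
                 state = s$state, pigd_score = s$pigd_score,
                 sample_rate = s$sample_rate)
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE)
    c(meta, list(csv = paste0(stem, ".csv"), json = paste0(stem, ".json")))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  abort_if(!file.exists(manifest), "no manifest.json in ", dir)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(entries, function(e) {
    tab <- utils::read.csv(file.path(dir, e$csv))
    structure(list(
      accel = t(as.matrix(tab[, c("ax", "ay", "az")])),
      gyro = t(as.matrix(tab[, c("gx", "gy", "gz")])),
      subject_id = e$subject_id, visit_id = e$visit_id,
      state = e$state, pigd_score = as.integer(e$pigd_score),
      severity = NA_real_, sample_rate = e$sample_rate,
      turn_truth = NULL
    ), class = "raw_session")
  })
}
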