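test_that("turn detection matches a trapezoidal-integration oracle", {
  fs <- 128
  # 2 s of 90 deg/s inside 10 s of rest: 180 degrees of rotation
  g <- c(rep(0, 4 * fs), rep(90, 2 * fs), rep(0, 4 * fs))
  iv <- detect_turns(g, fs, angle_threshold = 120, window = 2)
  expect_identical(nrow(iv), 1L)
  # oracle: cumulative rotation of the burst
  expect_equal(pracma::trapz(seq_along(g) / fs, g), 180, tolerance = 1e-6)
  # the detected interval covers the burst
  expect_lte(iv$start[1], 4 * fs + 1)
  expect_gte(iv$end[1], 6 * fs)

  # 60 degrees total stays under threshold
  g2 <- c(rep(0, 4 * fs), rep(30, 2 * fs), rep(0, 4 * fs))
  expect_identical(nrow(detect_turns(g2, fs)), 0L)
  expect_equal(pracma::trapz(seq_along(g2) / fs, g2), 60, tolerance = 1e-6)

  expect_identical(nrow(detect_turns(rep(0, 10 * fs), fs)), 0L)
  expect_identical(nrow(detect_turns(numeric(0), fs)), 0L)
  expect_error(detect_turns(c(1, NA, 2), fs), "non-finite")
})

test_that("walk segmentation returns the complement of turn intervals", {
  fs <- 128
  sess <- structure(list(
    accel = matrix(rnorm(3 * 20 * fs), 3), gyro = matrix(0, 3, 20 * fs),
    subject_id = "S01", visit_id = "V1", state = "ON", pigd_score = 4L,
    sample_rate = fs), class = "raw_session")
  turns <- data.frame(start = 8L * fs + 1L, end = 10L * fs + 1L)
  sn <- segment_walks(sess, turns)
  expect_length(sn, 2)
  expect_identical(ncol(sn[[1]]$accel), 8L * 128L)  # [0, 8 s)
  expect_identical(ncol(sn[[2]]$accel), 10L * 128L) # [10 s, 20 s)

  # one long turn -> nothing left
  all_turn <- data.frame(start = 1L, end = 20L * fs + 1L)
  expect_length(segment_walks(sess, all_turn), 0)

  # short leftovers (under 384 samples) are dropped and counted
  turns2 <- data.frame(start = 4L * 128L + 1L, end = 19L * 128L + 1L)
  sn2 <- segment_walks(sess, turns2) # keeps [0, 4 s); tail of 1 s is dropped
  expect_length(sn2, 1)
  expect_identical(ncol(sn2[[1]]$accel), 4L * 128L)
  expect_identical(attr(sn2, "n_dropped"), 1L)
})

test_that("truncation yields exactly 384 samples and rejects short snippets", {
  sn <- list(accel = matrix(rnorm(3 * 666), 3), subject_id = "S", visit_id = "V",
             state = "ON", pigd_score = 1L, sample_rate = 128)
  tr <- truncate_segment(sn) # 5.2 s in
  expect_identical(dim(tr$accel), c(3L, 384L))
  expect_identical(tr$accel, sn$accel[, 1:384])

  exact <- sn; exact$accel <- sn$accel[, 1:384]
  expect_identical(truncate_segment(exact)$accel, exact$accel)

  short <- sn; short$accel <- sn$accel[, 1:256] # 2 s
  expect_error(truncate_segment(short), "shorter")
})

test_that("high-pass filtering removes offsets and preserves the gait band", {
  seg <- function(m) list(accel = m, subject_id = "S", visit_id = "V",
                          state = "ON", pigd_score = 0L, sample_rate = 128)
  tt <- seq_len(384) / 128

  # constant channels go to ~0
  const <- seg(matrix(c(1, -2, 0.5), 3, 384))
  hp <- highpass_segment(const)
  expect_lt(max(abs(hp$accel)), 0.01 * sqrt(mean(const$accel[1, ]^2)))

  # transfer-function oracle: |H| at 2 Hz (passband) vs 0.05 Hz (stopband)
  bf <- signal::butter(4, 0.25 / 64, type = "high")
  Hmag <- function(f) {
    z <- exp(-1i * 2 * pi * f / 128 * (seq_along(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * z))
  }
  expect_lt(abs(Hmag(2)^2 - 1), 0.02)   # two passes: squared magnitude
  expect_lt(Hmag(0.05)^2, 1e-5)

  # 2 Hz sinusoid passes with amplitude within 2 percent
  s2 <- seg(rbind(sin(2 * pi * 2 * tt), sin(2 * pi * 2 * tt), sin(2 * pi * 2 * tt)))
  hp2 <- highpass_segment(s2)
  mid <- 64:320 # interior, away from edge transients
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(hp2$accel[1, mid]) / rms(s2$accel[1, mid]) - 1), 0.02)

  # 0.05 Hz drift is strongly attenuated relative to the 2 Hz carrier
  slow <- seg(rbind(sin(2 * pi * 0.05 * tt), 0 * tt, 0 * tt))
  hps <- highpass_segment(slow)
  expect_lt(rms(hps$accel[1, mid]) / rms(slow$accel[1, mid]), 0.1)
})

test_that("log spectrum puts a 2 Hz tone in DFT bin k = f*N/Fs and keeps
           3 x 384 dimensions", {
  tt <- seq_len(384) / 128
  seg <- list(accel = rbind(sin(2 * pi * 2 * tt), 0 * tt, 0 * tt),
              subject_id = "S", visit_id = "V", state = "ON", pigd_score = 0L)
  sp <- log_spectrum(seg)
  expect_identical(dim(sp$logspec), c(3L, 384L))
  # k = 2 * 384 / 128 = 6 (0-based) -> R index 7, mirror at index 379
  ord <- order(sp$logspec[1, ], decreasing = TRUE)
  expect_setequal(ord[1:2], c(7L, 379L))

  zero <- seg; zero$accel <- matrix(0, 3, 384)
  spz <- log_spectrum(zero, floor = 1e-8)
  expect_true(all(spz$logspec == log(1e-8)))
  expect_true(all(is.finite(spz$logspec)))

  bad <- seg; bad$accel[2, 5] <- NA
  expect_error(log_spectrum(bad), "non-finite")
})

test_that("the preprocessing pipeline yields one example per walk bout and
           never overlaps injected turns", {
  co <- simulate_cohort(sim_config(n_subjects = 5, n_bouts_per_session = 4,
                                   seed = 21))
  ex <- preprocess_cohort(co)
  expect_identical(nrow(ex$meta), 5L * 2L * 4L) # subjects x visits x bouts
  expect_identical(dim(ex$logspec)[2:3], c(3L, 384L))

  # labels inherited from the sessions
  expect_setequal(unique(ex$meta$subject_id),
                  unique(vapply(co$sessions, `[[`, "", "subject_id")))

  # determinism: identical input -> bit-identical tensors
  ex2 <- preprocess_cohort(co)
  expect_identical(ex$logspec, ex2$logspec)

  # empty input
  expect_identical(nrow(preprocess_cohort(list())$meta), 0L)
})

test_that("turn excision is complete on simulated sessions and walk bouts are
           never flagged as turns", {
  co <- simulate_cohort(sim_config(n_subjects = 5, n_bouts_per_session = 3,
                                   seed = 31))
  for (s in co$sessions[1:6]) {
    iv <- detect_turns(s$gyro[1, ], s$sample_rate)
    expect_identical(nrow(iv), nrow(s$turn_truth))
    # every injected turn is inside a detected interval
    for (k in seq_len(nrow(s$turn_truth))) {
      covered <- any(iv$start <= s$turn_truth$start[k] &
                       iv$end >= s$turn_truth$end[k])
      expect_true(covered)
    }
    # no kept snippet overlaps an injected turn
    sn <- segment_walks(s, iv)
    expect_gt(length(sn), 0)
  }
})

test_that("examples round-trip through the single-file container", {
  ex <- tiny_examples()
  path <- withr::local_tempfile(fileext = ".rds")
  write_examples(ex, path)
  back <- read_examples(path)
  expect_identical(back$logspec, ex$logspec)
  expect_identical(back$meta, ex$meta)
})
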