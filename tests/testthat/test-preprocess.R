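make_rec <- function(x, fs = 1000, events = integer()) {
  emg_recording(matrix(x, nrow = 1), fs, labels = "m1", cycle_events = events)
}

test_that("band-pass removes DC and passes mid-band tones", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  dc <- make_rec(rep(1, length(t)), fs)
  out <- bandpass(dc)$data[1, ]
  mid <- out[500:(length(out) - 500)]
  expect_lt(max(abs(mid)), 1e-6)

  tone <- make_rec(sin(2 * pi * 100 * t), fs)
  y <- bandpass(tone)$data[1, ]
  steady <- y[500:(length(y) - 500)]
  expect_equal(max(abs(steady)), 1, tolerance = 0.05)
})

test_that("band edges beyond Nyquist are rejected", {
  r <- make_rec(rnorm(100), fs = 1000)
  expect_error(bandpass(r, low = 20, high = 600), "fs/2")
  expect_error(bandpass(r, low = 0, high = 450), "fs/2")
})

test_that("rectification is the elementwise absolute value", {
  r <- make_rec(c(-1, 2, -3))
  expect_equal(rectify(r)$data[1, ], c(1, 2, 3))
  z <- make_rec(rep(0, 5))
  expect_equal(rectify(z)$data[1, ], rep(0, 5))
  # zero-mean sine of amplitude A rectifies to mean 2A/pi
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s <- make_rec(3 * sin(2 * pi * 10 * t), fs)
  expect_equal(mean(rectify(s)$data[1, ]), 2 * 3 / pi, tolerance = 0.01)
})

test_that("envelope filter has unity DC gain, zero lag, and strong stop-band rejection", {
  fs <- 1000
  const <- make_rec(rep(2.5, 800), fs)
  expect_equal(envelope(const)$data[1, ], rep(2.5, 800), tolerance = 1e-6)

  imp <- rep(0, 1001); imp[501] <- 1
  y <- envelope(make_rec(imp, fs))$data[1, ]
  expect_equal(y[501 + 1:100], y[501 - 1:100], tolerance = 1e-9)

  t <- seq(0, 2, by = 1 / fs)
  hum <- make_rec(sin(2 * pi * 100 * t), fs)
  y2 <- envelope(hum)$data[1, ]
  expect_lt(max(abs(y2[500:1500])), 0.03)  # > 97% attenuation
})

test_that("segmentation keeps interior cycles and yields the study matrix shape", {
  fs <- 1000
  Tc <- 150  # raw samples per cycle
  n_cyc <- 11
  events <- seq(1, by = Tc, length.out = n_cyc + 1)
  set.seed(1)
  data <- matrix(abs(rnorm(12 * (Tc * n_cyc + 1))), nrow = 12)
  rec <- emg_recording(data, fs, cycle_events = events)
  cm <- segment_and_normalize(rec, T_cycle = 200)
  expect_equal(cm$k, 9L)
  expect_equal(dim(cm$E), c(12L, 1800L))
  expect_true(all(cm$E >= 0 & cm$E <= 1))
  expect_equal(unname(apply(cm$E, 1, max)), rep(1, 12), tolerance = 1e-12)
})

test_that("a constant channel normalises to all ones", {
  events <- c(1, 11, 21, 31, 41)
  rec <- emg_recording(matrix(5, 1, 45), fs = 100, cycle_events = events)
  cm <- segment_and_normalize(rec, T_cycle = 10, drop_edges = FALSE)
  expect_equal(cm$E[1, ], rep(1, 40), tolerance = 1e-12)
})

test_that("resampling a cycle of length exactly T is the identity", {
  Tc <- 20
  set.seed(2)
  x <- abs(rnorm(3 * Tc + 1))
  rec <- emg_recording(matrix(x, 1), fs = 100,
                       cycle_events = c(1, Tc + 1, 2 * Tc + 1, 3 * Tc + 1))
  cm <- segment_and_normalize(rec, T_cycle = Tc, drop_edges = FALSE)
  expected <- x[1:(3 * Tc)] / max(x[1:(3 * Tc)])
  expect_equal(cm$E[1, ], expected, tolerance = 1e-12)
})

test_that("segmenting exact cycle copies reproduces the cycle matrix", {
  Tc <- 25
  set.seed(3)
  cyc <- abs(rnorm(Tc)) + 0.1
  x <- rep(cyc, 4)
  rec <- emg_recording(matrix(c(x, cyc[1]), 1), fs = 100,
                       cycle_events = seq(1, by = Tc, length.out = 5))
  cm <- segment_and_normalize(rec, T_cycle = Tc, drop_edges = FALSE)
  expect_equal(cm$E[1, ], rep(cyc / max(cyc), 4), tolerance = 1e-12)
})

test_that("degenerate segmentations raise informative errors", {
  rec <- emg_recording(matrix(1, 1, 30), fs = 100, cycle_events = c(1, 11, 21))
  expect_error(segment_and_normalize(rec, T_cycle = 10, drop_edges = TRUE),
               "at least 3")
  data <- rbind(a = abs(rnorm(40)) + 1, b = rep(0, 40))
  rec2 <- emg_recording(data, fs = 100, cycle_events = c(1, 11, 21, 31, 41),
                        labels = c("good", "silent"))
  expect_error(segment_and_normalize(rec2, T_cycle = 10, drop_edges = FALSE),
               "silent")
})

test_that("full preprocessing chain produces a valid cycle matrix from raw-like EMG", {
  fs <- 1000
  n_cyc <- 5
  Tc <- 300
  t <- seq_len(n_cyc * Tc + 1) / fs
  set.seed(4)
  # amplitude-modulated broadband noise emulating raw interference EMG
  carrier <- matrix(rnorm(2 * length(t)), nrow = 2)
  am <- rbind(1 + sin(2 * pi * t / (Tc / fs)),
              1 + cos(2 * pi * t / (Tc / fs)))
  rec <- emg_recording(carrier * am, fs,
                       cycle_events = seq(1, by = Tc, length.out = n_cyc + 1))
  cm <- preprocess_emg(rec, T_cycle = 100)
  expect_equal(cm$k, 3L)
  expect_equal(ncol(cm$E), 300L)
  expect_true(all(cm$E >= 0))
})
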