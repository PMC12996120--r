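test_that("bandpass keeps the passband and rejects the stopband", {
  fs <- 160
  # slow drift far below the low edge is suppressed
  slow <- sine_recording(0.2, fs = fs, dur = 60, amp = 10)
  out <- bandpass(slow, 1, 45)
  expect_lt(sqrt(mean(out$data[1, ]^2)),
            0.10 * sqrt(mean(slow$data[1, ]^2)))
  # a 10 Hz rhythm passes essentially untouched
  mid <- sine_recording(10, fs = fs, dur = 60, amp = 10)
  out <- bandpass(mid, 1, 45)
  expect_equal(sqrt(mean(out$data[1, ]^2)),
               sqrt(mean(mid$data[1, ]^2)), tolerance = 0.05)
})

test_that("out-of-band line noise is attenuated at least 20 dB", {
  fs <- 200
  t <- (0:(fs * 30 - 1)) / fs
  x <- 10 * sin(2 * pi * 10 * t) + 10 * sin(2 * pi * 60 * t)
  rec <- eeg_recording(matrix(x, 1), fs, "Cz")
  out <- bandpass(rec, 1, 45)
  # oracle: periodogram of the filtered output
  pg <- Mod(fft(out$data[1, ]))^2
  f <- (seq_along(pg) - 1) * fs / length(pg)
  p10 <- max(pg[abs(f - 10) < 0.2])
  p60 <- max(pg[abs(f - 60) < 0.2])
  expect_gt(10 * log10(p10 / p60), 20)
})

test_that("bandpass validates its band edges", {
  rec <- sine_recording(10, fs = 100, dur = 5)
  expect_error(bandpass(rec, 1, 50), "Nyquist")
  expect_error(bandpass(rec, 1, 60), "Nyquist")
  expect_error(bandpass(rec, 45, 1), "lo < hi")
  expect_error(bandpass(rec, 0, 45), "lo < hi")
})

test_that("bad-channel detection flags variance outliers only", {
  set.seed(42)
  base <- matrix(rnorm(8 * 1000), 8)
  labels <- paste0("ch", 1:8)
  # identical channels: zero spread in variances, nothing flagged
  same <- eeg_recording(matrix(rep(base[1, ], each = 8), 8), 100, labels)
  expect_identical(detect_bad_channels(same), character(0))
  # an all-zeros recording is degenerate, not an error
  zeros <- eeg_recording(matrix(0, 8, 1000), 100, labels)
  expect_identical(detect_bad_channels(zeros), character(0))
  # one channel with variance 100 among unit-variance channels; note the
  # z-score uses the SD over *all* channel variances, so the outlier's own
  # leverage caps the attainable z at (n-1)/sqrt(n): with 8 channels no
  # single outlier can reach z = 3, with 20 channels it can
  bad8 <- base
  bad8[5, ] <- rnorm(1000, sd = 10)
  v8 <- apply(bad8, 1, var)                    # oracle: direct z-score
  expect_identical(detect_bad_channels(eeg_recording(bad8, 100, labels)),
                   labels[v8 > mean(v8) + 3 * sd(v8)])
  labels20 <- paste0("ch", 1:20)
  bad20 <- matrix(rnorm(20 * 1000), 20)
  bad20[5, ] <- rnorm(1000, sd = 10)
  rec <- eeg_recording(bad20, 100, labels20)
  v <- apply(bad20, 1, var)
  expect_identical(detect_bad_channels(rec),
                   labels20[v > mean(v) + 3 * sd(v)])
  expect_identical(detect_bad_channels(rec), "ch5")
  # invariant to channel ordering
  perm <- sample(20)
  rec_p <- eeg_recording(bad20[perm, ], 100, labels20[perm])
  expect_setequal(detect_bad_channels(rec_p), detect_bad_channels(rec))
  expect_error(detect_bad_channels(eeg_recording(bad8[1:2, ], 100,
                                                 labels[1:2])),
               "3 channels")
})

test_that("interpolation rebuilds a bad channel from its neighbours", {
  fs <- 100
  t <- (0:(fs * 10 - 1)) / fs
  common <- sin(2 * pi * 10 * t)
  labels <- c("O1", "O2", "Oz", "Pz", "P3")
  dat <- matrix(rep(common, each = 5), 5)
  dat[3, ] <- rnorm(length(t), sd = 40)        # Oz is broken
  rec <- eeg_recording(dat, fs, labels)
  # no-op on an empty bad list
  expect_equal(interpolate_bad(rec, character(0)), rec)
  fixed <- interpolate_bad(rec, "Oz")
  expect_gt(cor(fixed$data["Oz", ], common), 0.99)
  # good channels untouched
  expect_equal(fixed$data["O1", ], dat[1, ])
  expect_error(interpolate_bad(rec, "Fz9"), "not present")
  expect_error(interpolate_bad(rec, labels), "unrecoverable")
})

test_that("average reference zeroes the cross-channel mean and is idempotent", {
  x <- rnorm(500)
  # [x, -x] is already average-referenced
  rec <- eeg_recording(rbind(x, -x), 100, c("a", "b"))
  expect_equal(average_reference(rec)$data, rec$data)
  # [x, x] collapses to zero
  rec2 <- eeg_recording(rbind(x, x), 100, c("a", "b"))
  expect_true(all(average_reference(rec2)$data == 0))
  # random data: per-sample mean becomes 0; applying twice changes nothing
  rec4 <- eeg_recording(matrix(rnorm(4 * 500), 4), 100, letters[1:4])
  ref1 <- average_reference(rec4)
  expect_lt(max(abs(colMeans(ref1$data))), 1e-12)
  expect_equal(average_reference(ref1)$data, ref1$data, tolerance = 1e-12)
  expect_warning(average_reference(eeg_recording(matrix(x, 1), 100, "a")),
                 "2 channels")
})

test_that("epoching counts and rejects as specified", {
  fs <- 160
  rec <- sine_recording(10, fs = fs, dur = 60, amp = 10,
                        channels = c("O1", "O2"))
  ep <- epoch_and_reject(rec)
  expect_length(ep$epochs, 15)                 # floor(60 / 4)
  expect_identical(ep$n_rejected, 0L)
  # an artifact burst in samples 1000-1010 kills exactly epoch 2
  rec2 <- rec
  rec2$data[1, 1000:1010] <- 200
  ep2 <- epoch_and_reject(rec2)
  expect_identical(ep2$n_rejected, 1L)
  expect_length(ep2$epochs, 14)
  # oracle: those samples live in epoch ceiling(1000 / 640) = 2
  expect_identical(ceiling(1000 / (4 * fs)), 2)
  # zero threshold rejects everything, with a warning
  expect_warning(ep0 <- epoch_and_reject(rec, amp_thresh_uv = 0), "all epochs")
  expect_length(ep0$epochs, 0)
  expect_identical(ep0$n_rejected, 15L)
  expect_error(epoch_and_reject(sine_recording(10, dur = 2)), "shorter")
})

test_that("rejection is monotone in the amplitude threshold", {
  set.seed(7)
  rec <- eeg_recording(matrix(rnorm(2 * 160 * 40, sd = 40), 2), 160,
                       c("a", "b"))
  thresholds <- c(20, 50, 80, 120, 200)
  rejected <- vapply(thresholds, function(th)
    suppressWarnings(epoch_and_reject(rec, amp_thresh_uv = th))$n_rejected,
    0L)
  expect_true(all(diff(rejected) <= 0))
})

test_that("epoch count is floor(duration / epoch length) for any rate", {
  for (fs in c(100, 160, 250)) {
    rec <- sine_recording(10, fs = fs, dur = 21.5, amp = 5,
                          channels = "Cz")
    ep <- epoch_and_reject(rec)
    expect_length(ep$epochs, floor(21.5 / 4))
  }
})

test_that("interpolating a posterior channel barely moves band centroids", {
  sp <- synth_spec(seed = 5)
  rec <- synth_recording(6, 10, sp, seed = 5)
  cfg <- pci_config()
  # pipeline with Oz interpolated from its neighbours
  rec_bad <- rec
  rec_bad$data["Oz", ] <- 0
  rec_interp <- interpolate_bad(rec_bad, "Oz")
  row_i <- suppressMessages(analyze_recording(rec_interp, cfg))
  # versus the same pipeline with Oz dropped entirely
  rec_drop <- rec
  rec_drop$data <- rec$data[rownames(rec$data) != "Oz", ]
  rec_drop$channel_names <- setdiff(rec$channel_names, "Oz")
  row_d <- suppressMessages(analyze_recording(rec_drop, cfg))
  expect_lt(abs(row_i$f_theta - row_d$f_theta), 0.05)
  expect_lt(abs(row_i$f_alpha - row_d$f_alpha), 0.05)
})
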