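test_that("branch filters pass in-band signal and suppress the line frequency", {
  rec10 <- sinusoid_rec(10, dur_s = 20)
  out10 <- filter_branch(rec10, "spectral")
  mid <- 2000:8000   # avoid filter edge transients
  atten <- 1 - max(abs(out10$data[1, mid]))
  expect_lt(atten, 0.05)

  rec50 <- sinusoid_rec(50, dur_s = 20)
  out50 <- filter_branch(rec50, "spectral")
  expect_lt(max(abs(out50$data[1, mid])), 0.05)  # > 95% attenuation

  dc <- eeg_recording(matrix(5, 1, 10000), 500, "Cz")
  outdc <- filter_branch(dc, "erp")
  expect_lt(abs(mean(outdc$data[1, ])), 0.5)

  lowfs <- eeg_recording(matrix(rnorm(200), 1), 50, "Cz")
  expect_error(filter_branch(lowfs, "spectral"), "sampling rate")
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  n <- 4001
  pulse <- exp(-((seq_len(n) - 2001)^2) / (2 * 20^2))
  rec <- eeg_recording(matrix(pulse, 1), 500, "Cz")
  out <- filter_branch(rec, "spectral")
  expect_equal(which.max(out$data[1, ]), 2001)   # peak latency shift < 1 sample
})

test_that("average reference zeroes the scalp mean and is idempotent", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(4 * 1000), 4), 500,
                       c("Fz", "Cz", "POz", "EOG"))
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data[1:3, ]))), 1e-9)
  expect_identical(out$data[4, ], rec$data[4, ])   # EOG untouched
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  const <- eeg_recording(matrix(5, 3, 100), 500, c("Fz", "Cz", "POz"))
  expect_true(all(rereference_average(const)$data == 0))

  single <- eeg_recording(matrix(rnorm(100), 1), 500, "Cz")
  expect_error(rereference_average(single), "two scalp channels")
})

test_that("Gratton-Coles recovers the propagation factor and decorrelates the EOG", {
  set.seed(7)
  n <- 20000
  eog <- fatigueflow:::pink_noise(n, 50)
  ch <- 0.5 * eog + rnorm(n, sd = 2)
  indep <- rnorm(n, sd = 2)
  rec <- eeg_recording(rbind(ch, indep, eog), 500, c("Cz", "Pz", "EOG"))
  out <- gratton_coles(rec)
  b <- attr(out, "propagation")
  expect_equal(unname(b["Cz"]), 0.5, tolerance = 0.02)
  expect_equal(unname(b["Pz"]), 0, tolerance = 0.02)
  expect_lt(abs(cor(out$data[1, ], eog)), 0.05)
  expect_equal(out$data[2, ], indep - b["Pz"] * eog,
               ignore_attr = TRUE, tolerance = 1e-12)

  flat <- eeg_recording(rbind(rnorm(100), rep(0, 100)), 500, c("Cz", "EOG"))
  expect_error(gratton_coles(flat), "zero variance")
})

test_that("ocular correction removes synthetic blinks from the scalp", {
  des <- small_design()
  rec <- gen_axcpt_eeg(list(theta_base = 1, theta_slope = 0, alpha_base = 1,
                            alpha_slope = 0, noise_sd = 3,
                            blink_rate_per_min = 20), des, seed = 6)
  eog <- get_channel(rec, "EOG")
  expect_gt(abs(cor(get_channel(rec, "Fz"), eog)), 0.5)  # blinks present
  out <- gratton_coles(rec)
  expect_lt(abs(cor(get_channel(out, "Fz"), eog)), 0.05)
})

test_that("artifact rejection implements the peak-to-peak rule exactly", {
  fs <- 500
  flat <- array(0, dim = c(3, 2, fs * 2))
  stepped <- flat
  stepped[2, 1, 500:520] <- 150    # 150 uV step inside 100 ms
  ep <- epoch_set(stepped, fs, c("Cz", "Pz"), c(0, 2000))
  out <- reject_artifacts(ep)
  expect_identical(out$rejected, c(FALSE, TRUE, FALSE))
  expect_identical(out$data, ep$data)   # data untouched

  expect_false(any(reject_artifacts(epoch_set(flat, fs, c("Cz", "Pz"),
                                              c(0, 2000)))$rejected))
  # idempotent
  expect_identical(reject_artifacts(out)$rejected, out$rejected)
})

test_that("windowed rejection agrees with a brute-force O(n^2) scan", {
  set.seed(42)
  fs <- 250
  w <- round(0.1 * fs)
  for (rep in 1:20) {
    x <- cumsum(rnorm(fs, sd = 12))   # random-walk epoch, borderline ranges
    arr <- array(x, dim = c(1, 1, fs))
    got <- reject_artifacts(epoch_set(arr, fs, "Cz", c(0, 1000)))$rejected
    brute <- any(vapply(seq_len(fs - w + 1), function(i)
      diff(range(x[i:(i + w - 1)])) > 100, logical(1)))
    expect_identical(got, brute)
  }
})

test_that("spectral segmentation yields the arithmetic epoch count per block", {
  fs <- 500
  n <- 70 * fs
  ev <- data.frame(sample = c(5 * fs + 1, 65 * fs), code = c("block_on", "block_off"))
  rec <- eeg_recording(matrix(seq_len(n) * 1.0, 1), fs, "Cz", ev)
  sets <- segment_spectral(rec)
  expect_length(sets, 1)
  n_ep <- dim(sets[[1]]$data)[1]
  expect_equal(n_ep, floor((60 - 2) / 1.8) + 1)   # 33 epochs in a 60 s block
  # consecutive epoch starts advance by exactly 1.8 s; every epoch maps to
  # an in-bounds source interval (the ramp encodes the sample index)
  starts <- sets[[1]]$data[, 1, 1]
  expect_equal(diff(starts), rep(1.8 * fs, n_ep - 1))
  expect_true(all(starts >= 5 * fs + 1))
  expect_true(all(starts + 2 * fs - 1 <= 65 * fs))

  short_ev <- data.frame(sample = c(1, fs / 2), code = c("block_on", "block_off"))
  short <- eeg_recording(matrix(0, 1, fs), fs, "Cz", short_ev)
  expect_error(segment_spectral(short), "shorter than one epoch")
})

test_that("six blocks in give six epoch sets out", {
  des <- small_design()
  rec <- gen_axcpt_eeg(quiet_spec(), des, seed = 1)
  expect_length(segment_spectral(rec), 6)
})

test_that("ERP segmentation anchors, baselines, and drops edge epochs", {
  rec <- gen_paired_click(2, 1, noise_sd = 0.5, n_pairs = 20, seed = 8)
  ep <- segment_erp(rec, "S1")
  expect_equal(dim(ep$data)[1], 20)
  times <- epoch_times(ep)
  expect_equal(range(times), c(-150, 450), tolerance = 2)
  base_idx <- which(times >= -50 & times <= 0)
  base_means <- apply(ep$data[, , base_idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-10)

  const <- eeg_recording(matrix(7, 2, 2000), 500, c("Cz", "Pz"),
                         data.frame(sample = 1000, code = "S1"))
  cep <- segment_erp(const, "S1")
  expect_true(all(cep$data == 0))   # constant signal vanishes after baseline

  edge <- eeg_recording(matrix(rnorm(2 * 400), 2), 500, c("Cz", "Pz"),
                        data.frame(sample = c(30, 100), code = "S1"))
  expect_message(segment_erp(edge, "S1"), "dropped")
})
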