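mk_rec <- function(dat, fs = 1000, events = NULL) {
  structure(list(data = dat, sfreq = fs,
                 channels = paste0("ch", seq_len(nrow(dat))),
                 events = if (is.null(events))
                   data.frame(onset_sample = integer(0), code = character(0))
                 else events,
                 subject_id = "S1", group = "HC"),
            class = "eeg_recording")
}

test_that("band-pass response matches the zero-phase Butterworth oracle", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  mid <- seq(5 * fs, 15 * fs)
  # zero-phase order-4 magnitude: |H(f)|^2 = 1/(1 + (f/30)^8) for the LP edge
  for (f0 in c(50, 10)) {
    rec <- mk_rec(rbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t)))
    out <- bandpass_filter(rec, 0.1, 30)
    ratio <- stats::sd(out$data[1, mid]) / stats::sd(rec$data[1, mid])
    theory <- 1 / (1 + (f0 / 30)^8)    # squared by forward-backward passes
    expect_lt(abs(ratio - theory), 0.1 * theory + 0.002)
  }
  # stop-band well attenuated, pass-band essentially untouched
  rec50 <- bandpass_filter(mk_rec(rbind(sin(2 * pi * 50 * t))), 0.1, 30)
  expect_lt(stats::sd(rec50$data[1, mid]), 0.02)
  rec10 <- bandpass_filter(mk_rec(rbind(sin(2 * pi * 10 * t))), 0.1, 30)
  expect_equal(stats::sd(rec10$data[1, mid]) / stats::sd(sin(2 * pi * 10 * t[mid])),
               1, tolerance = 0.05)
})

test_that("band-pass rejects DC and validates band edges", {
  rec <- mk_rec(matrix(7, 2, 4000))
  out <- bandpass_filter(rec, 0.1, 30)
  expect_lt(max(abs(out$data)), 1e-8)
  expect_error(bandpass_filter(rec, 30, 0.1), "invalid band")
  expect_error(bandpass_filter(rec, 0, 30), "invalid band")
  expect_error(bandpass_filter(rec, 1, 600), "invalid band")
})

test_that("average reference zeroes the cross-channel mean at every sample", {
  set.seed(1)
  rec <- mk_rec(matrix(rnorm(5 * 500), 5, 500))
  out <- average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # constant offset on all channels is removed entirely
  rec2 <- mk_rec(matrix(3.3, 4, 100))
  expect_equal(average_reference(rec2)$data, matrix(0, 4, 100))
  # already zero-mean montage is unchanged
  zm <- sweep(rec$data, 2, colMeans(rec$data))
  expect_equal(average_reference(mk_rec(zm))$data, zm)
  expect_error(average_reference(mk_rec(matrix(1, 1, 10))), "single channel")
})

test_that("epoching slices the verbatim window and drops edge events", {
  set.seed(2)
  fs <- 1000
  dat <- matrix(rnorm(2 * 8000), 2, 8000)
  ons <- c(10L, seq(1000L, 7000L, by = 1500L))   # first event underruns
  rec <- mk_rec(dat, fs, data.frame(onset_sample = ons,
                                    code = rep("target", length(ons))))
  expect_warning(ep <- epoch_recording(rec, c(-100, 600)), "dropped")
  expect_equal(n_trials(ep), length(ons) - 1L)
  expect_equal(dim(ep$data)[3], 700L)
  # epoch content equals the raw slice
  expect_equal(ep$data[1, , ], dat[, (1000 - 100):(1000 + 599)])
  expect_equal(ep$t_axis[1], -100)
  expect_equal(ep$meta$trial_index, which(ons != 10L))
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  set.seed(3)
  ep <- mk_noise_epochs(5, C = 2, Tn = 28)
  ep$t_axis <- seq(-100, by = 4, length.out = 28)
  b1 <- baseline_correct(ep)
  idx <- b1$t_axis >= -100 & b1$t_axis < 0
  base <- apply(b1$data[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
  b2 <- baseline_correct(b1)
  expect_equal(b2$data, b1$data)
  # constant epochs become all zero
  epc <- b1; epc$data[] <- 7
  expect_equal(max(abs(baseline_correct(epc)$data)), 0)
  expect_error(baseline_correct(ep, c(900, 1000)), "no samples")
})

test_that("decimation keeps every ratio-th sample with a consistent axis", {
  set.seed(4)
  ep <- mk_noise_epochs(3, C = 2, Tn = 700, sfreq = 1000)
  ep$t_axis <- seq(-100, by = 1, length.out = 700)
  dn <- decimate_epochs(ep, 250)
  expect_equal(dim(dn$data)[3], 175L)
  expect_equal(dn$t_axis[1], -100)
  expect_equal(diff(dn$t_axis)[1], 4)
  expect_equal(dn$data[2, 1, ], ep$data[2, 1, seq(1, 700, by = 4)])
  expect_identical(decimate_epochs(ep, 1000)$data, ep$data)
  expect_error(decimate_epochs(ep, 300), "integer multiple")
})

test_that("the pipeline enforces stage order, metadata survival and the hook", {
  cfg <- noiseless_config(tiny_sim_config(trials = 3))
  rec <- simulate_subject(cfg, "HC", 1)
  hooked <- FALSE
  ep <- preprocess_pipeline(rec, codes = c("target", "nontarget"),
                            artifact_fun = function(r) { hooked <<- TRUE; r })
  expect_true(hooked)
  expect_equal(dim(ep$data)[3], 175L)
  expect_equal(ep$sfreq, 250)
  expect_equal(sum(ep$meta$stimulus_code == "target"), 3L)
  expect_true(all(ep$meta$subject_id == "HC01"))
  # aliasing guard: low-pass edge above the output Nyquist is refused
  expect_error(preprocess_pipeline(rec, hi = 130, sfreq_out = 250),
               "aliasing")
})

test_that("epoch sets round-trip through save/load and CSV export", {
  set.seed(6)
  ep <- mk_noise_epochs(2, C = 2, Tn = 8)
  f <- tempfile(fileext = ".rds"); fcsv <- tempfile(fileext = ".csv")
  save_epochs(ep, f, csv = fcsv)
  back <- load_epochs(f)
  expect_equal(back$data, ep$data)
  expect_equal(back$meta, ep$meta)
  wide <- utils::read.csv(fcsv)
  expect_equal(nrow(wide), n_trials(ep) * 2)
  unlink(c(f, fcsv))
})
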