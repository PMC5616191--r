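make_rec <- function(x, fs, shanks = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  lfp_recording(x, fs, shanks %||% seq_len(nrow(x)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("downsampling keeps the factor, the count, and kills aliases", {
  set.seed(1)
  rec <- make_rec(rnorm(200000), 20000)
  ds <- downsample(rec, 1250)
  expect_equal(ds$fs, 1250)
  expect_equal(ncol(ds$samples), 12500)

  expect_identical(downsample(rec, 20000), rec)
  expect_error(downsample(rec, 1300), "integer multiple")

  # pure 900 Hz tone must not fold back: residual power < 1% of tone power
  t <- (0:199999) / 20000
  tone <- make_rec(sin(2 * pi * 900 * t), 20000)
  out <- downsample(tone, 1250)$samples[1, ]
  expect_lt(mean(out^2) / mean(tone$samples^2), 0.01)
})

test_that("band-pass and notch filtering are zero-phase with the right stops", {
  fs <- 1250
  t <- (0:(10 * fs - 1)) / fs

  # DC sits outside the passband: away from the filter edges, a constant
  # offset of 10 units decays to near zero
  t60 <- (0:(60 * fs - 1)) / fs
  dc <- bandpass_notch(make_rec(rep(10, length(t60)), fs))$samples[1, ]
  expect_lt(abs(mean(dc[(20 * fs):(40 * fs)])), 0.5)

  s50 <- make_rec(sin(2 * pi * 50 * t), fs)
  out50 <- bandpass_notch(s50)$samples[1, ]
  atten_db <- 10 * log10(mean(out50^2) / mean(s50$samples^2))
  expect_lt(atten_db, -20)

  s8 <- sin(2 * pi * 8 * t)
  out8 <- bandpass_notch(make_rec(s8, fs))$samples[1, ]
  mid <- (2 * fs):(8 * fs)  # avoid filter edges
  expect_equal(sqrt(mean(out8[mid]^2)) / sqrt(mean(s8[mid]^2)), 1,
               tolerance = 0.05)
  cc <- ccf(out8[mid], s8[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass_notch(make_rec(s8, fs), band = c(0.1, 700)),
               "inside")
})

test_that("variance z-scoring flags constructed outliers and only those", {
  fs <- 100
  set.seed(42)
  x <- rnorm(40 * 100)
  ep <- data.frame(label = "run", start = seq(0, 3900, by = 100),
                   end = seq(100, 4000, by = 100))
  rec <- make_rec(x, fs)
  flags <- detect_artifacts(rec, ep, z_thresh = 4)
  expect_false(any(flags$flagged))

  x2 <- x
  x2[501:600] <- x2[501:600] * sqrt(10)
  flags2 <- detect_artifacts(make_rec(x2, fs), ep, z_thresh = 4)
  expect_true(flags2$flagged[6])
  expect_equal(sum(flags2$flagged), 1)

  expect_error(detect_artifacts(rec, ep[1, ]), "at least 2")
  expect_error(detect_artifacts(rec, ep[0, ]), "empty")
})

test_that("epoch extraction applies the run/baseline placement rules", {
  fs <- 1250
  trials <- data.frame(
    trial_id = 1:4,
    trial_start_s = c(20, 50, 80, 110),
    stop_entry_s = c(32, 56.4, 95, 122),
    intertrial_start_s = c(10, 40, 78.5, 100),
    intertrial_end_s = c(20, 50, 80, 110),
    correct = c(1, 1, 1, 0))
  expect_warning(ep <- extract_epochs(trials, 5, fs), "shorter")

  # trial 1: run epoch is the last 5 s before stop-area entry
  run1 <- ep[ep$label == "run", ][1, ]
  expect_equal(run1$start, round(27 * fs))
  expect_equal(run1$end, round(32 * fs))
  # baseline occupies the 5 s immediately preceding trial start
  bl1 <- ep[ep$label == "baseline", ][1, ]
  expect_equal(bl1$end, round(20 * fs))
  expect_equal(bl1$start, round(15 * fs))

  # trial 2 lasts 6.4 s <= 7 s: excluded; trial 3's intertrial is too short
  # (its run epoch is kept, its baseline dropped with a warning); trial 4
  # incorrect: excluded
  expect_equal(nrow(ep), 3)
  expect_equal(sum(ep$label == "run"), 2)
  expect_equal(sum(ep$label == "baseline"), 1)
  expect_true(all(ep$end - ep$start == round(5 * fs)))

  # entry exactly 5 s into the recording: run starts at sample 0
  tr0 <- data.frame(trial_id = 1, trial_start_s = -3, stop_entry_s = 5,
                    intertrial_start_s = -10, intertrial_end_s = -3,
                    correct = 1)
  ep0 <- suppressWarnings(extract_epochs(tr0, 5, fs, min_duration = 7))
  expect_equal(ep0[ep0$label == "run", "start"], 0)
})

test_that("rereferencing cancels shared signals and is idempotent", {
  fs <- 250
  set.seed(7)
  s <- simulate_theta_source(source_spec(8, 1, 1), 40, fs, 5)
  n <- length(s)
  x <- rbind(s + rnorm(n, sd = 0.3), s + rnorm(n, sd = 0.3),
             s + rnorm(n, sd = 0.3), s + rnorm(n, sd = 0.3))
  rec <- lfp_recording(x, fs, c(1, 1, 2, 2))

  # identical channels cancel exactly under both derivations
  same <- lfp_recording(rbind(s, s, s, s), fs, c(1, 1, 2, 2))
  expect_lt(max(abs(rereference_bipolar(same, 1, 2)$samples)), 1e-12)
  expect_lt(max(abs(rereference_car(same)$samples)), 1e-12)

  # equal-gain mixture: bipolar output carries no source component
  bip <- rereference_bipolar(rec, 1, 2)
  expect_equal(nrow(bip$samples), 2)
  expect_lt(abs(cor(bip$samples[1, ], s)), 0.05)

  # CAR centering identity: across-shank mean of output is ~0 at every sample
  car <- rereference_car(rec)
  shank_means <- (colMeans(car$samples[1:2, ]) +
                    colMeans(car$samples[3:4, ])) / 2
  expect_lt(max(abs(shank_means)), 1e-12)
  # idempotence on centered data
  expect_equal(rereference_car(car)$samples, car$samples, tolerance = 1e-12)

  expect_error(rereference_bipolar(rec, 1, 1), "differ")
  expect_error(rereference_car(lfp_recording(x[1:2, ], fs, c(1, 1))),
               "2 shanks")
})

test_that("recording, spike, and epoch files round-trip", {
  dir <- withr::local_tempdir()
  rec <- lfp_recording(matrix(rnorm(300), 3), 250, c(1, 1, 2),
                       c("striatum", "striatum", "cortex"))
  bp <- file.path(dir, "rec.dat")
  write_recording(rec, bp, scenario = "volume_conduction", seed = 1)
  rt <- read_recording(bp)
  expect_equal(rt$samples, rec$samples, tolerance = 1e-6)  # float32 storage
  expect_equal(rt$fs, 250)
  expect_equal(rt$channel_shank_map, rec$channel_shank_map)

  spikes <- list(unit01 = c(0.5, 1.25), unit02 = numeric(0))
  sp <- file.path(dir, "spikes.csv")
  write_spikes(spikes, sp)
  expect_equal(read_spikes(sp)$unit01, c(0.5, 1.25))

  ep <- data.frame(label = c("run", "baseline"), start = c(0L, 500L),
                   end = c(250L, 750L))
  attr(ep, "fs") <- 250
  fp <- file.path(dir, "ep.csv")
  write_epoch_set(ep, fp)
  rt_ep <- read_epoch_set(fp, 250)
  expect_equal(rt_ep$start, ep$start)
  expect_equal(rt_ep$end, ep$end)

  cfgp <- file.path(dir, "cfg.yaml")
  write_config_yaml(list(fs = 1250, theta_band = c(6, 10)), cfgp)
  expect_equal(read_config_yaml(cfgp)$theta_band, c(6, 10))
})
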