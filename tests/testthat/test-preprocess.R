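# construction, referencing, GFP -------------------------------------------

test_that("average reference zeroes channel means and is idempotent", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(5 * 100) + 3, 5, 100), fs = 100)
  ar <- average_reference(rec)
  expect_equal(max(abs(colMeans(ar$data))), 0, tolerance = 1e-9)
  expect_equal(ar$reference, "average")
  ar2 <- average_reference(ar)
  expect_equal(ar2$data, ar$data, tolerance = 1e-12)
  # the worked one-sample example: (3, 1, 2) -> (1, -1, 0)
  rec3 <- eeg_recording(cbind(c(3, 1, 2), c(3, 1, 2)), fs = 10)
  expect_equal(average_reference(rec3)$data[, 1], c(1, -1, 0),
               ignore_attr = TRUE)
})

test_that("GFP is the population standard deviation across channels", {
  rec <- eeg_recording(cbind(c(1, -1), c(5, 5)), fs = 10)
  g <- compute_gfp(rec)
  expect_equal(g$values, c(1, 0))
  rec4 <- eeg_recording(cbind(c(2, 0, -2, 0), c(2, 0, -2, 0)), fs = 10)
  expect_equal(compute_gfp(rec4)$values[1], sqrt(2))
  # offset invariance and RMS identity after average reference
  set.seed(2)
  X <- matrix(rnorm(8 * 50), 8, 50)
  g1 <- compute_gfp(eeg_recording(X, 100))$values
  g2 <- compute_gfp(eeg_recording(X + matrix(rnorm(50), 8, 50,
                                             byrow = TRUE), 100))$values
  expect_equal(g1, g2, tolerance = 1e-9)
  ar <- average_reference(eeg_recording(X, 100))
  expect_equal(compute_gfp(ar)$values, sqrt(colMeans(ar$data^2)),
               tolerance = 1e-9)
})

test_that("GFP peak detection finds strict interior maxima", {
  g <- structure(list(values = c(0, 1, 0, 2, 0), peak_indices = integer(0),
                      fs = 10), class = "gfp_series")
  expect_equal(detect_gfp_peaks(g)$peak_indices, c(2L, 4L))
  g$values <- 1:5                       # monotone
  expect_length(detect_gfp_peaks(g)$peak_indices, 0)
  g$values <- c(0, 3, 3, 0, 1)          # plateau: first sample wins
  expect_equal(detect_gfp_peaks(g)$peak_indices, 2L)
  # rectified 10 Hz over 1 s at 125 Hz has ~20 peaks
  v <- abs(sin(2 * pi * 10 * (0:124) / 125))
  g$values <- v
  pk <- detect_gfp_peaks(g)$peak_indices
  expect_true(abs(length(pk) - 20) <= 1)
  expect_true(all(diff(pk) > 0))
  expect_true(all(v[pk] > v[pk - 1]))
})

# filtering and resampling --------------------------------------------------

test_that("band-pass keeps the passband and kills drift", {
  fs <- 125; tt <- seq(0, 20, by = 1 / fs)[-1]
  mid <- seq(round(length(tt) * .2), round(length(tt) * .8))
  sine <- sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(sine, sine), fs)
  out <- bandpass_filter(rec, 1, 40)
  expect_equal(sd(out$data[1, mid]) / sd(sine[mid]), 1, tolerance = 0.05)
  drift <- sin(2 * pi * 0.1 * tt)
  outd <- bandpass_filter(eeg_recording(rbind(drift, drift), fs), 1, 40)
  atten_db <- 20 * log10(sd(outd$data[1, mid]) / sd(drift[mid]))
  expect_lt(atten_db, -20)
  z <- eeg_recording(matrix(0, 2, 500), fs)
  expect_equal(bandpass_filter(z, 1, 40)$data, z$data)
  expect_error(bandpass_filter(rec, 1, 80), class = "msdyn_parameter_error")
})

test_that("resampling is anti-aliased with exact length arithmetic", {
  fs <- 1000; tt <- seq_len(1000) / fs
  sine <- sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(sine, sine), fs)
  out <- resample_recording(rec, 125)
  expect_equal(ncol(out$data), 125)
  expect_equal(out$fs, 125)
  # 10 Hz amplitude from a sin/cos regression on the middle of the record
  mid <- 30:95
  t_new <- mid / 125
  basis <- cbind(sin(2 * pi * 10 * t_new), cos(2 * pi * 10 * t_new))
  amp <- sqrt(sum(coef(lm(out$data[1, mid] ~ basis + 0))^2))
  expect_equal(amp, 1, tolerance = 0.05)
  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, 2000), class = "msdyn_parameter_error")
  # resampling twice to the same target changes nothing further
  out2 <- resample_recording(out, 125)
  expect_identical(out2$data, out$data)
})

# spherical-spline interpolation --------------------------------------------

test_that("spherical spline rebuilds a degree-1 field and spares good channels", {
  pos <- sphere_positions(32)
  field <- pos[, 3]                         # first-degree spherical harmonic
  amp <- c(5, -3, 8, 1)
  X <- outer(field, amp)
  rec <- eeg_recording(X, fs = 10, positions = pos)
  bad <- rec$channel_names[which.max(abs(field))]
  rec_b <- rec
  rec_b$data[match(bad, rec$channel_names), ] <- 0
  rec_b$bad_channels <- bad
  out <- interpolate_channels(rec_b, bad)
  i <- match(bad, rec$channel_names)
  expect_equal(out$data[i, ], X[i, ], tolerance = 0.05)
  expect_identical(out$data[-i, ], rec_b$data[-i, ])   # untouched, bit-exact
  expect_identical(interpolate_channels(rec, character(0)), rec)
  rec_np <- eeg_recording(X, fs = 10)
  rec_np$bad_channels <- bad
  expect_error(interpolate_channels(rec_np, bad),
               class = "msdyn_capability_error")
  expect_error(interpolate_channels(rec_b, rec$channel_names[1:31]),
               class = "msdyn_parameter_error")
})

# io -------------------------------------------------------------------------

test_that("matrix + sidecar round-trips a recording", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(4 * 1000), 4, 1000), fs = 125)
  path <- tempfile(fileext = ".tsv")
  write_recording_matrix(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$fs, 125)
  expect_equal(back$reference, "original")
  # missing fs key is a format error
  side <- paste0(sub("\\.[^.]+$", "", path), ".yaml")
  yaml::write_yaml(list(channel_names = rec$channel_names), side)
  expect_error(read_recording(path), class = "msdyn_format_error")
  writeLines("a b c", path)
  yaml::write_yaml(list(fs = 10), side)
  expect_error(read_recording(path), class = "msdyn_parse_error")
})

test_that("EDF round-trips within 16-bit quantisation", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(3 * 250, sd = 20), 3, 250), fs = 125,
                       channel_names = c("Fz", "Cz", "Pz"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(nrow(back$data), 3)
  expect_equal(ncol(back$data), 250)
  expect_equal(back$fs, 125)
  expect_equal(back$channel_names, c("Fz", "Cz", "Pz"))
  rng <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(back$data - rec$data)), rng / 65000 * 2)
})
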