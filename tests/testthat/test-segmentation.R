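test_that("back-fitting assigns every sample to its best template, ignoring polarity", {
  Tm <- make_template_maps(12, 3, seed = 1)
  model <- model_from_maps(Tm)
  lab <- rep(2L, 50)
  rec <- toy_recording(Tm, lab)
  seg <- backfit_labels(rec, model)
  expect_true(all(seg$labels == 2))
  expect_true(all(seg$corr > 0.999))
  # flipping the sign of odd samples changes nothing
  rec2 <- rec
  rec2$data[, seq(1, 50, 2)] <- -rec2$data[, seq(1, 50, 2)]
  expect_identical(backfit_labels(rec2, model)$labels, seg$labels)
  # equidistant sample: lower class index wins
  x <- Tm[1, ] + Tm[2, ]
  rec3 <- average_reference(eeg_recording(cbind(x, x), fs = 125))
  expect_equal(backfit_labels(rec3, model)$labels, c(1L, 1L))
  # zero-variance sample inherits the previous label
  rec4 <- rec
  rec4$data[, 10] <- 0
  seg4 <- backfit_labels(rec4, model)
  expect_equal(seg4$labels[10], seg4$labels[9])
  expect_equal(seg4$corr[10], 0)
})

test_that("Besag smoothing absorbs a single-sample flicker", {
  C <- 8
  Tm <- make_template_maps(C, 2, seed = 2)
  model <- model_from_maps(Tm)
  lab <- c(1L, 1L, 1L, 2L, 1L, 1L, 1L)
  set.seed(3)
  X <- Tm[lab, ] + matrix(rnorm(7 * C, sd = 0.05), 7, C)  # constant-GFP carrier
  rec <- average_reference(eeg_recording(t(X), fs = 125))
  seg <- backfit_labels(rec, model)
  expect_equal(seg$labels, lab)        # flicker survives plain backfit
  sm <- smooth_labels(seg, rec, model, smoothing_params(3, 10))
  expect_true(all(sm$labels == 1L))
  # direct evaluation of the smoothing objective at the flicker sample:
  # the class-1 cost must undercut class 2 once the neighbourhood term counts
  Xc <- t(rec$data) - rowMeans(t(rec$data))
  d2 <- rowSums(Xc^2) - (Xc %*% t(model$maps))^2
  e <- sum(d2[cbind(1:7, sm$labels)]) / (7 * (C - 1))
  cost <- function(k, t, labels) d2[t, k] / (2 * e * (C - 1)) -
    10 * sum(labels[max(1, t - 3):min(7, t + 3)][-(t - max(1, t - 3) + 1)] == k)
  expect_lt(cost(1, 4, sm$labels), cost(2, 4, sm$labels))
  # lambda = 0 and uniform labels are fixed points
  expect_identical(smooth_labels(seg, rec, model,
                                 smoothing_params(3, 0))$labels, seg$labels)
  uni <- backfit_labels(toy_recording(Tm, rep(1L, 40)), model)
  expect_true(all(smooth_labels(toy_recording(Tm, rep(1L, 40)) |>
                                  backfit_labels(model),
                                toy_recording(Tm, rep(1L, 40)), model,
                                smoothing_params(3, 25))$labels == 1L))
  expect_error(smooth_labels(seg, rec, model, smoothing_params(10, 1)),
               class = "msdyn_parameter_error")
})

test_that("stronger smoothing never fragments the labelling further", {
  Tm <- make_template_maps(16, 4, seed = 4)
  model <- model_from_maps(Tm)
  spec <- synthetic_spec(n_channels = 16, duration = 10, snr = 2, k_true = 4,
                         seed = 5)
  lab <- simulate_label_sequence(spec, "control", seed = 6)
  rec <- simulate_recording(spec, Tm, lab, seed = 7)
  seg <- backfit_labels(rec, model)
  runs <- vapply(c(0, 2, 5, 10, 20), function(lam)
    nrow(extract_segments(smooth_labels(seg, rec, model,
                                        smoothing_params(3, lam)))), 0)
  expect_true(all(diff(runs) <= 0))
})

test_that("segment extraction enumerates maximal runs with boundary flags", {
  seg <- segmentation_from_labels(c(1, 1, 2, 2, 2, 1), fs = 125, k = 2)
  runs <- extract_segments(seg)
  expect_equal(runs$class, c(1, 2, 1))
  expect_equal(runs$start, c(1, 3, 6))
  expect_equal(runs$length, c(2, 3, 1))
  expect_equal(runs$boundary, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(extract_segments(
    segmentation_from_labels(rep(3, 9), 125, 3))), 1)
  expect_equal(nrow(extract_segments(
    segmentation_from_labels(c(1, 2, 1, 2), 125, 2))), 4)
})

test_that("temporal parameters match hand enumeration", {
  lab <- c(1, 1, 1, 1, 2, 2, 1, 1, 3, 3)
  seg <- segmentation_from_labels(lab, fs = 125, k = 3)
  tp <- temporal_parameters(seg, boundary_mode = "inclusive")
  expect_equal(tp$coverage, c(60, 20, 20))
  expect_equal(tp$occurrence[1], 2 / (10 / 125))
  expect_equal(tp$duration[1], 3 * 1000 / 125)
  expect_equal(sum(tp$coverage), 100, tolerance = 1e-6)
  # occurrence x duration = coverage identity, boundary-inclusive
  expect_equal(tp$occurrence * tp$duration / 1000, tp$coverage / 100,
               tolerance = 1e-9)
  # single class throughout
  one <- temporal_parameters(segmentation_from_labels(rep(1, 250), 125, 1),
                             boundary_mode = "inclusive")
  expect_equal(one$coverage, 100)
  expect_equal(one$occurrence, 1 / 2)
  expect_equal(one$duration, 2000)
  # exclusive mode drops the truncated edge runs
  tpx <- temporal_parameters(seg, boundary_mode = "exclusive")
  expect_equal(tpx$occurrence, c(1, 1, 0) / (10 / 125))
  expect_equal(tpx$duration[2], 2 * 8)
  expect_error(temporal_parameters(segmentation_from_labels(integer(0),
                                                            125, 2)),
               class = "msdyn_parameter_error")
})

test_that("GEV is the GFP^2-weighted squared-correlation mass per class", {
  Q <- make_template_maps(10, 6, seed = 8)
  Tm <- Q[1:2, ]
  model <- model_from_maps(Tm)
  lab <- rep(1L, 30)
  rec <- toy_recording(Tm, lab)
  seg <- backfit_labels(rec, model)
  gev <- global_explained_variance(rec, seg, model)
  expect_equal(gev$gev_total, 1, tolerance = 1e-9)
  expect_equal(sum(gev$gev_class), gev$gev_total, tolerance = 1e-12)
  # hand-set correlations: corr^2 0.64 and 0.36 on equal GFP mass -> 0.5
  rec2 <- average_reference(eeg_recording(cbind(Tm[1, ], Tm[2, ]) * 5,
                                          fs = 125))
  seg2 <- segmentation_from_labels(c(1L, 2L), 125, 2)
  seg2$corr <- c(0.8, 0.6)
  gev2 <- global_explained_variance(rec2, seg2, model)
  expect_equal(gev2$gev_total, 0.5, tolerance = 1e-9)
  # data orthogonal to every template has GEV 0
  other <- Q[5:6, ]
  rec3 <- toy_recording(other, rep(1L, 30))
  seg3 <- backfit_labels(rec3, model)
  expect_lt(global_explained_variance(rec3, seg3, model)$gev_total, 1e-6)
  # sign flips leave GEV untouched
  rec4 <- rec
  rec4$data <- -rec4$data
  expect_equal(global_explained_variance(rec4, backfit_labels(rec4, model),
                                         model)$gev_total,
               gev$gev_total, tolerance = 1e-12)
  z <- eeg_recording(matrix(0, 4, 30) + 1, fs = 125)
  zr <- average_reference(z)
  expect_error(global_explained_variance(
    zr, segmentation_from_labels(rep(1, 30), 125, 2), model),
    class = "msdyn_undefined_gev_error")
})
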