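noise_epochs <- function(n_trials, n_channels, srate = 1000,
                         window = c(-100, 700), sd = 1, seed = 1) {
  ns <- n_epoch_samples(window, srate)
  set.seed(seed)
  arr <- array(rnorm(n_trials * n_channels * ns, sd = sd),
               c(n_trials, n_channels, ns))
  mon <- make_montage(max(n_channels, 8))
  mon <- channel_montage(mon$labels[seq_len(n_channels)],
                         mon$positions_mm[seq_len(n_channels), ])
  epoch_set(arr, mon, srate, window)
}

test_that("average reference removes the channel mean and is idempotent", {
  ep <- noise_epochs(3, 8)
  ep$data[, 1, ] <- 3; ep$data[, 2, ] <- 1
  rr <- rereference_average(ep)
  expect_lt(max(abs(apply(rr$data, c(1, 3), mean))), 1e-9)
  # two channels (3, 1) -> (1, -1)
  two <- noise_epochs(1, 2)
  two$data[1, 1, ] <- 3; two$data[1, 2, ] <- 1
  rr2 <- rereference_average(two)
  expect_equal(as.vector(rr2$data[1, 1, 1:5]), rep(1, 5))
  expect_equal(as.vector(rr2$data[1, 2, 1:5]), rep(-1, 5))
  # idempotence
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  # GFP unchanged by re-referencing
  g0 <- gfp(average_epochs(ep))
  g1 <- gfp(average_epochs(rr))
  expect_equal(g1$values, g0$values, tolerance = 1e-9)
  one <- noise_epochs(1, 2)
  one$data <- one$data[, 1, , drop = FALSE]
  one$montage <- channel_montage("E001", matrix(c(0, 0, 90), 1))
  expect_error(rereference_average(one), "2 channels")
})

test_that("baseline correction removes constant offsets and is idempotent", {
  ep <- noise_epochs(2, 6)
  ep$data[, 3, ] <- 7                       # constant-offset channel
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data[, 3, ])), 0)
  # default baseline = the pre-stimulus samples
  tms <- epoch_times_ms(ep)
  expect_true(all(tms[tms <= 0] >= ep$window_ms[1]))
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-500, -400)), "baseline window")
})

test_that("baseline correction and average reference commute for GFP", {
  ep <- noise_epochs(4, 12, seed = 3)
  a <- gfp(average_epochs(baseline_correct(rereference_average(ep))))
  b <- gfp(average_epochs(rereference_average(baseline_correct(ep))))
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("multiquadric interpolation reproduces nodes, constants and smooth fields", {
  mon <- make_montage(24)
  ep <- noise_epochs(1, 24, srate = 100, window = c(-100, 390))
  # constant field: interpolant must return the constant
  ep$data[1, , ] <- 5
  bad <- "E007"
  ep$data[1, 7, ] <- 999
  out <- interpolate_bad_channels(ep, bad)
  expect_equal(as.vector(out$data[1, 7, ]),
               rep(5, dim(ep$data)[3]), tolerance = 1e-6)
  expect_equal(out$data[1, -7, ], ep$data[1, -7, ])  # good channels untouched

  # bad channel colocated with a good one reproduces its values
  mon2 <- mon
  mon2$positions_mm[7, ] <- mon2$positions_mm[8, ]
  ep2 <- noise_epochs(1, 24, srate = 100, window = c(-100, 390), seed = 5)
  ep2$montage <- mon2
  target <- ep2$data[1, 8, ]
  out2 <- interpolate_bad_channels(ep2, "E007")
  expect_equal(as.vector(out2$data[1, 7, ]), as.vector(target),
               tolerance = 1e-6)

  # smooth low-order field sampled on the montage: reconstruction error far
  # below the field scale
  f <- function(p) 0.8 + 0.01 * p[, 2] + 0.005 * p[, 3]
  vals <- f(mon$positions_mm)
  ep3 <- noise_epochs(1, 24, srate = 100, window = c(-100, 390))
  for (s in seq_len(dim(ep3$data)[3])) ep3$data[1, , s] <- vals
  truth <- ep3$data[1, 5, 1]
  ep3$data[1, 5, ] <- -100
  out3 <- interpolate_bad_channels(ep3, "E005")
  expect_lt(max(abs(out3$data[1, 5, ] - truth)), 0.05 * diff(range(vals)))

  expect_error(interpolate_bad_channels(ep, "nope"), "unknown channel")
  expect_error(interpolate_bad_channels(ep, sprintf("E%03d", 1:22)),
               "too many bad channels")
})

test_that("epoch averaging is the arithmetic mean with 1/sqrt(n) noise shrinkage", {
  ep <- noise_epochs(1, 6)
  expect_equal(average_epochs(ep), ep$data[1, , ],
               ignore_attr = TRUE)
  ep2 <- noise_epochs(2, 6)
  ep2$data[2, , ] <- -ep2$data[1, , ]
  expect_equal(max(abs(average_epochs(ep2))), 0)
  ep3 <- noise_epochs(200, 4, sd = 2, seed = 9)
  erp <- average_epochs(ep3)
  expect_equal(sd(as.vector(erp)), 2 / sqrt(200), tolerance = 0.1)
})

test_that("GFP matches closed forms and its invariances", {
  ns <- 5
  erp_same <- matrix(3.3, 4, ns)
  expect_equal(gfp(erp_same)$values, rep(0, ns))
  erp_pm <- rbind(rep(1, ns), rep(-1, ns))
  expect_equal(gfp(erp_pm)$values, rep(1, ns))
  erp4 <- matrix(c(2, 0, -2, 0), 4, ns)
  expect_equal(gfp(erp4)$values, rep(sqrt(2), ns), tolerance = 1e-12)

  set.seed(4)
  erp <- matrix(rnorm(16 * 30), 16, 30)
  g0 <- gfp(erp)$values
  expect_equal(gfp(erp[sample.int(16), ])$values, g0, tolerance = 1e-9)
  offset <- matrix(rnorm(30), 16, 30, byrow = TRUE)
  expect_equal(gfp(erp + offset)$values, g0, tolerance = 1e-9)
  reref <- sweep(erp, 2, colMeans(erp))
  expect_equal(gfp(reref)$values, g0, tolerance = 1e-9)
  expect_error(gfp(erp[1, , drop = FALSE]), "2 channels")
})

test_that("POI finding takes the windowed argmax with earliest-tie rule", {
  t_ms <- seq(-100, 700, by = 2)
  v <- exp(-(t_ms - 300)^2 / (2 * 30^2))
  g <- structure(list(times_ms = t_ms, values = v), class = "gfp_series")
  poi <- find_component_poi(g, c(200, 350), half_width_ms = 40)
  expect_equal(poi$peak_ms, 300)
  expect_equal(c(poi$start_ms, poi$end_ms), c(260, 340))
  expect_equal(poi$end_ms - poi$start_ms, 80)

  # two equal maxima: earliest wins
  v2 <- numeric(length(t_ms))
  v2[t_ms == 280] <- 1; v2[t_ms == 320] <- 1
  g2 <- structure(list(times_ms = t_ms, values = v2), class = "gfp_series")
  expect_equal(find_component_poi(g2, c(200, 350))$peak_ms, 280)

  # flat window warns and falls back to the window start
  g3 <- structure(list(times_ms = t_ms, values = rep(1, length(t_ms))),
                  class = "gfp_series")
  expect_warning(p3 <- find_component_poi(g3, c(200, 350)), "flat")
  expect_equal(p3$peak_ms, 200)
  expect_true(p3$flat)

  # clipping to the epoch support is flagged
  p4 <- find_component_poi(g, c(680, 700), half_width_ms = 40)
  expect_true(p4$clipped)
  expect_lte(p4$end_ms, max(t_ms))
})

test_that("component amplitude averages the GFP over the inclusive POI", {
  t_ms <- seq(0, 100, by = 10)
  g <- structure(list(times_ms = t_ms, values = rep(2, 11)),
                 class = "gfp_series")
  poi <- structure(list(component = "N2", peak_ms = 50, start_ms = 30,
                        end_ms = 70, clipped = FALSE, flat = FALSE),
                   class = "poi")
  expect_equal(component_amplitude(g, poi), 2)
  # endpoints inclusive: samples at 30 and 70 participate
  g2 <- g; g2$values <- as.numeric(t_ms %in% c(30, 70))
  expect_equal(component_amplitude(g2, poi), 2 / 5)
  out <- structure(list(component = "N2", peak_ms = 50, start_ms = -30,
                        end_ms = 70, clipped = FALSE, flat = FALSE),
                   class = "poi")
  expect_error(component_amplitude(g, out), "outside")
})

test_that("amplitudes shrink monotonically with planted ERP attenuation", {
  truth_at <- function(eff) ground_truth("1-2", erp_per_pct = eff,
                                         noise_sd = c(rt_ms = 0, fa = 0,
                                                      erp_uv = 0))
  mon <- make_montage(16)
  amps <- sapply(c(0, 0.003, 0.006, 0.009), function(eff) {
    ep <- simulate_epochs(setNames(70, "1-2"), truth_at(eff), mon,
                          n_trials = 1, srate_hz = 256, seed = 1)
    g <- gfp(average_epochs(ep))
    poi <- find_component_poi(g, c(200, 350), component = "N2")
    component_amplitude(g, poi)
  })
  expect_true(all(diff(amps) < 0))
  # closed-form scaling: amplitude proportional to max(0, 1 - eff * sev)
  expect_equal(amps[2] / amps[1], 1 - 0.003 * 70, tolerance = 1e-6)
})

test_that("epoch fixture files round-trip", {
  truth <- ground_truth()
  ep <- simulate_epochs(setNames(10, "1-2"), truth, make_montage(12),
                        n_trials = 3, srate_hz = 256, seed = 2)
  dir <- tempfile()
  write_epochs_fixture(ep, dir)
  back <- read_epochs_fixture(dir)
  expect_equal(dim(back$data), dim(ep$data))
  expect_equal(back$srate_hz, ep$srate_hz)
  # float32 storage: agreement to single precision
  expect_lt(max(abs(back$data - ep$data)), 1e-4)
  expect_equal(back$montage$labels, ep$montage$labels)
})
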