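test_that("phantom brain partitions parcels across hemispheres deterministically", {
  g <- grid_spec(c(32, 32, 32))
  a1 <- make_phantom_brain(g, n_parcels = 4, seed = 1)
  a2 <- make_phantom_brain(g, n_parcels = 4, seed = 1)
  expect_identical(as.integer(a1$parcellation), as.integer(a2$parcellation))
  expect_identical(as.integer(a1$brain_mask), as.integer(a2$brain_mask))
  expect_equal(nrow(a1$parcel_table), 4L)
  expect_equal(sum(a1$parcel_table$hemisphere == "L"), 2L)
  expect_equal(sum(a1$parcel_table$hemisphere == "R"), 2L)
  # parcels nonzero only inside the brain, ids contiguous, all non-empty
  expect_true(all(a1$parcellation[a1$brain_mask == 0L] == 0L))
  counts <- table(as.integer(a1$parcellation)[as.integer(a1$parcellation) > 0])
  expect_identical(sort(as.integer(names(counts))), 1:4)
  expect_true(all(counts >= 1))

  a3 <- make_phantom_brain(grid_spec(c(64, 64, 64)), n_parcels = 20, seed = 7)
  cc <- table(as.integer(a3$parcellation)[as.integer(a3$parcellation) > 0])
  expect_equal(length(cc), 20L)
  expect_true(all(cc >= 1))
  expect_lte(sum(cc), sum(a3$brain_mask))
})

test_that("phantom construction rejects invalid sizes", {
  expect_error(grid_spec(c(4, 32, 32)), "dimensions")
  expect_error(make_phantom_brain(grid_spec(c(32, 32, 32)), 5, seed = 1),
               "even")
  expect_error(make_phantom_brain(grid_spec(c(8, 8, 8)), 200, seed = 1),
               "limiting dimension")
})

test_that("streamline atlas honors endpoint contracts and determinism", {
  a <- make_phantom_brain(grid_spec(c(32, 32, 32)), 4, seed = 2)
  spec1 <- data.frame(parcel_a = 1, parcel_b = 2, n_streamlines = 4)
  s <- make_streamline_atlas(a, spec1, jitter_sd_mm = 1.5, seed = 3)
  expect_length(s$paths, 4L)
  for (p in s$paths) {
    expect_identical(a$parcellation[matrix(p[1, ], ncol = 3)], 1L)
    expect_identical(a$parcellation[matrix(p[nrow(p), ], ncol = 3)], 2L)
    expect_true(all(abs(diff(p)) <= 1L))
  }
  # zero jitter: paths between identical endpoints coincide
  s0a <- make_streamline_atlas(a, spec1, jitter_sd_mm = 0, seed = 5)
  s0b <- make_streamline_atlas(a, spec1, jitter_sd_mm = 0, seed = 5)
  expect_identical(s0a$paths, s0b$paths)

  specN <- data.frame(parcel_a = c(1, 1, 2), parcel_b = c(2, 3, 4),
                      n_streamlines = 10)
  sa <- make_streamline_atlas(a, specN, seed = 11)
  sb <- make_streamline_atlas(a, specN, seed = 11)
  expect_identical(sa$paths, sb$paths)
  expect_error(
    make_streamline_atlas(a, data.frame(parcel_a = 1, parcel_b = 1,
                                        n_streamlines = 1), seed = 1),
    "distinct")
})

test_that("lesion cohorts respect volume range, side and connectivity", {
  a <- make_phantom_brain(grid_spec(c(32, 32, 32)), 6, seed = 4)
  brain_vol <- sum(a$brain_mask)
  les <- sample_lesions(a, 30, volume_pct_range = c(0.05, 1.72),
                        side_ratio_right = 0.3, seed = 9)
  expect_length(les, 30L)
  for (l in les) {
    pct <- 100 * sum(l) / brain_vol
    # target volumes are drawn in-range then rounded to whole voxels
    expect_gte(sum(l), 1)
    expect_lte(pct, 1.72 + 100 / brain_vol)
    h <- attr(l, "hemisphere")
    side_vox <- unique(a$hemispheres[l == 1L])
    expect_identical(side_vox, if (h == "L") 1L else 2L)
    expect_identical(n_components6(l), 1L)
  }
  # degenerate side ratio: everything left
  les_l <- sample_lesions(a, 10, volume_pct_range = c(0.1, 1),
                          side_ratio_right = 0, seed = 2)
  expect_true(all(vapply(les_l, attr, "", which = "hemisphere") == "L"))
})

test_that("simulated behavior matches its closed-form null and responds to planted effects", {
  truth0 <- ground_truth(noise_sd = c(rt_ms = 0, fa = 0, erp_uv = 0))
  sev <- setNames(numeric(3), c("1-2", "1-3", "2-3"))
  # null case: FA rate equals the configured baseline in expectation
  fa_hat <- mean(vapply(1:300, function(s) {
    r <- simulate_behavior(sev, truth0, n_go = 30, n_nogo = 30, seed = s)
    mean(r$trials$responded[r$trials$type == "nogo"])
  }, numeric(1)))
  expect_equal(fa_hat, behavior_params()$fa_baseline, tolerance = 0.05)

  # full session shape: 8 blocks of 60 trials -> 240 go + 240 nogo
  r <- simulate_behavior(sev, truth0, n_go = 240, n_nogo = 240, seed = 1)
  expect_equal(sum(r$trials$type == "go"), 240L)
  expect_equal(sum(r$trials$type == "nogo"), 240L)
  expect_true(all(is.na(r$trials$rt_ms) == (r$trials$responded == 0L)))

  # planted effect at 100% severity raises the FA rate (paired seeds)
  truth1 <- ground_truth("1-2", fa_per_pct = 0.005,
                         noise_sd = c(rt_ms = 0, fa = 0, erp_uv = 0))
  sev1 <- sev; sev1["1-2"] <- 100
  fa0 <- mean(vapply(1:150, function(s)
    mean(simulate_behavior(sev, truth1, 30, 30, seed = s)$trials$responded[
      simulate_behavior(sev, truth1, 30, 30, seed = s)$trials$type == "nogo"]),
    numeric(1)))
  fa1 <- mean(vapply(1:150, function(s) {
    r <- simulate_behavior(sev1, truth1, 30, 30, seed = s)
    mean(r$trials$responded[r$trials$type == "nogo"])
  }, numeric(1)))
  expect_gt(fa1, fa0)
})

test_that("simulated epochs have the stated sample count and noise-free GFP structure", {
  truth0 <- ground_truth(noise_sd = c(rt_ms = 0, fa = 0, erp_uv = 0))
  sev <- setNames(numeric(1), "1-2")
  mon <- make_montage(16)
  ep <- simulate_epochs(sev, truth0, mon, n_trials = 2, srate_hz = 1024,
                        seed = 1)
  expect_identical(dim(ep$data)[3], 820L)   # floor(800 * 1.024) + 1
  # average-reference contract: topographies are zero-sum
  expect_lt(max(abs(apply(ep$data, c(1, 3), mean))), 1e-9)

  g <- gfp(average_epochs(ep))
  v <- g$values
  loc_max <- which(diff(sign(diff(v))) == -2) + 1L
  loc_max <- loc_max[v[loc_max] > 0.05 * max(v)]
  expect_length(loc_max, 2L)
  peaks <- g$times_ms[loc_max]
  expect_lt(abs(peaks[1] - 300), 15)
  expect_lt(abs(peaks[2] - 400), 15)

  # full attenuation: flat zero signal at zero noise
  truth_full <- ground_truth("1-2", erp_per_pct = 1,
                             noise_sd = c(rt_ms = 0, fa = 0, erp_uv = 0))
  sev1 <- setNames(100, "1-2")
  ep0 <- simulate_epochs(sev1, truth_full, mon, n_trials = 2,
                         srate_hz = 256, seed = 1)
  expect_equal(max(abs(ep0$data)), 0)
  expect_equal(attr(ep0, "attenuation_scale"), 0)
  expect_error(simulate_epochs(sev, truth0, mon, n_trials = 0, seed = 1),
               "n_trials")
})

test_that("make_study is reproducible and causally consistent", {
  cfg <- tiny_config(seed = 42L)
  s1 <- make_study(cfg)
  s2 <- make_study(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$behavior[[3]]$trials, s2$behavior[[3]]$trials)
  expect_identical(s1$epochs[[2]]$data, s2$epochs[[2]]$data)

  # severity matrix re-derivable from the saved lesions bit-identically
  idx <- assign_endpoints(s1$streamlines, s1$atlas$parcellation)
  m2 <- disconnection_matrix(s1$lesions, s1$streamlines, idx)
  expect_identical(unclass(s1$matrix), unclass(m2))

  # shape contract
  expect_identical(dim(s1$matrix), c(14L, 30L))
  expect_identical(length(s1$behavior), 14L)
})

test_that("a global-null study decouples symptoms from severities", {
  # with no true edges, severity-symptom correlations vanish at large n
  # cohort large enough that a 0.05 bound sits beyond 3.5 sampling SDs of
  # every one of the ~25 testable correlations simultaneously
  cfg <- study_config(grid_dims = c(32, 32, 32), n_parcels = 10L,
                      n_connections = 30L, streamlines_per_connection = 4L,
                      n_patients = 5000L, volume_pct_range = c(0.05, 1.72),
                      n_go = 30L, n_nogo = 30L, simulate_eeg = FALSE,
                      n_true_edges = 0L, seed = 77L)
  st <- make_study(cfg)
  beh <- score_cohort(st$behavior)
  keep <- apply(st$matrix, 2, sd) > 0
  cors <- cor(st$matrix[, keep, drop = FALSE], beh$performance_index)
  expect_lt(max(abs(cors)), 0.05)
})

test_that("planted effects follow the stated affine link at zero noise", {
  truth <- ground_truth("1-2", rt_ms_per_pct = 1.2, fa_per_pct = 0.004,
                        noise_sd = c(rt_ms = 0, fa = 0, erp_uv = 0))
  p <- behavior_params()
  for (sv in c(0, 25, 60)) {
    sev <- setNames(sv, "1-2")
    rts <- unlist(lapply(1:200, function(s) {
      r <- simulate_behavior(sev, truth, 60, 60, seed = 1000 + s)
      r$trials$rt_ms[r$trials$type == "go" & r$trials$responded == 1L]
    }))
    expected_rt <- p$rt_mu_ms + 1.2 * sv + p$rt_tau_ms
    expect_equal(mean(rts), expected_rt, tolerance = 0.01)
    fa <- mean(unlist(lapply(1:200, function(s) {
      r <- simulate_behavior(sev, truth, 60, 60, seed = 1000 + s)
      r$trials$responded[r$trials$type == "nogo"]
    })))
    expect_equal(fa, min(0.99, max(0.01, p$fa_baseline + 0.004 * sv)),
                 tolerance = 0.05)
  }
})
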