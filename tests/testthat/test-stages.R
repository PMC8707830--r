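test_that("profiles are replicate means and the full design gives 16", {
  sim <- quick_sim(seed = 1)
  prof <- timepoint_profiles(sim$matrix)
  expect_equal(nrow(prof$values), 16)
  expect_equal(prof$meta$n_replicates, rep(3L, 16))

  # hand-checkable mean
  vals <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 3,
                 dimnames = list(paste0("s", 1:3), c("m1", "m2")))
  smp <- data.frame(sample_id = paste0("s", 1:3), variety = "A",
                    timepoint_hai = 6, replicate = 1:3)
  m <- metabolome_matrix(vals, smp, data.frame(metabolite_id = c("m1", "m2")))
  p <- timepoint_profiles(m)
  expect_equal(unname(p$values["A@6", ]), c(2, 20))

  # identical replicates: profile equals any one replicate
  sim0 <- quick_sim(seed = 2, noise_cv = 0)
  p0 <- timepoint_profiles(sim0$matrix)
  one <- sim0$matrix$samples$replicate == 1
  expect_equal(unname(p0$values[paste0(sim0$matrix$samples$variety[one], "@",
                                       sim0$matrix$samples$timepoint_hai[one]), ]),
               unname(sim0$matrix$values[one, ]), tolerance = 1e-12)
})

test_that("profile correlations are symmetric with unit diagonal", {
  sim <- quick_sim(seed = 3)
  cm <- profile_correlation(timepoint_profiles(sim$matrix))
  m <- unclass(cm)
  expect_equal(diag(m), setNames(rep(1, 16), rownames(m)))
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))

  # centered negation correlates at -1
  x <- c(5, 1, 4, 2, 8)
  prof <- structure(list(values = rbind(a = x, b = 2 * mean(x) - x),
                         meta = tibble::tibble(profile_id = c("a", "b"),
                                               variety = c("A", "B"),
                                               timepoint_hai = c(0, 0),
                                               n_replicates = c(1L, 1L))),
                    class = "timepoint_profiles")
  cm2 <- profile_correlation(prof)
  expect_equal(unclass(cm2)["a", "b"], -1, tolerance = 1e-12)
})

test_that("a constant profile yields missing correlations with a warning", {
  prof <- structure(list(values = rbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                         meta = tibble::tibble(profile_id = c("a", "b"),
                                               variety = c("A", "B"),
                                               timepoint_hai = c(0, 0),
                                               n_replicates = c(1L, 1L))),
                    class = "timepoint_profiles")
  expect_warning(cm <- profile_correlation(prof), "constant profile")
  expect_true(is.na(unclass(cm)["a", "b"]))
  expect_equal(diag(unclass(cm)), c(a = 1, b = 1))
})

test_that("degenerate stage counts behave as contracted", {
  sim <- quick_sim(seed = 4)
  cm <- profile_correlation(timepoint_profiles(sim$matrix))
  tps <- c(0, 3, 6, 9, 12, 24, 36, 48)
  s1 <- segment_stages(cm, "fast", k = 1)
  expect_equal(s1$stages, list(tps))
  s8 <- segment_stages(cm, "fast", k = 8)
  expect_equal(s8$stages, as.list(tps))
  expect_error(segment_stages(cm, "fast", k = 0), "k must be")
  expect_error(segment_stages(cm, "fast", k = 9), "exceeds")
  expect_error(segment_stages(cm, "nope", k = 3), "not present")
})

test_that("planted plateau regimes are segmented at their boundaries", {
  cfg <- synthetic_config(n_metabolites = 150, n_associated = 30,
                          noise_cv = 0, stage_regimes = c(12, 36),
                          rng_seed = 6)
  cm <- profile_correlation(timepoint_profiles(generate_dataset(cfg)$matrix))
  seg <- segment_stages(cm, "fast", k = 3)
  expect_equal(seg$boundaries, c(12, 36))
  expect_equal(seg$stages[[1]], c(0, 3, 6, 9, 12))
  expect_equal(seg$stages[[3]], 48)
})

test_that("segmentations are nested across k", {
  sim <- quick_sim(seed = 7)
  cm <- profile_correlation(timepoint_profiles(sim$matrix))
  bounds <- lapply(1:8, function(k) segment_stages(cm, "slow", k)$boundaries)
  for (k in 2:8)
    expect_true(all(bounds[[k - 1]] %in% bounds[[k]]))
})

test_that("correlations are invariant under global positive affine maps", {
  sim <- quick_sim(seed = 8)
  mat <- sim$matrix
  cm0 <- unclass(profile_correlation(timepoint_profiles(mat)))
  mat2 <- metabolome_matrix(mat$values * 3.7 + 11, mat$samples,
                            mat$metabolites)
  cm2 <- unclass(profile_correlation(timepoint_profiles(mat2)))
  expect_equal(cm0, cm2, tolerance = 1e-9)
})

test_that("zero lag is recovered as zero at zero noise", {
  cfg <- synthetic_config(n_metabolites = 100, n_associated = 20,
                          lag_hours = 0, noise_cv = 0, rng_seed = 2)
  cm <- profile_correlation(timepoint_profiles(generate_dataset(cfg)$matrix))
  lag <- estimate_lag(cm, "fast", "slow")
  expect_equal(lag$per_timepoint$lag_hours, rep(0, 8))
  expect_equal(lag$median_lag, 0)
})

test_that("planted lags are recovered on the aligned grid at zero noise", {
  for (L in c(6, 12)) {
    cfg <- synthetic_config(n_metabolites = 150, n_associated = 30,
                            lag_hours = L, noise_cv = 0,
                            stage_regimes = c(12, 36), rng_seed = 3)
    cm <- profile_correlation(timepoint_profiles(generate_dataset(cfg)$matrix))
    lag <- estimate_lag(cm, "fast", "slow")
    tps <- c(0, 3, 6, 9, 12, 24, 36, 48)
    aligned <- tps[(tps - L) %in% tps]
    got <- lag$per_timepoint$lag_hours[lag$per_timepoint$timepoint_hai %in%
                                         aligned]
    expect_equal(median(got), L)
  }
})

test_that("per-stage median lags are reported when a segmentation is given", {
  sim <- quick_sim(seed = 9)
  cm <- profile_correlation(timepoint_profiles(sim$matrix))
  seg <- segment_stages(cm, "slow", k = 3)
  lag <- estimate_lag(cm, "fast", "slow", segmentation = seg)
  expect_length(lag$per_stage, 3)
})
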