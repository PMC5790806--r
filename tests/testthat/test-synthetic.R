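test_that("degenerate tie rates give empty and saturated networks", {
  cfg0 <- synth_config(n_subjects = 10, n_cohort = 15, tie_base_rate = 0,
                       seed = 1)
  nom0 <- simulate_network(cfg0)
  expect_true(all(nom0$entries == 0))

  cfg1 <- synth_config(n_subjects = 10, n_cohort = 15, tie_base_rate = 1,
                       demographic_assortativity = 0, seed = 1)
  nom1 <- simulate_network(cfg1)
  m <- nom1$entries
  expect_true(all(m[upper.tri(m) | lower.tri(m)] == 1))
  expect_equal(network_stats(nom1)$dyad_reciprocity, 1)
})

test_that("dyad-level reciprocity tracks the configured target", {
  recips <- vapply(1:20, function(s) {
    cfg <- synth_config(n_cohort = 80, seed = s)
    network_stats(simulate_network(cfg))$dyad_reciprocity
  }, numeric(1))
  expect_true(all(abs(recips - 0.309) < 0.1))
})

test_that("full assortativity restricts ties to same-gender pairs", {
  cfg <- synth_config(n_cohort = 50, demographic_assortativity = 1,
                      tie_base_rate = 0.3, seed = 4)
  demo <- simulate_demographics(cfg$n_cohort, split_seed(cfg$seed, "demo"))
  nom <- simulate_network(cfg, demo)
  tied <- which(nom$entries == 1, arr.ind = TRUE)
  expect_gt(nrow(tied), 0)
  expect_true(all(demo$gender[tied[, 1]] == demo$gender[tied[, 2]]))
})

test_that("demographics are complete and reproducible", {
  one <- simulate_demographics(1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))

  a <- simulate_demographics(30, seed = 9)
  b <- simulate_demographics(30, seed = 9)
  expect_identical(a, b)
})

test_that("identical configs give bit-identical studies", {
  s1 <- small_study(seed = 5)
  s2 <- small_study(seed = 5)
  expect_identical(s1$nominations$entries, s2$nominations$entries)
  expect_identical(s1$timeseries$series, s2$timeseries$series)
  expect_identical(s1$dyad_table, s2$dyad_table)
})

test_that("perfect coupling makes all subjects identical", {
  d <- matrix(2, 4, 4); diag(d) <- 0
  cfg <- synth_config(n_subjects = 4, n_cohort = 4, n_rois = 3,
                      n_timepoints = 50, trait_decay = 1, noise_sd = 0,
                      common_signal_sd = 0, missing_rate = 0, seed = 2)
  ts <- simulate_timeseries(d, cfg)
  for (i in 2:4) {
    expect_equal(ts$series[i, , ], ts$series[1, , ], tolerance = 1e-6)
  }
  sim <- dyadic_roi_correlations(ts)
  expect_true(all(abs(sim$raw - 1) < 1e-8))
})

test_that("with trait_decay = 1 the expected correlation is flat in distance", {
  d <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)
  cfg <- synth_config(n_subjects = 3, n_cohort = 3, n_rois = 2,
                      n_timepoints = 50, trait_decay = 1, seed = 2)
  ts <- simulate_timeseries(d, cfg)
  ec <- ts$ground_truth$expected_correlation_by_distance
  expect_true(all(abs(ec - ec[1]) < 1e-12))
  expect_equal(ts$ground_truth$true_distance_effect, 0)
})

test_that("the planted effect orders mean similarity by distance", {
  hits <- vapply(1:30, function(s) {
    st <- small_study(seed = 100 + s, n_subjects = 16, n_cohort = 60,
                      n_rois = 6, n_timepoints = 80)
    tab <- st$dyad_table
    if (!all(c(1, 3) %in% tab$distance)) return(NA)
    mean(tab$composite[tab$distance == 1]) >
      mean(tab$composite[tab$distance == 3])
  }, logical(1))
  hits <- hits[!is.na(hits)]
  expect_gt(length(hits), 20)
  expect_gt(mean(hits), 0.9)
})

test_that("missing ROIs are injected at the configured rate", {
  d <- matrix(1, 30, 30); diag(d) <- 0
  cfg <- synth_config(n_subjects = 30, n_cohort = 30, n_rois = 40,
                      n_timepoints = 10, missing_rate = 0.2, seed = 8)
  ts <- simulate_timeseries(d, cfg)
  rate <- mean(!ts$present_mask)
  expect_gt(rate, 0.12)
  expect_lt(rate, 0.28)
  knocked <- which(!ts$present_mask, arr.ind = TRUE)
  expect_true(all(is.na(ts$series[cbind(knocked, 1)])))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(tie_base_rate = 1.2), "tie_base_rate")
  expect_error(synth_config(trait_decay = 0), "trait_decay")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_timepoints = 3), "n_timepoints")
  expect_error(
    simulate_timeseries(matrix(NA_real_, 2, 2), synth_config()), "NA"
  )
})
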