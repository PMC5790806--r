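test_that("dyadic correlations reproduce closed-form Pearson values", {
  s <- array(0, c(2, 2, 4))
  s[1, 1, ] <- c(1, 2, 3, 4); s[2, 1, ] <- c(1, 2, 3, 5)
  s[1, 2, ] <- c(1, 2, 3, 4); s[2, 2, ] <- -c(1, 2, 3, 4)
  sim <- dyadic_roi_correlations(make_ts(s))
  expect_equal(unname(round(sim$raw[1, 1], 4)), 0.9827)
  expect_equal(unname(sim$raw[1, 2]), -1)

  s2 <- array(rnorm(2 * 1 * 10), c(2, 1, 10))
  s2[2, 1, ] <- s2[1, 1, ]
  sim2 <- dyadic_roi_correlations(make_ts(s2))
  expect_equal(unname(sim2$raw[1, 1]), 1)
})

test_that("zero-variance series become missing with a warning", {
  s <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  s[2, 1, ] <- 7 # constant
  expect_warning(sim <- dyadic_roi_correlations(make_ts(s)),
                 "zero-variance")
  expect_true(is.na(sim$raw[1, 1]))
  expect_false(is.na(sim$raw[1, 2]))
})

test_that("imputation fills column means and flags the cells", {
  set.seed(1)
  s <- array(rnorm(4 * 2 * 8), c(4, 2, 8))
  present <- matrix(TRUE, 4, 2)
  present[2, 1] <- FALSE # kills dyads (1,2), (2,3), (2,4) in ROI 1
  s[2, 1, ] <- NA
  sim <- dyadic_roi_correlations(make_ts(s, present))
  imp <- impute_missing(sim)
  miss <- is.na(sim$raw[, 1])
  expect_equal(sum(miss), 3)
  expect_equal(unique(imp$raw[miss, 1]),
               mean(sim$raw[!miss, 1]))
  expect_identical(imp$imputed_flags, is.na(sim$raw))

  ## no missing entries: identity
  sim_full <- dyadic_roi_correlations(make_ts(array(rnorm(48), c(3, 2, 8))))
  expect_identical(impute_missing(sim_full)$raw, sim_full$raw)
})

test_that("a fully missing ROI aborts with its name", {
  s <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  present <- matrix(TRUE, 3, 2)
  present[, 2] <- FALSE
  sim <- dyadic_roi_correlations(make_ts(s, present,
                                         roi_names = c("ok", "gone")))
  expect_error(impute_missing(sim), "gone")
})

test_that("per-ROI normalization gives mean 0, SD 1 columns", {
  set.seed(2)
  s <- array(rnorm(6 * 3 * 20), c(6, 3, 20))
  sim <- normalize_per_roi(impute_missing(dyadic_roi_correlations(make_ts(s))))
  expect_true(all(abs(colMeans(sim$z)) < 1e-12))
  expect_true(all(abs(apply(sim$z, 2, sd) - 1) < 1e-12))

  ## hand case: column (1,2,3) -> (-1, 0, 1) with sample SD, and two
  ## identical columns normalize identically
  fake <- sim
  fake$raw <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  fake$roi_names <- c("a", "b")
  fz <- normalize_per_roi(fake)$z
  expect_equal(unname(fz[, 1]), c(-1, 0, 1))
  expect_equal(fz[, 1], fz[, 2], ignore_attr = TRUE)

  ## zero-SD column is degenerate
  fake$raw <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2)
  expect_error(normalize_per_roi(fake), "zero-SD")
})

test_that("weighted composite follows the volume weights", {
  set.seed(3)
  s <- array(rnorm(4 * 2 * 15), c(4, 2, 15))
  sim <- normalize_per_roi(impute_missing(dyadic_roi_correlations(make_ts(s))))

  eq <- weighted_composite(sim, weighting = "equal")
  expect_equal(eq$composite, rowMeans(sim$z))

  w <- c(roi001 = 3, roi002 = 1)
  vw <- weighted_composite(sim, volumes = w)
  expect_equal(vw$composite, as.numeric(sim$z %*% c(3, 1)) / 4)

  ## hand case: z row (1, -1), volumes (3, 1) -> 0.5
  expect_equal(as.numeric(c(1, -1) %*% c(3, 1)) / 4, 0.5)

  w0 <- c(roi001 = 1, roi002 = 0)
  v0 <- weighted_composite(sim, volumes = w0)
  expect_equal(v0$composite, sim$z[, 1])

  expect_error(weighted_composite(sim, volumes = c(roi001 = -1,
                                                   roi002 = 1)),
               "negative")
})

test_that("dyad table has one canonical row per pair with controls", {
  st <- small_study(seed = 21, n_subjects = 6, n_cohort = 25, n_rois = 3,
                    n_timepoints = 40)
  tab <- st$dyad_table
  expect_equal(nrow(tab), choose(6, 2))
  expect_true(all(tab$id_i < tab$id_j))
  expect_true(all(tab$friend == (tab$distance == 1)))
  expect_true(all(paste0("z_", st$similarity$roi_names) %in% names(tab)))

  d2 <- st$demographics[st$fmri_subjects, ]
  d2$gender <- "F"; d2$ethnicity <- "e"; d2$nationality <- "n"
  d2$age <- 30; d2$handedness <- "R"
  tab2 <- build_dyad_table(st$similarity,
                           st$distances$capped_category[
                             st$fmri_subjects, st$fmri_subjects],
                           d2)
  expect_true(all(tab2$diff_gender == 0))
  expect_true(all(tab2$age_diff == 0))

  expect_error(
    build_dyad_table(st$similarity,
                     st$distances$capped_category[1:3, 1:3],
                     st$demographics),
    "absent"
  )
})

test_that("similarities are invariant to subject relabeling", {
  set.seed(4)
  s <- array(rnorm(5 * 3 * 25), c(5, 3, 25))
  ids <- sprintf("S%03d", 1:5)
  ts1 <- make_ts(s, ids = ids)
  perm <- c(3, 1, 5, 2, 4)
  ts2 <- make_ts(s[perm, , ], ids = ids[perm])
  r1 <- dyadic_roi_correlations(ts1)
  r2 <- dyadic_roi_correlations(ts2)
  key1 <- paste(r1$dyads$id_i, r1$dyads$id_j)
  key2 <- paste(pmin(r2$dyads$id_i, r2$dyads$id_j),
                pmax(r2$dyads$id_i, r2$dyads$id_j))
  expect_setequal(key1, key2)
  m <- match(key1, key2)
  expect_equal(r1$raw, r2$raw[m, ], ignore_attr = TRUE)
})
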