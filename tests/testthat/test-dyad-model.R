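## A reusable simulated ordinal dataset with a known planted effect.
make_ord_data <- function(n = 500, beta = -0.5, tau = c(-1.5, 0.5, 2),
                          seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  data.frame(
    y = sim_ordered(cbind(x, z), c(beta, 0.3), tau),
    x = x, z = z,
    id_i = sample(letters[1:12], n, replace = TRUE),
    id_j = sample(LETTERS[1:12], n, replace = TRUE)
  )
}

test_that("ordered fit matches an independent proportional-odds solver", {
  skip_if_not_installed("MASS")
  d <- make_ord_data(n = 600, seed = 2)
  fit <- dyad_model(y ~ x + z, d, family = "ordered", standardize = FALSE)
  ref <- MASS::polr(ordered(y) ~ x + z, d)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$tau), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("two-category ordered fit equals the binary logistic fit", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x)) + 1 # categories 1, 2
  d <- data.frame(y = y, x = x)
  ord <- dyad_model(y ~ x, d, family = "ordered", standardize = FALSE)
  d$lowcat <- as.integer(d$y == 1)
  bin <- dyad_model(lowcat ~ x, d, family = "binary",
                    standardize = FALSE)
  ## P(Y = 1) = plogis(tau_1 - x beta): slope of 'lowcat' is -beta
  expect_equal(unname(ord$beta["x"]), -unname(bin$beta["x"]),
               tolerance = 1e-6)
  expect_equal(unname(ord$tau[1]), unname(bin$beta["(Intercept)"]),
               tolerance = 1e-6)
})

test_that("planted ordinal effects are recovered", {
  est <- vapply(1:25, function(s) {
    d <- make_ord_data(n = 861, beta = -0.5, seed = 100 + s)
    dyad_model(y ~ x + z, d, family = "ordered",
               standardize = FALSE)$beta[["x"]]
  }, numeric(1))
  expect_true(all(est < 0))
  expect_lt(abs(mean(est) + 0.5), 3 * sd(est) / sqrt(length(est)) + 0.02)
})

test_that("binary recovery and degenerate predictors behave", {
  est <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-1 + 0.4 * x))
    dyad_model(y ~ x, data.frame(x = x, y = y), family = "binary",
               standardize = FALSE)$beta[["x"]]
  }, numeric(1))
  expect_true(all(abs(est - 0.4) < 0.1))

  set.seed(9)
  d0 <- data.frame(y = rbinom(80, 1, 0.3), x = 0)
  expect_warning(
    fit0 <- dyad_model(y ~ x, d0, family = "binary",
                       standardize = FALSE),
    "aliased"
  )
  expect_equal(unname(fit0$beta["x"]), 0)
  expect_equal(unname(fit0$beta["(Intercept)"]),
               qlogis(mean(d0$y)), tolerance = 1e-6)
})

test_that("perfect separation is flagged as a failure", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = rep(c(-1, 1), each = 20))
  expect_error(
    dyad_model(y ~ x, d, family = "binary", standardize = FALSE),
    "separation|converge"
  )
})

test_that("standardization rescales coefficients exactly", {
  d <- make_ord_data(n = 400, seed = 5)
  d$x <- d$x * 3 + 1
  raw <- dyad_model(y ~ x + z, d, family = "ordered",
                    standardize = FALSE)
  std <- dyad_model(y ~ x + z, d, family = "ordered", standardize = TRUE)
  expect_equal(unname(std$beta["x"]),
               unname(raw$beta["x"]) * sd(d$x), tolerance = 1e-6)
})

test_that("clustered vcov reduces to the robust sandwich for singletons", {
  d <- make_ord_data(n = 120, seed = 6)
  fit <- dyad_model(y ~ x + z, d, family = "ordered",
                    standardize = FALSE)
  ids <- as.character(seq_len(fit$n))
  V <- twoway_cluster_vcov(fit, ids, ids)
  hc0 <- fit$bread %*% crossprod(fit$scores) %*% fit$bread
  expect_equal(V, hc0, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("two-way clustered vcov matches an independent implementation", {
  skip_if_not_installed("sandwich")
  set.seed(7)
  n <- 90
  d <- data.frame(
    x = rnorm(n), w = rnorm(n),
    g1 = sample(letters[1:6], n, replace = TRUE),
    g2 = sample(LETTERS[1:5], n, replace = TRUE)
  )
  d$y <- 1 + 0.5 * d$x - 0.2 * d$w + rnorm(n)
  fit <- lm(y ~ x + w, d)
  V <- twoway_cluster_vcov(fit, d$g1, d$g2)
  Vref <- sandwich::vcovCL(fit, cluster = ~ g1 + g2, data = d,
                           type = "HC0", cadjust = FALSE, multi0 = FALSE,
                           fix = TRUE)
  expect_equal(V, Vref, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("duplicating dyads leaves beta and clustered SEs unchanged", {
  d <- make_ord_data(n = 200, seed = 8)
  cl <- ~ id_i + id_j
  fit1 <- dyad_model(y ~ x + z, d, family = "ordered", cluster = cl,
                     standardize = FALSE)
  d2 <- rbind(d, d)
  fit2 <- dyad_model(y ~ x + z, d2, family = "ordered", cluster = cl,
                     standardize = FALSE)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-5)
  ## clustered SEs are invariant under exact duplication ...
  expect_equal(fit1$se, fit2$se, tolerance = 1e-3)
  ## ... while naive SEs shrink by sqrt(2)
  naive1 <- sqrt(diag(fit1$vcov_naive))
  naive2 <- sqrt(diag(fit2$vcov_naive))
  expect_equal(unname(naive2 / naive1), rep(1 / sqrt(2), length(naive1)),
               tolerance = 1e-3)
})

test_that("likelihood-ratio tests behave on identical and nested models", {
  d <- make_ord_data(n = 400, beta = -0.8, seed = 10)
  full <- dyad_model(y ~ x + z, d, family = "ordered",
                     standardize = FALSE)
  same <- dyad_model(y ~ x + z, d, family = "ordered",
                     standardize = FALSE)
  res0 <- lr_test(full, same)
  expect_equal(res0$chi2, 0, tolerance = 1e-6)
  expect_equal(res0$p, 1)

  red <- dyad_model(y ~ z, d, family = "ordered", standardize = FALSE)
  res <- lr_test(full, red)
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.001) # strong planted effect

  other <- make_ord_data(n = 399, seed = 11)
  redo <- dyad_model(y ~ z, other, family = "ordered",
                     standardize = FALSE)
  expect_error(lr_test(full, redo), "share data")
})

test_that("per-ROI regressions share the FDR family and degenerate cases", {
  st <- small_study(seed = 31, n_subjects = 14, n_cohort = 50,
                    n_rois = 4, n_timepoints = 60)
  tab <- st$dyad_table
  fdr <- per_roi_regressions(tab)
  expect_equal(nrow(fdr), 4)
  expect_true(all(fdr$converged))
  expect_true(all(fdr$p_fdr >= fdr$p - 1e-12))
  ## BH monotone in raw-p order
  o <- order(fdr$p)
  expect_true(all(diff(fdr$p_fdr[o]) >= -1e-12))

  ## identical columns give identical estimates; single ROI: adjusted = raw
  tab2 <- tab
  for (rn in paste0("z_", st$similarity$roi_names)) {
    tab2[[rn]] <- tab$z_roi001
  }
  fdr2 <- per_roi_regressions(tab2)
  expect_true(all(abs(fdr2$beta - fdr2$beta[1]) < 1e-6))
  fdr1 <- per_roi_regressions(tab, rois = "roi001")
  expect_equal(fdr1$p_fdr, fdr1$p)
})

test_that("odds interpretation matches the reporting convention", {
  expect_equal(odds_interpretation(0.388), 47)
  expect_equal(odds_interpretation(0), 0)
  expect_equal(odds_interpretation(log(2)), 100)
})

test_that("deviation coding contrasts each category against the rest", {
  ## two categories with adjusted means +1 / -1 -> estimates +2 / -2
  d <- data.frame(
    composite = rep(c(1, -1), each = 20),
    distance = rep(c(1, 2), each = 20),
    id_i = rep(letters[1:10], 4), id_j = rep(LETTERS[1:10], each = 4)
  )
  est <- deviation_coded_estimates(d, controls = character(0))
  expect_equal(est$estimate, c(2, -2), tolerance = 1e-10)

  ## constant similarity -> all contrasts zero
  d$composite <- 0.7
  est0 <- deviation_coded_estimates(d, controls = character(0))
  expect_equal(est0$estimate, c(0, 0), tolerance = 1e-12)

  ## a control balanced within categories leaves estimates unchanged
  set.seed(12)
  d2 <- data.frame(
    composite = rnorm(40) + rep(c(0.5, 0, -0.25, 0.1), each = 10),
    distance = rep(1:4, each = 10),
    ctrl = rep(c(-1, 1), 20),
    id_i = sample(letters[1:8], 40, replace = TRUE),
    id_j = sample(LETTERS[1:8], 40, replace = TRUE)
  )
  base <- deviation_coded_estimates(d2, controls = character(0))
  with_ctrl <- deviation_coded_estimates(d2, controls = "ctrl")
  expect_equal(base$estimate, with_ctrl$estimate, tolerance = 1e-10)

  d2$distance[d2$distance == 4] <- 3
  d3 <- d2
  d3$distance <- factor(d3$distance, levels = 1:4)
  expect_error(deviation_coded_estimates(d3, controls = character(0)),
               "empty")
})

test_that("model methods are coherent", {
  d <- make_ord_data(n = 300, seed = 13)
  fit <- dyad_model(y ~ x + z, d, family = "ordered",
                    cluster = ~ id_i + id_j, standardize = FALSE)
  pr <- predict(fit, type = "probs")
  expect_equal(rowSums(pr), rep(1, nrow(d)), tolerance = 1e-12)
  expect_equal(nrow(summary(fit)$coefficients), 2)
  expect_equal(unname(coef(fit)), unname(fit$beta))
  expect_equal(dim(vcov(fit)), c(5, 5)) # 3 thresholds + 2 slopes
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(300, 3))
  expect_true(all(unlist(sims) %in% 1:4))
  sims2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sims, sims2)
})
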