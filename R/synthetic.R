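#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic cohort: the size of the survey
#' cohort and of the scanned subsample, the dimensions of the ROI time
#' series, and the parameters that control network structure and the
#' planted association between social distance and neural similarity.
#'
#' The planted effect works through latent interpretation components:
#' subject loadings on each of `n_components` components are drawn with
#' pairwise correlation `trait_decay^d(i,j)`, where `d` is geodesic
#' distance on the reciprocal-tie graph (capped at `distance_cap`). With
#' `trait_decay < 1` the expected inter-subject time series correlation is
#' strictly decreasing in social distance; `trait_decay = 1` gives a null
#' model in which similarity carries no distance information.
#'
#' @param n_subjects scanned subsample size (dyad table rows are
#'   `choose(n_subjects, 2)`).
#' @param n_cohort full survey cohort size.
#' @param n_rois number of ROIs per subject.
#' @param n_timepoints length of each concatenated ROI time series.
#' @param n_components number of latent interpretation components.
#' @param trait_decay dyadic loading correlation per unit geodesic
#'   distance, in (0, 1].
#' @param noise_sd standard deviation of idiosyncratic noise.
#' @param common_signal_sd standard deviation of the stimulus-locked
#'   signal shared by all subjects (drives the baseline inter-subject
#'   correlation common to every dyad).
#' @param tie_base_rate baseline probability that a dyad shares at least
#'   one (possibly unreciprocated) nomination.
#' @param reciprocity_target dyad-level reciprocity the network generator
#'   aims for: probability that a tied dyad is mutual.
#' @param demographic_assortativity in `[0, 1]`; 0 ignores demographics,
#'   1 restricts ties to same-gender pairs.
#' @param missing_rate per (subject, ROI) probability of a missing series.
#' @param distance_cap distances at or above this value (and unreachable
#'   pairs) collapse into the top category.
#' @param seed master seed; all stages derive their own streams from it
#'   via [split_seed()].
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 42, n_cohort = 279, n_rois = 80,
                         n_timepoints = 1000, n_components = 5,
                         trait_decay = 0.5, noise_sd = 1,
                         common_signal_sd = 0.5, tie_base_rate = 0.146,
                         reciprocity_target = 0.309,
                         demographic_assortativity = 0.3,
                         missing_rate = 0.009, distance_cap = 4,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_cohort = as.integer(n_cohort),
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    n_components = as.integer(n_components), trait_decay = trait_decay,
    noise_sd = noise_sd, common_signal_sd = common_signal_sd,
    tie_base_rate = tie_base_rate, reciprocity_target = reciprocity_target,
    demographic_assortativity = demographic_assortativity,
    missing_rate = missing_rate, distance_cap = as.integer(distance_cap),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_cohort < 2 || n_subjects < 2 || n_subjects > n_cohort) {
      stop("need 2 <= n_subjects <= n_cohort", call. = FALSE)
    }
    if (n_timepoints <= 3) stop("n_timepoints must exceed 3", call. = FALSE)
    if (n_rois < 1 || n_components < 1) {
      stop("n_rois and n_components must be >= 1", call. = FALSE)
    }
    if (trait_decay <= 0 || trait_decay > 1) {
      stop("trait_decay must lie in (0, 1]", call. = FALSE)
    }
    if (noise_sd < 0 || common_signal_sd < 0) {
      stop("standard deviations must be non-negative", call. = FALSE)
    }
    for (nm in c("tie_base_rate", "reciprocity_target",
                 "demographic_assortativity")) {
      v <- cfg[[nm]]
      if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
    if (missing_rate < 0 || missing_rate >= 1) {
      stop("missing_rate must lie in [0, 1)", call. = FALSE)
    }
  })
  structure(cfg, class = "synth_config")
}

#' Simulate subject demographics
#'
#' Draws gender, ethnicity, nationality (categorical), age in years, and
#' handedness for `n` subjects. Marginals are stylized after a graduate
#' cohort: two genders, four ethnicity levels, five nationality levels,
#' ages uniform on 25-32, about 90% right-handed.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param ids optional subject identifiers (default `S001`, ...).
#' @return a data.frame with one row per subject.
#' @export
simulate_demographics <- function(n, seed = 1L, ids = NULL) {
  stopifnot(n >= 1)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  data.frame(
    subject_id = ids,
    gender = sample(c("F", "M"), n, replace = TRUE),
    ethnicity = sample(paste0("eth", 1:4), n, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)),
    nationality = sample(paste0("nat", 1:5), n, replace = TRUE,
                         prob = c(0.45, 0.25, 0.15, 0.1, 0.05)),
    age = sample(25:32, n, replace = TRUE),
    handedness = sample(c("R", "L"), n, replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a friendship nomination network
#'
#' Generates a directed binary who-named-whom matrix over the cohort.
#' Each unordered pair first receives an any-tie probability: the base
#' rate modulated by demographic homophily (same gender gates the tie at
#' full assortativity; shared ethnicity or nationality give a milder
#' boost). Tied dyads are then mutual with probability
#' `max(reciprocity_target, p_any)`, otherwise a single direction is
#' chosen at random, so that dyad-level reciprocity tracks the configured
#' target in the sparse regime while a saturated graph (`tie_base_rate =
#' 1`) is fully mutual.
#'
#' @param config a [synth_config()].
#' @param demographics optional data.frame from [simulate_demographics()];
#'   generated internally when omitted.
#' @return a `nomination_matrix` (see [nomination_matrix()]).
#' @export
simulate_network <- function(config, demographics = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cohort
  if (is.null(demographics)) {
    demographics <- simulate_demographics(n, split_seed(config$seed, "demo"))
  }
  stopifnot(nrow(demographics) == n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, "network"))
  a <- config$demographic_assortativity
  same_g <- outer(demographics$gender, demographics$gender, "==")
  same_e <- outer(demographics$ethnicity, demographics$ethnicity, "==")
  same_n <- outer(demographics$nationality, demographics$nationality, "==")
  p_any <- config$tie_base_rate *
    ((1 - a) + a * same_g) *
    (1 + 0.3 * a * (same_e + same_n) / 2)
  p_any <- pmin(p_any, 1)
  m <- matrix(0L, n, n)
  ut <- upper.tri(m)
  tied <- runif(sum(ut)) < p_any[ut]
  p_mut <- pmax(config$reciprocity_target, p_any[ut])
  mutual <- tied & (runif(sum(ut)) < p_mut)
  fwd <- runif(sum(ut)) < 0.5 # direction of single ties
  up <- mutual | (tied & !mutual & fwd)
  dn <- mutual | (tied & !mutual & !fwd)
  m[ut] <- as.integer(up)
  m <- t(m)
  m[ut] <- as.integer(dn)
  m <- t(m)
  nomination_matrix(m, demographics$subject_id)
}

#' Simulate multi-subject ROI time series with a planted distance effect
#'
#' Each subject's ROI series follows
#' \deqn{x_{ir}(t) = c_r(t) + \sum_k w_{ik} f_{kr}(t) + \sigma
#'   \epsilon_{irt},}
#' where `c_r` is a stimulus-locked signal common to all subjects, `f_kr`
#' are component time courses shared across subjects, and the subject
#' loadings `w_{.k}` for each component are drawn from a multivariate
#' normal whose correlation matrix is `trait_decay^d(i,j)` (distances
#' capped at `distance_cap`, unreachable pairs treated as the cap),
#' repaired to the nearest positive-semidefinite matrix by eigenvalue
#' clipping and re-scaled to unit diagonal. Missing (subject, ROI) series
#' are knocked out i.i.d. at `missing_rate` and set to `NA`.
#'
#' @param distances numeric matrix of pairwise geodesic distances for the
#'   scanned subjects (finite after capping; `Inf` allowed and capped).
#' @param config a [synth_config()].
#' @param subject_ids optional identifiers, defaults to rownames of
#'   `distances` or `S001`, ...
#' @return a list with elements
#'   \describe{
#'     \item{series}{array `[n_subjects, n_rois, n_timepoints]`}
#'     \item{present_mask}{logical matrix `[n_subjects, n_rois]`}
#'     \item{roi_names, volumes, subject_ids}{labels and per-ROI mean
#'       volumes (mm^3)}
#'     \item{ground_truth}{subject loadings, component time courses, the
#'       expected raw inter-subject correlation at each capped distance,
#'       and `true_distance_effect`, the expected correlation drop from
#'       distance 1 to the cap}
#'   }
#' @export
simulate_timeseries <- function(distances, config, subject_ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  d <- as.matrix(distances)
  n <- nrow(d)
  stopifnot(ncol(d) == n, n >= 2)
  if (any(is.na(d))) stop("distances must not contain NA", call. = FALSE)
  d <- pmin(d, config$distance_cap) # Inf collapses into the cap
  diag(d) <- 0
  if (any(!is.finite(d))) stop("non-finite distances survived capping",
                               call. = FALSE)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(distances) %||% sprintf("S%03d", seq_len(n))
  }
  R <- config$n_rois
  Tt <- config$n_timepoints
  K <- config$n_components

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, "timeseries"))

  ## Loading correlation: rho^d, PSD-repaired, unit diagonal.
  C <- config$trait_decay^d
  C <- psd_clip(C)
  dg <- diag(C)
  if (any(dg <= 0)) stop("degenerate loading correlation", call. = FALSE)
  C <- C / sqrt(outer(dg, dg))
  e <- eigen(C, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)

  W <- L %*% matrix(rnorm(n * K), n, K) # subject loadings, cor ~ C
  Fk <- array(rnorm(K * R * Tt), c(K, R, Tt)) # component time courses
  common <- matrix(rnorm(R * Tt, sd = config$common_signal_sd), R, Tt)

  series <- array(NA_real_, c(n, R, Tt))
  Fmat <- matrix(Fk, K, R * Tt)
  for (i in seq_len(n)) {
    sig <- matrix(W[i, ] %*% Fmat, R, Tt)
    series[i, , ] <- common + sig +
      matrix(rnorm(R * Tt, sd = config$noise_sd), R, Tt)
  }
  present <- matrix(runif(n * R) >= config$missing_rate, n, R)
  for (i in seq_len(n)) for (r in seq_len(R)) {
    if (!present[i, r]) series[i, r, ] <- NA_real_
  }

  roi_names <- if (R == 80) roi_labels() else sprintf("roi%03d", seq_len(R))
  volumes <- exp(rnorm(R, mean = log(6000), sd = 0.6)) # mm^3, lognormal
  names(volumes) <- roi_names

  dd <- seq_len(config$distance_cap)
  tot_var <- config$common_signal_sd^2 + K + config$noise_sd^2
  exp_cor <- (config$common_signal_sd^2 + K * config$trait_decay^dd) / tot_var
  gt <- list(
    subject_loadings = W,
    component_timecourses = Fk,
    expected_correlation_by_distance = stats::setNames(
      exp_cor, paste0("d", dd)
    ),
    true_distance_effect = exp_cor[1] - exp_cor[config$distance_cap]
  )
  list(
    series = series, present_mask = present, roi_names = roi_names,
    volumes = volumes, subject_ids = subject_ids, ground_truth = gt
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining the generator stages: cohort demographics
#' and nomination network, reciprocal-tie graph and geodesic distances on
#' the full cohort, selection of the scanned subsample, ROI time series
#' with the planted distance effect, and the assembled dyad table.
#'
#' @param config a [synth_config()].
#' @return a list with `config`, `demographics`, `nominations`, `graph`,
#'   `distances` (full cohort), `fmri_subjects` (indices into the cohort),
#'   `timeseries`, `similarity` (z-scored, imputed), and `dyad_table`.
#' @export
simulate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  demo <- simulate_demographics(config$n_cohort,
                                split_seed(config$seed, "demo"))
  nom <- simulate_network(config, demo)
  g <- build_graph(nom, tie_rule = "reciprocal")
  dist_full <- geodesic_distances(g, cap = config$distance_cap)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, "subsample"))
  sub <- sort(sample(config$n_cohort, config$n_subjects))

  dsub <- dist_full$distances[sub, sub, drop = FALSE]
  rownames(dsub) <- colnames(dsub) <- demo$subject_id[sub]
  ts <- simulate_timeseries(dsub, config,
                            subject_ids = demo$subject_id[sub])
  sim <- dyadic_roi_correlations(ts)
  sim <- impute_missing(sim)
  sim <- normalize_per_roi(sim)
  sim <- weighted_composite(sim, ts$volumes)
  dyads <- build_dyad_table(
    sim,
    distances = dist_full$capped_category[sub, sub, drop = FALSE],
    demographics = demo[sub, , drop = FALSE]
  )
  list(
    config = config, demographics = demo, nominations = nom, graph = g,
    distances = dist_full, fmri_subjects = sub, timeseries = ts,
    similarity = sim, dyad_table = dyads
  )
}

## Save/restore the global RNG state so seeded generators do not perturb
## the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
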