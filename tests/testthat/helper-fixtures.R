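## Shared fixtures, all generated in code.

## Tiny ROI time series set with fully controllable values.
make_ts <- function(series, present = NULL, roi_names = NULL,
                    volumes = NULL, ids = NULL) {
  n <- dim(series)[1]
  R <- dim(series)[2]
  list(
    series = series,
    present_mask = present %||% matrix(TRUE, n, R),
    roi_names = roi_names %||% sprintf("roi%03d", seq_len(R)),
    subject_ids = ids %||% sprintf("S%03d", seq_len(n)),
    volumes = volumes
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Nomination matrix from a directed edge list over LETTERS ids.
nom_from_edges <- function(edges, ids) {
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) m[e[1], e[2]] <- 1L
  nomination_matrix(m, ids)
}

## Draw ordinal responses from the proportional-odds model
## logit P(Y <= k) = tau_k - x'beta.
sim_ordered <- function(x, beta, tau) {
  eta <- drop(as.matrix(x) %*% beta)
  K <- length(tau) + 1
  cum <- stats::plogis(outer(tau, eta, "-")) # (K-1) x n
  u <- runif(length(eta))
  1L + colSums(outer(rep(1, K - 1), u) > cum)
}

## Small synthetic study used across tests (kept cheap).
small_study <- function(seed = 11, n_subjects = 20, n_cohort = 70,
                        n_rois = 8, n_timepoints = 100, ...) {
  simulate_study(synth_config(
    n_subjects = n_subjects, n_cohort = n_cohort, n_rois = n_rois,
    n_timepoints = n_timepoints, seed = seed, ...
  ))
}
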