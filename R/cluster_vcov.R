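#' Two-way cluster-robust covariance matrix
#'
#' Sandwich covariance for models whose observations are clustered along
#' two overlapping dimensions — in dyadic data, the two members of each
#' pair. Following the multi-way clustering decomposition,
#' \deqn{V = V_{1} + V_{2} - V_{1 \cap 2},}
#' where each component is a one-way clustered sandwich
#' \eqn{B\,(\sum_g s_g s_g^\top)\,B} with cluster score sums `s_g` and
#' inverse observed information (or `(X'X)^{-1}` for least squares) as
#' the bread `B`. The intersection clusters are the observation-level
#' pairs of ids — for dyads, the dyads themselves. Any negative
#' eigenvalues of the assembled matrix are clipped to zero.
#'
#' @param model a fitted [dyad_model()], or an [stats::lm()] fit.
#' @param id1,id2 cluster ids for the two dimensions, one entry per
#'   observation (for a dyad table, the two subject id columns).
#' @param adjust apply a `G/(G - 1)` finite-sample multiplier to each
#'   component, with `G` that component's number of clusters (default
#'   `FALSE`).
#' @return covariance matrix for the model parameters.
#' @export
twoway_cluster_vcov <- function(model, id1, id2, adjust = FALSE) {
  UseMethod("twoway_cluster_vcov")
}

#' @export
twoway_cluster_vcov.dyad_model <- function(model, id1, id2,
                                           adjust = FALSE) {
  .twoway_sandwich(model$scores, model$bread, id1, id2, adjust)
}

#' @export
twoway_cluster_vcov.lm <- function(model, id1, id2, adjust = FALSE) {
  X <- stats::model.matrix(model)
  S <- stats::residuals(model) * X
  bread <- solve(crossprod(X))
  .twoway_sandwich(S, bread, id1, id2, adjust)
}

.twoway_sandwich <- function(S, bread, id1, id2, adjust = FALSE) {
  n <- nrow(S)
  id1 <- as.character(id1)
  id2 <- as.character(id2)
  if (length(id1) != n || length(id2) != n) {
    stop("cluster id vectors must have one entry per observation",
         call. = FALSE)
  }
  meat <- function(ids) {
    sg <- rowsum(S, ids, reorder = FALSE)
    M <- crossprod(sg)
    if (adjust) {
      G <- nrow(sg)
      if (G > 1) M <- M * G / (G - 1)
    }
    M
  }
  inter <- paste(id1, id2, sep = "\r")
  V <- bread %*% (meat(id1) + meat(id2) - meat(inter)) %*% bread
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (any(e$values < 0)) {
    V <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    V <- (V + t(V)) / 2
    dimnames(V) <- dimnames(bread)
  }
  V
}

#' Per-ROI dyadic regressions with FDR correction
#'
#' Fits one ordered logistic regression per ROI — that ROI's normalized
#' similarity plus the demographic controls predicting the capped social
#' distance — with two-way cluster-robust standard errors, then applies
#' Benjamini-Hochberg step-up correction across the family of ROIs that
#' converged. Non-converging ROIs are recorded and excluded from the FDR
#' family with a warning.
#'
#' @param table a [build_dyad_table()] result.
#' @param rois ROI names (default: all `z_` columns of the table).
#' @param controls control column names (default [dyad_controls()]).
#' @param cluster as in [dyad_model()] (default: the dyad member ids).
#' @param standardize standardize predictors (default `TRUE`).
#' @return a data.frame of class `fdr_table`: `roi`, `beta`, `se`, `p`,
#'   `p_fdr`, `converged`, sorted as supplied.
#' @export
per_roi_regressions <- function(table, rois = NULL, controls = dyad_controls(),
                                cluster = ~ id_i + id_j,
                                standardize = TRUE) {
  stopifnot(is.data.frame(table))
  if (is.null(rois)) {
    rois <- sub("^z_", "", grep("^z_", names(table), value = TRUE))
  }
  cols <- paste0("z_", rois)
  stopifnot(all(cols %in% names(table)))
  out <- data.frame(
    roi = rois, beta = NA_real_, se = NA_real_, p = NA_real_,
    p_fdr = NA_real_, converged = FALSE, stringsAsFactors = FALSE
  )
  for (k in seq_along(rois)) {
    fo <- stats::reformulate(c(cols[k], controls), response = "distance")
    fit <- tryCatch(
      dyad_model(fo, table, family = "ordered", cluster = cluster,
                 standardize = standardize),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      out$beta[k] <- fit$beta[[cols[k]]]
      out$se[k] <- fit$se[[cols[k]]]
      out$p[k] <- fit$p[[cols[k]]]
      out$converged[k] <- TRUE
    }
  }
  if (any(!out$converged)) {
    warning(sum(!out$converged),
            " ROI regression(s) failed to converge; excluded from the ",
            "FDR family", call. = FALSE)
  }
  ok <- out$converged
  out$p_fdr[ok] <- bh_adjust(out$p[ok])
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The FDR adjustment applied across the per-ROI regression family:
#' adjusted `p_(i) = min_{j >= i} min(1, m p_(j) / j)` over the sorted
#' raw p-values. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Deviation-coded social-distance contrasts on composite similarity
#'
#' For each social-distance category, estimates the difference between
#' that category's control-adjusted mean composite similarity and the
#' average of the other categories' adjusted means, with 95% confidence
#' intervals from the two-way cluster-robust covariance. Implemented as a
#' linear model with sum-to-zero category contrasts plus the controls;
#' the contrast for category `k` is `K/(K-1)` times its sum-coded
#' coefficient.
#'
#' @param table a [build_dyad_table()] result.
#' @param response column holding the similarity outcome
#'   (default `"composite"`).
#' @param category column holding the distance category
#'   (default `"distance"`).
#' @param controls control columns (default [dyad_controls()]); use
#'   `character(0)` for none.
#' @param cluster two-column cluster ids (default the dyad member ids).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `category`, `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
deviation_coded_estimates <- function(table, response = "composite",
                                      category = "distance",
                                      controls = dyad_controls(),
                                      cluster = c("id_i", "id_j"),
                                      conf_level = 0.95) {
  stopifnot(is.data.frame(table))
  f <- table[[category]]
  f <- if (is.factor(f)) f else factor(f) # declared levels are kept
  K <- nlevels(f)
  if (K < 2) stop("need at least 2 categories", call. = FALSE)
  if (any(tabulate(f, K) == 0)) stop("empty category", call. = FALSE)
  dat <- table
  dat$.cat <- f
  fo <- stats::reformulate(c(".cat", controls), response = response)
  fit <- stats::lm(fo, dat, contrasts = list(.cat = "contr.sum"))
  cl <- .resolve_cluster(cluster, table, nrow(table))
  V <- twoway_cluster_vcov(fit, cl[[1]], cl[[2]])
  b <- stats::coef(fit)
  cat_idx <- grep("^\\.cat", names(b))
  stopifnot(length(cat_idx) == K - 1)
  ## L maps coefficients to per-category sum-coded effects, scaled by
  ## K/(K-1) to express "this category vs mean of the others"
  L <- matrix(0, K, length(b))
  for (k in seq_len(K - 1)) L[k, cat_idx[k]] <- 1
  L[K, cat_idx] <- -1
  L <- L * K / (K - 1)
  est <- drop(L %*% b)
  se <- sqrt(diag(L %*% V %*% t(L)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    category = levels(f), estimate = est, se = se,
    ci_lo = est - zq * se, ci_hi = est + zq * se,
    stringsAsFactors = FALSE
  )
}
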