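#' Dyad-level ordered or binary logistic regression
#'
#' Fits the dyad-level models relating social distance to neural
#' similarity. The ordered (proportional-odds) model uses the
#' parameterization
#' \deqn{\mathrm{logit}\, P(Y \le k \mid x) = \tau_k - x^\top\beta,}
#' so a negative coefficient on a similarity predictor means that more
#' similar dyads sit at shorter social distances. The binary model is an
#' ordinary logistic regression of an indicator (by convention,
#' reciprocated friendship: distance category 1).
#'
#' Because each subject appears in many dyads, observations are not
#' independent. Standard errors are therefore made cluster-robust by
#' clustering simultaneously on both members of each dyad (two-way
#' clustering, see [twoway_cluster_vcov()]) when `cluster` is supplied.
#'
#' Estimation of the ordered model is by maximum likelihood with an
#' analytic gradient (BFGS, thresholds parameterized through
#' log-differences to stay ordered; started from cumulative category
#' frequencies and zero slopes). The binary model is fit with
#' [stats::glm()]. Either way the object carries per-observation score
#' contributions and the observed-information bread needed for the
#' sandwich.
#'
#' @param formula model formula, e.g.
#'   `distance ~ composite + diff_gender + age_diff`. For the ordered
#'   family the response must have at least 2 occupied integer/ordered
#'   categories; for the binary family it must be 0/1 or logical.
#' @param data a data.frame, typically a [build_dyad_table()] result.
#' @param family `"ordered"` or `"binary"`.
#' @param cluster two-column object naming the two clustering dimensions
#'   per observation, usually `data[, c("id_i", "id_j")]`, or a one-sided
#'   formula such as `~ id_i + id_j` evaluated in `data`. `NULL` keeps
#'   naive (model-based) standard errors.
#' @param standardize if `TRUE` (default) numeric, non-binary predictors
#'   are scaled to mean 0 and SD 1 before fitting; the scales are stored
#'   so coefficients can be mapped back.
#' @param cluster_adjust apply the finite-sample multiplier
#'   `G/(G - 1)` per clustering dimension (default `FALSE`).
#' @param tol convergence tolerance on the score norm.
#' @param maxit maximum optimizer iterations.
#' @return an object of class `dyad_model` with components `beta`
#'   (named slope vector), `tau` (thresholds, ordered family), `loglik`,
#'   `vcov` (clustered when requested), `vcov_naive`, `se`, `p`
#'   (two-tailed normal reference on `beta/se`), `n`, `scores`, `bread`,
#'   `fitted_probs`, and bookkeeping fields. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `nobs`, `predict`, `simulate`, `anova`.
#' @export
dyad_model <- function(formula, data, family = c("ordered", "binary"),
                       cluster = NULL, standardize = TRUE,
                       cluster_adjust = FALSE, tol = 1e-8, maxit = 200) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y_raw <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  has_int <- "(Intercept)" %in% colnames(X)
  Xs <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]

  scales <- rep(1, ncol(Xs))
  centers <- rep(0, ncol(Xs))
  names(scales) <- names(centers) <- colnames(Xs)
  if (standardize && ncol(Xs) > 0) {
    for (jc in seq_len(ncol(Xs))) {
      v <- Xs[, jc]
      if (length(unique(v)) > 2) {
        centers[jc] <- mean(v)
        s <- stats::sd(v)
        if (s > 0) scales[jc] <- s
        Xs[, jc] <- (v - centers[jc]) / scales[jc]
      }
    }
  }

  cl <- .resolve_cluster(cluster, data, nrow(Xs))

  fit <- if (family == "ordered") {
    .fit_ordered_logit(y_raw, Xs, tol = tol, maxit = maxit)
  } else {
    .fit_binary_logit(y_raw, Xs, has_intercept = has_int)
  }

  vc_naive <- tryCatch(solve(fit$info), error = function(e) {
    stop("singular information matrix (rank-deficient design?)",
         call. = FALSE)
  })
  bread <- vc_naive # inverse observed information
  obj <- structure(list(
    call = match.call(), formula = formula, family = family,
    beta = fit$beta, tau = fit$tau, loglik = fit$loglik,
    n = nrow(Xs), n_params = length(fit$par),
    scores = fit$scores, bread = bread, vcov_naive = vc_naive,
    fitted_probs = fit$fitted_probs, y = fit$y, X = Xs,
    levels = fit$levels, converged = fit$converged,
    standardize = standardize, centers = centers, scales = scales,
    cluster = cl, cluster_adjust = cluster_adjust
  ), class = "dyad_model")
  if (!fit$converged) {
    stop(sprintf(
      "dyad_model did not converge (max |score| = %.3g); %s",
      fit$grad_norm,
      "possible separation or degenerate design"
    ), call. = FALSE)
  }
  obj$vcov <- if (is.null(cl)) {
    vc_naive
  } else {
    twoway_cluster_vcov(obj, cl[[1]], cl[[2]], adjust = cluster_adjust)
  }
  se <- sqrt(diag(obj$vcov))
  keep <- names(obj$beta)
  obj$se <- se[keep]
  obj$z <- obj$beta / obj$se
  obj$p <- 2 * stats::pnorm(-abs(obj$z))
  obj
}

.resolve_cluster <- function(cluster, data, n) {
  if (is.null(cluster)) {
    return(NULL)
  }
  if (inherits(cluster, "formula")) {
    vars <- all.vars(cluster)
    if (length(vars) != 2) {
      stop("cluster formula must name exactly two id variables",
           call. = FALSE)
    }
    cluster <- data[, vars, drop = FALSE]
  } else if (is.character(cluster) && length(cluster) == 2 &&
             all(cluster %in% names(data))) {
    cluster <- data[, cluster, drop = FALSE]
  }
  cl <- as.data.frame(cluster, stringsAsFactors = FALSE)
  if (ncol(cl) != 2) stop("cluster must have two columns", call. = FALSE)
  if (nrow(cl) != n) {
    stop("cluster id vectors must match the number of observations",
         call. = FALSE)
  }
  cl
}

## ---- ordered logit internals -------------------------------------------

## Likelihood pieces for logit P(Y <= k) = tau_k - eta, eta = X beta.
.ord_parts <- function(tau, beta, X, y, K) {
  eta <- if (ncol(X) > 0) drop(X %*% beta) else rep(0, nrow(X))
  hi <- c(tau, Inf)[y] - eta
  lo <- c(-Inf, tau)[y] - eta
  Fhi <- stats::plogis(hi)
  Flo <- stats::plogis(lo)
  p <- pmax(Fhi - Flo, 1e-300)
  fhi <- stats::dlogis(hi)
  flo <- stats::dlogis(lo)
  list(p = p, fhi = fhi, flo = flo, eta = eta)
}

.ord_loglik <- function(tau, beta, X, y, K) {
  sum(log(.ord_parts(tau, beta, X, y, K)$p))
}

## Per-observation scores in (tau, beta) space: n x (K-1+p).
.ord_scores <- function(tau, beta, X, y, K) {
  pr <- .ord_parts(tau, beta, X, y, K)
  n <- length(y)
  Km1 <- K - 1
  S <- matrix(0, n, Km1 + ncol(X))
  ## d/d tau_k: + f(hi)/p when k == y, - f(lo)/p when k == y - 1
  idx_hi <- which(y <= Km1)
  S[cbind(idx_hi, y[idx_hi])] <-
    S[cbind(idx_hi, y[idx_hi])] + pr$fhi[idx_hi] / pr$p[idx_hi]
  idx_lo <- which(y >= 2)
  S[cbind(idx_lo, y[idx_lo] - 1)] <-
    S[cbind(idx_lo, y[idx_lo] - 1)] - pr$flo[idx_lo] / pr$p[idx_lo]
  if (ncol(X) > 0) {
    deta <- -(pr$fhi - pr$flo) / pr$p
    S[, Km1 + seq_len(ncol(X))] <- deta * X
  }
  S
}

.fit_ordered_logit <- function(y_raw, X, tol = 1e-8, maxit = 200) {
  if (is.ordered(y_raw) || is.factor(y_raw)) {
    levels_y <- levels(droplevels(factor(y_raw)))
    y <- as.integer(droplevels(factor(y_raw)))
  } else {
    levels_y <- as.character(sort(unique(y_raw)))
    y <- match(y_raw, sort(unique(y_raw)))
  }
  K <- length(levels_y)
  if (K < 2) stop("response has fewer than 2 occupied categories",
                  call. = FALSE)
  p <- ncol(X)
  n <- length(y)

  ## theta = (tau_1, log diff tau, beta); tau = cumsum(c(t1, exp(.)))
  freq <- cumsum(tabulate(y, K))[seq_len(K - 1)] / n
  tau0 <- stats::qlogis(freq)
  theta0 <- c(tau0[1], if (K > 2) log(diff(tau0)) else NULL, rep(0, p))

  unpack <- function(theta) {
    t1 <- theta[1]
    tau <- if (K > 2) cumsum(c(t1, exp(theta[2:(K - 1)]))) else t1
    beta <- if (p > 0) theta[(K - 1) + seq_len(p)] else numeric(0)
    list(tau = tau, beta = beta)
  }
  negll <- function(theta) {
    pr <- unpack(theta)
    -.ord_loglik(pr$tau, pr$beta, X, y, K)
  }
  neggr <- function(theta) {
    pr <- unpack(theta)
    g_tb <- colSums(.ord_scores(pr$tau, pr$beta, X, y, K))
    ## chain rule to theta: dtau_j/dtheta_1 = 1; dtau_j/dtheta_m =
    ## exp(theta_m) for j >= m
    g_theta <- g_tb
    if (K > 2) {
      gt <- g_tb[seq_len(K - 1)]
      g_theta[1] <- sum(gt)
      for (mth in 2:(K - 1)) {
        g_theta[mth] <- exp(theta[mth]) * sum(gt[mth:(K - 1)])
      }
    }
    -g_theta
  }
  opt <- stats::optim(theta0, negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  pr <- unpack(opt$par)
  S <- .ord_scores(pr$tau, pr$beta, X, y, K)
  grad_norm <- max(abs(colSums(S)))
  ## score norm tolerance scales with n; huge coefficients signal
  ## separation even when the gradient has flattened out
  converged <- is.finite(grad_norm) &&
    grad_norm < max(1e-3, tol * n) &&
    all(abs(c(pr$tau, pr$beta)) < 30)

  par <- c(pr$tau, pr$beta)
  names(par) <- c(paste0("tau", seq_len(K - 1)), colnames(X))
  info <- .num_hessian_neg(function(th) {
    tau <- th[seq_len(K - 1)]
    beta <- th[(K - 1) + seq_len(p)]
    .ord_loglik(tau, beta, X, y, K)
  }, par)
  dimnames(info) <- list(names(par), names(par))
  colnames(S) <- names(par)

  eta <- if (p > 0) drop(X %*% pr$beta) else rep(0, n)
  cum <- stats::plogis(outer(rep(1, n), pr$tau) - eta)
  probs <- cbind(cum, 1)[, seq_len(K), drop = FALSE] -
    cbind(0, cum)[, seq_len(K), drop = FALSE]
  colnames(probs) <- levels_y

  beta <- pr$beta
  names(beta) <- colnames(X)
  tau <- pr$tau
  names(tau) <- paste0("tau", seq_len(K - 1))
  list(
    beta = beta, tau = tau, par = par,
    loglik = -opt$value, scores = S, info = info,
    fitted_probs = probs, y = y, levels = levels_y,
    converged = converged, grad_norm = grad_norm
  )
}

## Negative Hessian (observed information) by central differences of the
## analytic-free log-likelihood.
.num_hessian_neg <- function(ll, par) {
  p <- length(par)
  H <- matrix(0, p, p)
  h <- 1e-4 * (abs(par) + 1e-2)
  f0 <- ll(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      pp <- par
      pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] + h[j]; fpp <- ll(pp)
      pp <- par
      pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] - h[j]; fpm <- ll(pp)
      pp <- par
      pp[i] <- pp[i] - h[i]; pp[j] <- pp[j] + h[j]; fmp <- ll(pp)
      pp <- par
      pp[i] <- pp[i] - h[i]; pp[j] <- pp[j] - h[j]; fmm <- ll(pp)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  -H
}

## ---- binary logit internals --------------------------------------------

.fit_binary_logit <- function(y_raw, X, has_intercept = TRUE) {
  y <- as.numeric(y_raw)
  if (!all(y %in% c(0, 1))) {
    stop("binary response must be 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("binary response is constant", call. = FALSE)
  }
  Xf <- if (has_intercept) cbind(`(Intercept)` = 1, X) else X
  fit <- stats::glm.fit(Xf, y, family = stats::binomial())
  mu <- fit$fitted.values
  sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  if (any(aliased)) {
    warning("aliased/constant predictor(s) ",
            paste(names(coefs)[aliased], collapse = ", "),
            "; coefficient set to 0", call. = FALSE)
    coefs[aliased] <- 0
    Xa <- Xf[, !aliased, drop = FALSE]
  } else {
    Xa <- Xf
  }
  S <- (y - mu) * Xa
  w <- mu * (1 - mu)
  info <- crossprod(Xa * sqrt(w))
  dimnames(info) <- list(colnames(Xa), colnames(Xa))
  grad_norm <- max(abs(colSums(S)))
  list(
    beta = coefs, tau = NULL, par = coefs[!aliased],
    loglik = sum(y * log(pmax(mu, 1e-300)) +
                   (1 - y) * log(pmax(1 - mu, 1e-300))),
    scores = S, info = info,
    fitted_probs = cbind(`0` = 1 - mu, `1` = mu), y = y,
    levels = c("0", "1"),
    converged = fit$converged && !sep,
    grad_norm = if (sep) Inf else grad_norm
  )
}

## ---- methods ------------------------------------------------------------

#' @export
print.dyad_model <- function(x, ...) {
  cat(sprintf("Dyadic %s logistic regression (n = %d dyads)\n",
              x$family, x$n))
  cat("Coefficients:\n")
  print(round(x$beta, 4))
  if (!is.null(x$tau)) {
    cat("Thresholds:\n")
    print(round(x$tau, 4))
  }
  cat(sprintf("Log-likelihood: %.3f\n", x$loglik))
  if (!is.null(x$cluster)) {
    cat("Standard errors clustered on both dyad members\n")
  }
  invisible(x)
}

#' @export
summary.dyad_model <- function(object, ...) {
  tab <- cbind(
    Estimate = object$beta,
    `Std. Error` = object$se,
    `z value` = object$z,
    `Pr(>|z|)` = object$p
  )
  out <- list(
    call = object$call, family = object$family, n = object$n,
    coefficients = tab, tau = object$tau, loglik = object$loglik,
    clustered = !is.null(object$cluster)
  )
  class(out) <- "summary.dyad_model"
  out
}

#' @export
print.summary.dyad_model <- function(x, ...) {
  cat(sprintf("Dyadic %s logistic regression (n = %d dyads)\n",
              x$family, x$n))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$tau)) {
    cat("Thresholds:", paste(sprintf("%.3f", x$tau), collapse = " "), "\n")
  }
  cat(sprintf(
    "Log-likelihood: %.3f; SEs %s\n", x$loglik,
    if (x$clustered) "two-way cluster-robust" else "model-based"
  ))
  invisible(x)
}

#' @export
coef.dyad_model <- function(object, ...) object$beta

#' @export
vcov.dyad_model <- function(object, ...) object$vcov

#' @export
logLik.dyad_model <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.dyad_model <- function(object, ...) object$n

#' Predicted category probabilities or classes
#'
#' @param object a `dyad_model`.
#' @param newdata optional data.frame; fitted data when omitted.
#' @param type `"probs"` (matrix of category probabilities), `"class"`
#'   (most probable category) or `"link"` (linear predictor `x'beta`).
#' @param ... unused.
#' @export
predict.dyad_model <- function(object, newdata = NULL,
                               type = c("probs", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
    for (jc in colnames(X)) {
      X[, jc] <- (X[, jc] - object$centers[jc]) / object$scales[jc]
    }
  }
  if (object$family == "binary") {
    Xf <- if ("(Intercept)" %in% names(object$beta)) {
      cbind(`(Intercept)` = 1, X)
    } else {
      X
    }
    eta <- drop(Xf %*% object$beta[colnames(Xf)])
    if (type == "link") {
      return(eta)
    }
    pr <- stats::plogis(eta)
    if (type == "probs") {
      return(cbind(`0` = 1 - pr, `1` = pr))
    }
    return(as.integer(pr > 0.5))
  }
  eta <- if (ncol(X) > 0) drop(X %*% object$beta[colnames(X)]) else
    rep(0, nrow(X))
  if (type == "link") {
    return(eta)
  }
  K <- length(object$levels)
  cum <- stats::plogis(outer(rep(1, length(eta)), object$tau) - eta)
  probs <- cbind(cum, 1)[, seq_len(K), drop = FALSE] -
    cbind(0, cum)[, seq_len(K), drop = FALSE]
  colnames(probs) <- object$levels
  if (type == "probs") {
    return(probs)
  }
  factor(object$levels[max.col(probs)], levels = object$levels)
}

#' Simulate responses from a fitted dyad model
#'
#' Draws response vectors from the fitted category probabilities, for
#' parametric-bootstrap and calibration work.
#'
#' @param object a `dyad_model`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns of simulated responses (on
#'   the original category labels for the ordered family, 0/1 for the
#'   binary family).
#' @export
simulate.dyad_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  pr <- object$fitted_probs
  draw <- function() {
    k <- apply(pr, 1, function(p) sample.int(ncol(pr), 1, prob = p))
    if (object$family == "binary") {
      k - 1L
    } else {
      as.integer(object$levels)[k]
    }
  }
  out <- as.data.frame(replicate(nsim, draw()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Likelihood-ratio test between nested dyad models
#'
#' @param full,reduced fitted `dyad_model` objects on the same data, the
#'   reduced model's parameters a subset of the full model's.
#' @return list with `chi2`, `df` and `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "dyad_model"), inherits(reduced, "dyad_model"))
  if (full$n != reduced$n || full$family != reduced$family) {
    stop("models must share data and family", call. = FALSE)
  }
  df <- full$n_params - reduced$n_params
  if (df < 0 ||
      !all(names(reduced$beta) %in% names(full$beta))) {
    stop("'reduced' is not nested in 'full'", call. = FALSE)
  }
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-6) {
    stop("full model has lower likelihood; models are not nested",
         call. = FALSE)
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' @export
anova.dyad_model <- function(object, ..., test = "LRT") {
  others <- list(...)
  if (length(others) != 1 || !inherits(others[[1]], "dyad_model")) {
    stop("supply exactly two dyad_model fits", call. = FALSE)
  }
  full <- if (object$n_params >= others[[1]]$n_params) object else
    others[[1]]
  red <- if (identical(full, object)) others[[1]] else object
  res <- lr_test(full, red)
  out <- data.frame(
    Df = res$df, Chisq = res$chi2, `Pr(>Chisq)` = res$p,
    check.names = FALSE
  )
  rownames(out) <- "full vs reduced"
  out
}

#' Percent change in odds for a log-odds coefficient
#'
#' Translates a logistic coefficient into the percent change in the odds
#' of the outcome per one-unit (for standardized predictors, one-SD)
#' increase of the predictor: `100 * (exp(beta) - 1)`.
#'
#' @param beta log-odds coefficient(s).
#' @param digits rounding (default 0, the reporting convention).
#' @return numeric percent change(s).
#' @examples
#' odds_interpretation(0.388) # 47
#' @export
odds_interpretation <- function(beta, digits = 0) {
  stopifnot(is.finite(beta))
  round(100 * (exp(beta) - 1), digits)
}
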