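#' Kolmogorov-Smirnov test of one distance category against the rest
#'
#' Two-sample, two-sided KS test comparing composite similarities of
#' dyads in category `k` with all remaining dyads, using the asymptotic
#' Kolmogorov reference distribution.
#'
#' @param values numeric vector of composite similarities, one per dyad.
#' @param categories distance category per dyad.
#' @param k the category singled out.
#' @return a `group_test_result` list: `statistic` (D), `p`, `n_group`,
#'   `n_rest`, `sidedness`, `method`.
#' @export
ks_group_vs_rest <- function(values, categories, k) {
  stopifnot(length(values) == length(categories))
  x <- values[categories == k]
  y <- values[categories != k]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(
    statistic = unname(res$statistic), p = res$p.value,
    n_group = length(x), n_rest = length(y),
    sidedness = "two_tailed", method = "ks"
  ), class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  lab <- if (x$method == "ks") "D" else "W"
  cat(sprintf("%s test (two-tailed): %s = %g, p = %.4g (n = %d vs %d)\n",
              toupper(x$method), lab, x$statistic, x$p, x$n_group,
              x$n_rest))
  invisible(x)
}

## Core rank-sum machinery. W is the rank sum of the first sample
## (so W - n1(n1+1)/2 is the Mann-Whitney U). Exact p by enumeration of
## the rank-sum null when n1*n2 <= exact_limit and no ties; otherwise a
## normal approximation with tie correction and continuity correction.
.rank_sum_test <- function(x, y, exact_limit = 400) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (all(c(x, y) == c(x, y)[1])) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(list(statistic = W, p = 1, exact = FALSE))
  }
  if (!ties && n1 * n2 <= exact_limit) {
    p <- min(1, 2 * min(
      stats::pwilcox(U, n1, n2),
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    ))
    return(list(statistic = W, p = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  zc <- U - mu
  zc <- sign(zc) * max(abs(zc) - 0.5, 0) # continuity correction
  z <- zc / sqrt(sigma2)
  list(statistic = W, p = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Wilcoxon rank-sum test of one distance category against the rest
#'
#' Rank-sum (Mann-Whitney) location test between the dyads of category
#' `k` and all remaining dyads. The reported statistic `W` is the rank
#' sum of the singled-out group. The p-value is exact (null enumeration)
#' when `n1 * n2 <= 400` and there are no ties, otherwise a normal
#' approximation with tie and continuity corrections.
#'
#' @inheritParams ks_group_vs_rest
#' @return a `group_test_result` list.
#' @export
wilcoxon_group_vs_rest <- function(values, categories, k) {
  stopifnot(length(values) == length(categories))
  x <- values[categories == k]
  y <- values[categories != k]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  res <- .rank_sum_test(x, y)
  structure(list(
    statistic = res$statistic, p = res$p,
    n_group = length(x), n_rest = length(y),
    sidedness = "two_tailed", exact = res$exact, method = "wilcoxon"
  ), class = "group_test_result")
}

#' Pairwise Wilcoxon rank-sum test between two distance categories
#'
#' @inheritParams ks_group_vs_rest
#' @param k1,k2 the two categories compared; `W` is the rank sum of
#'   category `k1`.
#' @return a `group_test_result` list.
#' @export
wilcoxon_pairwise <- function(values, categories, k1, k2) {
  x <- values[categories == k1]
  y <- values[categories == k2]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  res <- .rank_sum_test(x, y)
  structure(list(
    statistic = res$statistic, p = res$p,
    n_group = length(x), n_rest = length(y),
    sidedness = "two_tailed", exact = res$exact, method = "wilcoxon"
  ), class = "group_test_result")
}

#' Topology-preserving network permutation test
#'
#' Tests whether dyads at each social distance are more (or less) similar
#' than expected if similarity carried no information about network
#' position. Each permutation draws a uniform random bijection of
#' subjects onto network nodes — equivalently, a simultaneous row/column
#' permutation of the dyadic similarity matrix — so the network topology
#' (and hence the multiset of distance categories) is held fixed while
#' the neural data are shuffled across positions. Per-category mean
#' composite similarity is recomputed for every relabeling.
#'
#' The default p-value is two-sided around the null mean with an add-one
#' correction:
#' `p_k = (1 + #\{|null - mean(null)| >= |obs - mean(null)|\}) /
#' (n_perm + 1)`. One-sided variants use the corresponding single tail.
#'
#' @param composite numeric vector of composite similarities per dyad.
#' @param dyad_index two-column matrix/data.frame of subject indices
#'   (`i`, `j`) per dyad, covering all pairs of `1..N`.
#' @param categories distance category per dyad (fixed by the network).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return a `permutation_result` list: `observed` (named per-category
#'   means), `null_distribution` (`n_perm x K`), `p`, `n_perm`, `seed`,
#'   `alternative`.
#' @export
network_permutation_test <- function(composite, dyad_index, categories,
                                     n_perm = 1000, seed = 1L,
                                     alternative = c("two_sided",
                                                     "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  idx <- as.matrix(dyad_index)[, 1:2, drop = FALSE]
  storage.mode(idx) <- "integer"
  D <- length(composite)
  stopifnot(nrow(idx) == D, length(categories) == D)
  n <- max(idx)
  S <- matrix(NA_real_, n, n)
  S[idx] <- composite
  S[idx[, 2:1]] <- composite
  cats <- sort(unique(categories))
  catf <- factor(categories, levels = cats)
  observed <- tapply(composite, catf, mean)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(cats),
                 dimnames = list(NULL, paste0("d", cats)))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n) # Fisher-Yates relabeling of subjects
    vals <- S[cbind(perm[idx[, 1]], perm[idx[, 2]])]
    null[b, ] <- tapply(vals, catf, mean)
  }
  mu0 <- colMeans(null)
  p <- vapply(seq_along(cats), function(kk) {
    obs_dev <- observed[kk] - mu0[kk]
    null_dev <- null[, kk] - mu0[kk]
    hits <- switch(alternative,
      two_sided = sum(abs(null_dev) >= abs(obs_dev)),
      greater = sum(null[, kk] >= observed[kk]),
      less = sum(null[, kk] <= observed[kk])
    )
    (1 + hits) / (n_perm + 1)
  }, numeric(1))
  names(p) <- paste0("d", cats)
  structure(list(
    observed = observed, null_distribution = null, p = p,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = alternative, categories = cats
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Node-relabeling permutation test (%d permutations, %s)\n",
    x$n_perm, x$alternative
  ))
  out <- data.frame(
    category = x$categories,
    observed = round(unname(x$observed), 4),
    null_mean = round(colMeans(x$null_distribution), 4),
    p = round(unname(x$p), 4)
  )
  print(out, row.names = FALSE)
  invisible(x)
}
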