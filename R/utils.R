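#' Derive a child seed from a master seed
#'
#' All randomized stages of the package draw their seeds from a single
#' master seed through this function, so that any stage can be regenerated
#' in isolation. The stream label is hashed to a fixed offset and combined
#' with the master seed by a multiplicative-congruential step, keeping the
#' result a valid 32-bit integer seed.
#'
#' @param seed integer master seed.
#' @param stream character label of the consuming stage (e.g. `"network"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the Lehmer generator
  h <- sum(utf8ToInt(stream) * (seq_len(nchar(stream)) %% 31 + 1))
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + h * 2654435769 %% m) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(max(1, x))
}

## Canonical dyad enumeration: all unordered pairs (i < j) of the given ids,
## ordered lexicographically on the *positions* of the ids as supplied.
dyad_pairs <- function(ids) {
  n <- length(ids)
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  data.frame(
    i = idx[ord, "row"], j = idx[ord, "col"],
    id_i = ids[idx[ord, "row"]], id_j = ids[idx[ord, "col"]],
    stringsAsFactors = FALSE
  )
}

#' Number of unordered dyads among n subjects
#'
#' @param n number of subjects.
#' @return `choose(n, 2)` as an integer.
#' @export
n_dyads <- function(n) {
  stopifnot(n >= 0)
  as.integer(choose(n, 2))
}

## Clip negative eigenvalues of a symmetric matrix to zero.
psd_clip <- function(m, tol = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= -tol)) {
    return(m)
  }
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
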