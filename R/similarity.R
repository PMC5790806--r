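#' Dyadic per-ROI inter-subject correlations
#'
#' For every unordered pair of subjects and every ROI, computes the
#' Pearson correlation between the two subjects' ROI-mean time series.
#' Entries are missing when either subject lacks the ROI, or when a
#' series has zero variance (flagged with a warning rather than forced
#' to zero).
#'
#' @param ts a ROI time series set as produced by [simulate_timeseries()]
#'   or [read_timeseries_dir()]: list with `series` array
#'   `[N, R, T]`, `present_mask`, `roi_names`, `subject_ids`, and
#'   optionally `volumes`.
#' @return a `similarity_matrix`: list with `raw` (`D x R`, `NA` where
#'   missing), `dyads` (data.frame of canonical `i < j` pairs),
#'   `roi_names`, `subject_ids`, `volumes` and empty `imputed_flags`.
#' @export
dyadic_roi_correlations <- function(ts) {
  s <- ts$series
  stopifnot(length(dim(s)) == 3)
  n <- dim(s)[1]
  R <- dim(s)[2]
  Tt <- dim(s)[3]
  if (Tt < 3) stop("need at least 3 time points", call. = FALSE)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  present <- ts$present_mask %||% matrix(TRUE, n, R)
  ## flag zero-variance present series as unusable
  for (i in seq_len(n)) {
    for (r in seq_len(R)) {
      if (present[i, r]) {
        v <- s[i, r, ]
        if (anyNA(v) || stats::sd(v) == 0) {
          if (!anyNA(v)) {
            warning(sprintf(
              "zero-variance series (subject %d, ROI %d) treated as missing",
              i, r
            ), call. = FALSE)
          }
          present[i, r] <- FALSE
        }
      }
    }
  }
  dy <- dyad_pairs(ts$subject_ids %||% sprintf("S%03d", seq_len(n)))
  D <- nrow(dy)
  raw <- matrix(NA_real_, D, R)
  ## per-ROI: correlate the subject x time slab once, read off dyad pairs
  for (r in seq_len(R)) {
    ok <- which(present[, r])
    if (length(ok) >= 2) {
      cm <- stats::cor(t(s[ok, r, , drop = FALSE][, 1, ]))
      idx_i <- match(dy$i, ok)
      idx_j <- match(dy$j, ok)
      both <- !is.na(idx_i) & !is.na(idx_j)
      raw[both, r] <- cm[cbind(idx_i[both], idx_j[both])]
    }
  }
  colnames(raw) <- ts$roi_names %||% sprintf("roi%03d", seq_len(R))
  structure(list(
    raw = raw, z = NULL, composite = NULL,
    imputed_flags = is.na(raw) & FALSE, # filled by impute_missing()
    dyads = dy, roi_names = colnames(raw),
    subject_ids = ts$subject_ids %||% sprintf("S%03d", seq_len(n)),
    volumes = ts$volumes, sd_type = NULL
  ), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "Similarity matrix: %d dyads x %d ROIs (%d missing, %d imputed)%s%s\n",
    nrow(x$raw), ncol(x$raw), sum(is.na(x$raw)), sum(x$imputed_flags),
    if (!is.null(x$z)) ", normalized" else "",
    if (!is.null(x$composite)) ", composite" else ""
  ))
  invisible(x)
}

#' Impute missing dyadic correlations by ROI means
#'
#' Each missing dyad-ROI correlation is replaced by the mean observed
#' correlation for that ROI across the remaining dyads; imputed cells are
#' flagged and kept in all downstream models.
#'
#' @param sim a `similarity_matrix` with `raw` values.
#' @return the `similarity_matrix` with no missing raw entries and
#'   `imputed_flags` set.
#' @export
impute_missing <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  raw <- sim$raw
  miss <- is.na(raw)
  if (any(miss)) {
    col_all_missing <- colSums(!miss) == 0
    if (any(col_all_missing)) {
      stop("ROI(s) with no observed dyad: ",
           paste(sim$roi_names[col_all_missing], collapse = ", "),
           call. = FALSE)
    }
    mu <- colMeans(raw, na.rm = TRUE)
    for (r in which(colSums(miss) > 0)) {
      raw[miss[, r], r] <- mu[r]
    }
  }
  sim$raw <- raw
  sim$imputed_flags <- miss
  sim
}

#' Normalize similarities per ROI
#'
#' Z-scores each ROI's similarity vector across dyads to mean 0 and SD 1,
#' so values express a dyad's synchrony relative to the other dyads for
#' that region.
#'
#' @param sim an imputed `similarity_matrix` (no missing raw entries).
#' @param sd_type `"sample"` (denominator `D - 1`, default) or
#'   `"population"` (denominator `D`).
#' @return the `similarity_matrix` with the `z` slot filled.
#' @export
normalize_per_roi <- function(sim, sd_type = c("sample", "population")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  sd_type <- match.arg(sd_type)
  raw <- sim$raw
  if (anyNA(raw)) {
    stop("missing entries present; run impute_missing() first",
         call. = FALSE)
  }
  D <- nrow(raw)
  if (D < 2) stop("need at least 2 dyads to normalize", call. = FALSE)
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, stats::sd)
  if (sd_type == "population") sdv <- sdv * sqrt((D - 1) / D)
  if (any(sdv == 0)) {
    stop("zero-SD ROI column(s): ",
         paste(sim$roi_names[sdv == 0], collapse = ", "), call. = FALSE)
  }
  sim$z <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  colnames(sim$z) <- sim$roi_names
  sim$sd_type <- sd_type
  sim
}

#' Volume-weighted composite similarity
#'
#' Collapses the normalized dyad-by-ROI matrix to one overall similarity
#' per dyad: a weighted mean of the per-ROI z-scores with weights
#' proportional to each region's average volume. With equal weights this
#' is the plain row mean.
#'
#' @param sim a normalized `similarity_matrix`.
#' @param volumes per-ROI non-negative volumes (mm^3); named vectors are
#'   matched to `roi_names`. Defaults to the volumes attached to the
#'   similarity object.
#' @param weighting `"volume"` (default) or `"equal"`.
#' @return the `similarity_matrix` with the `composite` slot filled.
#' @export
weighted_composite <- function(sim, volumes = NULL,
                               weighting = c("volume", "equal")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  weighting <- match.arg(weighting)
  if (is.null(sim$z)) {
    stop("normalize_per_roi() must run before weighted_composite()",
         call. = FALSE)
  }
  R <- ncol(sim$z)
  if (weighting == "equal") {
    w <- rep(1, R)
  } else {
    w <- volumes %||% sim$volumes
    if (is.null(w)) stop("volumes required for volume weighting",
                         call. = FALSE)
    if (!is.null(names(w))) {
      if (!all(sim$roi_names %in% names(w))) {
        stop("volumes missing for some ROIs", call. = FALSE)
      }
      w <- w[sim$roi_names]
    }
    stopifnot(length(w) == R)
    if (any(w < 0)) stop("negative ROI volume", call. = FALSE)
    if (sum(w) <= 0) stop("volumes sum to zero", call. = FALSE)
  }
  sim$composite <- as.numeric(sim$z %*% w) / sum(w)
  sim$weighting <- weighting
  sim
}

#' Assemble the dyad-level analysis table
#'
#' One row per unordered pair of scanned subjects, combining the capped
#' social-distance category, demographic dissimilarity controls, the
#' composite similarity and the per-ROI z-scored similarities. This table
#' is the input to every regression, nonparametric test and classifier in
#' the package.
#'
#' @param sim a `similarity_matrix` with `z` and `composite` filled.
#' @param distances square matrix of capped distance categories for the
#'   scanned subjects (e.g. `geodesic_distances(g)$capped_category`
#'   restricted to the scanned rows/columns), with dimnames matching the
#'   subject ids.
#' @param demographics data.frame with `subject_id`, `gender`,
#'   `ethnicity`, `nationality`, `age`, `handedness`.
#' @return a data.frame of class `dyad_table`: `id_i`, `id_j`,
#'   `distance` (integer category), `friend` (distance == 1),
#'   `diff_gender`, `diff_ethnicity`, `diff_nationality`,
#'   `diff_handedness` (0/1), `age_diff` (years), `composite`, and one
#'   `z_<roi>` column per ROI.
#' @export
build_dyad_table <- function(sim, distances, demographics) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (is.null(sim$z) || is.null(sim$composite)) {
    stop("similarity matrix must be normalized with a composite",
         call. = FALSE)
  }
  ids <- sim$subject_ids
  dmat <- as.matrix(distances)
  if (!is.null(rownames(dmat))) {
    if (!all(ids %in% rownames(dmat))) {
      stop("subject(s) in fMRI set absent from distance matrix: ",
           paste(setdiff(ids, rownames(dmat)), collapse = ", "),
           call. = FALSE)
    }
    dmat <- dmat[ids, ids]
  } else {
    stopifnot(nrow(dmat) == length(ids))
  }
  if (!all(ids %in% demographics$subject_id)) {
    stop("subject(s) in fMRI set absent from demographics: ",
         paste(setdiff(ids, demographics$subject_id), collapse = ", "),
         call. = FALSE)
  }
  demo <- demographics[match(ids, demographics$subject_id), ]
  dy <- sim$dyads
  tab <- data.frame(
    id_i = dy$id_i, id_j = dy$id_j,
    distance = as.integer(dmat[cbind(dy$i, dy$j)]),
    stringsAsFactors = FALSE
  )
  tab$friend <- as.integer(tab$distance == 1L)
  tab$diff_gender <- as.integer(demo$gender[dy$i] != demo$gender[dy$j])
  tab$diff_ethnicity <-
    as.integer(demo$ethnicity[dy$i] != demo$ethnicity[dy$j])
  tab$diff_nationality <-
    as.integer(demo$nationality[dy$i] != demo$nationality[dy$j])
  tab$diff_handedness <-
    as.integer(demo$handedness[dy$i] != demo$handedness[dy$j])
  tab$age_diff <- abs(demo$age[dy$i] - demo$age[dy$j])
  tab$composite <- sim$composite
  z <- as.data.frame(sim$z)
  names(z) <- paste0("z_", sim$roi_names)
  tab <- cbind(tab, z)
  class(tab) <- c("dyad_table", "data.frame")
  tab
}

#' Names of the control-dissimilarity columns of a dyad table
#'
#' @return character vector of the demographic control column names.
#' @export
dyad_controls <- function() {
  c("diff_gender", "diff_ethnicity", "diff_nationality", "age_diff",
    "diff_handedness")
}
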