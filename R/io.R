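## All tabular IO uses one CSV dialect: comma separator, "." decimal,
## UTF-8, mandatory header, NA written as an empty field.

.read_csv <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.write_csv <- function(x, path, row.names = FALSE) {
  utils::write.csv(x, path, row.names = row.names, na = "")
}

#' Read a nomination matrix from CSV
#'
#' Accepts either an edge list with columns `nominator_id,nominee_id` or
#' a square adjacency matrix whose header row and first column carry the
#' subject ids. Duplicate directed edges are deduplicated with a
#' warning; self-edges and unknown ids are errors.
#'
#' @param path CSV file path.
#' @param subject_ids for edge lists, the full roster (defaults to the
#'   ids appearing in the file, sorted).
#' @return a [nomination_matrix()].
#' @export
read_nominations <- function(path, subject_ids = NULL) {
  df <- .read_csv(path)
  if (all(c("nominator_id", "nominee_id") %in% names(df))) {
    from <- as.character(df$nominator_id)
    to <- as.character(df$nominee_id)
    if (any(from == to)) {
      stop("self-edge in rows ",
           paste(which(from == to), collapse = ", "), call. = FALSE)
    }
    ids <- subject_ids %||% sort(unique(c(from, to)))
    unknown <- setdiff(c(from, to), ids)
    if (length(unknown) > 0) {
      stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(from, to, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate directed edge(s) deduplicated", call. = FALSE)
      keep <- !duplicated(key)
      from <- from[keep]
      to <- to[keep]
    }
    m <- matrix(0L, length(ids), length(ids),
                dimnames = list(ids, ids))
    m[cbind(match(from, ids), match(to, ids))] <- 1L
    return(nomination_matrix(m, ids))
  }
  ## square adjacency: first column = ids
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop("adjacency header ids must match first-column ids",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  nomination_matrix(m, ids)
}

#' Write a nomination matrix as a CSV edge list
#'
#' @param nominations a [nomination_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nominations <- function(nominations, path) {
  stopifnot(inherits(nominations, "nomination_matrix"))
  idx <- which(nominations$entries == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  .write_csv(data.frame(
    nominator_id = nominations$subject_ids[idx[, 1]],
    nominee_id = nominations$subject_ids[idx[, 2]]
  ), path)
  invisible(path)
}

#' Export a social graph
#'
#' @param graph a `social_graph`.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"` (plain two-column text).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path,
                             format = c("graphml", "edgelist")) {
  stopifnot(inherits(graph, "social_graph"))
  format <- match.arg(format)
  g <- graph$graph
  igraph::V(g)$name <- graph$subject_ids
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(el, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Write per-subject ROI time series to a directory
#'
#' One CSV per subject, named `<subject_id>.csv`, T rows by R columns
#' with ROI names as header; missing ROIs are written as empty (NA)
#' columns. Also writes `volumes.csv` (`roi_name,volume_mm3`) when
#' volumes are present.
#'
#' @param ts a ROI time series set (see [dyadic_roi_correlations()]).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_timeseries_dir <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(ts$series)[1]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  for (i in seq_len(n)) {
    m <- t(ts$series[i, , ]) # T x R
    df <- as.data.frame(lapply(seq_len(ncol(m)), function(r) fmt(m[, r])))
    names(df) <- ts$roi_names
    .write_csv(df, file.path(dir, paste0(ts$subject_ids[i], ".csv")))
  }
  if (!is.null(ts$volumes)) {
    .write_csv(data.frame(roi_name = ts$roi_names,
                          volume_mm3 = fmt(unname(ts$volumes[ts$roi_names]))),
               file.path(dir, "volumes.csv"))
  }
  invisible(dir)
}

#' Read per-subject ROI time series from a directory
#'
#' Reads every `*.csv` in `dir` except `volumes.csv` as one subject's
#' T-by-R series (subject id = file name); derives the missing mask from
#' all-NA columns; reorders columns by ROI name with a warning when
#' subjects disagree on ordering.
#'
#' @param dir directory of per-subject CSV files.
#' @param volumes_path optional volumes CSV (default
#'   `dir/volumes.csv` when present).
#' @return a ROI time series set: list with `series` `[N, R, T]`,
#'   `present_mask`, `roi_names`, `subject_ids`, `volumes`.
#' @export
read_timeseries_dir <- function(dir, volumes_path = NULL) {
  files <- sort(setdiff(list.files(dir, pattern = "\\.csv$"),
                        "volumes.csv"))
  if (length(files) == 0) stop("no subject files in ", dir, call. = FALSE)
  ids <- sub("\\.csv$", "", files)
  mats <- lapply(file.path(dir, files), .read_csv)
  roi_names <- colnames(mats[[1]])
  Tt <- nrow(mats[[1]])
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != Tt) {
      stop("inconsistent number of time points in ", files[i],
           call. = FALSE)
    }
    if (!identical(colnames(mats[[i]]), roi_names)) {
      if (!setequal(colnames(mats[[i]]), roi_names)) {
        stop("inconsistent ROI sets in ", files[i], call. = FALSE)
      }
      warning("reordering ROI columns of ", files[i], call. = FALSE)
      mats[[i]] <- mats[[i]][, roi_names]
    }
  }
  n <- length(mats)
  R <- length(roi_names)
  series <- array(NA_real_, c(n, R, Tt))
  present <- matrix(TRUE, n, R)
  for (i in seq_len(n)) {
    m <- as.matrix(mats[[i]])
    for (r in seq_len(R)) {
      v <- m[, r]
      if (all(is.na(v))) {
        present[i, r] <- FALSE
      } else {
        series[i, r, ] <- v
      }
    }
  }
  volumes <- NULL
  vp <- volumes_path %||% file.path(dir, "volumes.csv")
  if (file.exists(vp)) {
    vdf <- .read_csv(vp)
    volumes <- stats::setNames(vdf$volume_mm3, vdf$roi_name)[roi_names]
  }
  list(series = series, present_mask = present, roi_names = roi_names,
       subject_ids = ids, volumes = volumes)
}

#' Read demographics or ROI volumes CSV
#'
#' @param path CSV with columns `subject_id,gender,ethnicity,nationality,
#'   age,handedness` (demographics) or `roi_name,volume_mm3` (volumes).
#' @return data.frame (demographics) or named numeric vector (volumes).
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_demographics <- function(path) {
  df <- .read_csv(path)
  need <- c("subject_id", "gender", "ethnicity", "nationality", "age",
            "handedness")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("demographics missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @rdname read_tables
#' @export
read_volumes <- function(path) {
  df <- .read_csv(path)
  stopifnot(all(c("roi_name", "volume_mm3") %in% names(df)))
  stats::setNames(df$volume_mm3, df$roi_name)
}

#' Write a dyad table to CSV
#'
#' @param table a [build_dyad_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_table <- function(table, path) {
  .write_csv(as.data.frame(table), path)
  invisible(path)
}

#' Read a dyad table from CSV
#'
#' @param path CSV written by [write_dyad_table()].
#' @return a `dyad_table` data.frame.
#' @export
read_dyad_table <- function(path) {
  tab <- .read_csv(path)
  class(tab) <- c("dyad_table", "data.frame")
  tab
}

#' Run the full dyadic analysis pipeline
#'
#' Orchestrates every stage on files or in-memory inputs: build the
#' social graph and its statistics, compute geodesic distances on the
#' full cohort, assemble the dyad-by-ROI similarity matrix (impute,
#' normalize, composite), build the dyad table, fit the composite
#' ordered and binary models with the likelihood-ratio test, run per-ROI
#' regressions with FDR, the KS/Wilcoxon category comparisons, the
#' network permutation test, and the cross-validated classifier with its
#' label-permutation test. Results are returned as a bundle and, when
#' `out_dir` is given, written to CSV/JSON files plus a plain-text run
#' log of every derived seed.
#'
#' @param config a list (or path to a YAML/JSON file) with entries
#'   `nominations`, `timeseries_dir`, `demographics`, `volumes` (paths),
#'   and optionally `tie_rule` (`"reciprocal"`), `distance_cap` (4),
#'   `weighting` (`"volume"`), `seed` (1), `n_perm` (1000),
#'   `classifier` (list of [classifier_config()] overrides), `out_dir`.
#' @return (invisibly) a list with `network_stats`, `distances`,
#'   `similarity`, `dyad_table`, `model_ordered`, `model_binary`,
#'   `model_reduced`, `lr`, `fdr_table`, `ks`, `wilcoxon`,
#'   `permutation`, `classifier`, `label_permutation`, `seeds`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  tie_rule <- config$tie_rule %||% "reciprocal"
  cap <- config$distance_cap %||% 4
  weighting <- config$weighting %||% "volume"
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- config$n_perm %||% 1000

  for (f in c("nominations", "timeseries_dir", "demographics")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("missing input: ", f, call. = FALSE)
    }
  }
  if (weighting == "volume" && is.null(config$volumes) &&
      !file.exists(file.path(config$timeseries_dir, "volumes.csv"))) {
    stop("volume weighting requested but no volumes file", call. = FALSE)
  }

  demo <- read_demographics(config$demographics)
  nom <- read_nominations(config$nominations,
                          subject_ids = demo$subject_id)
  ts <- read_timeseries_dir(config$timeseries_dir,
                            volumes_path = config$volumes)
  volumes <- ts$volumes
  if (!is.null(config$volumes)) volumes <- read_volumes(config$volumes)

  stats_out <- network_stats(nom)
  g <- build_graph(nom, tie_rule = tie_rule)
  dist_full <- geodesic_distances(g, cap = cap)

  sim <- dyadic_roi_correlations(ts)
  sim <- impute_missing(sim)
  sim <- normalize_per_roi(sim)
  sim <- weighted_composite(sim, volumes, weighting = weighting)
  tab <- build_dyad_table(sim, dist_full$capped_category, demo)

  controls <- dyad_controls()
  ## controls without variation (tiny or homogeneous samples) would make
  ## the design rank-deficient
  controls <- controls[vapply(controls, function(cc) {
    stats::var(tab[[cc]]) > 0
  }, logical(1))]
  cl <- ~ id_i + id_j
  fo_full <- stats::reformulate(c("composite", controls), "distance")
  fo_red <- stats::reformulate(controls, "distance")
  m_ord <- dyad_model(fo_full, tab, "ordered", cluster = cl)
  m_red <- dyad_model(fo_red, tab, "ordered", cluster = cl)
  m_bin <- dyad_model(stats::reformulate(c("composite", controls),
                                         "friend"),
                      tab, "binary", cluster = cl)
  lr <- lr_test(m_ord, m_red)
  fdr <- per_roi_regressions(tab, controls = controls)

  cats <- sort(unique(tab$distance))
  ks <- lapply(cats, function(k) {
    ks_group_vs_rest(tab$composite, tab$distance, k)
  })
  wil <- lapply(cats, function(k) {
    wilcoxon_group_vs_rest(tab$composite, tab$distance, k)
  })
  names(ks) <- names(wil) <- paste0("d", cats)
  dy <- dyad_pairs(sim$subject_ids)
  seeds <- list(
    permutation = split_seed(seed, "permtest"),
    classifier = split_seed(seed, "classifier")
  )
  perm <- network_permutation_test(tab$composite, dy[, c("i", "j")],
                                   tab$distance, n_perm = n_perm,
                                   seed = seeds$permutation)
  ccfg_args <- config$classifier %||% list()
  ccfg_args$seed <- ccfg_args$seed %||% seeds$classifier
  ccfg <- do.call(classifier_config, ccfg_args)
  feats <- as.matrix(tab[, grep("^z_", names(tab)), drop = FALSE])
  clf <- cross_validated_predict(feats, tab$distance, ccfg)
  lperm <- label_permutation_test(feats, tab$distance, ccfg,
                                  observed = clf)

  bundle <- list(
    network_stats = stats_out, distances = dist_full, similarity = sim,
    dyad_table = tab, model_ordered = m_ord, model_binary = m_bin,
    model_reduced = m_red, lr = lr, fdr_table = fdr, ks = ks,
    wilcoxon = wil, permutation = perm, classifier = clf,
    label_permutation = lperm, seeds = seeds
  )
  if (!is.null(config$out_dir)) {
    .write_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

.model_json <- function(m) {
  list(beta = as.list(m$beta), se = as.list(m$se), p = as.list(m$p),
       tau = as.list(m$tau %||% numeric(0)), loglik = m$loglik, n = m$n,
       family = m$family)
}

.write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_dyad_table(bundle$dyad_table,
                   file.path(out_dir, "dyad_table.csv"))
  jsonlite::write_json(
    list(ordered = .model_json(bundle$model_ordered),
         binary = .model_json(bundle$model_binary),
         lr = bundle$lr),
    file.path(out_dir, "models.json"),
    auto_unbox = TRUE, digits = NA
  )
  .write_csv(as.data.frame(bundle$fdr_table),
             file.path(out_dir, "per_roi_regressions.csv"))
  .write_csv(as.data.frame(bundle$classifier$confusion),
             file.path(out_dir, "confusion.csv"), row.names = TRUE)
  .write_csv(as.data.frame(bundle$permutation$null_distribution),
             file.path(out_dir, "permutation_null.csv"))
  st <- bundle$network_stats
  jsonlite::write_json(
    list(
      network = st[c("n", "density_reciprocal", "density_any",
                     "total_reciprocity", "dyad_reciprocity",
                     "diameter", "connected")],
      permutation_p = as.list(bundle$permutation$p),
      classifier = list(
        overall_accuracy = bundle$classifier$overall_accuracy,
        macro_accuracy = bundle$classifier$macro_accuracy,
        p = bundle$label_permutation$p
      )
    ),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  log_lines <- c(
    paste0("package neurodyad ",
           as.character(utils::packageVersion("neurodyad"))),
    paste0("R ", R.version.string),
    vapply(names(bundle$seeds), function(nm) {
      paste0("seed ", nm, " = ", bundle$seeds[[nm]])
    }, character(1))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
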