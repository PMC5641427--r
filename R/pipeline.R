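# End-to-end orchestration: contours -> EFD -> abnormality filter -> PCA ->
# measurements -> group statistics, with deterministic CSV outputs.

#' Flatten a set of specimen contours into the EFD coefficient matrix
#'
#' @param records List of specimen records (see [sample_population()]) or a
#'   named list of contour matrices.
#' @param n_harmonics Harmonics (default 20, giving 77 coefficients).
#' @return List with \code{matrix} (specimens x 4N-3, row names = ids),
#'   \code{efds} (the normalized per-specimen efd objects) and
#'   \code{groups} (named group labels, NA when unknown).
#' @export
efd_table <- function(records, n_harmonics = 20L) {
  if (!length(records)) stop("no specimens")
  is_rec <- is.list(records[[1L]]) && !is.null(records[[1L]]$contour)
  ids <- character(length(records))
  groups <- character(length(records))
  efds <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    xy <- if (is_rec) rec$contour else rec
    ids[i] <- if (is_rec) rec$specimen_id
              else if (!is.null(names(records))) names(records)[i]
              else sprintf("specimen_%04d", i)
    groups[i] <- if (is_rec && !is.null(rec$group_label)) rec$group_label else NA_character_
    efds[[i]] <- efd_normalize(efd_estimate(ensure_ccw(xy), n_harmonics))
  }
  m <- do.call(rbind, lapply(efds, flatten_coeffs))
  rownames(m) <- ids
  names(efds) <- ids
  names(groups) <- ids
  list(matrix = m, efds = efds, groups = groups)
}

#' Run the full morphometric analysis pipeline
#'
#' Stages: (1) EFD estimation and normalization for every specimen;
#' (2) two-pass PCA abnormality filter on PC1 scores; (3) morphological
#' measurements of the retained specimens; (4) group statistics when at
#' least two labeled groups remain (skipped with a notice otherwise).
#' The run is deterministic given the inputs and configuration; when
#' \code{out_dir} is given, coefficient table, scores, abnormal ids,
#' measurements, statistics and the configuration are written as CSV/text.
#'
#' @param records List of specimen records or named list of contours.
#' @param n_harmonics Maximum harmonic number (default 20).
#' @param abnormal_threshold PC1 score cut-off for the abnormality filter
#'   (default 0.55).
#' @param reference_group Group whose mean anchors percent differences;
#'   required when statistics are computed (no silent default).
#' @param out_dir Optional output directory.
#' @return List with \code{coefficients}, \code{filter} (pass-1/pass-2
#'   models and abnormal ids), \code{measurements}, \code{statistics} (or
#'   \code{NULL}), \code{config}.
#' @export
run_pipeline <- function(records, n_harmonics = 20L, abnormal_threshold = 0.55,
                         reference_group = NULL, out_dir = NULL) {
  tab <- efd_table(records, n_harmonics)
  message(sprintf("stage efd: %d specimens, %d coefficients",
                  nrow(tab$matrix), ncol(tab$matrix)))
  flt <- filter_abnormal(tab$matrix, threshold = abnormal_threshold)
  message(sprintf("stage filter: %d in, %d excluded (PC1 > %.2f), %d out",
                  nrow(tab$matrix), length(flt$abnormal_ids),
                  abnormal_threshold, nrow(flt$normal)))
  if (nrow(flt$normal) < 3L) stop("stage filter: fewer than 3 specimens retained")
  keep <- rownames(flt$normal)
  is_rec <- is.list(records[[1L]]) && !is.null(records[[1L]]$contour)
  rec_ids <- if (is_rec) vapply(records, `[[`, character(1L), "specimen_id")
             else names(tab$efds)
  meas <- measure_heads(records[match(keep, rec_ids)], n_harmonics)
  message(sprintf("stage measure: %d specimens", nrow(meas)))
  glab <- meas$group_label
  stats_tab <- NULL
  n_groups <- length(unique(glab[!is.na(glab)]))
  if (n_groups >= 2L) {
    if (is.null(reference_group))
      stop("stage statistics: reference_group must be named explicitly")
    stats_tab <- compare_groups(meas, reference_group = reference_group)
    message(sprintf("stage statistics: %d groups, reference '%s'",
                    n_groups, reference_group))
  } else {
    message("stage statistics: skipped (fewer than 2 labeled groups)")
  }
  config <- list(n_harmonics = n_harmonics,
                 abnormal_threshold = abnormal_threshold,
                 reference_group = reference_group %||% NA_character_,
                 n_specimens_in = nrow(tab$matrix),
                 n_abnormal = length(flt$abnormal_ids))
  out <- list(coefficients = tab$matrix,
              coefficient_table = coefficient_table(tab),
              filter = flt, measurements = meas,
              statistics = stats_tab, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach group labels to contours via an external label map
#'
#' @param contours Named list of contour matrices (names = specimen ids).
#' @param label_map Data frame with columns \code{specimen_id},
#'   \code{group_label} (for example read from a CSV).
#' @return A list of specimen records suitable for [run_pipeline()].
#' @export
apply_label_map <- function(contours, label_map) {
  need <- c("specimen_id", "group_label")
  if (!all(need %in% names(label_map)))
    stop("label map needs columns: ", paste(need, collapse = ", "))
  ids <- names(contours)
  orphan <- setdiff(ids, label_map$specimen_id)
  if (length(orphan))
    stop("unmatched specimen ids (no group label): ",
         paste(orphan, collapse = ", "))
  lab <- label_map$group_label[match(ids, label_map$specimen_id)]
  lapply(seq_along(contours), function(i) {
    list(specimen_id = ids[i], contour = as_contour(contours[[i]]),
         true_aspect = NA_real_, is_abnormal = NA, group_label = lab[i])
  })
}

#' Per-specimen coefficient table with normalization records
#'
#' @param tab Result of [efd_table()].
#' @return Data frame: \code{specimen_id}, \code{N}, \code{scale_px},
#'   \code{rotation_rad}, \code{phase_rad}, then the 4N-3 ordered shape
#'   parameters (\code{d1}, \code{a2}, \code{b2}, ...).
#' @export
coefficient_table <- function(tab) {
  meta <- data.frame(
    specimen_id = rownames(tab$matrix),
    N = vapply(tab$efds, `[[`, integer(1L), "n_harmonics"),
    scale_px = vapply(tab$efds, `[[`, numeric(1L), "scale_px"),
    rotation_rad = vapply(tab$efds, `[[`, numeric(1L), "rotation_rad"),
    phase_rad = vapply(tab$efds, `[[`, numeric(1L), "phase_rad"),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(tab$matrix, check.names = FALSE))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv(res$coefficient_table, file.path(out_dir, "coefficients.csv"))
  sc <- data.frame(specimen_id = rownames(res$filter$pass2$scores),
                   res$filter$pass2$scores, check.names = FALSE)
  .write_csv(sc, file.path(out_dir, "scores_pass2.csv"))
  writeLines(res$filter$abnormal_ids, file.path(out_dir, "abnormal_ids.txt"))
  .write_csv(res$measurements, file.path(out_dir, "measurements.csv"))
  if (!is.null(res$statistics)) {
    .write_csv(res$statistics$summary, file.path(out_dir, "group_summary.csv"))
    .write_csv(res$statistics$tests, file.path(out_dir, "group_tests.csv"))
  }
  cfg <- res$config
  writeLines(paste0(names(cfg), "=", unlist(cfg)),
             file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' Group summary and comparison statistics for a measurement table
#'
#' Per-measure group means, SDs and CVs; percent differences of every group
#' mean against the declared reference group; pairwise classical tests
#' (pooled t, F, Kolmogorov-Smirnov) against the reference; and the
#' Steel-Dwass all-pairs table when three or more groups are present.
#'
#' @param measurements Data frame from [measure_heads()] (needs
#'   \code{group_label}).
#' @param reference_group Reference group name (must be present).
#' @param measure Column to analyze (default \code{"aspect_ratio"}).
#' @param tail Direction for the one-tailed t-test of each group against
#'   the reference (\code{"greater"}: test group mean smaller than
#'   reference is the alternative... the tail names follow
#'   [stats::t.test()] with x = reference sample).
#' @return List with \code{summary} (one row per group) and \code{tests}
#'   (pairwise table; Steel-Dwass rows flagged in \code{test_name}).
#' @export
compare_groups <- function(measurements, reference_group,
                           measure = "aspect_ratio", tail = "greater") {
  if (!measure %in% names(measurements)) stop("no such measure: ", measure)
  glab <- measurements$group_label
  if (all(is.na(glab))) stop("measurements carry no group labels")
  groups <- split(measurements[[measure]], glab)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (!reference_group %in% names(groups))
    stop("reference group '", reference_group, "' not among: ",
         paste(names(groups), collapse = ", "))
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               cv_percent = cv_percent(v),
               percent_diff_vs_ref = percent_difference(
                 mean(groups[[reference_group]]), mean(v)),
               stringsAsFactors = FALSE)
  }))
  ref <- groups[[reference_group]]
  tests <- do.call(rbind, lapply(setdiff(names(groups), reference_group),
    function(g) {
      v <- groups[[g]]
      tt <- classic_test(ref, v, "t_one", tail = tail)
      ft <- classic_test(ref, v, "f_var")
      ks <- classic_test(ref, v, "ks_two")
      data.frame(
        group1 = reference_group, group2 = g,
        test_name = c(tt$test_name, ft$test_name, ks$test_name),
        statistic = c(tt$statistic, ft$statistic, ks$statistic),
        p_value = c(tt$p_value, ft$p_value, ks$p_value),
        significance_label = c(tt$significance_label, ft$significance_label,
                               ks$significance_label),
        stringsAsFactors = FALSE)
    }))
  if (length(groups) >= 3L) {
    sd_tab <- steel_dwass(groups)
    tests <- rbind(tests, data.frame(
      group1 = sd_tab$group1, group2 = sd_tab$group2,
      test_name = "Steel-Dwass test", statistic = sd_tab$statistic,
      p_value = sd_tab$p_value,
      significance_label = sd_tab$significance_label,
      stringsAsFactors = FALSE))
  }
  list(summary = summ, tests = tests, reference_group = reference_group,
       measure = measure)
}
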