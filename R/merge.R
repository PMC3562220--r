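#' Merge configuration
#'
#' Tolerances and policies for [merge_results()]. 5 ppm is appropriate for
#' high-resolution instruments (Orbitrap/FT class); the retention time
#' tolerance should reflect the chromatographic stability of the runs being
#' merged (use [find_overlapping_mzs()] across replicate extractions to pick
#' it; 10 s is a workable default for well-aligned tables).
#'
#' @param mz_tolerance_ppm m/z grouping tolerance in parts per million.
#' @param rt_tolerance_s retention time sub-grouping tolerance in seconds.
#' @param t_test_alpha significance level of the paired t-test comparing
#'   intensities of a redundant pair: when set, pairs whose intensities
#'   differ significantly (p < alpha) are kept as distinct features instead
#'   of collapsed. `NA` (default) reports the test but never blocks a
#'   collapse.
#' @param tie_break policy when several members share the minimum median
#'   metric: `"intensity"` (higher mean intensity wins, then lower table
#'   index, then lower row index) or `"first"` (lower table then row index).
#' @return An object of class `merge_config`.
#' @export
merge_config <- function(mz_tolerance_ppm = 5, rt_tolerance_s = 10,
                         t_test_alpha = NA, tie_break = c("intensity",
                                                          "first")) {
  tie_break <- match.arg(tie_break)
  stopifnot(mz_tolerance_ppm > 0, rt_tolerance_s > 0)
  if (!is.na(t_test_alpha) &&
      (t_test_alpha <= 0 || t_test_alpha >= 1))
    stop("t_test_alpha must lie in (0, 1) or be NA")
  structure(list(mz_tolerance_ppm = mz_tolerance_ppm,
                 rt_tolerance_s = rt_tolerance_s,
                 t_test_alpha = t_test_alpha,
                 tie_break = tie_break),
            class = "merge_config")
}

#' Group features by m/z within a ppm tolerance
#'
#' Sorted single-linkage gap chaining: features are sorted by m/z and a new
#' group starts whenever the gap to the previous feature exceeds the
#' tolerance, with the ppm gap referenced to the lower (previous) of the two
#' adjacent m/z values. This is exactly the transitive closure of the
#' pairwise relation "within tolerance of each other", so the result is
#' independent of input order; note that a chain of close features can span
#' more than the tolerance between its extremes.
#'
#' @param mz numeric vector of m/z values.
#' @param tol_ppm tolerance in ppm.
#' @return List of integer vectors, each the (original) indices of one
#'   group, ordered by ascending m/z; every feature occurs in exactly one
#'   group.
#' @export
group_by_mz <- function(mz, tol_ppm) {
  chain_groups(mz, function(lo, hi) (hi - lo) <= tol_ppm * 1e-6 * lo)
}

#' Sub-group features by retention time within a tolerance
#'
#' Same gap-chaining rule as [group_by_mz()] but on retention times with an
#' absolute tolerance in seconds.
#'
#' @param rt numeric vector of retention times (seconds).
#' @param tol_s tolerance in seconds.
#' @return List of integer index vectors ordered by ascending RT.
#' @export
subgroup_by_rt <- function(rt, tol_s) {
  chain_groups(rt, function(lo, hi) (hi - lo) <= tol_s)
}

# Single-linkage chaining on a sorted 1-d coordinate. `within(lo, hi)` says
# whether two adjacent sorted values belong to the same group.
chain_groups <- function(x, within) {
  n <- length(x)
  if (!n) return(list())
  ord <- order(x)
  xs <- x[ord]
  breaks <- logical(n)
  breaks[1] <- TRUE
  if (n > 1)
    breaks[-1] <- !within(xs[-n], xs[-1])
  ids <- cumsum(breaks)
  unname(split(ord, ids))
}

#' Paired t-test on the shared intensity profile of two features
#'
#' Classical paired t on the per-profile differences, restricted to profiles
#' in which both features were observed. Used by [merge_results()] to report
#' whether two redundant features carry significantly different intensity
#' levels. Degenerate inputs get sentinels rather than errors: all-zero
#' differences give `t = 0, p = 1`; constant nonzero differences (sd zero)
#' give `t = +/-Inf, p = 0` with a note.
#'
#' @param x,y intensity vectors over the same profiles (`NA` = missing).
#' @return List with `t`, `p`, `df`, `n_pairs`, and `note` (`""`,
#'   `"zero-variance differences"`, or `"unavailable: < 2 complete pairs"`).
#' @export
paired_t <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, n_pairs = n,
                note = "unavailable: < 2 complete pairs"))
  if (all(d == 0))
    return(list(t = 0, p = 1, df = n - 1, n_pairs = n, note = ""))
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1, n_pairs = n,
                note = "zero-variance differences"))
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1), df = n - 1,
       n_pairs = n, note = "")
}

#' Pick the most reproducible member of a redundant sub-group
#'
#' The member with the minimum median reproducibility metric (median PID for
#' duplicate designs, median CV otherwise) represents the sub-group in the
#' merged table. Ties go to the member with higher mean observed intensity,
#' then lower input-table index, then lower row index. If no member has an
#' evaluable metric the highest-intensity member is chosen with a warning.
#'
#' @param medians per-member median metric (NA = unavailable).
#' @param mean_intensity per-member mean observed intensity.
#' @param table_idx,row_idx per-member provenance used for final tie-breaks.
#' @param tie_break `"intensity"` or `"first"` (see [merge_config()]).
#' @return Integer position of the chosen member.
#' @export
select_representative <- function(medians, mean_intensity, table_idx,
                                  row_idx, tie_break = "intensity") {
  stopifnot(length(medians) >= 1)
  if (all(is.na(medians))) {
    warning("sub-group with no evaluable reproducibility metric; ",
            "falling back to highest mean intensity")
    return(order(-mean_intensity, table_idx, row_idx)[1])
  }
  key_int <- if (tie_break == "intensity") -mean_intensity else 0
  ord <- order(is.na(medians), medians, key_int, table_idx, row_idx)
  ord[1]
}

#' Merge feature tables from multiple extraction settings
#'
#' The four-step merge: (1) all input features are pooled into one list;
#' (2) pooled features are grouped by m/z within `mz_tolerance_ppm`
#' ([group_by_mz()]); (3) each m/z group is sub-grouped by retention time
#' within `rt_tolerance_s` ([subgroup_by_rt()]); (4) each multi-member
#' sub-group is redundant — a paired t-test compares the two intensity
#' profiles of size-2 sub-groups, and the member with minimum median PID (or
#' CV) is kept as the sub-group's representative. Singleton sub-groups pass
#' through unchanged, so the merged table unites the settings' unique
#' features with the most reproducible version of their shared ones.
#'
#' When `t_test_alpha` is set in the config, a size-2 sub-group whose paired
#' t-test has `p < alpha` is treated as two genuinely different features and
#' both members are kept.
#'
#' With more than two tables, merging folds pairwise in input order (the
#' two-setting merge applied repeatedly), with a warning.
#'
#' @param tables list of two or more [feature_table()]s sharing identical
#'   profile columns in identical order.
#' @param design a [replicate_design()]; used to compute per-table feature
#'   reproducibility before merging.
#' @param config a [merge_config()].
#' @return List with `table` (the merged [feature_table()]) and `report` (a
#'   `merge_report`: input/output counts plus one row per collapsed or
#'   t-split sub-group with the chosen representative, member medians and
#'   the t statistic / p-value).
#' @export
merge_results <- function(tables, design, config = merge_config()) {
  stopifnot(is.list(tables), length(tables) >= 2)
  ref <- tables[[1]]$profile_ids
  for (k in seq_along(tables)) {
    if (!identical(tables[[k]]$profile_ids, ref))
      stop("configuration error: table ", k,
           " has different profile columns than table 1")
  }
  if (length(tables) > 2) {
    warning("merging ", length(tables),
            " tables by folding pairwise in input order; the merge is ",
            "defined for the two-setting case")
    acc <- merge_results(tables[1:2], design, config)
    for (k in 3:length(tables)) {
      nxt <- merge_results(list(acc$table, tables[[k]]), design, config)
      nxt$report$n_input_features <-
        c(acc$report$n_input_features[-length(acc$report$n_input_features)],
          nxt$report$n_input_features[2])
      acc <- nxt
    }
    return(acc)
  }

  t1 <- tables[[1]]; t2 <- tables[[2]]
  q <- lapply(tables, evaluate_features, design = design)
  medians <- c(q[[1]]$median, q[[2]]$median)

  # step 1: pooled list with provenance
  mz <- c(t1$mz, t2$mz)
  rt <- c(t1$rt, t2$rt)
  intens <- rbind(t1$intensities, t2$intensities)
  table_idx <- rep(1:2, c(n_features(t1), n_features(t2)))
  row_idx <- c(seq_len(n_features(t1)), seq_len(n_features(t2)))
  mean_int <- rowMeans(intens, na.rm = TRUE)
  mean_int[is.nan(mean_int)] <- 0

  keep <- integer()
  collapses <- list()
  n_subgroups <- 0L
  n_singleton <- 0L
  n_tsplit <- 0L

  for (g in group_by_mz(mz, config$mz_tolerance_ppm)) {
    for (sg_local in subgroup_by_rt(rt[g], config$rt_tolerance_s)) {
      sg <- g[sg_local]
      n_subgroups <- n_subgroups + 1L
      if (length(sg) == 1) {
        n_singleton <- n_singleton + 1L
        keep <- c(keep, sg)
        next
      }
      tt <- if (length(sg) == 2)
        paired_t(intens[sg[1], ], intens[sg[2], ])
      else
        list(t = NA_real_, p = NA_real_, note = "n > 2 members")
      if (!is.na(config$t_test_alpha) && length(sg) == 2 &&
          !is.na(tt$p) && tt$p < config$t_test_alpha) {
        n_tsplit <- n_tsplit + 1L
        keep <- c(keep, sg)
        next
      }
      chosen <- sg[select_representative(medians[sg], mean_int[sg],
                                         table_idx[sg], row_idx[sg],
                                         config$tie_break)]
      keep <- c(keep, chosen)
      collapses[[length(collapses) + 1L]] <- data.frame(
        representative_mz = mz[chosen], representative_rt = rt[chosen],
        representative_table = table_idx[chosen],
        n_members = length(sg),
        member_medians = paste(round(medians[sg], 4), collapse = ";"),
        t = tt$t, p = tt$p, t_note = tt$note,
        stringsAsFactors = FALSE)
    }
  }

  keep <- keep[order(mz[keep], rt[keep])]
  label1 <- if (nzchar(t1$setting_label)) t1$setting_label else "setting1"
  label2 <- if (nzchar(t2$setting_label)) t2$setting_label else "setting2"
  merged <- feature_table(mz[keep], rt[keep],
                          intens[keep, , drop = FALSE], ref,
                          paste(label1, "u", label2))
  report <- structure(list(
    n_input_features = c(n_features(t1), n_features(t2)),
    n_pooled = length(mz),
    n_subgroups = n_subgroups,
    n_unique_passthrough = n_singleton,
    n_redundant_collapsed = length(collapses),
    n_t_split = n_tsplit,
    n_output = length(keep),
    collapses = if (length(collapses)) do.call(rbind, collapses)
                else data.frame()
  ), class = "merge_report")
  list(table = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("merge_report: inputs ",
      paste(x$n_input_features, collapse = " + "),
      " -> ", x$n_output, " features\n",
      "  sub-groups: ", x$n_subgroups,
      " (", x$n_unique_passthrough, " unique, ",
      x$n_redundant_collapsed, " collapsed, ",
      x$n_t_split, " kept distinct by t-test)\n", sep = "")
  invisible(x)
}

#' Write a merge report as delimited text plus a log
#'
#' @param report a `merge_report` from [merge_results()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Paths written, invisibly.
#' @export
write_merge_report <- function(report, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "merge_collapses.tsv"))
  if (nrow(report$collapses)) {
    utils::write.table(report$collapses, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste("representative_mz", "representative_rt",
                     "representative_table", "n_members", "member_medians",
                     "t", "p", "t_note", sep = "\t"), p1)
  }
  p2 <- file.path(dir, paste0(prefix, "merge_log.txt"))
  writeLines(c(
    paste("input features:", paste(report$n_input_features,
                                   collapse = " + ")),
    paste("pooled:", report$n_pooled),
    paste("sub-groups:", report$n_subgroups),
    paste("unique pass-through:", report$n_unique_passthrough),
    paste("redundant collapsed:", report$n_redundant_collapsed),
    paste("kept distinct by t-test:", report$n_t_split),
    paste("output features:", report$n_output)), p2)
  invisible(c(p1, p2))
}
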