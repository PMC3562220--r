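#' Percent intensity difference between two replicate intensities
#'
#' PID is the percent ratio of the absolute intensity difference to the mean
#' intensity: `100 * |a - b| / ((a + b) / 2)`. It is symmetric,
#' scale-invariant and bounded by \[0, 200\]; 0 means perfect agreement, 200
#' means one replicate saw nothing at all.
#'
#' @param a,b nonnegative intensities (vectorized).
#' @return PID in percent; `NA` where both intensities are zero (the metric
#'   is undefined there and such pairs are excluded upstream).
#' @examples
#' pid(100, 300)  # 100
#' pid(0, 5)      # 200
#' @export
pid <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE))
    stop("pid: intensities must be nonnegative")
  out <- 200 * abs(a - b) / (a + b)
  out[(a + b) == 0] <- NA_real_
  out
}

#' Coefficient of variation of replicate intensities, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation, the standard reproducibility measure for designs with three or
#' more analytical replicates.
#'
#' @param values numeric vector of at least two observed intensities.
#' @return CV in percent; `NA` if the mean is zero (metric undefined).
#' @examples
#' cv(c(2, 4, 6))  # 50
#' @export
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("cv: at least 2 observed values required, got ", length(values))
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Per-feature reproducibility summaries (PID or CV)
#'
#' For every feature, the reproducibility metric is computed within each
#' biological sample over that sample's analytical replicates, skipping
#' samples in which any replicate intensity is missing. With exactly two
#' replicates per sample the metric is PID; with three or more it is CV. The
#' per-sample values are then condensed to the six-number summary (min, Q1,
#' median, mean, Q3, max; quartiles by linear interpolation, the `summary()`
#' convention) that drives downstream filtering and representative selection.
#'
#' @param ft a [feature_table()].
#' @param design a [replicate_design()] covering the table's profiles; every
#'   biological sample must carry the same replicate count `r >= 2`.
#' @return A data.frame of class `feature_quality` with columns `mz`, `time`,
#'   `n_samples_used`, `min`, `q1`, `median`, `mean`, `q3`, `max`, and
#'   attributes `metric_kind` (`"PID"` or `"CV"`) and `per_sample` (features
#'   x samples metric matrix). Features with no evaluable sample have an
#'   all-`NA` summary row.
#' @export
evaluate_features <- function(ft, design) {
  design <- check_design(design, ft, min_replicates = 2)
  idx <- sample_index(design)
  r <- lengths(idx)
  if (length(unique(r)) > 1)
    stop("configuration error: replicate counts differ across samples: ",
         paste(sprintf("%s=%d", names(r), r), collapse = ", "),
         " (a uniform design is required)")
  r <- r[[1]]
  kind <- if (r == 2) "PID" else "CV"
  n <- n_features(ft)
  per_sample <- matrix(NA_real_, n, length(idx),
                       dimnames = list(NULL, names(idx)))
  for (s in seq_along(idx)) {
    cols <- ft$intensities[, idx[[s]], drop = FALSE]
    complete <- rowSums(is.na(cols)) == 0
    if (!any(complete)) next
    if (r == 2) {
      per_sample[complete, s] <- pid(cols[complete, 1], cols[complete, 2])
    } else {
      per_sample[complete, s] <-
        apply(cols[complete, , drop = FALSE], 1, cv)
    }
  }
  summ <- t(apply(per_sample, 1, six_number))
  out <- data.frame(mz = ft$mz, time = ft$rt,
                    n_samples_used = rowSums(!is.na(per_sample)))
  out <- cbind(out, as.data.frame(summ))
  attr(out, "metric_kind") <- kind
  attr(out, "per_sample") <- per_sample
  class(out) <- c("feature_quality", "data.frame")
  out
}

# min, Q1, median, mean, Q3, max over the non-missing values; all-NA input
# yields an all-NA row (feature had no evaluable sample).
six_number <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(c(min = NA_real_, q1 = NA_real_, median = NA_real_,
             mean = NA_real_, q3 = NA_real_, max = NA_real_))
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], mean = mean(x), q3 = q[4],
    max = q[5])
}

#' Per-sample reproducibility: mean pairwise Pearson correlation
#'
#' For each biological sample with at least two analytical replicates, the
#' Pearson correlation of replicate intensity vectors is computed over the
#' complete features (features with no missing value in any profile of the
#' table) for every unordered replicate pair, then averaged. Replicate
#' vectors with zero variance over the complete features make Pearson r
#' undefined; such pairs are excluded from the mean and counted.
#'
#' @param ft a [feature_table()].
#' @param design a [replicate_design()].
#' @param log2_intensities correlate `log2(intensity)` instead of raw
#'   intensities (complete features only, so no zeros are present under the
#'   default missing convention).
#' @return A data.frame of class `sample_quality` with columns `sample_id`,
#'   `n_replicates`, `mean_pairwise_correlation`, `n_pairs_used`,
#'   `n_pairs_undefined`, and attribute `n_complete_features`. If fewer than
#'   3 complete features exist, correlations are `NA` and the attribute
#'   `reason` explains why.
#' @export
evaluate_samples <- function(ft, design, log2_intensities = FALSE) {
  design <- check_design(design, ft, min_replicates = 2)
  idx <- sample_index(design)
  complete <- rowSums(is.na(ft$intensities)) == 0
  n_complete <- sum(complete)
  out <- data.frame(sample_id = names(idx),
                    n_replicates = unname(lengths(idx)),
                    mean_pairwise_correlation = NA_real_,
                    n_pairs_used = 0L, n_pairs_undefined = 0L,
                    stringsAsFactors = FALSE)
  attr(out, "n_complete_features") <- n_complete
  if (n_complete < 3) {
    attr(out, "reason") <- paste0(
      "quality unavailable: only ", n_complete,
      " feature(s) complete across all profiles (need >= 3)")
    class(out) <- c("sample_quality", "data.frame")
    return(out)
  }
  x <- ft$intensities[complete, , drop = FALSE]
  if (log2_intensities) x <- log2(x)
  for (s in seq_along(idx)) {
    cols <- idx[[s]]
    rs <- c(); undef <- 0L
    for (i in seq_along(cols)[-length(cols)]) {
      for (j in seq((i + 1), length(cols))) {
        a <- x[, cols[i]]; b <- x[, cols[j]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          undef <- undef + 1L
        } else {
          rs <- c(rs, stats::cor(a, b))
        }
      }
    }
    out$mean_pairwise_correlation[s] <-
      if (length(rs)) mean(rs) else NA_real_
    out$n_pairs_used[s] <- length(rs)
    out$n_pairs_undefined[s] <- undef
  }
  class(out) <- c("sample_quality", "data.frame")
  out
}

#' Drop biological samples below a replicate-correlation threshold
#'
#' Removes all profile columns of biological samples whose mean pairwise
#' replicate correlation falls below `samp_filt_thresh` (strictly below, the
#' usual "r < 0.7" quality cut). `NA` disables the filter.
#'
#' @param ft a [feature_table()].
#' @param design a [replicate_design()].
#' @param qualities result of [evaluate_samples()] on this table/design.
#' @param samp_filt_thresh correlation threshold in \[-1, 1\], or `NA` to
#'   disable.
#' @return List with elements `table` (reduced [feature_table()]), `design`
#'   (reduced design) and `dropped` (character vector of dropped sample ids).
#' @export
filter_samples <- function(ft, design, qualities, samp_filt_thresh = 0.7) {
  if (is.na(samp_filt_thresh))
    return(list(table = ft, design = design, dropped = character()))
  bad <- qualities$sample_id[
    !is.na(qualities$mean_pairwise_correlation) &
      qualities$mean_pairwise_correlation < samp_filt_thresh]
  if (!length(bad))
    return(list(table = ft, design = design, dropped = character()))
  keep_profiles <- design$profile_id[!design$sample_id %in% bad]
  if (!length(keep_profiles))
    stop("empty result: every biological sample fell below the ",
         "correlation threshold ", samp_filt_thresh)
  ft2 <- subset_profiles(ft, keep_profiles)
  d2 <- design[design$profile_id %in% keep_profiles, , drop = FALSE]
  rownames(d2) <- NULL
  message("filter_samples: dropped ", length(bad), " sample(s): ",
          paste(bad, collapse = ", "))
  list(table = ft2,
       design = structure(d2, class = c("replicate_design", "data.frame")),
       dropped = bad)
}

#' Retain features whose median reproducibility metric beats a threshold
#'
#' Keeps features with median PID (or CV) strictly below
#' `feat_filt_thresh` percent, preserving row order. Features whose summary
#' is unavailable (no evaluable sample) are dropped when the filter is
#' active. `NA` disables the filter.
#'
#' @param ft a [feature_table()].
#' @param qualities result of [evaluate_features()] on this table.
#' @param feat_filt_thresh percent threshold (e.g. 30), or `NA` to disable.
#' @return The filtered [feature_table()].
#' @export
filter_features <- function(ft, qualities, feat_filt_thresh = 30) {
  if (is.na(feat_filt_thresh)) return(ft)
  if (nrow(qualities) != n_features(ft))
    stop("qualities were not computed on this table (",
         nrow(qualities), " vs ", n_features(ft), " features)")
  keep <- !is.na(qualities$median) & qualities$median < feat_filt_thresh
  if (!any(keep))
    warning("filter_features: no feature passed the threshold ",
            feat_filt_thresh, "%; returning an empty table")
  subset_features(ft, keep)
}

#' Write per-sample and per-feature quality reports
#'
#' @param sample_q result of [evaluate_samples()] (or `NULL` to skip).
#' @param feature_q result of [evaluate_features()] (or `NULL` to skip).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_quality_reports <- function(sample_q, feature_q, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(sample_q)) {
    p <- file.path(dir, paste0(prefix, "sample_quality.tsv"))
    utils::write.table(
      data.frame(sample_id = sample_q$sample_id,
                 n_replicates = sample_q$n_replicates,
                 mean_r = round(sample_q$mean_pairwise_correlation, 6)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(feature_q)) {
    p <- file.path(dir, paste0(prefix, "feature_quality.tsv"))
    d <- data.frame(mz = sprintf("%.7f", feature_q$mz),
                    time = sprintf("%.4f", feature_q$time),
                    metric_kind = attr(feature_q, "metric_kind"))
    d <- cbind(d, round(feature_q[, c("min", "q1", "median", "mean",
                                      "q3", "max")], 4))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
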