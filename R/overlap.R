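#' Matching configuration for cross-dataset feature comparison
#'
#' @param mz_thresh_ppm m/z matching threshold in ppm. The ppm difference of
#'   a candidate pair is referenced to the smaller of the two m/z values, so
#'   matching is symmetric in the two lists.
#' @param time_thresh_s retention time threshold in seconds, or `NA` to
#'   match on m/z alone.
#' @return An object of class `match_config`.
#' @export
match_config <- function(mz_thresh_ppm = 5, time_thresh_s = NA) {
  stopifnot(mz_thresh_ppm > 0)
  if (!is.na(time_thresh_s) && time_thresh_s <= 0)
    stop("time_thresh_s must be > 0 or NA (disabled)")
  structure(list(mz_thresh_ppm = mz_thresh_ppm,
                 time_thresh_s = time_thresh_s),
            class = "match_config")
}

#' Find features shared by two feature lists
#'
#' Reports every pair `(i in L1, j in L2)` whose m/z values agree within
#' `mz_thresh_ppm` (ppm referenced to the smaller m/z) and, unless the time
#' threshold is disabled, whose retention times agree within
#' `time_thresh_s`. Many-to-many matches are all reported.
#'
#' @param l1,l2 data.frames with columns `mz` and `time` (a
#'   [feature_table()] is accepted and converted).
#' @param config a [match_config()].
#' @return List of class `match_result`: `pairs` (data.frame `index1`,
#'   `index2`, `mz1`, `time1`, `mz2`, `time2`, `ppm_error`, `rt_diff`),
#'   `unique1`, `unique2` (integer indices with no match in the other list).
#' @export
find_overlapping_mzs <- function(l1, l2, config = match_config()) {
  l1 <- as_mz_frame(l1); l2 <- as_mz_frame(l2)
  n1 <- nrow(l1); n2 <- nrow(l2)
  pairs <- list()
  if (n1 && n2) {
    # sort L2 by mz, scan a ppm window per L1 feature
    ord2 <- order(l2$mz)
    mz2s <- l2$mz[ord2]
    for (i in seq_len(n1)) {
      m <- l1$mz[i]
      # window generous enough for either reference convention
      tol <- config$mz_thresh_ppm * 1e-6 * max(m, max(mz2s))
      lo <- findInterval(m - tol, mz2s) + 1L
      hi <- findInterval(m + tol, mz2s)
      if (lo > hi) next
      for (j in ord2[lo:hi]) {
        dppm <- abs(m - l2$mz[j]) / min(m, l2$mz[j]) * 1e6
        if (dppm > config$mz_thresh_ppm) next
        drt <- abs(l1$time[i] - l2$time[j])
        if (!is.na(config$time_thresh_s) && drt > config$time_thresh_s)
          next
        pairs[[length(pairs) + 1L]] <-
          c(i, j, l1$mz[i], l1$time[i], l2$mz[j], l2$time[j], dppm, drt)
      }
    }
  }
  pairs <- if (length(pairs)) {
    d <- as.data.frame(do.call(rbind, pairs))
    names(d) <- c("index1", "index2", "mz1", "time1", "mz2", "time2",
                  "ppm_error", "rt_diff")
    d[order(d$index1, d$index2), , drop = FALSE]
  } else {
    data.frame(index1 = integer(), index2 = integer(), mz1 = numeric(),
               time1 = numeric(), mz2 = numeric(), time2 = numeric(),
               ppm_error = numeric(), rt_diff = numeric())
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unique1 = setdiff(seq_len(n1), pairs$index1),
                 unique2 = setdiff(seq_len(n2), pairs$index2)),
            class = "match_result")
}

as_mz_frame <- function(x) {
  if (inherits(x, "feature_table"))
    return(data.frame(mz = x$mz, time = x$rt))
  stopifnot(is.data.frame(x), all(c("mz", "time") %in% names(x)))
  x[, c("mz", "time")]
}

#' Find features unique to each of two feature lists
#'
#' The complement of [find_overlapping_mzs()] per list: features with no
#' counterpart in the other list within the configured thresholds.
#'
#' @inheritParams find_overlapping_mzs
#' @return List with `unique1` and `unique2`, data.frames of the unmatched
#'   features (columns `index`, `mz`, `time`).
#' @export
find_unique_mzs <- function(l1, l2, config = match_config()) {
  l1 <- as_mz_frame(l1); l2 <- as_mz_frame(l2)
  m <- find_overlapping_mzs(l1, l2, config)
  list(unique1 = data.frame(index = m$unique1, mz = l1$mz[m$unique1],
                            time = l1$time[m$unique1]),
       unique2 = data.frame(index = m$unique2, mz = l2$mz[m$unique2],
                            time = l2$time[m$unique2]))
}

#' Venn region counts for two or three feature lists
#'
#' Each feature of each dataset is assigned to the Venn region of all
#' datasets in which it has at least one match (always including its own),
#' so region counts are feature counts, not match counts, and each
#' dataset's regions sum to that dataset's feature count. `counts` gives a
#' single consolidated number per region: the maximum of the contributing
#' datasets' own tallies for that region (for identical lists A = B this
#' yields |A| in the intersection, not 2|A|).
#'
#' @param datasets named list of 2 or 3 feature lists (data.frames with
#'   `mz`/`time` or [feature_table()]s).
#' @param config a [match_config()].
#' @return List of class `venn_counts`: `counts` (named numeric, regions
#'   like `"A"`, `"A&B"`), `per_dataset` (matrix datasets x regions whose
#'   rows sum to the dataset sizes) and `sizes`.
#' @export
venn_counts <- function(datasets, config = match_config()) {
  k <- length(datasets)
  if (k < 2 || k > 3)
    stop("unsupported: venn_counts takes 2 or 3 datasets, got ", k)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- LETTERS[seq_len(k)]
  nm <- names(datasets)
  frames <- lapply(datasets, as_mz_frame)
  sizes <- vapply(frames, nrow, 0L)

  # membership[[d]][i, e]: does feature i of dataset d match dataset e?
  membership <- lapply(seq_len(k), function(d) {
    m <- matrix(FALSE, nrow(frames[[d]]), k, dimnames = list(NULL, nm))
    m[, d] <- TRUE
    for (e in seq_len(k)[-d]) {
      res <- find_overlapping_mzs(frames[[d]], frames[[e]], config)
      m[unique(res$pairs$index1), e] <- TRUE
    }
    m
  })

  regions <- region_labels(nm)
  per_dataset <- matrix(0L, k, length(regions),
                        dimnames = list(nm, regions))
  for (d in seq_len(k)) {
    if (!nrow(membership[[d]])) next
    lab <- apply(membership[[d]], 1, function(r)
      paste(nm[r], collapse = "&"))
    tab <- table(lab)
    per_dataset[d, names(tab)] <- as.integer(tab)
  }
  counts <- apply(per_dataset, 2, max)
  structure(list(counts = counts, per_dataset = per_dataset,
                 sizes = sizes),
            class = "venn_counts")
}

region_labels <- function(nm) {
  k <- length(nm)
  labs <- character()
  for (size in seq_len(k)) {
    combos <- utils::combn(nm, size, simplify = FALSE)
    labs <- c(labs, vapply(combos, paste, "", collapse = "&"))
  }
  labs
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("venn_counts over", length(x$sizes), "datasets:\n")
  print(x$counts)
  invisible(x)
}

#' Write Venn counts as JSON
#'
#' @param vc a `venn_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(vc, path) {
  jsonlite::write_json(
    list(sizes = as.list(x_named(vc$sizes)),
         counts = as.list(x_named(vc$counts)),
         per_dataset = apply(vc$per_dataset, 1, function(r)
           as.list(x_named(r)), simplify = FALSE)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

x_named <- function(v) stats::setNames(as.vector(v), names(v))

#' Configuration for rare-feature detection
#'
#' @param min_samps minimum number of biological samples in which the
#'   feature must satisfy the replicate-presence rule.
#' @param min_reps minimum percentage (0-100] of a sample's analytical
#'   replicates in which the feature must be observed; the required
#'   replicate count is `ceiling(min_reps/100 * r)`.
#' @return An object of class `rare_feature_config`.
#' @export
rare_feature_config <- function(min_samps = 1, min_reps = 100) {
  stopifnot(min_samps >= 1, min_reps > 0, min_reps <= 100)
  structure(list(min_samps = min_samps, min_reps = min_reps),
            class = "rare_feature_config")
}

#' Features consistently present within individual samples
#'
#' Identifies rare features — present in only some biological samples but in
#' most analytical replicates of those samples, the signature of an
#' individual-specific exposure rather than noise. A feature qualifies in a
#' sample when it is observed (non-missing) in at least
#' `ceiling(min_reps/100 * r)` of the sample's `r` replicates; it is
#' retained when it qualifies in at least `min_samps` samples.
#'
#' @param ft a [feature_table()].
#' @param design a [replicate_design()].
#' @param config a [rare_feature_config()].
#' @return The retained features as a [feature_table()], with attribute
#'   `indices` giving their row positions in the input.
#' @export
check_mz_in_replicates <- function(ft, design,
                                   config = rare_feature_config()) {
  design <- check_design(design, ft)
  idx <- sample_index(design)
  qualifies <- matrix(FALSE, n_features(ft), length(idx))
  for (s in seq_along(idx)) {
    r <- length(idx[[s]])
    need <- ceiling(config$min_reps / 100 * r)
    obs <- rowSums(!is.na(ft$intensities[, idx[[s]], drop = FALSE]))
    qualifies[, s] <- obs >= need
  }
  keep <- which(rowSums(qualifies) >= config$min_samps)
  out <- subset_features(ft, keep)
  attr(out, "indices") <- keep
  out
}

#' Write match results as delimited text
#'
#' @param match a `match_result` from [find_overlapping_mzs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_result <- function(match, path) {
  d <- match$pairs
  out <- data.frame(mz_1 = sprintf("%.7f", d$mz1),
                    time_1 = sprintf("%.4f", d$time1),
                    mz_2 = sprintf("%.7f", d$mz2),
                    time_2 = sprintf("%.4f", d$time2),
                    ppm_error = sprintf("%.4f", d$ppm_error),
                    rt_diff = sprintf("%.4f", d$rt_diff))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
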