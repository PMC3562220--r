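#' Construct a feature table
#'
#' A feature table is the standard exchange object of untargeted LC/MS
#' post-processing: one row per detected feature (an ion characterized by its
#' mass-to-charge ratio and chromatographic retention time) and one intensity
#' column per LC/MS profile (injection). Missing intensities are stored as
#' `NA`; the zero-vs-missing convention of upstream extractors is resolved at
#' the I/O boundary (see [read_feature_table()]).
#'
#' @param mz numeric vector of mass-to-charge ratios, all `> 0`.
#' @param rt numeric vector of retention times in seconds, all `>= 0`.
#' @param intensities numeric matrix, `length(mz)` rows by
#'   `length(profile_ids)` columns; values `>= 0` or `NA` (missing).
#' @param profile_ids character vector of unique profile (injection) labels.
#' @param setting_label free-text tag identifying the extraction setting that
#'   produced the table, e.g. `"min.run=3,min.pres=0.3"`.
#' @return An object of class `feature_table`.
#' @examples
#' ft <- feature_table(
#'   mz = c(100.0021, 250.1333), rt = c(50, 300),
#'   intensities = matrix(c(1e5, 2e5, 1.1e5, NA), nrow = 2),
#'   profile_ids = c("S1a", "S1b")
#' )
#' n_features(ft)
#' @export
feature_table <- function(mz, rt, intensities, profile_ids,
                          setting_label = "") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  colnames(intensities) <- profile_ids
  rownames(intensities) <- NULL
  ft <- structure(
    list(mz = as.numeric(mz), rt = as.numeric(rt),
         intensities = intensities,
         profile_ids = as.character(profile_ids),
         setting_label = as.character(setting_label)[1]),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate a feature table
#'
#' Checks every structural invariant of the class and stops with a
#' row/column-addressed message on the first violation.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  n <- length(ft$mz)
  if (length(ft$rt) != n)
    stop("feature table: mz and rt lengths differ (", n, " vs ",
         length(ft$rt), ")")
  if (!is.matrix(ft$intensities) || nrow(ft$intensities) != n)
    stop("feature table: intensity matrix must have one row per feature")
  if (ncol(ft$intensities) != length(ft$profile_ids))
    stop("feature table: ", ncol(ft$intensities),
         " intensity columns for ", length(ft$profile_ids), " profile ids")
  if (anyDuplicated(ft$profile_ids))
    stop("feature table: duplicate profile ids: ",
         paste(unique(ft$profile_ids[duplicated(ft$profile_ids)]),
               collapse = ", "))
  bad <- which(!is.finite(ft$mz) | ft$mz <= 0)
  if (length(bad))
    stop("feature table: non-positive or non-finite m/z at row ", bad[1])
  bad <- which(!is.finite(ft$rt) | ft$rt < 0)
  if (length(bad))
    stop("feature table: negative or non-finite retention time at row ",
         bad[1])
  neg <- which(ft$intensities < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("feature table: negative intensity at row ", neg[1, 1],
         ", column '", ft$profile_ids[neg[1, 2]], "'")
  invisible(ft)
}

#' @rdname feature_table
#' @param ft a `feature_table`.
#' @export
n_features <- function(ft) length(ft$mz)

#' @rdname feature_table
#' @export
n_profiles <- function(ft) length(ft$profile_ids)

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", n_features(x), " features x ", n_profiles(x),
      " profiles", sep = "")
  if (nzchar(x$setting_label)) cat("  [", x$setting_label, "]", sep = "")
  cat("\n")
  if (n_features(x)) {
    cat("  m/z ", format(min(x$mz), digits = 7), "-",
        format(max(x$mz), digits = 7),
        ", RT ", format(min(x$rt)), "-", format(max(x$rt)), " s, ",
        format(100 * mean(is.na(x$intensities)), digits = 3),
        "% missing\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  d <- data.frame(mz = x$mz, time = x$rt)
  cbind(d, as.data.frame(x$intensities))
}

#' Subset the features (rows) of a feature table
#'
#' @param ft a `feature_table`.
#' @param i integer or logical row index.
#' @return A `feature_table` with the selected features, profiles unchanged.
#' @export
subset_features <- function(ft, i) {
  feature_table(ft$mz[i], ft$rt[i],
                ft$intensities[i, , drop = FALSE],
                ft$profile_ids, ft$setting_label)
}

#' Subset the profiles (columns) of a feature table
#'
#' @param ft a `feature_table`.
#' @param keep character vector of profile ids (or logical/integer index).
#' @return A `feature_table` restricted to the selected profiles.
#' @export
subset_profiles <- function(ft, keep) {
  if (is.character(keep)) {
    miss <- setdiff(keep, ft$profile_ids)
    if (length(miss))
      stop("unknown profile id(s): ", paste(miss, collapse = ", "))
    keep <- match(keep, ft$profile_ids)
  }
  feature_table(ft$mz, ft$rt,
                ft$intensities[, keep, drop = FALSE],
                ft$profile_ids[keep], ft$setting_label)
}

#' Construct a replicate design
#'
#' Maps each profile (injection) column of a feature table to the biological
#' sample it was drawn from. Analytical replicates are repeated injections of
#' the same biological sample; quality metrics operate within those groups.
#'
#' @param profile_id character vector of profile labels.
#' @param sample_id character vector, same length, of biological sample ids.
#' @return An object of class `replicate_design`: a data.frame with columns
#'   `profile_id` and `sample_id`.
#' @export
replicate_design <- function(profile_id, sample_id) {
  if (length(profile_id) != length(sample_id))
    stop("replicate design: profile_id and sample_id lengths differ")
  if (anyDuplicated(profile_id))
    stop("replicate design: duplicate profile id(s): ",
         paste(unique(profile_id[duplicated(profile_id)]), collapse = ", "))
  structure(
    data.frame(profile_id = as.character(profile_id),
               sample_id = as.character(sample_id),
               stringsAsFactors = FALSE),
    class = c("replicate_design", "data.frame")
  )
}

#' Check a replicate design against a feature table
#'
#' Every profile column of the table must appear exactly once in the design.
#'
#' @param design a `replicate_design`.
#' @param ft a `feature_table`.
#' @param min_replicates minimum replicate count required per biological
#'   sample (use 2 for quality metrics).
#' @return The design restricted and reordered to the table's profiles,
#'   invisibly usable downstream.
#' @export
check_design <- function(design, ft, min_replicates = 1) {
  miss <- setdiff(ft$profile_ids, design$profile_id)
  if (length(miss))
    stop("replicate design: profile(s) missing from design: ",
         paste(miss, collapse = ", "))
  d <- design[match(ft$profile_ids, design$profile_id), , drop = FALSE]
  rownames(d) <- NULL
  reps <- table(d$sample_id)
  if (any(reps < min_replicates))
    stop("replicate design: sample(s) with fewer than ", min_replicates,
         " replicates: ",
         paste(names(reps)[reps < min_replicates], collapse = ", "))
  structure(d, class = c("replicate_design", "data.frame"))
}

#' Split profile indices by biological sample
#'
#' @param design a `replicate_design` aligned to a table (see
#'   [check_design()]).
#' @return Named list: for each sample id, the integer positions of its
#'   replicate profiles in the design's row order.
#' @keywords internal
sample_index <- function(design) {
  split(seq_len(nrow(design)), design$sample_id)
}
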