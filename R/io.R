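#' Read a feature table from delimited text
#'
#' Expects the layout written by apLCMS-style extractors and by
#' [write_feature_table()]: a header row, first column m/z, second column
#' retention time in seconds, remaining columns one intensity value per LC/MS
#' profile. The delimiter is auto-detected between tab and comma unless given.
#'
#' Extractors commonly emit `0` for features absent from a profile; by
#' default a stored `0` is interpreted as missing (`NA`). Set
#' `zero_as_missing = FALSE` to treat zeros as observed intensities.
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param zero_as_missing interpret stored 0 intensities as missing.
#' @param setting_label optional tag recorded on the returned table; defaults
#'   to the file name without extension.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, sep = NULL, zero_as_missing = TRUE,
                               setting_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(trimws(header)))
    stop("format error: empty file or blank header: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "", quote = "\"",
                         na.strings = c("NA", ""))
  if (ncol(d) < 3)
    stop("format error: expected columns mz, time and at least one profile ",
         "column, found ", ncol(d), " column(s): ", path)
  h <- tolower(names(d)[1:2])
  if (!(h[1] %in% c("mz", "m.z", "m/z")) ||
      !(h[2] %in% c("time", "rt", "retention.time")))
    stop("format error: first two columns must be 'mz' and 'time', found '",
         names(d)[1], "', '", names(d)[2], "'")
  for (j in 1:2) {
    v <- d[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad))
        stop("parse error: non-numeric ", c("m/z", "time")[j],
             " at data row ", bad[1], ": '", v[bad[1]], "'")
      d[[j]] <- suppress
    }
  }
  prof <- names(d)[-(1:2)]
  if (anyDuplicated(prof))
    stop("validation error: duplicate profile column name(s): ",
         paste(unique(prof[duplicated(prof)]), collapse = ", "))
  intens <- as.matrix(d[, -(1:2), drop = FALSE])
  if (!is.numeric(intens)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(intens), nrow = nrow(intens)))) & !is.na(intens),
      arr.ind = TRUE)
    if (nrow(bad))
      stop("parse error: non-numeric intensity at data row ", bad[1, 1],
           ", column '", prof[bad[1, 2]], "'")
    intens <- matrix(as.numeric(intens), nrow = nrow(intens),
                     dimnames = list(NULL, prof))
  }
  if (zero_as_missing) intens[intens == 0] <- NA_real_
  if (is.null(setting_label))
    setting_label <- tools::file_path_sans_ext(basename(path))
  feature_table(d[[1]], d[[2]], intens, prof, setting_label)
}

#' Write a feature table to delimited text
#'
#' Columns `mz`, `time`, then one column per profile. m/z is written with 7
#' decimal places (well below 1 ppm at m/z 85-850) and intensities in
#' scientific notation with 6 significant digits, so a read/write round trip
#' preserves the table to that precision. Missing intensities are written as
#' `0` under the default zero-as-missing convention, or as `NA` otherwise.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @param zero_as_missing write `NA` intensities as `0` (the apLCMS-style
#'   convention); if `FALSE`, write literal `NA`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, sep = "\t",
                                zero_as_missing = TRUE) {
  validate_feature_table(ft)
  intens <- ft$intensities
  cells <- matrix(sprintf("%.6g", intens), nrow = nrow(intens),
                  ncol = ncol(intens))
  cells[is.na(intens)] <- if (zero_as_missing) "0" else "NA"
  d <- data.frame(mz = sprintf("%.7f", ft$mz),
                  time = sprintf("%.4f", ft$rt),
                  stringsAsFactors = FALSE)
  for (j in seq_along(ft$profile_ids)) d[[2 + j]] <- cells[, j]
  names(d) <- c("mz", "time", ft$profile_ids)
  ok <- tryCatch({
    utils::write.table(d, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a replicate design from two-column delimited text
#'
#' Columns `profile_id` and `sample_id`, header optional (detected).
#'
#' @param path path to the design file.
#' @param sep delimiter; auto-detected between tab and comma when `NULL`.
#' @return A [replicate_design()].
#' @export
read_replicate_design <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("profile", tolower(first))
  d <- utils::read.table(path, header = has_header, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "")
  if (ncol(d) < 2)
    stop("format error: replicate design needs two columns (profile_id, ",
         "sample_id): ", path)
  replicate_design(d[[1]], d[[2]])
}

#' Write a replicate design
#'
#' @param design a [replicate_design()].
#' @param path output path.
#' @param sep delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_replicate_design <- function(design, path, sep = "\t") {
  utils::write.table(design, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
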