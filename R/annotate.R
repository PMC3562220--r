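# Exact particle/molecule masses in unified atomic mass units
# (CODATA-consistent); the single source of truth for adduct arithmetic.
PROTON_MASS <- 1.00727646677
WATER_MASS <- 18.0105646863
SODIUM_MASS <- 22.9897692820   # atomic Na
HYDROGEN_MASS <- 1.0078250319  # atomic H
NH4_MASS <- 18.0338254        # NH4+ neutral-equivalent (N + 4H)
POTASSIUM_MASS <- 38.9637064864

#' Built-in adduct registry
#'
#' Each adduct maps a neutral monoisotopic mass `M` to an observed m/z via
#' `(M + offset) / charge`. The registry covers the common positive-mode
#' protonated forms (M+H and its water losses) plus sodium, ammonium,
#' potassium and the deprotonated negative-mode form.
#'
#' @return data.frame with columns `name`, `offset` (u) and `charge`.
#' @export
adduct_registry <- function() {
  data.frame(
    name = c("M", "M+H", "M+H-H2O", "M+H-2H2O", "M+Na", "M+NH4", "M+K",
             "M-H"),
    offset = c(0,
               PROTON_MASS,
               PROTON_MASS - WATER_MASS,
               PROTON_MASS - 2 * WATER_MASS,
               SODIUM_MASS - HYDROGEN_MASS + PROTON_MASS,
               NH4_MASS - HYDROGEN_MASS + PROTON_MASS,
               POTASSIUM_MASS - HYDROGEN_MASS + PROTON_MASS,
               -PROTON_MASS),
    charge = 1,
    stringsAsFactors = FALSE)
}

#' Theoretical m/z of an adduct of a neutral compound
#'
#' @param m neutral monoisotopic mass in u, `> 0` (vectorized).
#' @param adduct adduct name present in [adduct_registry()], e.g. `"M+H"`.
#' @return Theoretical m/z, `(M + offset) / charge`.
#' @examples
#' adduct_mz(180.06339, "M+H")      # hexose [M+H]+ = 181.07066
#' adduct_mz(180.06339, "M+H-H2O")  # in-source water loss = 163.06010
#' @export
adduct_mz <- function(m, adduct) {
  stopifnot(all(m > 0))
  reg <- adduct_registry()
  k <- match(adduct, reg$name)
  if (is.na(k))
    stop("unknown adduct '", adduct, "'; registry has: ",
         paste(reg$name, collapse = ", "))
  (m + reg$offset[k]) / reg$charge[k]
}

#' Read a local compound database
#'
#' TSV with columns `id`, `name`, `monoisotopic_mass` and optional
#' external-identifier columns (`kegg_id`, `hmdb_id`, `pubchem_cid`,
#' `chebi_id`, `cas`, `lipidmaps_id`), carried through to annotation
#' reports as opaque strings. A small bundled demo database is available
#' via `system.file("extdata", "demo_compound_db.tsv", package =
#' "mzmerge")`.
#'
#' @param path path to the TSV.
#' @return data.frame of class `compound_db`.
#' @export
read_compound_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  need <- c("id", "name", "monoisotopic_mass")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("compound database missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(d$monoisotopic_mass) | d$monoisotopic_mass <= 0))
    stop("compound database: non-positive monoisotopic mass at row ",
         which(!is.finite(d$monoisotopic_mass) |
                 d$monoisotopic_mass <= 0)[1])
  class(d) <- c("compound_db", "data.frame")
  d
}

#' Annotate m/z values against a local compound database
#'
#' For every query m/z, reports every (compound, adduct) combination whose
#' theoretical m/z lies within `ppm_thresh` of the query, ppm referenced to
#' the query m/z (the window `query * (1 +/- ppm * 1e-6)` brackets the
#' candidate masses). Queries with no hit are listed as unannotated. The
#' search is a sorted binary search over the expanded (compound x adduct)
#' mass list; it is exactly equivalent to exhaustive pairwise search.
#'
#' @param mz numeric vector of query m/z values.
#' @param db a [read_compound_db()] data.frame (or any data.frame with
#'   `id`, `name`, `monoisotopic_mass`).
#' @param adducts character vector of adduct names from
#'   [adduct_registry()].
#' @param ppm_thresh matching threshold in ppm, `> 0`.
#' @return List of class `annotation_result`: `hits` (data.frame `query_mz`,
#'   `adduct`, `id`, `name`, `theoretical_mz`, `ppm_error`, plus any
#'   external-id columns of `db`) and `unannotated` (queries with no hit).
#' @export
batch_annotate <- function(mz, db, adducts = c("M+H", "M+H-H2O"),
                           ppm_thresh = 5) {
  stopifnot(ppm_thresh > 0, nrow(db) >= 1)
  extra <- setdiff(names(db), c("id", "name", "monoisotopic_mass"))
  # expand compound x adduct once, sort by theoretical m/z
  theo <- do.call(rbind, lapply(adducts, function(a)
    data.frame(adduct = a, row = seq_len(nrow(db)),
               theoretical_mz = adduct_mz(db$monoisotopic_mass, a),
               stringsAsFactors = FALSE)))
  theo <- theo[order(theo$theoretical_mz), , drop = FALSE]
  hits <- list()
  for (q in mz) {
    tol <- ppm_thresh * 1e-6 * q
    lo <- findInterval(q - tol, theo$theoretical_mz) + 1L
    hi <- findInterval(q + tol, theo$theoretical_mz)
    if (lo > hi) next
    sel <- theo[lo:hi, , drop = FALSE]
    h <- data.frame(query_mz = q, adduct = sel$adduct,
                    id = db$id[sel$row], name = db$name[sel$row],
                    theoretical_mz = sel$theoretical_mz,
                    ppm_error = (q - sel$theoretical_mz) / q * 1e6,
                    stringsAsFactors = FALSE)
    for (col in extra) h[[col]] <- db[[col]][sel$row]
    hits[[length(hits) + 1L]] <- h
  }
  hits <- if (length(hits)) do.call(rbind, hits) else {
    h <- data.frame(query_mz = numeric(), adduct = character(),
                    id = character(), name = character(),
                    theoretical_mz = numeric(), ppm_error = numeric(),
                    stringsAsFactors = FALSE)
    for (col in extra) h[[col]] <- character()
    h
  }
  rownames(hits) <- NULL
  structure(list(hits = hits,
                 unannotated = setdiff(mz, hits$query_mz),
                 ppm_thresh = ppm_thresh, adducts = adducts),
            class = "annotation_result")
}

#' Write an annotation report (text or HTML)
#'
#' The text report is a TSV of the hit table followed by the unannotated
#' queries; the HTML report renders the same hit set as a standalone table
#' with external-database identifiers turned into hyperlinks. Both are
#' deterministic for a given result.
#'
#' @param result an `annotation_result` from [batch_annotate()].
#' @param path output path.
#' @param format `"text"` or `"html"`.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(result, path,
                                    format = c("text", "html")) {
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    d <- result$hits
    d$query_mz <- sprintf("%.7f", d$query_mz)
    d$theoretical_mz <- sprintf("%.7f", d$theoretical_mz)
    d$ppm_error <- sprintf("%.4f", d$ppm_error)
    utils::write.table(d, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(result$unannotated)) {
      writeLines("", con)
      writeLines("# unannotated queries", con)
      writeLines(sprintf("# %.7f", result$unannotated), con)
    }
    return(invisible(path))
  }
  writeLines(annotation_html(result), path)
  invisible(path)
}

link_templates <- c(
  kegg_id = "https://www.genome.jp/dbget-bin/www_bget?cpd:%s",
  hmdb_id = "https://hmdb.ca/metabolites/%s",
  pubchem_cid = "https://pubchem.ncbi.nlm.nih.gov/compound/%s",
  chebi_id = "https://www.ebi.ac.uk/chebi/searchId.do?chebiId=%s",
  lipidmaps_id = "https://www.lipidmaps.org/databases/lmsd/%s")

annotation_html <- function(result) {
  d <- result$hits
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cols <- names(d)
  head_row <- paste0("<tr>", paste0("<th>", esc(cols), "</th>",
                                    collapse = ""), "</tr>")
  fmt_cell <- function(col, v) {
    if (col %in% names(link_templates) && nzchar(v) && !is.na(v))
      return(sprintf("<a href=\"%s\">%s</a>",
                     sprintf(link_templates[[col]], esc(v)), esc(v)))
    if (col %in% c("query_mz", "theoretical_mz"))
      return(sprintf("%.7f", as.numeric(v)))
    if (col == "ppm_error") return(sprintf("%.4f", as.numeric(v)))
    esc(as.character(v))
  }
  body <- vapply(seq_len(nrow(d)), function(i) {
    cells <- vapply(cols, function(cl) {
      v <- d[[cl]][i]
      paste0("<td>", fmt_cell(cl, if (is.na(v)) "" else v), "</td>")
    }, "")
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, "")
  un <- if (length(result$unannotated)) {
    c("<h2>Unannotated queries</h2>", "<ul>",
      sprintf("<li>%.7f</li>", result$unannotated), "</ul>")
  } else character()
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>m/z annotation report</title>",
    "<style>table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px}</style></head><body>",
    sprintf("<h1>m/z annotation report (%g ppm; adducts: %s)</h1>",
            result$ppm_thresh, esc(paste(result$adducts,
                                         collapse = ", "))),
    "<table>", head_row, body, "</table>", un, "</body></html>")
}
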