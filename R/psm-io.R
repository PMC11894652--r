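#' Read a tab-delimited PSM table
#'
#' Reads peptide-spectrum matches (PSMs) from a tab-separated file such as a
#' Crux `tide-search` output, and returns a tidy tibble with one row per match.
#' Scores are oriented so that *higher is better* throughout the package; if
#' your score is an E-value or p-value (lower is better), set
#' `negate_scores = TRUE`.
#'
#' Rows whose score does not parse as a finite number are dropped with a
#' warning reporting how many were rejected.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param role Role of every match in the table: `"sample"` (target matches of
#'   the sample spectra), `"entrapment"` (matches of foreign-organism query
#'   spectra against the same search space), or `"decoy"`.
#' @param column_map Named character vector mapping the fields `spectrum`,
#'   `peptide` and `score` to column names in the file. Defaults follow Crux
#'   `tide-search` conventions.
#' @param negate_scores If `TRUE`, scores are negated on input so that higher
#'   is better.
#'
#' @return A tibble with columns `spectrum_id` (character), `peptide`
#'   (character, the modified-sequence key), `score` (double, higher is
#'   better) and `role` (character).
#' @seealso [peptide_rollup()], [write_psm_table()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("scan\tsequence\txcorr score",
#'              "1\tPEPTIDEK\t3.1",
#'              "2\tLESSK\t1.4"), tf)
#' read_psm_table(tf, role = "sample")
read_psm_table <- function(path,
                           role = c("sample", "entrapment", "decoy"),
                           column_map = c(spectrum = "scan",
                                          peptide = "sequence",
                                          score = "xcorr score"),
                           negate_scores = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop("PSM table not found: ", path, call. = FALSE)
  }
  needed <- c("spectrum", "peptide", "score")
  missing_keys <- setdiff(needed, names(column_map))
  if (length(missing_keys) > 0) {
    stop("column_map must name columns for: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  absent <- setdiff(unname(column_map[needed]), names(tbl))
  if (length(absent) > 0) {
    stop("Column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) {
    stop("PSM table is empty: ", path, call. = FALSE)
  }
  score_raw <- suppressWarnings(as.numeric(tbl[[column_map[["score"]]]]))
  ok <- is.finite(score_raw)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " row(s) with unparseable scores rejected from ",
            path, call. = FALSE)
  }
  out <- tibble::tibble(
    spectrum_id = as.character(tbl[[column_map[["spectrum"]]]])[ok],
    peptide = as.character(tbl[[column_map[["peptide"]]]])[ok],
    score = if (negate_scores) -score_raw[ok] else score_raw[ok],
    role = role
  )
  out
}

#' Write a PSM table to a tab-separated file
#'
#' Writes the `spectrum_id`, `peptide` and `score` columns of a PSM tibble,
#' using the same column-name mapping accepted by [read_psm_table()] so that a
#' read/write/read round trip preserves the records exactly.
#'
#' @param psms A tibble as returned by [read_psm_table()].
#' @param path Output file path.
#' @inheritParams read_psm_table
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path,
                            column_map = c(spectrum = "scan",
                                           peptide = "sequence",
                                           score = "xcorr score")) {
  stopifnot(all(c("spectrum_id", "peptide", "score") %in% names(psms)))
  out <- tibble::tibble(a = psms$spectrum_id, b = psms$peptide,
                        c = format(psms$score, digits = 17, trim = TRUE,
                                   scientific = FALSE))
  names(out) <- unname(column_map[c("spectrum", "peptide", "score")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Collapse PSMs to one best match per peptide
#'
#' Peptide-level rollup: for each distinct peptide key (the modified sequence
#' exactly as given; no I/L equivalence) only the top-scoring PSM is retained.
#' Ties within a peptide are broken by first occurrence in input order, so the
#' operation is deterministic and idempotent.
#'
#' @param psms A tibble with at least `peptide` and `score` columns.
#' @return A tibble with one row per distinct peptide, in order of each kept
#'   record's first appearance.
#' @export
#' @examples
#' psms <- tibble::tibble(spectrum_id = c("1", "2", "3"),
#'                        peptide = c("A", "A", "B"),
#'                        score = c(3, 2, 1.5), role = "sample")
#' peptide_rollup(psms)
peptide_rollup <- function(psms) {
  stopifnot(all(c("peptide", "score") %in% names(psms)))
  if (nrow(psms) == 0) {
    return(psms)
  }
  psms |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::slice(which.max(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}
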