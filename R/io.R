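## Tabular I/O. All pipeline tables are TSV with a header; numeric fields are
## written with enough digits to round-trip exactly through read.delim.

read_tsv_checked <- function(path, required, integer_cols = character()) {
  if (!file.exists(path)) abort_parse("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_parse(path, ": missing required columns: ", paste(missing, collapse = ", "))
  for (col in integer_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val != floor(val) | val < 0)
    if (length(bad))
      abort_parse(path, ": line ", bad[1] + 1L, ": column '", col,
                  "' must be a non-negative integer, got '", raw[bad[1]], "'")
    df[[col]] <- as.integer(val)
  }
  df
}

#' Read a known-editing-site table
#'
#' Expects a TSV with header columns `transcript_id`, `position`, `ref_base`
#' and optionally `in_vivo_level` (fraction in `[0, 1]`). Rows whose reference
#' base is not `"A"` and duplicated sites are rejected with an error.
#'
#' @param path path to the TSV file.
#' @return A validated `editing_sites` data.frame.
#' @seealso [validate_sites()]
#' @export
read_site_table <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "position", "ref_base"),
                         integer_cols = "position")
  if ("in_vivo_level" %in% names(df)) {
    lvl <- suppressWarnings(as.numeric(df$in_vivo_level))
    bad <- which(!is.na(df$in_vivo_level) & df$in_vivo_level != "" & is.na(lvl))
    if (length(bad))
      abort_parse(path, ": line ", bad[1] + 1L, ": unparseable in_vivo_level '",
                  df$in_vivo_level[bad[1]], "'")
    df$in_vivo_level <- lvl
  }
  bad <- which(df$ref_base != "A")
  if (length(bad))
    abort_parse(path, ": line ", bad[1] + 1L,
                ": ref_base must be 'A', got '", df$ref_base[bad[1]], "'")
  validate_sites(df)
}

#' Read a per-sample per-site base-count table
#'
#' Expects a TSV with header `transcript_id`, `position`, `sample_id`,
#' `a_count`, `c_count`, `g_count`, `t_count`. Counts must be non-negative
#' integers; duplicate (site, sample) rows are an error, never summed.
#'
#' @param path path to the TSV file.
#' @return A validated `site_base_counts` data.frame.
#' @export
read_count_table <- function(path) {
  df <- read_tsv_checked(path, COUNT_COLS,
                         integer_cols = c("position", "a_count", "c_count",
                                          "g_count", "t_count"))
  validate_counts(df)
}

#' Write a result table as TSV
#'
#' Serializes any pipeline result data.frame (differential results, detection
#' results, levels, counts, truth tables) to a tab-separated file with a
#' header. Doubles are printed with 17 significant digits so that
#' [read_results_table()] reproduces them bit-identically.
#'
#' @param results a data.frame; an empty one yields a header-only file.
#' @param path output path; its directory must exist.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results)) abort_validation("results must not be NULL")
  if (!dir.exists(dirname(path))) abort_parse("cannot write to ", path,
                                              ": directory does not exist")
  out <- as.data.frame(results)
  for (col in names(out)) {
    x <- out[[col]]
    if (is.double(x)) out[[col]] <- sprintf("%.17g", x)
    if (is.logical(x)) out[[col]] <- ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a TSV written by [write_results_table()]
#'
#' @param path path to the TSV file.
#' @return A data.frame with column types inferred (integers stay integer,
#'   17-digit doubles round-trip exactly).
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) abort_parse("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (col in names(df)) {
    if (is.character(df[[col]]))
      df[[col]] <- type.convert(df[[col]], as.is = TRUE)
  }
  df
}
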