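## samtools text-pileup reader. Only the classic 6-column layout is needed:
## chrom, pos (1-based), ref, depth, base string, base-quality string.
##
## Base-string dialect handled here:
##   . ,            match to the reference base (either read strand)
##   ACGTN acgtn    explicit base calls
##   ^X             read start; X encodes mapping quality, not a base
##   $              read end marker
##   +N<seq> -N<seq> insertion/deletion following the current call
##   * #            placeholder for a deleted base (consumes a quality char)
##   < >            reference skip (consumes a quality char)

parse_pileup_bases <- function(bases, quals, ref) {
  n <- nchar(bases)
  chars <- if (n) strsplit(bases, "", fixed = TRUE)[[1]] else character()
  qn <- nchar(quals)
  calls <- character(qn)
  call_q <- integer(qn)
  k <- 0L  # quality index consumed so far
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # skip the mapping-quality character too
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # indel sequence carries no quality entries
    } else {
      k <- k + 1L
      if (k > qn)
        abort_parse("malformed pileup: base/quality string length mismatch ",
                    "(more calls than qualities)")
      base <- switch(ch, "." = ref, "," = ref, toupper(ch))
      calls[k] <- base
      call_q[k] <- utf8ToInt(substr(quals, k, k)) - 33L
      i <- i + 1L
    }
  }
  if (k != qn)
    abort_parse("malformed pileup: base/quality string length mismatch (",
                k, " calls vs ", qn, " qualities)")
  list(calls = calls, quals = call_q)
}

#' Convert a text pileup to quality-filtered base counts
#'
#' Walks a samtools text pileup (chrom, 1-based position, reference base,
#' depth, base string, base-quality string) and, for each listed editing site
#' present in the pileup, counts the A/C/G/T calls whose Phred base quality is
#' at least `qc$min_base_quality`. Positions not in the site list are skipped;
#' read start/end markers, indels and deletion placeholders are handled per the
#' pileup dialect. `N` calls and deletion/skip placeholders consume a quality
#' character but are never counted.
#'
#' @param pileup_lines character vector of pileup lines, or a path to a pileup
#'   file (detected via `file.exists`).
#' @param sites an `editing_sites` table (see [validate_sites()]); the pileup
#'   `chrom` column is matched against `transcript_id`.
#' @param sample_id sample identifier stamped on the output rows.
#' @param qc a [quality_filter_config()]; only `min_base_quality` is applied
#'   here (mapping quality acts upstream, when the pileup is produced).
#' @return A `site_base_counts` data.frame with one row per covered site.
#' @export
counts_from_pileup <- function(pileup_lines, sites, sample_id = "sample",
                               qc = quality_filter_config()) {
  sites <- validate_sites(sites)
  if (length(pileup_lines) == 1 && !grepl("\t", pileup_lines) &&
      file.exists(pileup_lines))
    pileup_lines <- readLines(pileup_lines)
  wanted <- site_key(sites$transcript_id, sites$position)
  rows <- list()
  for (lineno in seq_along(pileup_lines)) {
    line <- pileup_lines[lineno]
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      abort_parse("pileup line ", lineno, ": expected >= 4 tab-separated fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) abort_parse("pileup line ", lineno, ": bad position '", f[2], "'")
    key <- site_key(f[1], pos)
    if (!key %in% wanted) next
    bases <- if (length(f) >= 5) f[5] else ""
    quals <- if (length(f) >= 6) f[6] else ""
    parsed <- tryCatch(parse_pileup_bases(bases, quals, toupper(f[3])),
                       axonedit_parse_error = function(e)
                         abort_parse("pileup line ", lineno, ": ", conditionMessage(e)))
    keep <- parsed$quals >= qc$min_base_quality
    calls <- parsed$calls[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = f[1], position = pos, sample_id = sample_id,
      a_count = sum(calls == "A"), c_count = sum(calls == "C"),
      g_count = sum(calls == "G"), t_count = sum(calls == "T"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript_id = character(), position = integer(),
                         sample_id = character(), a_count = integer(),
                         c_count = integer(), g_count = integer(),
                         t_count = integer(), stringsAsFactors = FALSE)
  validate_counts(out)
}
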