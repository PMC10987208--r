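#' MAPseq taxonomy-assignment parsing and taxon matching
#'
#' MAPseq-style files are tab-delimited, one read (or contig) per line:
#' the first column is the read label and one of the later columns carries
#' a `;`-separated taxonomic lineage whose tokens may bear rank prefixes
#' (`sk__`, `g__`, `s__`, ...) and use underscores for spaces
#' (`s__Lecudina_longissima`). Lines starting with `#` are comments.
#' The right-most tab field containing a `;` is taken as the lineage.
#'
#' @name mapseq
NULL

#' Normalize one lineage rank token
#'
#' Strips a leading `<letters>__` rank prefix, maps underscores to spaces,
#' trims, and lowercases.  A token that is empty after stripping (a bare
#' `"p__"`) normalizes to `NA_character_`.  The function is idempotent.
#'
#' @param token Character vector of raw lineage tokens.
#' @return Character vector of normalized tokens; `NA` where empty.
#' @examples
#' normalize_rank_token("s__Lecudina_longissima")  # "lecudina longissima"
#' normalize_rank_token("p__")                     # NA
#' @export
normalize_rank_token <- function(token) {
  out <- sub("^[A-Za-z]+__", "", token)
  out <- gsub("_", " ", out, fixed = TRUE)
  out <- tolower(trimws(out))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Parse a MAPseq assignment file
#'
#' Reads every non-comment, non-blank line into one record: the read label
#' (column 1), the normalized lineage tokens, and the 1-based line number.
#' Malformed lines (no label) are tallied, never fatal: files of hundreds
#' of thousands of reads must not abort on one bad row.
#'
#' @param path Path to a MAPseq file, plain or gzip-compressed.
#' @return A list with `records` (list of `list(query_label, lineage,
#'   raw_line_no)`) and `n_malformed` (count of skipped malformed lines).
#' @export
parse_mapseq_file <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  parse_mapseq_lines(readLines(con, warn = FALSE))
}

# core line-list parser; shared by file and in-memory callers
parse_mapseq_lines <- function(lines) {
  records <- vector("list", length(lines))
  n_rec <- 0L
  n_malformed <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    label <- trimws(fields[[1L]])
    if (!nzchar(label) || grepl("\\s", label)) {
      n_malformed <- n_malformed + 1L
      next
    }
    lineage <- character(0)
    lineage_fields <- which(grepl(";", fields, fixed = TRUE))
    if (length(lineage_fields) > 0L) {
      raw <- strsplit(fields[[max(lineage_fields)]], ";", fixed = TRUE)[[1L]]
      lineage <- normalize_rank_token(raw)
      lineage <- lineage[!is.na(lineage)]
    }
    n_rec <- n_rec + 1L
    records[[n_rec]] <- list(
      query_label = label,
      lineage = lineage,
      raw_line_no = i
    )
  }
  list(records = records[seq_len(n_rec)], n_malformed = n_malformed)
}

#' Does a lineage match a taxon query?
#'
#' Matching is exact on normalized tokens, never substring, so
#' `"lecudina"` never matches `"paralecudina"`.  A monomial query matches
#' if some lineage token equals the query token or some token's first word
#' equals it (the genus prefix rule: `"lecudina"` matches
#' `"lecudina longissima"`).  A binomial query matches only if some single
#' token equals the two-word form, so a genus-only lineage does not match
#' a binomial query.
#'
#' @param query A [taxon_query][parse_taxon_query].
#' @param lineage Character vector of normalized lineage tokens.
#' @return `TRUE` or `FALSE`.
#' @export
lineage_matches <- function(query, lineage) {
  if (length(lineage) == 0L) return(FALSE)
  if (query$rank_hint == "binomial") {
    return(query_comparison_form(query) %in% lineage)
  }
  target <- query$tokens[[1L]]
  if (target %in% lineage) return(TRUE)
  first_words <- sub(" .*$", "", lineage)
  target %in% first_words
}

#' Collect read labels classified as the query taxon
#'
#' Streams a MAPseq file in fixed-size line chunks and returns the set of
#' read labels whose lineage matches the query; memory is proportional to
#' the number of matches, not the file size.
#'
#' @param path Path to a MAPseq file, plain or gzip.
#' @param query A [taxon_query][parse_taxon_query].
#' @param chunk_size Lines read per chunk.
#' @return A list with `labels` (unique matching labels, first-seen
#'   order), `match_count` (matching lines), `n_lines` (assignment lines
#'   scanned) and `n_malformed`.
#' @export
collect_matching_labels <- function(path, query, chunk_size = 4096L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  labels <- character(0)
  match_count <- 0L
  n_lines <- 0L
  n_malformed <- 0L
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    parsed <- parse_mapseq_lines(lines)
    n_malformed <- n_malformed + parsed$n_malformed
    n_lines <- n_lines + length(parsed$records)
    for (rec in parsed$records) {
      if (lineage_matches(query, rec$lineage)) {
        match_count <- match_count + 1L
        labels <- c(labels, rec$query_label)
      }
    }
    offset <- offset + length(lines)
  }
  list(
    labels = unique(labels),
    match_count = match_count,
    n_lines = n_lines,
    n_malformed = n_malformed
  )
}
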