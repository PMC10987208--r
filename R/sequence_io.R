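#' FASTA/FASTQ reading and label-based extraction
#'
#' Readers accept plain or gzip-compressed files.  A record's label is the
#' header token up to the first whitespace; the remainder of the header is
#' kept as the description.  Pair suffixes such as `/1`/`/2` are not
#' stripped — MAPseq labels are assumed to match the sequence file they
#' were computed from, and any mismatch surfaces in the missing-label
#' report rather than being papered over.
#'
#' @name sequence_io
NULL

#' Read sequence records from a FASTA or FASTQ file
#'
#' FASTA supports multi-line (wrapped) sequences; FASTQ is strict 4-line
#' records whose quality string must match the sequence length (qualities
#' are then discarded — the pipeline's terminal product is FASTA).
#' Iteration order is file order; base case is preserved.
#'
#' @param path Path to the file, plain or gzip.
#' @param format `"fasta"` or `"fastq"`.
#' @return List of `sequence_record`s: `label`, `description` (`NA` if
#'   none), `bases`.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (format == "fasta") parse_fasta_lines(lines) else parse_fastq_lines(lines)
}

parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0L || headers[[1L]] != 1L) {
    stop("malformed fasta: sequence data before first '>' header",
         call. = FALSE)
  }
  ends <- c(headers[-1L] - 1L, length(lines))
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    header <- sub("^>", "", lines[[headers[[i]]]])
    body <- lines[seq.int(headers[[i]] + 1L, length.out = ends[[i]] - headers[[i]])]
    out[[i]] <- new_sequence_record(header, paste(body, collapse = ""))
  }
  out
}

parse_fastq_lines <- function(lines) {
  while (length(lines) > 0L && !nzchar(lines[[length(lines)]])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 4L != 0L) {
    stop("malformed fastq at record ", length(lines) %/% 4L + 1L,
         ": truncated 4-line record", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- lines[seq.int((k - 1L) * 4L + 1L, length.out = 4L)]
    if (!startsWith(block[[1L]], "@") || !startsWith(block[[3L]], "+")) {
      stop("malformed fastq at record ", k, ": bad record delimiters",
           call. = FALSE)
    }
    if (nchar(block[[2L]]) != nchar(block[[4L]])) {
      stop("malformed fastq at record ", k,
           ": sequence and quality lengths differ", call. = FALSE)
    }
    out[[k]] <- new_sequence_record(sub("^@", "", block[[1L]]), block[[2L]])
  }
  out
}

new_sequence_record <- function(header, bases) {
  header <- trimws(header)
  label <- sub("\\s.*$", "", header)
  description <- if (grepl("\\s", header)) {
    trimws(sub("^\\S+\\s+", "", header))
  } else {
    NA_character_
  }
  if (!nzchar(label)) stop("sequence record with empty label", call. = FALSE)
  structure(list(label = label, description = description, bases = bases),
            class = "sequence_record")
}

#' Extract the records whose labels are wanted
#'
#' Yields records with `label` in `wanted`, preserving file order, and
#' reports per-file counts: `found + missing == length(wanted)` always.
#' Wanted labels absent from the file are reported, never an error.
#'
#' @param records List of `sequence_record`s (from [read_sequences()]).
#' @param wanted Character vector of wanted labels.
#' @return List with `records` (the extracted subset), `found`,
#'   `missing`, and `missing_labels`.
#' @export
extract_by_labels <- function(records, wanted) {
  wanted <- unique(as.character(wanted))
  if (length(wanted) == 0L) {
    return(list(records = list(), found = 0L, missing = 0L,
                missing_labels = character(0)))
  }
  labels <- vapply(records, `[[`, character(1), "label")
  keep <- labels %in% wanted
  present <- wanted %in% labels
  list(
    records = records[keep],
    found = sum(present),
    missing = sum(!present),
    missing_labels = wanted[!present]
  )
}

#' Write sequence records as wrapped FASTA
#'
#' Sixty-column body wrap; header is `>label description` (description
#' omitted when absent).  The file is written atomically: a partially
#' written file never appears under the final name.
#'
#' @param records List of `sequence_record`s.
#' @param path Output path.
#' @param width Wrap width in bases.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(records, path, width = 60L) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  con <- file(tmp, open = "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  for (rec in records) {
    header <- if (is.na(rec$description)) rec$label
      else paste(rec$label, rec$description)
    writeLines(paste0(">", header), con)
    n <- nchar(rec$bases)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(rec$bases, starts, pmin(starts + width - 1L, n)), con)
  }
  ok <- TRUE
  invisible(length(records))
}
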