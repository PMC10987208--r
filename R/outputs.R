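#' Aggregated outputs: master FASTA, occurrence CSV, annotation, coverage
#'
#' Extracted reads from all occurrences are gathered into one master
#' FASTA whose headers are prefixed with the source occurrence id, linked
#' row-for-row to `occurrences.csv`.  Identical bases appearing under
#' different occurrences are retained — each occurrence's evidence stands
#' alone, and deduplication would destroy the locality linkage that is
#' the point of the tool.
#'
#' @name outputs
NULL

#' Build a unique output label for a linked sequence
#'
#' `<occurrence_id>_<source_label>`; a collision with an already-used
#' label appends `.2`, `.3`, ... in order of appearance.
#'
#' @param occurrence_id Positive integer occurrence key.
#' @param source_label Read label from the source file.
#' @param used Character vector of labels already emitted in this run.
#' @return A single label string.
#' @export
make_output_label <- function(occurrence_id, source_label, used = character(0)) {
  stopifnot(nzchar(source_label), occurrence_id > 0)
  base <- paste0(occurrence_id, "_", source_label)
  if (!(base %in% used)) return(base)
  k <- 2L
  while (paste0(base, ".", k) %in% used) k <- k + 1L
  paste0(base, ".", k)
}

# bind extracted records of one occurrence into linked_sequence objects,
# keeping labels unique across the whole run via the `used` accumulator
link_sequences <- function(occurrence_id, records, used = character(0)) {
  linked <- vector("list", length(records))
  for (i in seq_along(records)) {
    lab <- make_output_label(occurrence_id, records[[i]]$label, used)
    used <- c(used, lab)
    linked[[i]] <- structure(
      list(occurrence_id = occurrence_id,
           source_label = records[[i]]$label,
           output_label = lab,
           bases = records[[i]]$bases),
      class = "linked_sequence"
    )
  }
  list(linked = linked, used = used)
}

#' Write the master FASTA of linked sequences
#'
#' One record per linked sequence, in the order given (occurrence order,
#' then file order).  Headers are the occurrence-prefixed output labels.
#'
#' @param linked List of `linked_sequence` objects.
#' @param path Output path (conventionally `seq_master.FASTA`).
#' @return Number of records written.
#' @export
write_master_fasta <- function(linked, path) {
  records <- lapply(linked, function(x) {
    new_sequence_record(x$output_label, x$bases)
  })
  write_fasta(records, path)
  length(linked)
}

#' Write the occurrence metadata table
#'
#' Header row plus one row per occurrence: `occurrence_id`,
#' `scientific_name`, `decimal_latitude`, `decimal_longitude`, `country`,
#' `n_sequences`, `had_ngs_ssu`.  Absent values serialize as empty fields
#' (never `0`); RFC 4180 quoting, UTF-8.
#'
#' @param records List of [occurrence_record][parse_occurrence_payload]s.
#' @param report A `project_report` (see [build_report()]).
#' @param path Output path (conventionally `occurrences.csv`).
#' @return Number of data rows written.
#' @export
write_occurrences_csv <- function(records, report, path) {
  per_occ <- report$per_occurrence
  counts <- stats::setNames(per_occ$n_sequences, per_occ$occurrence_id)
  had <- stats::setNames(per_occ$had_ngs_ssu, per_occ$occurrence_id)
  df <- data.frame(
    occurrence_id = vapply(records, `[[`, integer(1), "occurrence_id"),
    scientific_name = vapply(records, `[[`, character(1), "scientific_name"),
    decimal_latitude = vapply(records, `[[`, numeric(1), "decimal_latitude"),
    decimal_longitude = vapply(records, `[[`, numeric(1), "decimal_longitude"),
    country = vapply(records, `[[`, character(1), "country"),
    stringsAsFactors = FALSE
  )
  key <- as.character(df$occurrence_id)
  df$n_sequences <- ifelse(is.na(counts[key]), 0L, counts[key])
  df$had_ngs_ssu <- ifelse(is.na(had[key]), FALSE, had[key])
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  nrow(df)
}

#' Annotate master-FASTA headers with occurrence metadata
#'
#' Appends the requested CSV columns, joined with `|`, to each header,
#' looked up by the header's occurrence-id prefix.  `|` is FASTA-header
#' safe and absent from read labels, which also lets re-annotation of an
#' already annotated file be detected and refused.  Sequence bodies are
#' untouched.
#'
#' @param master_path Path to the master FASTA.
#' @param csv_path Path to the occurrence CSV.
#' @param fields Ordered character vector of CSV column names to append;
#'   empty means "annotate nothing" and copies the file unchanged.
#' @param out_path Output path; default inserts `.annotated` before the
#'   extension.
#' @return The output path, invisibly.
#' @export
annotate_fasta <- function(master_path, csv_path, fields,
                           out_path = NULL) {
  if (is.null(out_path)) {
    out_path <- sub("(\\.[^.]+)$", ".annotated\\1", master_path)
    if (identical(out_path, master_path)) {
      out_path <- paste0(master_path, ".annotated")
    }
  }
  if (length(fields) == 0L) {
    file.copy(master_path, out_path, overwrite = TRUE)
    return(invisible(out_path))
  }
  meta <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                          colClasses = c(occurrence_id = "character"))
  unknown <- setdiff(fields, names(meta))
  if (length(unknown) > 0L) {
    stop("unknown annotation field(s): ", paste(unknown, collapse = ", "),
         "; available columns: ", paste(names(meta), collapse = ", "),
         call. = FALSE)
  }
  records <- read_sequences(master_path, "fasta")
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (grepl("|", rec$label, fixed = TRUE)) {
      stop("refusing to annotate an already annotated file (header '",
           rec$label, "' contains '|')", call. = FALSE)
    }
    occ <- sub("_.*$", "", rec$label)
    row <- match(occ, meta$occurrence_id)
    if (is.na(row)) {
      stop("occurrence id ", occ, " (record '", rec$label,
           "') not present in ", csv_path, call. = FALSE)
    }
    values <- vapply(fields, function(f) {
      v <- meta[[f]][row]
      if (is.na(v)) "" else as.character(v)
    }, character(1))
    out[[i]] <- structure(
      list(label = paste(c(rec$label, values), collapse = "|"),
           description = rec$description, bases = rec$bases),
      class = "sequence_record"
    )
  }
  write_fasta(out, out_path)
  invisible(out_path)
}

#' Assemble the project report
#'
#' @param records List of occurrence records searched.
#' @param per_occurrence Data frame with columns `occurrence_id`,
#'   `n_sequences`, `had_ngs_ssu` (had both a fetched sequence file and a
#'   fetched MAPseq file, regardless of match success).
#' @return A `project_report` with `n_occurrences`, `n_with_ngs_ssu`,
#'   `n_sequences`, `per_occurrence`, `proportion_with_data`.
#' @export
build_report <- function(records, per_occurrence) {
  n_occ <- length(records)
  n_with <- sum(per_occurrence$had_ngs_ssu)
  structure(
    list(
      n_occurrences = n_occ,
      n_with_ngs_ssu = n_with,
      n_sequences = sum(per_occurrence$n_sequences),
      per_occurrence = per_occurrence,
      proportion_with_data = if (n_occ > 0) n_with / n_occ else 0
    ),
    class = "project_report"
  )
}

#' @export
print.project_report <- function(x, ...) {
  cat("<project_report>\n")
  cat("  occurrences searched:     ", x$n_occurrences, "\n")
  cat("  with NGS SSU data:        ", x$n_with_ngs_ssu,
      sprintf(" (%.1f%%)", 100 * x$proportion_with_data), "\n", sep = "")
  cat("  sequences extracted:      ", x$n_sequences, "\n")
  invisible(x)
}

#' Render the occurrence-coverage summary
#'
#' Writes a bar plot of occurrences with and without next-generation SSU
#' data, plus a machine-readable JSON sidecar carrying `n_occurrences`,
#' `n_with_ngs_ssu` and `proportion_with_data`.  The sidecar is the
#' stable, testable surface; the image is for humans.
#'
#' @param report A `project_report`.
#' @param path Output image path (`.png`); the sidecar takes the same
#'   path with extension `.json`.
#' @return The image path, invisibly.
#' @export
render_coverage_plot <- function(report, path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(
      n_occurrences = report$n_occurrences,
      n_with_ngs_ssu = report$n_with_ngs_ssu,
      proportion_with_data = report$proportion_with_data
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  grDevices::png(path, width = 720, height = 540)
  on.exit(grDevices::dev.off())
  if (report$n_occurrences == 0L) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no occurrences", cex = 1.6)
    graphics::title("Occurrence coverage")
  } else {
    counts <- c(
      `with NGS SSU data` = report$n_with_ngs_ssu,
      `without` = report$n_occurrences - report$n_with_ngs_ssu
    )
    graphics::barplot(
      counts, col = c("steelblue", "grey80"),
      main = sprintf(
        "Occurrence coverage: %d of %d (%.1f%%) link to NGS SSU data",
        report$n_with_ngs_ssu, report$n_occurrences,
        100 * report$proportion_with_data),
      ylab = "occurrences"
    )
  }
  invisible(path)
}
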