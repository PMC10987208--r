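# Independent reference implementations used as oracles.  These share no
# code with the package: they re-derive the same contracts by the most
# naive route available, so agreement is evidence, not tautology.

# naive lineage-token matcher: explicit loops, no vectorized tricks
naive_lineage_match <- function(query_tokens, lineage) {
  if (length(lineage) == 0L) return(FALSE)
  if (length(query_tokens) == 2L) {
    target <- paste(query_tokens[1], query_tokens[2])
    for (tok in lineage) if (identical(tok, target)) return(TRUE)
    return(FALSE)
  }
  for (tok in lineage) {
    if (identical(tok, query_tokens[1])) return(TRUE)
    words <- strsplit(tok, " ", fixed = TRUE)[[1]]
    if (length(words) > 0L && identical(words[1], query_tokens[1])) return(TRUE)
  }
  FALSE
}

# naive parse-everything-then-filter reference for MAPseq matching:
# materializes all lines, independent field handling
naive_collect_labels <- function(lines, query_tokens) {
  out <- character(0)
  for (line in lines) {
    if (line == "" || substr(line, 1, 1) == "#") next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    label <- fields[1]
    if (label == "" || grepl("[[:space:]]", label)) next
    lineage <- character(0)
    for (f in rev(fields)) {
      if (grepl(";", f, fixed = TRUE)) {
        toks <- strsplit(f, ";", fixed = TRUE)[[1]]
        toks <- sub("^[A-Za-z]+__", "", toks)
        toks <- tolower(trimws(gsub("_", " ", toks)))
        lineage <- toks[toks != ""]
        break
      }
    }
    if (naive_lineage_match(query_tokens, lineage)) out <- c(out, label)
  }
  unique(out)
}

# random MAPseq content with matching reads, adversarial decoys, junk and
# malformed lines; returns the line vector (ground truth comes from the
# naive reference, not from construction)
random_mapseq_lines <- function(n_lines, genus = "Lecudina",
                                species = "longissima") {
  pool <- c(
    sprintf("sk__Eukaryota;p__Apicomplexa;g__%s", genus),
    sprintf("sk__Eukaryota;p__Apicomplexa;g__%s;s__%s_%s", genus, genus, species),
    sprintf("sk__Eukaryota;g__%s;s__%s_sibling", genus, genus),
    sprintf("sk__Eukaryota;g__Para%s;s__Para%s_%s", genus, genus, species),
    sprintf("sk__Eukaryota;g__%sella;s__%sella_minor", genus, genus),
    sprintf("sk__Eukaryota;g__%s;s__%s_%sforma", genus, genus, species),
    "sk__Bacteria;p__Proteobacteria;g__Vibrio;s__Vibrio_harveyi",
    "sk__Eukaryota;p__;g__;s__"
  )
  lines <- character(n_lines)
  for (i in seq_len(n_lines)) {
    r <- runif(1)
    if (r < 0.05) {
      lines[i] <- "# comment line"
    } else if (r < 0.08) {
      lines[i] <- ""
    } else if (r < 0.11) {
      lines[i] <- sprintf("read_%04d\tno_lineage_here\t0.99", i)
    } else if (r < 0.13) {
      lines[i] <- "\tmalformed\tsk__X;g__Y"  # empty label
    } else {
      lines[i] <- sprintf("read_%04d\tref_%03d\t%.3f\t%s",
                          i, sample.int(999, 1), runif(1, 0.8, 1),
                          sample(pool, 1))
    }
  }
  lines
}

# write lines to a plain or gzipped temp file, returning the path
write_lines_maybe_gz <- function(lines, gz = FALSE, ext = ".mseq") {
  path <- tempfile(fileext = paste0(ext, if (gz) ".gz"))
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

# random FASTA / FASTQ content as a list(lines, labels)
random_sequence_lines <- function(n_records, format = "fasta") {
  labels <- sprintf("seq_%04d", sample.int(99999L, n_records))
  lines <- character(0)
  for (lab in labels) {
    len <- sample(20:120, 1)
    bases <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    if (format == "fasta") {
      # wrap some records to exercise multi-line bodies
      if (runif(1) < 0.5) {
        starts <- seq.int(1L, len, by = 31L)
        body <- substring(bases, starts, pmin(starts + 30L, len))
      } else {
        body <- bases
      }
      lines <- c(lines, paste0(">", lab, " desc=", len), body)
    } else {
      lines <- c(lines, paste0("@", lab, " desc=", len), bases, "+",
                 paste(rep("F", len), collapse = ""))
    }
  }
  list(lines = lines, labels = labels)
}

# small complete fixture + pipeline run in fresh temp dirs
run_fixture_pipeline <- function(taxon, seed, n_occurrences = 6,
                                 p_with_resources = 0.5, ...) {
  fx <- tempfile("fx")
  proj <- tempfile("proj")
  manifest <- generate_fixture(taxon, fx, n_occurrences = n_occurrences,
                               p_with_resources = p_with_resources,
                               seed = seed, ...)
  report <- suppressWarnings(
    run_pipeline(proj, taxon, transport = fixture_transport(fx)))
  list(fixture = fx, project = proj, manifest = manifest, report = report)
}
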