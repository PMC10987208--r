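#' Generate a complete offline project fixture
#'
#' Builds a directory tree that the [fixture_transport()] can serve:
#' paginated occurrence payloads in the occurrence-search dialect,
#' per-occurrence FASTA/FASTQ files (some gzipped) and MAPseq
#' taxonomy-assignment files, plus a ground-truth `manifest.json`.
#' Exactly the manifest's `matching_labels` carry lineages containing the
#' query taxon at the query's rank; decoy reads carry adversarial
#' near-miss lineages (superstring genera like `<Genus>ella`,
#' `Para<genus>`, sibling species, and — against binomial queries —
#' genus-only lineages), guarding the exact-token matching rule.
#' Sequence bases are uniform over ACGT: biological realism is irrelevant
#' to linkage correctness, which is what the fixture tests.
#'
#' Generation is fully deterministic for a given seed: regenerating into
#' a fresh directory yields a byte-identical tree.
#'
#' @param taxon Query string or [taxon_query][parse_taxon_query].
#' @param dir Directory to create the fixture in (created if absent).
#' @param n_occurrences Number of occurrence records.
#' @param p_with_resources Fraction of occurrences carrying both a
#'   sequence file and a MAPseq file.
#' @param reads_per_occurrence Integer range (lo, hi) of taxon-matching
#'   reads per resource-bearing occurrence.
#' @param decoys_per_occurrence Integer range of near-miss decoy reads.
#' @param seed Integer RNG seed.
#' @param page_size Occurrence payloads per page file.
#' @param p_missing_coords Fraction of occurrences without coordinates.
#' @param p_gzip Fraction of resource files that are gzip-compressed.
#' @param p_fastq Fraction of sequence files in FASTQ (rest FASTA).
#' @param seq_length Range (lo, hi) of read lengths in nt.
#' @param n_seq_only Number of resource-bearing occurrences that get a
#'   sequence file but no MAPseq file (to exercise the
#'   incomplete-resource rule); taken out of the resource-bearing set.
#' @return The fixture manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
generate_fixture <- function(taxon, dir,
                             n_occurrences = 20L,
                             p_with_resources = 0.6,
                             reads_per_occurrence = c(8L, 25L),
                             decoys_per_occurrence = c(6L, 20L),
                             seed = 1L,
                             page_size = 300L,
                             p_missing_coords = 0.1,
                             p_gzip = 0.5,
                             p_fastq = 0.3,
                             seq_length = c(150L, 1800L),
                             n_seq_only = 0L) {
  if (is.character(taxon)) taxon <- parse_taxon_query(taxon)
  if (p_with_resources < 0 || p_with_resources > 1) {
    stop("p_with_resources must be a fraction in [0, 1]", call. = FALSE)
  }
  if (length(reads_per_occurrence) != 2L ||
      reads_per_occurrence[1] > reads_per_occurrence[2] ||
      reads_per_occurrence[1] < 0) {
    stop("reads_per_occurrence must be a non-negative (lo, hi) range",
         call. = FALSE)
  }
  if (length(decoys_per_occurrence) != 2L ||
      decoys_per_occurrence[1] > decoys_per_occurrence[2] ||
      decoys_per_occurrence[1] < 0) {
    stop("decoys_per_occurrence must be a non-negative (lo, hi) range",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pages"), showWarnings = FALSE)
  dir.create(file.path(dir, "resources"), showWarnings = FALSE)

  set.seed(seed)
  ids <- sample.int(899999L, n_occurrences) + 100000L
  n_with <- round(p_with_resources * n_occurrences)
  has_resources <- rep(FALSE, n_occurrences)
  if (n_with > 0) has_resources[sample.int(n_occurrences, n_with)] <- TRUE
  n_seq_only <- min(n_seq_only, n_with)
  seq_only <- rep(FALSE, n_occurrences)
  if (n_seq_only > 0) {
    seq_only[sample(which(has_resources), n_seq_only)] <- TRUE
  }

  genus <- taxon$tokens[[1L]]
  genus_cap <- paste0(toupper(substr(genus, 1, 1)), substr(genus, 2, nchar(genus)))
  sci_name <- if (taxon$rank_hint == "binomial") {
    paste(genus_cap, taxon$tokens[[2L]])
  } else {
    genus_cap
  }
  countries <- c("JP", "US", "AU", "BR", "NO", "ZA", "CL", "IN", "CA", "NZ")

  occurrences <- vector("list", n_occurrences)
  payloads <- vector("list", n_occurrences)
  expected <- 0L

  for (i in seq_len(n_occurrences)) {
    occ_id <- ids[[i]]
    missing_coords <- stats::runif(1) < p_missing_coords
    lat <- if (missing_coords) NULL else round(stats::runif(1, -90, 90), 4)
    lon <- if (missing_coords) NULL else round(stats::runif(1, -180, 180), 4)
    country <- sample(countries, 1L)

    matching_labels <- character(0)
    decoy_labels <- character(0)
    urls <- list()

    if (has_resources[[i]]) {
      n_match <- sample_range(reads_per_occurrence)
      n_decoy <- sample_range(decoys_per_occurrence)
      labels <- sprintf("ERZ%d.read_%04d", occ_id, seq_len(n_match + n_decoy))
      shuffled <- sample(labels)
      matching_labels <- shuffled[seq_len(n_match)]
      decoy_labels <- setdiff(shuffled, matching_labels)

      fmt <- if (stats::runif(1) < p_fastq) "fastq" else "fasta"
      gz <- stats::runif(1) < p_gzip
      occ_dir <- file.path(dir, "resources", occ_id)
      dir.create(occ_dir, showWarnings = FALSE)

      seq_name <- paste0("ERZ", occ_id, "_MERGED_SSU.", fmt, if (gz) ".gz")
      write_fixture_sequences(
        file.path(occ_dir, seq_name), shuffled, fmt, gz, seq_length)
      urls <- c(urls, paste0("fixture://resources/", occ_id, "/", seq_name))

      if (!seq_only[[i]]) {
        map_gz <- stats::runif(1) < p_gzip
        map_name <- paste0("ERZ", occ_id, "_MAPSEQ.mseq", if (map_gz) ".gz")
        write_fixture_mapseq(
          file.path(occ_dir, map_name), taxon, matching_labels, decoy_labels,
          map_gz)
        urls <- c(urls, paste0("fixture://resources/", occ_id, "/", map_name))
        expected <- expected + length(matching_labels)
      }
    }

    payloads[[i]] <- c(
      list(key = occ_id, scientificName = sci_name,
           basisOfRecord = "MATERIAL_SAMPLE", country = country),
      if (!is.null(lat)) list(decimalLatitude = lat, decimalLongitude = lon),
      list(associated_sequence_resources = urls)
    )
    occurrences[[i]] <- list(
      occurrence_id = occ_id,
      scientific_name = sci_name,
      has_resources = has_resources[[i]],
      seq_only = seq_only[[i]],
      matching_labels = as.list(matching_labels),
      decoy_labels = as.list(decoy_labels),
      decimal_latitude = lat,
      decimal_longitude = lon,
      country = country
    )
  }

  # page files in server (generation) order, honouring the search dialect
  n_pages <- max(1L, ceiling(n_occurrences / page_size))
  for (p in seq_len(n_pages)) {
    idx <- seq.int((p - 1L) * page_size + 1L,
                   min(p * page_size, n_occurrences))
    if (n_occurrences == 0L) idx <- integer(0)
    jsonlite::write_json(
      list(offset = (p - 1L) * page_size,
           limit = page_size,
           endOfRecords = p == n_pages,
           count = n_occurrences,
           results = payloads[idx]),
      file.path(dir, "pages", sprintf("page-%04d.json", p)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  manifest <- list(
    seed = seed,
    taxon = list(raw = taxon$raw, tokens = as.list(taxon$tokens),
                 rank_hint = taxon$rank_hint),
    n_occurrences = n_occurrences,
    n_with_resources = n_with,
    page_size = page_size,
    expected_master_count = expected,
    occurrences = occurrences
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture's ground-truth manifest
#'
#' @param dir Fixture directory.
#' @return The manifest as a nested list.
#' @export
read_fixture_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"))
}

sample_range <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  as.integer(sample(seq.int(range[1], range[2]), 1L))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fixture_sequences <- function(path, labels, format, gz, seq_length) {
  con <- if (gz) gzfile(path, open = "wb") else file(path, open = "wb")
  lines <- character(0)
  for (lab in labels) {
    len <- sample_range(seq_length)
    bases <- random_bases(len)
    if (format == "fasta") {
      starts <- seq.int(1L, len, by = 60L)
      lines <- c(lines, paste0(">", lab, " len=", len),
                 substring(bases, starts, pmin(starts + 59L, len)))
    } else {
      qual <- paste(rep("I", len), collapse = "")
      lines <- c(lines, paste0("@", lab, " len=", len), bases, "+", qual)
    }
  }
  writeLines(lines, con)
  close(con)
  invisible(path)
}

# lineages: matching reads carry the taxon at the query rank; decoys carry
# adversarial near-misses that exact-token matching must reject
write_fixture_mapseq <- function(path, taxon, matching_labels, decoy_labels,
                                 gz) {
  genus <- taxon$tokens[[1L]]
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  genus_cap <- cap(genus)
  species <- if (taxon$rank_hint == "binomial") taxon$tokens[[2L]] else "sp1"

  match_lineages <- if (taxon$rank_hint == "binomial") {
    # must carry the exact binomial as a single species token
    c(sprintf("sk__Eukaryota;p__Phylum1;c__Class1;g__%s;s__%s_%s",
              genus_cap, genus_cap, species),
      sprintf("sk__Eukaryota;p__Phylum1;g__%s;s__%s_%s",
              genus_cap, genus_cap, species))
  } else {
    # genus token, or a species of the genus (matched via the genus rule)
    c(sprintf("sk__Eukaryota;p__Phylum1;c__Class1;g__%s", genus_cap),
      sprintf("sk__Eukaryota;p__Phylum1;g__%s;s__%s_speciesa",
              genus_cap, genus_cap),
      sprintf("sk__Eukaryota;g__%s;s__%s_speciesb", genus_cap, genus_cap))
  }
  decoy_lineages <- c(
    # superstring genus: <Genus>ella
    sprintf("sk__Eukaryota;p__Phylum1;g__%sella;s__%sella_minor",
            genus_cap, genus_cap),
    # superstring prefix genus: Para<genus>
    sprintf("sk__Eukaryota;p__Phylum1;g__Para%s;s__Para%s_%s",
            genus, genus, species),
    # unrelated lineage
    "sk__Bacteria;p__Proteobacteria;g__Vibrio;s__Vibrio_harveyi",
    # empty-rank tail
    sprintf("sk__Eukaryota;p__Phylum1;g__%sella;s__", genus_cap)
  )
  if (taxon$rank_hint == "binomial") {
    decoy_lineages <- c(
      decoy_lineages,
      # genus-only: must not match a binomial query
      sprintf("sk__Eukaryota;p__Phylum1;g__%s", genus_cap),
      # sibling species of the same genus
      sprintf("sk__Eukaryota;p__Phylum1;g__%s;s__%s_sibling",
              genus_cap, genus_cap),
      # superstring species epithet
      sprintf("sk__Eukaryota;p__Phylum1;g__%s;s__%s_%sforma",
              genus_cap, genus_cap, species)
    )
  }

  all_labels <- c(matching_labels, decoy_labels)
  lineages <- c(
    if (length(matching_labels) > 0)
      sample(match_lineages, length(matching_labels), replace = TRUE),
    if (length(decoy_labels) > 0)
      sample(decoy_lineages, length(decoy_labels), replace = TRUE)
  )
  ord <- sample.int(length(all_labels))
  lines <- c(
    "#query\tdbhit\tidentity\ttaxonomy",
    sprintf("%s\tref_%04d\t%.3f\t%s",
            all_labels[ord],
            sample.int(9999L, length(all_labels), replace = TRUE),
            round(stats::runif(length(all_labels), 0.80, 1.00), 3),
            lineages[ord])
  )
  con <- if (gz) gzfile(path, open = "wb") else file(path, open = "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
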