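test_that("output labels concatenate id and read label, dodging collisions", {
  expect_equal(make_output_label(101, "readA"), "101_readA")
  used <- "101_readA"
  second <- make_output_label(101, "readA", used)
  expect_equal(second, "101_readA.2")
  third <- make_output_label(101, "readA", c(used, second))
  expect_equal(third, "101_readA.3")
})

test_that("linked labels stay unique over many random collisions", {
  set.seed(19)
  used <- character(0)
  labels <- character(300)
  for (i in 1:300) {
    lab <- make_output_label(sample(5:7, 1),
                             sample(c("a", "b", "c"), 1), used)
    labels[i] <- lab
    used <- c(used, lab)
  }
  expect_equal(anyDuplicated(labels), 0)
  expect_true(all(grepl("^[0-9]+_", labels)))
})

test_that("master FASTA writes linked records in order and round-trips", {
  linked <- list(
    structure(list(occurrence_id = 101L, source_label = "readA",
                   output_label = "101_readA", bases = "ACGTACGT"),
              class = "linked_sequence"),
    structure(list(occurrence_id = 202L, source_label = "readB",
                   output_label = "202_readB",
                   bases = paste(rep("ACGT", 40), collapse = "")),
              class = "linked_sequence"))
  path <- tempfile(fileext = ".FASTA")
  expect_equal(write_master_fasta(linked, path), 2)
  back <- read_sequences(path, "fasta")
  expect_equal(vapply(back, `[[`, character(1), "label"),
               c("101_readA", "202_readB"))
  expect_equal(back[[2]]$bases, linked[[2]]$bases)

  empty <- tempfile(fileext = ".FASTA")
  expect_equal(write_master_fasta(list(), empty), 0)
  expect_true(file.exists(empty))
  expect_length(read_sequences(empty, "fasta"), 0)
})

test_that("occurrence CSV serializes absences as empty fields and conserves counts", {
  recs <- list(
    structure(list(occurrence_id = 11L, scientific_name = "Lecudina sp.",
                   decimal_latitude = 43.06, decimal_longitude = 141.35,
                   country = "JP", basis_of_record = NA_character_,
                   resource_links = list()), class = "occurrence_record"),
    structure(list(occurrence_id = 22L, scientific_name = "Lecudina sp.",
                   decimal_latitude = NA_real_, decimal_longitude = NA_real_,
                   country = NA_character_, basis_of_record = NA_character_,
                   resource_links = list()), class = "occurrence_record"))
  per <- data.frame(occurrence_id = c(11L, 22L), n_sequences = c(3L, 0L),
                    had_resources = c(TRUE, FALSE),
                    had_ngs_ssu = c(TRUE, FALSE))
  report <- build_report(recs, per)
  path <- tempfile(fileext = ".csv")
  expect_equal(write_occurrences_csv(recs, report, path), 2)

  raw <- readLines(path)
  expect_equal(length(raw), 3)  # header + 2 rows
  expect_match(raw[1], "^\"?occurrence_id\"?,")
  # absent coordinates are empty fields, not zeros
  fields <- strsplit(raw[3], ",")[[1]]
  expect_equal(fields[3], "")
  expect_equal(fields[4], "")

  df <- utils::read.csv(path)
  expect_equal(sum(df$n_sequences), report$n_sequences)
  expect_true(is.na(df$decimal_latitude[2]))

  empty_path <- tempfile(fileext = ".csv")
  empty_report <- build_report(list(),
                               data.frame(occurrence_id = integer(0),
                                          n_sequences = integer(0),
                                          had_resources = logical(0),
                                          had_ngs_ssu = logical(0)))
  expect_equal(write_occurrences_csv(list(), empty_report, empty_path), 0)
  expect_equal(length(readLines(empty_path)), 1)
})

test_that("header annotation joins CSV fields with '|' and refuses re-annotation", {
  run <- run_fixture_pipeline("Lecudina", seed = 61, n_occurrences = 8,
                              p_with_resources = 0.8)
  master <- file.path(run$project, "seq_master.FASTA")
  csv <- file.path(run$project, "occurrences.csv")
  out <- annotate_fasta(master, csv,
                        c("decimal_latitude", "decimal_longitude"))
  ann <- read_sequences(out, "fasta")
  meta <- utils::read.csv(csv, colClasses = c(occurrence_id = "character"))
  expect_gt(length(ann), 0)
  for (rec in ann) {
    parts <- strsplit(rec$label, "|", fixed = TRUE)[[1]]
    expect_length(parts, 3)
    row <- match(sub("_.*$", "", parts[1]), meta$occurrence_id)
    expected_lat <- meta$decimal_latitude[row]
    if (is.na(expected_lat)) {
      expect_equal(parts[2], "")
    } else {
      expect_equal(as.numeric(parts[2]), expected_lat)
    }
  }
  # bodies untouched
  orig <- read_sequences(master, "fasta")
  expect_identical(vapply(ann, `[[`, character(1), "bases"),
                   vapply(orig, `[[`, character(1), "bases"))

  expect_error(annotate_fasta(out, csv, "country"), "already annotated")
  expect_error(annotate_fasta(master, csv, "elevation"),
               "unknown annotation field")

  # empty field list copies the file unchanged
  noop <- annotate_fasta(master, csv, character(0),
                         out_path = tempfile(fileext = ".FASTA"))
  expect_identical(readLines(noop), readLines(master))
})

test_that("coverage sidecar carries the availability proportion", {
  per <- data.frame(occurrence_id = 1:10, n_sequences = 0L,
                    had_resources = rep(c(TRUE, FALSE), 5),
                    had_ngs_ssu = rep(c(TRUE, FALSE), 5))
  recs <- replicate(10, structure(list(occurrence_id = 1L),
                                  class = "occurrence_record"),
                    simplify = FALSE)
  report <- build_report(recs, per)
  path <- tempfile(fileext = ".png")
  render_coverage_plot(report, path)
  side <- jsonlite::read_json(sub("\\.png$", ".json", path))
  expect_equal(side$n_occurrences, 10)
  expect_equal(side$n_with_ngs_ssu, 5)
  expect_equal(side$proportion_with_data, 0.5)
  expect_true(file.exists(path))

  # degenerate and saturated boundaries
  r0 <- build_report(list(), per[0, ])
  p0 <- tempfile(fileext = ".png")
  render_coverage_plot(r0, p0)
  expect_equal(jsonlite::read_json(sub("\\.png$", ".json", p0))$proportion_with_data, 0)

  per_all <- transform(per, had_ngs_ssu = TRUE)
  r1 <- build_report(recs, per_all)
  p1 <- tempfile(fileext = ".png")
  render_coverage_plot(r1, p1)
  expect_equal(jsonlite::read_json(sub("\\.png$", ".json", p1))$proportion_with_data, 1)
})
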