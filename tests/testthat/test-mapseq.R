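test_that("rank tokens normalize by prefix strip, underscore and case rules", {
  expect_equal(normalize_rank_token("s__Lecudina_longissima"),
               "lecudina longissima")
  expect_equal(normalize_rank_token("g__Lecudina"), "lecudina")
  expect_equal(normalize_rank_token("sk__Eukaryota"), "eukaryota")
  expect_true(is.na(normalize_rank_token("p__")))
  expect_true(is.na(normalize_rank_token("")))
  expect_equal(normalize_rank_token("  Vibrio_harveyi  "), "vibrio harveyi")
})

test_that("normalization is idempotent on random tokens", {
  set.seed(101)
  pieces <- c("sk__", "g__", "s__", "")
  words <- c("Lecudina", "Para_lecudina", "X", "a_b_c", "", "Vibrio")
  for (i in 1:200) {
    tok <- paste0(sample(pieces, 1), sample(words, 1))
    once <- normalize_rank_token(tok)
    if (!is.na(once)) expect_identical(normalize_rank_token(once), once)
  }
})

test_that("MAPseq lines parse into label + normalized lineage", {
  lines <- c(
    "#query\thit\ttaxonomy",
    "read1\tref_1\t0.99\tsk__Eukaryota;g__Lecudina;s__Lecudina_longissima",
    "",
    "read2\tno_semicolons_here",
    "read3\t0.88;0.12\tsk__Bacteria;g__Vibrio"  # right-most ';' field wins
  )
  path <- write_lines_maybe_gz(lines)
  parsed <- parse_mapseq_file(path)
  expect_length(parsed$records, 3)
  expect_equal(parsed$n_malformed, 0)
  expect_equal(parsed$records[[1]]$query_label, "read1")
  expect_equal(parsed$records[[1]]$lineage,
               c("eukaryota", "lecudina", "lecudina longissima"))
  expect_equal(parsed$records[[2]]$lineage, character(0))
  expect_equal(parsed$records[[3]]$lineage, c("bacteria", "vibrio"))
  expect_equal(parsed$records[[3]]$raw_line_no, 5)
})

test_that("malformed lines are tallied, never fatal", {
  lines <- c("ok1\tx\tsk__A;g__B", "\tempty_label\tsk__A;g__B",
             "ok2\tx\tsk__A;g__B")
  parsed <- parse_mapseq_file(write_lines_maybe_gz(lines))
  expect_length(parsed$records, 2)
  expect_equal(parsed$n_malformed, 1)
})

test_that("lineage matching is exact-token with the genus-prefix rule", {
  mono <- parse_taxon_query("Lecudina")
  bi <- parse_taxon_query("Lecudina longissima")

  expect_true(lineage_matches(mono, c("eukaryota", "lecudina")))
  expect_true(lineage_matches(mono, c("eukaryota", "lecudina longissima")))
  expect_false(lineage_matches(mono, c("eukaryota", "paralecudina")))
  expect_false(lineage_matches(mono, c("lecudinaella", "lecudinaella minor")))
  expect_false(lineage_matches(mono, character(0)))

  expect_true(lineage_matches(bi, c("lecudina", "lecudina longissima")))
  expect_false(lineage_matches(bi, c("eukaryota", "lecudina")))  # genus only
  expect_false(lineage_matches(bi, c("lecudina sibling")))
  expect_false(lineage_matches(bi, c("lecudina longissimaforma")))
  expect_false(lineage_matches(bi, character(0)))
})

test_that("lineage matching agrees with a brute-force token scan", {
  set.seed(77)
  tokens <- c("lecudina", "lecudina longissima", "lecudina sibling",
              "paralecudina", "paralecudina longissima", "lecudinaella",
              "eukaryota", "vibrio harveyi", "lecudina longissimaforma")
  queries <- list(parse_taxon_query("Lecudina"),
                  parse_taxon_query("Lecudina longissima"),
                  parse_taxon_query("Vibrio"),
                  parse_taxon_query("Harveyi"))
  for (i in 1:300) {
    lineage <- sample(tokens, sample(0:5, 1))
    for (q in queries) {
      expect_identical(lineage_matches(q, lineage),
                       naive_lineage_match(q$tokens, lineage),
                       info = paste(paste(q$tokens, collapse = " "), "|",
                                    paste(lineage, collapse = ";")))
    }
  }
})

test_that("streaming label collection equals the parse-all oracle", {
  set.seed(42)
  for (rep in 1:10) {
    lines <- random_mapseq_lines(400)
    gz <- rep %% 2 == 0
    path <- write_lines_maybe_gz(lines, gz = gz)
    for (raw in c("Lecudina", "Lecudina longissima")) {
      q <- parse_taxon_query(raw)
      got <- collect_matching_labels(path, q, chunk_size = 37)
      expect_identical(sort(got$labels),
                       sort(naive_collect_labels(lines, q$tokens)),
                       info = paste("rep", rep, raw))
    }
  }
})

test_that("species-level matches are a subset of genus-level matches", {
  set.seed(55)
  for (rep in 1:10) {
    path <- write_lines_maybe_gz(random_mapseq_lines(300))
    genus <- collect_matching_labels(path, parse_taxon_query("Lecudina"))
    species <- collect_matching_labels(
      path, parse_taxon_query("Lecudina longissima"))
    expect_true(all(species$labels %in% genus$labels))
  }
})

test_that("empty files and decoy-only files yield no matches", {
  empty <- write_lines_maybe_gz(character(0))
  got <- collect_matching_labels(empty, parse_taxon_query("Lecudina"))
  expect_length(got$labels, 0)
  expect_equal(got$match_count, 0)

  decoys <- c(
    "d1\tr\tsk__Eukaryota;g__Paralecudina;s__Paralecudina_longissima",
    "d2\tr\tsk__Eukaryota;g__Lecudinaella;s__Lecudinaella_minor")
  got2 <- collect_matching_labels(write_lines_maybe_gz(decoys),
                                  parse_taxon_query("Lecudina"))
  expect_length(got2$labels, 0)
})
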