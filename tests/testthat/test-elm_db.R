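test_that("class table parsing honours comments, quoting and row order", {
  dir <- tempfile()
  dir.create(dir)
  path <- write_fixture_tsv(fixture_classes_df(), file.path(dir, "classes.tsv"),
    comments = c("comment line one", "comment line two"), quote_cells = TRUE
  )
  cls <- load_motif_classes(path)
  expect_equal(nrow(cls), 3L)
  expect_equal(cls$identifier[1], "LIG_PALB2_WD40_1")
  expect_equal(cls$pattern[1], "....WF.L") # verbatim after quote-stripping
  expect_equal(cls$probability, c(1e-4, 2e-3, 5e-3))
  expect_equal(cls$identifier, fixture_classes_df()$identifier) # order preserved

  # header-only file: empty collection, no error
  writeLines("accession\tidentifier\tregex\tprobability", path)
  expect_equal(nrow(load_motif_classes(path)), 0L)
})

test_that("class table schema and validation errors are specific", {
  dir <- tempfile()
  dir.create(dir)
  df <- fixture_classes_df()

  no_regex <- df[setdiff(names(df), "regex")]
  p <- write_fixture_tsv(no_regex, file.path(dir, "noregex.tsv"))
  expect_error(load_motif_classes(p), "regex", class = "slimscan_schema_error")

  dup <- rbind(df, df[1, ])
  p <- write_fixture_tsv(dup, file.path(dir, "dup.tsv"))
  expect_error(load_motif_classes(p), "LIG_PALB2_WD40_1", class = "slimscan_validation_error")

  bad_prob <- df
  bad_prob$probability[2] <- "1.5"
  p <- write_fixture_tsv(bad_prob, file.path(dir, "prob.tsv"))
  expect_error(load_motif_classes(p), "probability", class = "slimscan_validation_error")

  expect_error(load_motif_classes(file.path(dir, "missing.tsv")), class = "slimscan_io_error")
})

test_that("instance rows are validated per row, filtered by logic, and de-duplicated", {
  dir <- tempfile()
  dir.create(dir)
  seqs <- c(P1 = strrep("A", 20))
  inst <- data.frame(
    class_identifier = paste0("C", 1:6),
    protein_accession = "P1",
    protein_name = "p",
    start = c(5L, 12L, 3L, 1L, 2L, 5L),
    end = c(12L, 5L, 30L, 4L, 6L, 12L),
    instance_logic = c("true positive", "true positive", "unknown", "false positive", "true negative", "unknown"),
    organism = "synthetic",
    stringsAsFactors = FALSE
  )
  p <- write_fixture_tsv(inst, file.path(dir, "instances.tsv"))
  expect_warning(
    expect_warning(loaded <- load_motif_instances(p, seqs), "start > end"),
    "exceeds instance protein length"
  )
  report <- attr(loaded, "report")
  expect_equal(report$n_rows, 6L)
  expect_equal(report$n_rejected, 2L) # start>end and end>length
  expect_equal(nrow(loaded), 4L)
  expect_equal(report$n_transferable, 2L) # true positive + unknown
  expect_setequal(
    loaded$class_identifier[loaded$transferable], c("C1", "C6")
  )
  expect_true(all(loaded$end <= nchar(seqs[loaded$protein_accession])))

  # non-integer coordinates are a row-level rejection too
  inst2 <- inst[1:2, ]
  inst2$start <- c("5", "x")
  inst2$end <- c("12", "9")
  p2 <- write_fixture_tsv(inst2, file.path(dir, "inst2.tsv"))
  expect_warning(l2 <- load_motif_instances(p2, seqs), "not positive integers")
  expect_equal(nrow(l2), 1L)

  # exact duplicate rows collapse to one
  inst3 <- inst[c(1, 1), ]
  p3 <- write_fixture_tsv(inst3, file.path(dir, "inst3.tsv"))
  l3 <- load_motif_instances(p3, seqs)
  expect_equal(nrow(l3), 1L)
  expect_equal(attr(l3, "report")$n_duplicates_dropped, 1L)
})

test_that("loading is insensitive to instance row order", {
  dir <- tempfile()
  dir.create(dir)
  seqs <- c(P1 = strrep("A", 50), P2 = strrep("C", 50))
  inst <- data.frame(
    class_identifier = c("C1", "C2", "C1"),
    protein_accession = c("P1", "P2", "P2"),
    protein_name = "p", start = c(5L, 7L, 2L), end = c(9L, 12L, 4L),
    instance_logic = "true positive", organism = "s",
    stringsAsFactors = FALSE
  )
  p1 <- write_fixture_tsv(inst, file.path(dir, "a.tsv"))
  p2 <- write_fixture_tsv(inst[c(3, 1, 2), ], file.path(dir, "b.tsv"))
  expect_identical(load_motif_instances(p1, seqs), load_motif_instances(p2, seqs))
})

test_that("a full cache loads with cross-validation and a load report", {
  dir <- make_manual_db_dir()
  expect_message(db <- load_database(dir), "2 instance")
  expect_s3_class(db, "slim_db")
  expect_equal(nrow(db$classes), 3L)
  expect_equal(nrow(db$instances), 2L)
  expect_equal(db$report$n_transferable, 2L)
  expect_equal(sort(names(db$sequences)), c("P1", "P2"))

  # instances naming unknown classes are rejected with a warning
  bad_inst <- data.frame(
    class_identifier = c("LIG_PALB2_WD40_1", "NOT_A_CLASS"),
    protein_accession = c("P1", "P1"), protein_name = "p",
    start = c(2L, 3L), end = c(9L, 6L),
    instance_logic = "true positive", organism = "s",
    stringsAsFactors = FALSE
  )
  dir2 <- make_manual_db_dir(instances = bad_inst)
  expect_warning(db2 <- load_database(dir2, quiet = TRUE), "NOT_A_CLASS")
  expect_equal(nrow(db2$instances), 1L)

  # missing file: a setup-required error
  file.remove(file.path(dir, "classes.tsv"))
  expect_error(load_database(dir), "setup", class = "slimscan_setup_error")
})

test_that("sequence-less instance proteins are kept but excluded from alignment targets", {
  inst <- data.frame(
    class_identifier = c("LIG_PALB2_WD40_1", "DOC_TEST_2"),
    protein_accession = c("P1", "P9"), protein_name = "p",
    start = c(2L, 1L), end = c(9L, 4L),
    instance_logic = "true positive", organism = "s",
    stringsAsFactors = FALSE
  )
  dir <- make_manual_db_dir(instances = inst)
  db <- load_database(dir, quiet = TRUE)
  expect_equal(nrow(db$instances), 2L)
  expect_false(db$instances$has_sequence[db$instances$protein_accession == "P9"])
  expect_equal(db$report$n_without_sequence, 1L)
  expect_equal(slimscan:::alignment_targets(db), "P1")
})

test_that("write -> load -> write round-trips the database byte-for-byte", {
  db <- load_database(make_manual_db_dir(), quiet = TRUE)
  d1 <- tempfile()
  write_database(db, d1)
  db2 <- load_database(d1, quiet = TRUE)
  for (field in c("classes", "instances", "sequences")) {
    expect_identical(db2[[field]], db[[field]], label = field)
  }
  d2 <- tempfile()
  write_database(db2, d2)
  for (f in c("classes.tsv", "instances.tsv", "instance_sequences.fasta")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), label = f)
  }
})

test_that("setup_database stages atomically and is idempotent", {
  src_dir <- make_manual_db_dir()
  source <- list(
    classes = file.path(src_dir, "classes.tsv"),
    instances = file.path(src_dir, "instances.tsv"),
    sequences = file.path(src_dir, "instance_sequences.fasta")
  )
  cache <- tempfile("cache")
  db <- setup_database(cache, source, quiet = TRUE)
  expect_s3_class(db, "slim_db")
  expect_match(db$version_tag, "^setup:")
  first <- lapply(
    file.path(cache, c("classes.tsv", "instances.tsv", "instance_sequences.fasta")),
    readLines
  )

  # re-running on the same source: byte-identical data files
  setup_database(cache, source, quiet = TRUE)
  second <- lapply(
    file.path(cache, c("classes.tsv", "instances.tsv", "instance_sequences.fasta")),
    readLines
  )
  expect_identical(first, second)

  # a broken source leaves the existing cache untouched
  expect_error(
    setup_database(cache, modifyList(source, list(classes = tempfile())), quiet = TRUE),
    class = "slimscan_setup_error"
  )
  expect_identical(
    readLines(file.path(cache, "classes.tsv")), first[[1]]
  )
})
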