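# Fixture builders shared across test files.  Everything is generated in
# code at test time; nothing is read from checked-in data files.

# Write a class/instance table in the cache TSV dialect, with optional
# leading comment lines and optional quoting of every cell.
write_fixture_tsv <- function(df, path, comments = character(), quote_cells = FALSE) {
  lines <- if (length(comments)) paste0("# ", comments) else character()
  fmt <- function(x) if (quote_cells) paste0('"', x, '"') else as.character(x)
  header <- paste(names(df), collapse = "\t")
  body <- apply(df, 1L, function(row) paste(fmt(row), collapse = "\t"))
  writeLines(c(lines, header, body), path)
  path
}

fixture_classes_df <- function() {
  data.frame(
    accession = c("ELME000001", "ELME000002", "ELME000003"),
    identifier = c("LIG_PALB2_WD40_1", "DOC_TEST_2", "MOD_TEST_3"),
    functional_site_name = c("WD40 ligand", "Docking site", "Phospho site"),
    description = c("Binds a WD40 domain", "Kinase docking", "Proline-directed phosphosite"),
    regex = c("....WF.L", "[RK]{2}.L", "P.[ST]P"),
    probability = c(0.0001, 0.002, 0.005),
    motif_type = c("LIG", "DOC", "MOD"),
    stringsAsFactors = FALSE
  )
}

write_fixture_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# A small hand-built database directory, independent of generate_database,
# for exercising the loader itself.
make_manual_db_dir <- function(dir = tempfile("manualdb"),
                               instances = NULL,
                               seqs = c(P1 = "MAAAAWFALKKALAAAAAAG", P2 = "MPKSPRRALLKAAG")) {
  dir.create(dir)
  write_fixture_tsv(fixture_classes_df(), file.path(dir, "classes.tsv"),
    comments = c("synthetic motif class table", "three classes")
  )
  if (is.null(instances)) {
    instances <- data.frame(
      class_identifier = c("LIG_PALB2_WD40_1", "MOD_TEST_3"),
      protein_accession = c("P1", "P2"),
      protein_name = c("protein one", "protein two"),
      start = c(2L, 3L),
      end = c(9L, 6L),
      instance_logic = c("true positive", "unknown"),
      organism = c("synthetic", "synthetic"),
      stringsAsFactors = FALSE
    )
  }
  write_fixture_tsv(instances, file.path(dir, "instances.tsv"))
  write_fixture_fasta(seqs, file.path(dir, "instance_sequences.fasta"))
  dir
}

make_fixture_db <- function(seed = 1L, dir = tempfile("fixdb"), ...) {
  generate_database(fixture_spec(seed = seed, ...), dir)
}

expect_valid_hit <- function(hit, query, subject, scheme = scoring_scheme()) {
  expect_s3_class(hit, "slim_hit")
  expect_gt(hit$score, 0)
  expect_true(hit$query_start >= 1 && hit$query_end <= nchar(query))
  expect_true(hit$subject_start >= 1 && hit$subject_end <= nchar(subject))
  expect_equal(
    slimscan:::rescore_trace(hit$column_trace, toupper(query), toupper(subject), hit, scheme),
    hit$score
  )
}
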