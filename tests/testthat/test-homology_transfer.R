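# Build a synthetic slim_hit with full control over the trace.
make_hit <- function(trace, q_start, s_start, subject_accession = "P1",
                     score = 100, query_len = 200, subject_len = 200) {
  ops <- strsplit(trace, "")[[1]]
  nq <- sum(ops %in% c("M", "I"))
  ns <- sum(ops %in% c("M", "D"))
  structure(
    list(
      query_id = "query", subject_accession = subject_accession, score = score,
      query_start = q_start, query_end = q_start + nq - 1L,
      subject_start = s_start, subject_end = s_start + ns - 1L,
      column_trace = trace, n_columns = length(ops),
      identity_pct = 90, query_cov_pct = 50, subject_cov_pct = 50
    ),
    class = "slim_hit"
  )
}

inst <- function(start, end, acc = "P1") {
  list(protein_accession = acc, start = start, end = end)
}

test_that("containment truth table: full, partial, exact-boundary", {
  hit_wide <- make_hit(strrep("M", 50), q_start = 1, s_start = 1) # s[1..50]
  expect_true(motif_in_overlap(inst(5, 12), hit_wide))

  hit_partial <- make_hit(strrep("M", 41), q_start = 1, s_start = 10) # s[10..50]
  expect_false(motif_in_overlap(inst(5, 12), hit_partial))

  hit_exact <- make_hit(strrep("M", 8), q_start = 1, s_start = 5) # s[5..12]
  expect_true(motif_in_overlap(inst(5, 12), hit_exact))

  expect_error(motif_in_overlap(inst(5, 12, acc = "OTHER"), hit_wide),
    class = "slimscan_contract_error"
  )
})

test_that("enlarging the subject span never flips containment to false", {
  set.seed(8)
  for (rep in 1:50) {
    s_start <- sample(1:20, 1)
    s_len <- sample(5:40, 1)
    hit <- make_hit(strrep("M", s_len), q_start = 1, s_start = s_start)
    i_start <- sample(1:60, 1)
    i_end <- i_start + sample(0:10, 1)
    base <- motif_in_overlap(inst(i_start, i_end), hit)
    grown <- make_hit(strrep("M", s_len + sample(1:10, 1)),
      q_start = 1,
      s_start = max(1L, s_start - sample(0:3, 1))
    )
    if (base) expect_true(motif_in_overlap(inst(i_start, i_end), grown))
  }
})

test_that("gapless projection is pure offset arithmetic", {
  # hit q[11..60] vs s[1..50], gapless: instance [5,12] projects to (15,22)
  hit <- make_hit(strrep("M", 50), q_start = 11, s_start = 1)
  expect_equal(project_to_query(inst(5, 12), hit), c(15L, 22L))
  # identity alignment: projection is the instance span itself
  hit_id <- make_hit(strrep("M", 100), q_start = 1, s_start = 1)
  expect_equal(project_to_query(inst(37, 44), hit_id), c(37L, 44L))
  # span-length preservation on gapless traces
  set.seed(12)
  for (rep in 1:30) {
    qs <- sample(1:30, 1)
    ss <- sample(1:30, 1)
    hit_r <- make_hit(strrep("M", 60), q_start = qs, s_start = ss)
    a <- ss + sample(0:20, 1)
    b <- a + sample(0:10, 1)
    proj <- project_to_query(inst(a, b), hit_r)
    expect_equal(proj[2] - proj[1], b - a)
    expect_equal(proj, unname(oracle_project(hit_r$column_trace, qs, ss, a, b)))
  }
  expect_error(project_to_query(inst(60, 70), hit), class = "slimscan_contract_error")
})

test_that("projection through gapped traces follows alignment columns, not offsets", {
  # subject positions 5..12; a 3-column query-gap (D) covers subject 5..7,
  # so the projected start shifts to the first query-consuming column
  trace <- paste0(strrep("M", 4), "DDD", strrep("M", 10)) # s 1..17? build explicitly
  # columns: M x4 (q1-4/s1-4), D x3 (s5-7), M x10 (q5-14/s8-17)
  hit <- make_hit(trace, q_start = 1, s_start = 1)
  expect_equal(project_to_query(inst(5, 12), hit), c(5L, 9L))
  expect_equal(
    project_to_query(inst(5, 12), hit),
    unname(oracle_project(trace, 1, 1, 5, 12))
  )

  # insertion in the query inside the motif stretches the projection
  trace_i <- paste0(strrep("M", 6), "III", strrep("M", 10)) # q gains 3 residues after s6
  hit_i <- make_hit(trace_i, q_start = 1, s_start = 1)
  expect_equal(project_to_query(inst(5, 12), hit_i), c(5L, 15L))
  expect_equal(
    project_to_query(inst(5, 12), hit_i),
    unname(oracle_project(trace_i, 1, 1, 5, 12))
  )

  # motif aligned entirely to a query gap: projection undefined
  trace_gap <- paste0(strrep("M", 4), strrep("D", 8)) # s5..12 all query-gap
  hit_g <- make_hit(trace_gap, q_start = 1, s_start = 1)
  expect_null(project_to_query(inst(5, 12), hit_g))
  expect_null(oracle_project(trace_gap, 1, 1, 5, 12))

  # random gapped traces agree with the independent column-walk oracle
  set.seed(33)
  for (rep in 1:100) {
    ops <- sample(c("M", "I", "D"), 40, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    trace_r <- paste(ops, collapse = "")
    ns <- sum(ops %in% c("M", "D"))
    if (ns < 3) next
    hit_r <- make_hit(trace_r, q_start = sample(1:10, 1), s_start = sample(1:10, 1))
    a <- hit_r$subject_start + sample(0:(ns - 2), 1)
    b <- min(a + sample(0:6, 1), hit_r$subject_end)
    got <- project_to_query(inst(a, b), hit_r)
    want <- oracle_project(trace_r, hit_r$query_start, hit_r$subject_start, a, b)
    if (is.null(want)) expect_null(got) else expect_equal(got, unname(want))
  }
})

test_that("the ortholog table carries all instances on hits with flags and projections", {
  db <- make_fixture_db(seed = 19)
  acc <- names(db$sequences)[4]
  query <- db$sequences[[acc]]
  hits <- find_hits(query, db, min_score = 50)
  tab <- build_ortholog_table(hits, db, query)
  expect_named(tab, slimscan:::ORTHOLOG_TABLE_COLS)

  own <- tab[tab$ortholog_accession == acc, ]
  expect_equal(nrow(own), 2L) # both implants on the self-hit
  expect_true(all(own$motif_in_overlap))
  expect_equal(own$motif_start_in_query, own$motif_start_in_ortholog)
  expect_equal(own$motif_end_in_query, own$motif_end_in_ortholog)
  expect_identical(
    own$motif_sequence_in_ortholog,
    substring(query, own$motif_start_in_query, own$motif_end_in_query)
  )
  # rows sorted by descending score
  expect_true(all(diff(tab$alignment_score) <= 0))
})

test_that("a truncated query flags uncovered instances as not contained", {
  db <- make_fixture_db(seed = 19)
  acc <- names(db$sequences)[2]
  full <- db$sequences[[acc]]
  imps <- db$implants[db$implants$protein_accession == acc, ]
  imps <- imps[order(imps$start), ]
  # cut the query just after the first implant: second implant cannot be contained
  cut_at <- imps$start[2] - 1L
  truncated <- substring(full, 1, cut_at)
  hits <- find_hits(truncated, db, min_score = 50)
  hits <- hits[vapply(hits, `[[`, character(1), "subject_accession") == acc]
  tab <- build_ortholog_table(hits, db, truncated)
  expect_equal(nrow(tab), 2L)
  tab <- tab[order(tab$motif_start_in_ortholog), ]
  expect_true(tab$motif_in_overlap[1])
  expect_false(tab$motif_in_overlap[2])
  expect_true(is.na(tab$motif_start_in_query[2]))
})

test_that("hits without transferable instances give an empty table with full header", {
  db <- make_fixture_db(seed = 19)
  tab <- build_ortholog_table(list(), db, "MAAAA")
  expect_equal(nrow(tab), 0L)
  expect_named(tab, slimscan:::ORTHOLOG_TABLE_COLS)
})

test_that("diverged queries recover every implant on the top hit", {
  db <- make_fixture_db(seed = 37)
  for (acc in names(db$sequences)[1:3]) {
    dq <- derive_query(acc, db, divergence = 0.1, preserve_implants = TRUE, seed = 101)
    hits <- find_hits(dq, db, min_score = 50)
    expect_equal(hits[[1]]$subject_accession, acc)
    tab <- build_ortholog_table(hits[1], db, dq)
    imps <- db$implants[db$implants$protein_accession == acc, ]
    expect_equal(nrow(tab), nrow(imps))
    expect_true(all(tab$motif_in_overlap))
    for (r in seq_len(nrow(tab))) {
      pat <- db$classes$pattern[db$classes$identifier == tab$motif_class_identifier[r]]
      piece <- substring(dq, tab$motif_start_in_query[r], tab$motif_end_in_query[r])
      expect_true(grepl(paste0("^(?:", pat, ")$"), piece, perl = TRUE),
        label = sprintf("%s projected span matches %s", acc, pat)
      )
    }
  }
})
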