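# Built-in protein local alignment: Smith-Waterman with affine gaps
# against the database's instance proteins, reporting identity and
# coverage percentages for each hit.  Defaults follow the conventions of
# the fast protein aligners this step stands in for: BLOSUM62, gap open
# 11, gap extend 1 (a gap of length L costs open + L*extend), and a raw
# score floor instead of E-value statistics.

AMBIGUITY_GROUPS <- list(B = c("N", "D"), Z = c("E", "Q"), J = c("I", "L"))

# 26x26 integer matrix over A..Z.  Core 20x20 taken from the named BLOSUM
# matrix shipped with Biostrings; ambiguity letters get field-standard
# extensions: B/Z/J average their constituent rows, X/O/U score 0 against
# everything.
build_substitution_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  core <- env[[name]]
  mat <- matrix(0L, 26, 26, dimnames = list(LETTERS, LETTERS))
  expand <- function(a) {
    if (a %in% AA_CANONICAL) a else if (!is.null(AMBIGUITY_GROUPS[[a]])) AMBIGUITY_GROUPS[[a]] else NULL
  }
  for (a in LETTERS) {
    ea <- expand(a)
    if (is.null(ea)) next # X, O, U and the like stay 0
    for (b in LETTERS) {
      eb <- expand(b)
      if (is.null(eb)) next
      mat[a, b] <- as.integer(round(mean(core[ea, eb, drop = FALSE])))
    }
  }
  mat
}

#' Alignment scoring scheme
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or a symmetric integer matrix with residue
#'   letters as dimnames.
#' @param gap_open Gap opening penalty (>= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty (>= 0, <= `gap_open`).
#' @return An object of class `slim_scoring`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L) {
  if (is.character(matrix)) {
    mat <- build_substitution_matrix(matrix)
  } else {
    if (!is.matrix(matrix) || is.null(rownames(matrix))) {
      stop_input("substitution matrix must be a named matrix or a Biostrings matrix name")
    }
    mat <- matrix(0L, 26, 26, dimnames = list(LETTERS, LETTERS))
    letters_in <- intersect(rownames(matrix), LETTERS)
    mat[letters_in, letters_in] <- as.integer(matrix[letters_in, letters_in])
  }
  if (!isTRUE(all.equal(mat, t(mat)))) stop_input("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0) stop_input("gap penalties must be >= 0")
  if (gap_extend > gap_open) stop_input("gap_extend must not exceed gap_open")
  structure(
    list(matrix = mat, gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
    class = "slim_scoring"
  )
}

seq_to_index <- function(seq) utf8ToInt(seq) - utf8ToInt("A")

# Score a column trace under a scheme; used for the score/trace
# consistency invariant and by tests.
rescore_trace <- function(trace, query, subject, hit, scheme) {
  ops <- strsplit(trace, "")[[1]]
  qi <- hit$query_start - 1L
  si <- hit$subject_start - 1L
  score <- 0L
  k <- 1L
  while (k <= length(ops)) {
    if (ops[k] == "M") {
      qi <- qi + 1L
      si <- si + 1L
      score <- score + scheme$matrix[substr(query, qi, qi), substr(subject, si, si)]
      k <- k + 1L
    } else {
      op <- ops[k]
      len <- 0L
      while (k <= length(ops) && ops[k] == op) {
        len <- len + 1L
        k <- k + 1L
      }
      if (op == "I") qi <- qi + len else si <- si + len
      score <- score - scheme$gap_open - scheme$gap_extend * len
    }
  }
  as.integer(score)
}

hit_from_raw <- function(raw, query, subject, query_id, subject_accession) {
  ops <- strsplit(raw$trace, "")[[1]]
  q_res <- strsplit(substring(query, raw$query_start, raw$query_end), "")[[1]]
  s_res <- strsplit(substring(subject, raw$subject_start, raw$subject_end), "")[[1]]
  is_m <- ops == "M"
  identical_cols <- sum(q_res[cumsum(ops %in% c("M", "I"))[is_m]] ==
    s_res[cumsum(ops %in% c("M", "D"))[is_m]])
  structure(
    list(
      query_id = query_id,
      subject_accession = subject_accession,
      score = raw$score,
      query_start = raw$query_start, query_end = raw$query_end,
      subject_start = raw$subject_start, subject_end = raw$subject_end,
      column_trace = raw$trace,
      n_columns = length(ops),
      identity_pct = 100 * identical_cols / length(ops),
      query_cov_pct = 100 * (raw$query_end - raw$query_start + 1) / nchar(query),
      subject_cov_pct = 100 * (raw$subject_end - raw$subject_start + 1) / nchar(subject)
    ),
    class = "slim_hit"
  )
}

#' @export
print.slim_hit <- function(x, ...) {
  cat(sprintf(
    "<slim_hit> %s vs %s  score %d  q[%d..%d] s[%d..%d]  identity %.1f%%  cov q %.1f%% / s %.1f%%\n",
    x$query_id, x$subject_accession, x$score,
    x$query_start, x$query_end, x$subject_start, x$subject_end,
    x$identity_pct, x$query_cov_pct, x$subject_cov_pct
  ))
  invisible(x)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gap penalties (Gotoh recurrence) and a
#' deterministic traceback (diagonal preferred over a gap in the subject,
#' over a gap in the query; among equal-score end cells the smallest query
#' end, then subject end, wins).
#'
#' @param query,subject Amino-acid sequences (non-empty; case-insensitive).
#' @param scheme A [scoring_scheme()].
#' @param min_score Minimum alignment score; `NULL` is returned below it.
#' @param query_id,subject_accession Labels carried into the hit.
#' @return A `slim_hit` (score, 1-based inclusive aligned spans on both
#'   sequences, column trace over `M`/`I`/`D`, identity and coverage
#'   percentages), or `NULL` when no alignment scores above zero /
#'   `min_score`.
#' @examples
#' hit <- smith_waterman("HEAGAWGHEE", "PAWHEAE")
#' hit$score
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           min_score = 1L, query_id = "query",
                           subject_accession = "subject") {
  query <- validate_sequence(query, "query sequence")
  subject <- validate_sequence(subject, "subject sequence")
  if (!nchar(query) || !nchar(subject)) stop_input("sequences must be non-empty")
  raw <- sw_align_cpp(
    seq_to_index(query), seq_to_index(subject),
    scheme$matrix, scheme$gap_open, scheme$gap_extend
  )
  if (raw$score <= 0 || raw$score < min_score) return(NULL)
  hit_from_raw(raw, query, subject, query_id, subject_accession)
}

# Accessions of proteins that can donate motifs: at least one transferable
# instance and a known sequence.
alignment_targets <- function(db) {
  ok <- db$instances$transferable & db$instances$has_sequence
  sort(unique(db$instances$protein_accession[ok]))
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Align a query against the database's motif-instance proteins
#'
#' Runs [smith_waterman()] against every transferable instance protein
#' (optionally restricted to proteins sharing at least one k-mer with the
#' query) and keeps hits at or above `min_score`.  The hit list is
#' identical for any thread count.
#'
#' @param query Amino-acid sequence.
#' @param db A `slim_db`.
#' @param scheme A [scoring_scheme()].
#' @param min_score Raw score floor for reported hits (default 50).
#' @param prefilter_k Shared k-mer prefilter length; 0 disables the
#'   prefilter.  The prefilter is a pure subset filter: it can only drop
#'   subjects that share no k-mer with the query.
#' @param threads Number of worker processes for the per-subject
#'   alignments (forked via the parallel package where available).
#' @param query_id Label carried into the hits.
#' @return List of `slim_hit`, sorted by descending score then ascending
#'   subject accession.
#' @export
find_hits <- function(query, db, scheme = scoring_scheme(), min_score = 50L,
                      prefilter_k = 0L, threads = 1L, query_id = "query") {
  query <- validate_sequence(query, "query sequence")
  if (threads < 1L) stop_input("threads must be >= 1")
  targets <- alignment_targets(db)
  if (prefilter_k > 0L && length(targets)) {
    qk <- kmer_set(query, prefilter_k)
    shares <- vapply(
      targets,
      function(acc) any(kmer_set(db$sequences[[acc]], prefilter_k) %in% qk),
      logical(1)
    )
    targets <- targets[shares]
  }
  align_one <- function(acc) {
    smith_waterman(query, db$sequences[[acc]], scheme,
      min_score = min_score, query_id = query_id, subject_accession = acc
    )
  }
  hits <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(targets, align_one, mc.cores = threads)
  } else {
    lapply(targets, align_one)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  ord <- order(-vapply(hits, `[[`, numeric(1), "score"),
    vapply(hits, `[[`, character(1), "subject_accession")
  )
  hits[ord]
}
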