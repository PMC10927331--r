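# Homology-based motif transfer: combine alignment hits with curated
# motif instances on the hit proteins to produce the ortholog result
# table, including the containment flag and alignment-column projection of
# instance coordinates onto the query.

#' Is a motif instance contained in a hit's aligned subject span?
#'
#' `TRUE` iff the instance interval `[start, end]` lies entirely inside
#' the subject-side aligned span of the hit (inclusive on both ends).
#' Partial overlap is `FALSE`: a motif that sticks out of the aligned
#' region was not fully observed in the alignment.
#'
#' @param instance One motif instance (list or one-row data frame with
#'   `protein_accession`, `start`, `end`).
#' @param hit A `slim_hit` on the same subject protein.
#' @return Logical scalar.
#' @export
motif_in_overlap <- function(instance, hit) {
  if (!identical(as.character(instance$protein_accession), hit$subject_accession)) {
    stop_contract(sprintf(
      "instance protein (%s) does not match hit subject (%s)",
      instance$protein_accession, hit$subject_accession
    ))
  }
  instance$start >= hit$subject_start && instance$end <= hit$subject_end
}

# Per-column bookkeeping for a hit's trace: which side each column
# consumes and the 1-based residue coordinate it lands on.
trace_columns <- function(hit) {
  ops <- strsplit(hit$column_trace, "")[[1]]
  consume_q <- ops %in% c("M", "I")
  consume_s <- ops %in% c("M", "D")
  list(
    ops = ops,
    consume_q = consume_q,
    consume_s = consume_s,
    q_pos = ifelse(consume_q, hit$query_start - 1L + cumsum(consume_q), NA_integer_),
    s_pos = ifelse(consume_s, hit$subject_start - 1L + cumsum(consume_s), NA_integer_)
  )
}

#' Project a contained motif instance onto the query
#'
#' Walks the hit's alignment columns: the projected start is the query
#' position of the first query-consuming column at or after the column
#' holding the instance's subject start; the projected end comes from the
#' symmetric backward walk from the instance's subject end.  Using
#' alignment columns (rather than offset arithmetic) keeps the projection
#' correct across insertions and deletions between query and ortholog.
#'
#' @param instance One motif instance (see [motif_in_overlap()]); must be
#'   contained in the hit's subject span.
#' @param hit A `slim_hit`.
#' @return Integer vector `c(query_start, query_end)`, or `NULL` when the
#'   motif's subject span aligns entirely to a gap in the query.
#' @export
project_to_query <- function(instance, hit) {
  if (!motif_in_overlap(instance, hit)) {
    stop_contract("project_to_query requires the instance to be contained in the hit's subject span")
  }
  tc <- trace_columns(hit)
  cs <- which(tc$consume_s & tc$s_pos == instance$start)[1L]
  ce <- which(tc$consume_s & tc$s_pos == instance$end)[1L]
  fwd <- which(tc$consume_q & seq_along(tc$ops) >= cs)
  bwd <- which(tc$consume_q & seq_along(tc$ops) <= ce)
  if (!length(fwd) || !length(bwd)) return(NULL)
  qs <- tc$q_pos[fwd[1L]]
  qe <- tc$q_pos[bwd[length(bwd)]]
  if (qs > qe) return(NULL)
  c(qs, qe)
}

ORTHOLOG_TABLE_COLS <- c(
  "ortholog_accession", "ortholog_protein_name", "organism",
  "motif_class_accession", "motif_class_identifier", "motif_type",
  "description", "probability", "instance_logic",
  "motif_start_in_ortholog", "motif_end_in_ortholog",
  "motif_sequence_in_ortholog", "alignment_score", "identity_pct",
  "query_cov_pct", "subject_cov_pct", "motif_in_overlap",
  "motif_start_in_query", "motif_end_in_query"
)

empty_ortholog_table <- function() {
  data.frame(
    ortholog_accession = character(), ortholog_protein_name = character(),
    organism = character(), motif_class_accession = character(),
    motif_class_identifier = character(), motif_type = character(),
    description = character(), probability = numeric(),
    instance_logic = character(), motif_start_in_ortholog = integer(),
    motif_end_in_ortholog = integer(), motif_sequence_in_ortholog = character(),
    alignment_score = integer(), identity_pct = numeric(),
    query_cov_pct = numeric(), subject_cov_pct = numeric(),
    motif_in_overlap = logical(), motif_start_in_query = integer(),
    motif_end_in_query = integer(), stringsAsFactors = FALSE
  )
}

#' Build the ortholog (homology-transfer) result table
#'
#' One row per (alignment hit, transferable motif instance on that hit's
#' subject protein).  Every row carries the containment flag; projected
#' query coordinates are filled in only when the instance is contained in
#' the aligned region and its span touches at least one query residue.
#' Non-transferable instances (curation logic "false positive" / "true
#' negative") are never emitted.
#'
#' @param hits List of `slim_hit` from [find_hits()].
#' @param db A `slim_db`.
#' @param query The resolved query sequence (used for bounds checks).
#' @return Data frame with the documented ortholog-table columns, sorted
#'   by descending hit score, subject accession, then instance start.
#' @export
build_ortholog_table <- function(hits, db, query) {
  query <- validate_sequence(query, "query sequence")
  rows <- list()
  for (hit in hits) {
    inst <- db$instances[
      db$instances$protein_accession == hit$subject_accession & db$instances$transferable, ,
      drop = FALSE
    ]
    if (!nrow(inst)) next
    cls_idx <- match(inst$class_identifier, db$classes$identifier)
    subject_seq <- db$sequences[[hit$subject_accession]]
    for (r in seq_len(nrow(inst))) {
      contained <- motif_in_overlap(inst[r, ], hit)
      proj <- if (contained) project_to_query(inst[r, ], hit) else NULL
      if (!is.null(proj) && (proj[1L] < 1L || proj[2L] > nchar(query))) {
        stop_contract("projected span outside the query sequence")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ortholog_accession = hit$subject_accession,
        ortholog_protein_name = inst$protein_name[r],
        organism = inst$organism[r],
        motif_class_accession = db$classes$accession[cls_idx[r]],
        motif_class_identifier = inst$class_identifier[r],
        motif_type = db$classes$motif_type[cls_idx[r]],
        description = db$classes$description[cls_idx[r]],
        probability = db$classes$probability[cls_idx[r]],
        instance_logic = inst$instance_logic[r],
        motif_start_in_ortholog = inst$start[r],
        motif_end_in_ortholog = inst$end[r],
        motif_sequence_in_ortholog = substring(subject_seq, inst$start[r], inst$end[r]),
        alignment_score = hit$score,
        identity_pct = hit$identity_pct,
        query_cov_pct = hit$query_cov_pct,
        subject_cov_pct = hit$subject_cov_pct,
        motif_in_overlap = contained,
        motif_start_in_query = if (is.null(proj)) NA_integer_ else proj[1L],
        motif_end_in_query = if (is.null(proj)) NA_integer_ else proj[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty_ortholog_table())
  out <- do.call(rbind, rows)
  out <- out[order(-out$alignment_score, out$ortholog_accession, out$motif_start_in_ortholog), , drop = FALSE]
  rownames(out) <- NULL
  out
}
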