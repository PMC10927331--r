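# End-to-end orchestration: resolve the query input (raw sequence or
# protein accession), run both the regex scan and the homology-transfer
# scan, and write/print the two result tables.  The two scans are
# independent: either table may be empty while the other is not, and they
# are never merged.

#' Resolve query input to an amino-acid sequence
#'
#' The input mode is always explicit — accessions are themselves valid
#' amino-acid strings, so guessing would be unsafe.  In accession mode the
#' database's own instance proteins are consulted first; only unknown
#' accessions go to the injected provider (e.g. a remote sequence service
#' or an offline fixture mapping).
#'
#' @param raw Input string: an amino-acid sequence or a protein accession.
#' @param mode `"sequence"` or `"accession"`.
#' @param db A `slim_db` (consulted in accession mode).
#' @param provider Accession resolver used when the accession is not an
#'   instance protein: a named character vector or a
#'   `function(accession) -> sequence or NULL`.
#' @return An object of class `slim_query` with fields `raw`, `mode`,
#'   `resolved_sequence` and `source` (one of `"literal"`,
#'   `"database-instance"`, `"remote-provider"`).
#' @export
resolve_input <- function(raw, mode = c("sequence", "accession"), db = NULL,
                          provider = NULL) {
  mode <- match.arg(mode)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop_input("query input must be a single non-empty string")
  }
  if (mode == "sequence") {
    seq <- validate_sequence(raw, "query sequence")
    return(structure(
      list(raw = raw, mode = mode, resolved_sequence = seq, source = "literal"),
      class = "slim_query"
    ))
  }
  if (!is.null(db) && raw %in% names(db$sequences)) {
    return(structure(
      list(
        raw = raw, mode = mode,
        resolved_sequence = db$sequences[[raw]], source = "database-instance"
      ),
      class = "slim_query"
    ))
  }
  seq <- NULL
  if (is.function(provider)) {
    seq <- provider(raw)
  } else if (!is.null(provider)) {
    seq <- if (raw %in% names(provider)) provider[[raw]] else NULL
  }
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) {
    stop_resolution(sprintf(
      "accession '%s' is not an instance protein and could not be resolved by the sequence provider",
      raw
    ))
  }
  structure(
    list(
      raw = raw, mode = mode,
      resolved_sequence = validate_sequence(seq, "provider sequence"),
      source = "remote-provider"
    ),
    class = "slim_query"
  )
}

#' Run the full motif query
#'
#' Computes both result tables for a resolved query: the regex table
#' (every motif-class pattern scanned against the query, overlapping
#' matches included) and the ortholog table (curated instances on
#' alignment hits, with containment flags and projected coordinates).
#'
#' @param input A `slim_query` from [resolve_input()], or a plain
#'   amino-acid sequence string (treated as sequence mode).
#' @param db A `slim_db`.
#' @param scheme A [scoring_scheme()].
#' @param min_score Alignment score floor for hits.
#' @param prefilter_k Shared k-mer prefilter length (0 = off).
#' @param threads Worker processes for the alignments.
#' @return An object of class `slim_result`: list with `regex_table`,
#'   `ortholog_table` and `provenance`.
#' @examples
#' db <- generate_database(fixture_spec(seed = 7), tempfile("fixdb"))
#' res <- run_query(db$sequences[[1]], db)
#' res
#' @export
run_query <- function(input, db, scheme = scoring_scheme(), min_score = 50L,
                      prefilter_k = 0L, threads = 1L) {
  if (is.character(input)) input <- resolve_input(input, "sequence")
  if (!inherits(input, "slim_query")) {
    stop_input("input must be a slim_query or an amino-acid sequence string")
  }
  query <- input$resolved_sequence
  records <- scan_sequence(query, db$classes)
  regex_table <- build_regex_table(records, db$classes)
  hits <- find_hits(query, db, scheme,
    min_score = min_score,
    prefilter_k = prefilter_k, threads = threads, query_id = input$raw
  )
  ortholog_table <- build_ortholog_table(hits, db, query)
  structure(
    list(
      regex_table = regex_table,
      ortholog_table = ortholog_table,
      provenance = list(
        db_version_tag = db$version_tag,
        input_mode = input$mode,
        input_source = input$source,
        query_length = nchar(query),
        parameters = list(
          gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
          min_score = min_score, prefilter_k = prefilter_k, threads = threads
        ),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "slim_result"
  )
}

#' One-call convenience wrapper
#'
#' `resolve_input()` followed by `run_query()`.
#'
#' @inheritParams resolve_input
#' @inheritParams run_query
#' @param query Input string (sequence or accession, per `mode`).
#' @param ... Passed on to [run_query()].
#' @return A `slim_result`.
#' @export
slim_scan <- function(query, db, mode = "sequence", provider = NULL, ...) {
  run_query(resolve_input(query, mode, db, provider), db, ...)
}

#' @export
print.slim_result <- function(x, ...) {
  cat(sprintf(
    "<slim_result> query of %d aa (%s input)\n  regex table:    %d candidate motif match(es), %d class(es)\n  ortholog table: %d transferred instance(s) on %d hit protein(s)\n",
    x$provenance$query_length, x$provenance$input_mode,
    nrow(x$regex_table), length(unique(x$regex_table$motif_class_identifier)),
    nrow(x$ortholog_table), length(unique(x$ortholog_table$ortholog_accession))
  ))
  invisible(x)
}

write_result_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = ""
  )
}

write_result_json <- function(df, path) {
  jsonlite::write_json(df, path, dataframe = "rows", na = "null", digits = NA, pretty = TRUE)
}

#' Write query results to disk (or standard output)
#'
#' Writes `regex.{tsv,json}`, `ortholog.{tsv,json}` and
#' `provenance.json` into `out_dir`.  With `out_dir = NULL` the two
#' tables are printed to standard output as one JSON object instead —
#' the CLI contract for use without an output folder.
#'
#' @param result A `slim_result`.
#' @param out_dir Output directory (created if needed), or `NULL`.
#' @param format `"both"`, `"tsv"` or `"json"`.
#' @param prefix Optional file-name prefix (used for multi-record FASTA
#'   input).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, out_dir = NULL, format = c("both", "tsv", "json"),
                          prefix = "") {
  format <- match.arg(format)
  if (is.null(out_dir)) {
    cat(jsonlite::toJSON(
      list(
        regex = result$regex_table, ortholog = result$ortholog_table,
        provenance = result$provenance
      ),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA, pretty = TRUE
    ), "\n")
    return(invisible(character()))
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io(sprintf("cannot create output directory: %s", out_dir))
  paths <- character()
  stem <- function(name) file.path(out_dir, paste0(prefix, name))
  if (format %in% c("both", "tsv")) {
    write_result_tsv(result$regex_table, p <- stem("regex.tsv")); paths <- c(paths, p)
    write_result_tsv(result$ortholog_table, p <- stem("ortholog.tsv")); paths <- c(paths, p)
  }
  if (format %in% c("both", "json")) {
    write_result_json(result$regex_table, p <- stem("regex.json")); paths <- c(paths, p)
    write_result_json(result$ortholog_table, p <- stem("ortholog.json")); paths <- c(paths, p)
  }
  jsonlite::write_json(result$provenance, p <- stem("provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, p)
  invisible(paths)
}
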