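# Local motif database: three flat files in one cache directory.
#
#   classes.tsv              one curated motif class per row
#   instances.tsv            one curated motif occurrence per row
#   instance_sequences.fasta amino-acid sequences of the instance proteins
#   meta.json                version_tag + load counts
#
# TSV dialect: optional "#"-prefixed comment lines before the header; a
# header row; tab-separated cells that may be wrapped in double quotes;
# embedded tabs unsupported.  All coordinates are 1-based and inclusive on
# both ends, matching the curated-database convention; any 0-based
# arithmetic happens at internal boundaries only.

DB_FILE_CLASSES <- "classes.tsv"
DB_FILE_INSTANCES <- "instances.tsv"
DB_FILE_SEQUENCES <- "instance_sequences.fasta"
DB_FILE_META <- "meta.json"

CLASS_COLS <- c(
  "accession", "identifier", "functional_site_name", "description",
  "regex", "probability", "motif_type"
)
INSTANCE_COLS <- c(
  "class_identifier", "protein_accession", "protein_name", "start", "end",
  "instance_logic", "organism"
)
TRANSFERABLE_LOGIC <- c("true positive", "unknown")

read_slim_tsv <- function(path, what) {
  if (!file.exists(path)) stop_io(sprintf("%s file not found: %s", what, path))
  out <- tryCatch(
    utils::read.delim(path,
      header = TRUE, sep = "\t", quote = "\"", comment.char = "#",
      stringsAsFactors = FALSE, check.names = FALSE, colClasses = "character"
    ),
    error = function(e) stop_io(sprintf("cannot read %s file %s: %s", what, path, conditionMessage(e)))
  )
  out
}

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_schema(sprintf(
      "%s table is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

fill_optional <- function(df, cols) {
  for (col in setdiff(cols, names(df))) df[[col]] <- rep(NA_character_, nrow(df))
  df
}

## ---- classes -------------------------------------------------------------

#' Load the motif-class table
#'
#' Reads a tab-separated motif-class table (optional `#` comment lines,
#' then a header naming at least `accession`, `identifier`, `regex`,
#' `probability`; cells may be double-quoted).  Patterns are returned
#' verbatim and are not compiled here; [compile_pattern()] does that at
#' scan time so one bad pattern cannot block database loading.
#'
#' @param path Path to the class TSV file.
#' @return A data frame with one row per class and columns `accession`,
#'   `identifier`, `functional_site_name`, `description`, `pattern`,
#'   `probability` (numeric), `motif_type`, in file row order.
#' @export
load_motif_classes <- function(path) {
  raw <- read_slim_tsv(path, "motif class")
  require_columns(raw, c("accession", "identifier", "regex", "probability"), "motif class")
  raw <- fill_optional(raw, CLASS_COLS)
  dup <- unique(raw$identifier[duplicated(raw$identifier)])
  if (length(dup)) {
    stop_validation(sprintf(
      "duplicate motif class identifier(s): %s", paste(dup, collapse = ", ")
    ))
  }
  prob <- suppressWarnings(as.numeric(raw$probability))
  bad <- which(is.na(prob) | prob <= 0 | prob > 1)
  if (length(bad)) {
    stop_validation(sprintf(
      "class probability must be a number in (0, 1]; offending row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  data.frame(
    accession = raw$accession,
    identifier = raw$identifier,
    functional_site_name = raw$functional_site_name,
    description = raw$description,
    pattern = raw$regex,
    probability = prob,
    motif_type = raw$motif_type,
    stringsAsFactors = FALSE
  )
}

## ---- instances -----------------------------------------------------------

#' Load the motif-instance table
#'
#' Reads curated motif occurrences (same TSV dialect as
#' [load_motif_classes()]).  Rows failing validation — non-integer
#' coordinates, `start > end`, or `end` beyond the known length of the
#' instance protein — are rejected with a per-row warning and counted in
#' the attached load report rather than aborting the load.  Instances with
#' curation logic `"false positive"` or `"true negative"` are loaded for
#' provenance but flagged non-transferable: they never appear in
#' homology-transfer output.
#'
#' @param path Path to the instance TSV file.
#' @param sequences Named character vector mapping protein accession to
#'   amino-acid sequence (used for bounds checking; may be empty).
#' @return A data frame with columns `class_identifier`,
#'   `protein_accession`, `protein_name`, `start`, `end` (integer, 1-based
#'   inclusive), `instance_logic`, `organism`, `transferable`,
#'   `has_sequence`, canonically sorted by (class, protein, start, end) and
#'   de-duplicated on that key.  The load report (counts and per-row
#'   rejection reasons) is attached as attribute `"report"`.
#' @export
load_motif_instances <- function(path, sequences = character()) {
  raw <- read_slim_tsv(path, "motif instance")
  require_columns(raw, c("class_identifier", "protein_accession", "start", "end"), "motif instance")
  raw <- fill_optional(raw, INSTANCE_COLS)
  raw$instance_logic[is.na(raw$instance_logic) | raw$instance_logic == ""] <- "unknown"

  n_in <- nrow(raw)
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  seqlen <- nchar(sequences)[match(raw$protein_accession, names(sequences))]

  reason <- rep(NA_character_, n_in)
  nonint <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end) | start < 1
  reason[nonint] <- "start/end are not positive integers"
  rev_coord <- !nonint & start > end
  reason[rev_coord] <- "start > end"
  too_long <- !nonint & !rev_coord & !is.na(seqlen) & end > seqlen
  reason[too_long] <- "end exceeds instance protein length"

  rejected <- which(!is.na(reason))
  for (i in rejected) {
    warning(sprintf(
      "instance row %d (%s on %s): %s; row rejected",
      i, raw$class_identifier[i], raw$protein_accession[i], reason[i]
    ), call. = FALSE)
  }

  keep <- setdiff(seq_len(n_in), rejected)
  inst <- data.frame(
    class_identifier = raw$class_identifier[keep],
    protein_accession = raw$protein_accession[keep],
    protein_name = raw$protein_name[keep],
    start = as.integer(start[keep]),
    end = as.integer(end[keep]),
    instance_logic = raw$instance_logic[keep],
    organism = raw$organism[keep],
    stringsAsFactors = FALSE
  )
  n_dup <- sum(duplicated(inst[c("class_identifier", "protein_accession", "start", "end")]))
  inst <- inst[!duplicated(inst[c("class_identifier", "protein_accession", "start", "end")]), , drop = FALSE]
  inst <- inst[order(inst$class_identifier, inst$protein_accession, inst$start, inst$end), , drop = FALSE]
  rownames(inst) <- NULL

  inst$has_sequence <- inst$protein_accession %in% names(sequences)
  inst$transferable <- inst$instance_logic %in% TRANSFERABLE_LOGIC

  attr(inst, "report") <- list(
    n_rows = n_in,
    n_loaded = nrow(inst),
    n_rejected = length(rejected),
    n_duplicates_dropped = n_dup,
    n_transferable = sum(inst$transferable),
    n_without_sequence = sum(!inst$has_sequence),
    rejections = if (length(rejected)) {
      data.frame(row = rejected, reason = reason[rejected], stringsAsFactors = FALSE)
    } else {
      data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE)
    }
  )
  inst
}

## ---- FASTA ---------------------------------------------------------------

read_instance_fasta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("sequence FASTA not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  # accession = first whitespace-delimited token of the header line
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(seqs))) {
    stop_validation(sprintf(
      "duplicate accession(s) in sequence FASTA: %s",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")
    ))
  }
  seqs
}

## ---- whole database ------------------------------------------------------

#' Load a motif database from its cache directory
#'
#' Expects the fixed cache layout (`classes.tsv`, `instances.tsv`,
#' `instance_sequences.fasta`, optional `meta.json`) produced by
#' [setup_database()], [write_database()] or [generate_database()].
#' Instances referencing an unknown motif class are rejected with a
#' warning; instance proteins without a sequence are kept for metadata but
#' excluded from the alignment target set.
#'
#' @param dir Cache directory.
#' @param quiet Suppress the load-report message.
#' @return An object of class `slim_db`: a list with `classes`,
#'   `instances`, `sequences` (named character vector), `version_tag` and
#'   `report`.
#' @export
load_database <- function(dir, quiet = FALSE) {
  paths <- file.path(dir, c(DB_FILE_CLASSES, DB_FILE_INSTANCES, DB_FILE_SEQUENCES))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_setup(sprintf(
      "motif database cache is incomplete (missing: %s); run setup_database() or `slimscan setup` first",
      paste(basename(missing), collapse = ", ")
    ))
  }
  classes <- load_motif_classes(paths[1L])
  sequences <- read_instance_fasta(paths[3L])
  instances <- load_motif_instances(paths[2L], sequences)

  unknown <- !instances$class_identifier %in% classes$identifier
  if (any(unknown)) {
    warning(sprintf(
      "%d instance row(s) reference unknown motif class(es) (%s); rows rejected",
      sum(unknown), paste(unique(instances$class_identifier[unknown]), collapse = ", ")
    ), call. = FALSE)
    instances <- instances[!unknown, , drop = FALSE]
    rownames(instances) <- NULL
  }

  version_tag <- "unversioned"
  meta_path <- file.path(dir, DB_FILE_META)
  if (file.exists(meta_path)) {
    meta <- tryCatch(jsonlite::read_json(meta_path), error = function(e) NULL)
    if (!is.null(meta$version_tag)) version_tag <- meta$version_tag
  }

  report <- attr(instances, "report")
  report$n_classes <- nrow(classes)
  report$n_sequences <- length(sequences)
  report$n_unknown_class <- sum(unknown)
  report$n_transferable <- sum(instances$transferable)

  if (!quiet) {
    message(sprintf(
      "slimscan db [%s]: %d classes, %d instance proteins, %d instances (%d transferable, %d rejected, %d without sequence)",
      version_tag, report$n_classes, report$n_sequences, report$n_loaded,
      report$n_transferable, report$n_rejected + report$n_unknown_class,
      report$n_without_sequence
    ))
  }

  structure(
    list(
      classes = classes, instances = instances, sequences = sequences,
      version_tag = version_tag, report = report
    ),
    class = "slim_db"
  )
}

#' @export
print.slim_db <- function(x, ...) {
  cat(sprintf(
    "<slim_db> %d motif classes, %d instances on %d proteins (version: %s)\n",
    nrow(x$classes), nrow(x$instances), length(x$sequences), x$version_tag
  ))
  invisible(x)
}

write_tsv_file <- function(df, path, comment) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = ""
  )
}

#' Write a motif database to a cache directory
#'
#' Writes the fixed three-file cache layout plus `meta.json`.  Writing a
#' loaded database and loading it again reproduces the same database
#' (write -> load -> write is idempotent on the three data files;
#' `meta.json` carries the write timestamp).
#'
#' @param db A `slim_db` object.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- db$classes
  out_cls <- data.frame(
    accession = cls$accession, identifier = cls$identifier,
    functional_site_name = cls$functional_site_name, description = cls$description,
    regex = cls$pattern, probability = cls$probability, motif_type = cls$motif_type,
    stringsAsFactors = FALSE
  )
  write_tsv_file(out_cls, file.path(dir, DB_FILE_CLASSES), "slimscan motif class table")
  write_tsv_file(
    db$instances[INSTANCE_COLS],
    file.path(dir, DB_FILE_INSTANCES), "slimscan motif instance table"
  )
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(db$sequences),
    file.path(dir, DB_FILE_SEQUENCES)
  )
  jsonlite::write_json(
    list(
      version_tag = db$version_tag,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_classes = nrow(db$classes),
      n_instances = nrow(db$instances),
      n_sequences = length(db$sequences)
    ),
    file.path(dir, DB_FILE_META),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Populate or update the local database cache
#'
#' Copies (or downloads) the three database files into the cache
#' directory.  The new cache is staged in a temporary sibling directory,
#' validated by a full load, and then swapped in atomically, so a failed
#' fetch leaves any existing cache untouched.  Re-running on the same
#' source yields a byte-identical cache except for the `meta.json`
#' version/timestamp.
#'
#' @param dir Cache directory to (re)create.
#' @param source Named character vector or list with entries `classes`,
#'   `instances`, `sequences`: local paths or http(s) URLs.
#' @param quiet Suppress the load-report message.
#' @return The loaded `slim_db`, invisibly.
#' @export
setup_database <- function(dir, source, quiet = FALSE) {
  needed <- c("classes", "instances", "sequences")
  if (!all(needed %in% names(source))) {
    stop_input(sprintf(
      "source must name entries %s", paste(needed, collapse = ", ")
    ))
  }
  targets <- c(DB_FILE_CLASSES, DB_FILE_INSTANCES, DB_FILE_SEQUENCES)
  names(targets) <- needed

  stage <- tempfile("slimscan_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  for (key in needed) {
    src <- as.character(source[[key]])
    dst <- file.path(stage, targets[[key]])
    if (grepl("^https?://", src)) {
      ok <- tryCatch(
        utils::download.file(src, dst, quiet = TRUE, mode = "wb") == 0L,
        error = function(e) FALSE, warning = function(w) FALSE
      )
      if (!ok) stop_setup(sprintf("download failed for %s (%s); existing cache left untouched", key, src))
    } else {
      if (!file.exists(src)) stop_setup(sprintf("source file for %s not found: %s", key, src))
      file.copy(src, dst, overwrite = TRUE)
    }
  }

  # validate before touching the live cache
  db <- load_database(stage, quiet = TRUE)

  jsonlite::write_json(
    list(
      version_tag = sprintf("setup:%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_classes = nrow(db$classes),
      n_instances = nrow(db$instances),
      n_sequences = length(db$sequences)
    ),
    file.path(stage, DB_FILE_META),
    auto_unbox = TRUE, pretty = TRUE
  )

  # atomic swap: stage -> dir (rename where possible, else copy+remove)
  parent <- dirname(normalizePath(dir, mustWork = FALSE))
  dir.create(parent, showWarnings = FALSE, recursive = TRUE)
  old <- tempfile("slimscan_old_", tmpdir = parent)
  had_old <- dir.exists(dir)
  if (had_old) file.rename(dir, old)
  if (!file.rename(stage, dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    file.copy(list.files(stage, full.names = TRUE), dir, overwrite = TRUE)
  }
  if (had_old) unlink(old, recursive = TRUE)

  invisible(load_database(dir, quiet = quiet))
}
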