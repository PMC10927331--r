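# Synthetic motif databases with known, implanted motif occurrences.
#
# The generator emulates the three-file database cache end to end: motif
# classes with realistic fixed-length patterns, instance proteins with
# uniform-background sequences, implanted pattern occurrences recorded as
# "true positive" instances, and a ground-truth manifest.  Everything is
# deterministic under the fixture-spec seed, so recovery tests have an
# unambiguous answer key.

DEFAULT_PATTERN_TEMPLATES <- c(
  "....WF.L",             # WD40-binding style ligand site
  "P.[ST]P..",            # proline-directed phosphosite context
  "[RK]{2}.L[LIVMF]",     # basic docking site
  "W..[FY]..L",           # aromatic ligand site
  "[ED]{2}[LIVM].{2}[FY]" # acidic ligand site
)

#' Specification for a synthetic motif database
#'
#' The defaults define the reference study conditions used throughout the
#' test suite: 5 motif classes with fixed-length patterns, 10 instance
#' proteins of 150-250 residues, 2 implanted occurrences per protein.
#'
#' @param n_classes Number of motif classes.
#' @param pattern_templates Regex sources (supported dialect) recycled
#'   across classes.
#' @param n_proteins Number of instance proteins.
#' @param protein_length_range `c(min, max)` residues.
#' @param implants_per_protein Implanted motif occurrences per protein.
#' @param divergence Default per-residue substitution probability used by
#'   [derive_query()] when deriving a query ortholog.
#' @param seed Integer RNG seed; identical specs produce byte-identical
#'   databases.
#' @return An object of class `slim_fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 5L,
                         pattern_templates = DEFAULT_PATTERN_TEMPLATES,
                         n_proteins = 10L,
                         protein_length_range = c(150L, 250L),
                         implants_per_protein = 2L,
                         divergence = 0.05,
                         seed = 1L) {
  stopifnot(
    n_classes >= 0, n_proteins >= 0, implants_per_protein >= 0,
    divergence >= 0, divergence <= 1,
    length(protein_length_range) == 2L,
    protein_length_range[1] >= 1, protein_length_range[2] >= protein_length_range[1]
  )
  structure(
    list(
      n_classes = as.integer(n_classes),
      pattern_templates = pattern_templates,
      n_proteins = as.integer(n_proteins),
      protein_length_range = as.integer(protein_length_range),
      implants_per_protein = as.integer(implants_per_protein),
      divergence = divergence,
      seed = as.integer(seed)
    ),
    class = "slim_fixture_spec"
  )
}

## ---- pattern sampling ----------------------------------------------------

# Sample one concrete string matching an AST from the supported dialect.
# Wildcards and classes draw a random canonical residue; quantifiers use
# their minimum repeat count so implanted spans are predictable;
# alternation picks a uniform branch.  Uses the current RNG stream.
sample_ast <- function(node, label) {
  switch(node$type,
    lit = node$char,
    any = sample(AA_CANONICAL, 1L),
    class = {
      allowed <- if (node$negated) {
        setdiff(AA_CANONICAL, node$chars)
      } else {
        intersect(node$chars, c(AA_CANONICAL, LETTERS))
      }
      if (!length(allowed)) {
        stop_validation(sprintf(
          "pattern %s admits no canonical residue in a character class; cannot sample", label
        ))
      }
      sample(allowed, 1L)
    },
    quant = paste(vapply(seq_len(node$min), function(i) sample_ast(node$node, label), character(1)),
      collapse = ""
    ),
    concat = paste(vapply(node$items, sample_ast, character(1), label = label), collapse = ""),
    alt = sample_ast(node$branches[[sample.int(length(node$branches), 1L)]], label),
    stop_contract("unknown AST node type")
  )
}

#' Sample a concrete string matching a motif pattern
#'
#' @param pattern Pattern source string (supported dialect) or a compiled
#'   `slim_pattern`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A string that matches the pattern when anchored at both ends.
#' @export
sample_from_pattern <- function(pattern, seed = NULL) {
  cp <- if (inherits(pattern, "slim_pattern")) pattern else compile_pattern(pattern)
  draw <- function() sample_ast(cp$ast, sQuote(cp$source))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

random_protein <- function(length) {
  paste(sample(AA_CANONICAL, length, replace = TRUE), collapse = "")
}

# sample() treats a length-1 integer as 1:n; guard against that
sample_between <- function(lo, hi) {
  if (lo == hi) lo else sample(seq(lo, hi), 1L)
}

splice_at <- function(seq, piece, start) {
  paste0(
    substring(seq, 1L, start - 1L), piece,
    substring(seq, start + nchar(piece), nchar(seq))
  )
}

## ---- database generation -------------------------------------------------

#' Generate a synthetic motif database with implanted occurrences
#'
#' Builds a complete database cache: classes with patterns drawn from the
#' spec templates, uniform-background proteins, and implanted occurrences
#' synthesized by sampling each class pattern and splicing the sample into
#' the protein at a recorded span.  Implants are placed in disjoint blocks
#' of each protein so spans never overlap.  The instance table rows are
#' exactly the implant records (logic `"true positive"`), and a
#' `ground_truth.json` manifest listing every implant is written alongside
#' the cache files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Directory to write the cache into.
#' @param quiet Suppress the load-report message.
#' @return The generated database as a `slim_db`, with the implant
#'   manifest attached as element `implants`.
#' @export
generate_database <- function(spec, dir, quiet = TRUE) {
  stopifnot(inherits(spec, "slim_fixture_spec"))
  with_seed(spec$seed, generate_database_impl(spec, dir, quiet))
}

generate_database_impl <- function(spec, dir, quiet) {
  motif_types <- c("LIG", "DOC", "DEG", "MOD", "TRG", "CLV")
  n_cls <- spec$n_classes
  templates <- if (n_cls > 0) {
    rep_len(spec$pattern_templates, n_cls)
  } else {
    character()
  }
  classes <- data.frame(
    accession = sprintf("ELMF%06d", seq_len(n_cls)),
    identifier = sprintf("FIX_CLASS_%02d", seq_len(n_cls)),
    functional_site_name = sprintf("Synthetic site %d", seq_len(n_cls)),
    description = sprintf("Synthetic motif class sampled from pattern %s", templates),
    pattern = templates,
    probability = signif(stats::runif(n_cls, 1e-4, 1e-2), 6),
    motif_type = rep_len(motif_types, n_cls),
    stringsAsFactors = FALSE
  )
  # compile up front: a template outside the supported dialect, or one that
  # admits no concrete string, must fail generation with the pattern named
  compiled <- lapply(seq_len(n_cls), function(k) {
    compile_pattern(classes$pattern[k], classes$identifier[k])
  })

  sequences <- character()
  inst_rows <- list()
  for (p in seq_len(spec$n_proteins)) {
    acc <- sprintf("FIXP%03d", p)
    len <- sample_between(spec$protein_length_range[1], spec$protein_length_range[2])
    seq <- random_protein(len)

    k_impl <- spec$implants_per_protein
    if (k_impl > 0L && n_cls > 0L) {
      cls_idx <- sample.int(n_cls, k_impl, replace = k_impl > n_cls)
      # one implant per equal-width block => spans are always disjoint
      block <- floor(len / k_impl)
      for (j in seq_len(k_impl)) {
        cp <- compiled[[cls_idx[j]]]
        piece <- sample_ast(cp$ast, classes$identifier[cls_idx[j]])
        w <- nchar(piece)
        lo <- (j - 1L) * block + 1L
        hi <- j * block - w + 1L
        if (hi < lo) {
          stop_validation(sprintf(
            "protein %s too short (%d aa) for %d implant(s) of pattern %s",
            acc, len, k_impl, sQuote(cp$source)
          ))
        }
        start <- sample_between(lo, hi)
        seq <- splice_at(seq, piece, start)
        inst_rows[[length(inst_rows) + 1L]] <- data.frame(
          class_identifier = classes$identifier[cls_idx[j]],
          protein_accession = acc,
          protein_name = sprintf("Synthetic instance protein %d", p),
          start = start,
          end = start + w - 1L,
          instance_logic = "true positive",
          organism = "synthetic",
          stringsAsFactors = FALSE
        )
      }
    }
    sequences[[acc]] <- seq
  }

  instances <- if (length(inst_rows)) {
    do.call(rbind, inst_rows)
  } else {
    data.frame(
      class_identifier = character(), protein_accession = character(),
      protein_name = character(), start = integer(), end = integer(),
      instance_logic = character(), organism = character(),
      stringsAsFactors = FALSE
    )
  }
  instances <- instances[order(
    instances$class_identifier, instances$protein_accession,
    instances$start, instances$end
  ), , drop = FALSE]
  rownames(instances) <- NULL
  instances$has_sequence <- rep(TRUE, nrow(instances))
  instances$transferable <- rep(TRUE, nrow(instances))

  db <- structure(
    list(
      classes = classes, instances = instances, sequences = sequences,
      version_tag = sprintf(
        "fixture:seed=%d;classes=%d;proteins=%d;implants=%d",
        spec$seed, n_cls, spec$n_proteins, spec$implants_per_protein
      ),
      report = NULL
    ),
    class = "slim_db"
  )
  write_database(db, dir)
  jsonlite::write_json(
    instances[c("class_identifier", "protein_accession", "start", "end")],
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", pretty = TRUE
  )

  out <- load_database(dir, quiet = quiet)
  out$implants <- instances[c("class_identifier", "protein_accession", "start", "end")]
  out
}

## ---- query derivation ----------------------------------------------------

#' Derive a diverged query ortholog from an instance protein
#'
#' Copies the instance protein and substitutes each residue independently
#' with probability `divergence`; replacements are drawn uniformly from
#' the 19 other canonical residues, so a substituted position always
#' changes.  With `preserve_implants = TRUE`, residues inside any curated
#' instance span on that protein are never substituted, emulating the
#' strong conservation of functional motifs in otherwise diverged
#' orthologs.
#'
#' @param protein_accession Accession of the source protein in `db`.
#' @param db A `slim_db`.
#' @param divergence Per-residue substitution probability in \[0, 1\].
#' @param preserve_implants Protect curated instance spans from
#'   substitution.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The derived amino-acid sequence.
#' @export
derive_query <- function(protein_accession, db, divergence = 0.05,
                         preserve_implants = TRUE, seed = NULL) {
  if (!protein_accession %in% names(db$sequences)) {
    stop_resolution(sprintf("unknown protein accession: %s", protein_accession))
  }
  if (divergence < 0 || divergence > 1) stop_input("divergence must be in [0, 1]")
  seq <- db$sequences[[protein_accession]]
  impl <- function() {
    res <- strsplit(seq, "")[[1]]
    protected <- rep(FALSE, length(res))
    if (preserve_implants) {
      spans <- db$instances[db$instances$protein_accession == protein_accession, , drop = FALSE]
      for (i in seq_len(nrow(spans))) {
        protected[spans$start[i]:spans$end[i]] <- TRUE
      }
    }
    hit <- stats::runif(length(res)) < divergence & !protected
    for (i in which(hit)) {
      res[i] <- sample(setdiff(AA_CANONICAL, res[i]), 1L)
    }
    paste(res, collapse = "")
  }
  if (is.null(seed)) impl() else with_seed(seed, impl())
}

## ---- worked-example sequence ---------------------------------------------

#' Synthesize a sequence whose only match of a pattern is one implant
#'
#' Generates a uniform-background sequence with a single sampled
#' occurrence of `pattern` spliced in at `start`, then verifies by
#' re-scanning that the implant is the unique match of that pattern in the
#' sequence.  If the random background happens to contain an accidental
#' second match the background is deterministically re-drawn (the implant
#' residues are kept), so the returned sequence always has exactly one
#' occurrence — the setting needed to demonstrate motif loss under a point
#' mutation.
#'
#' @param pattern Pattern source string.
#' @param length Sequence length in residues.
#' @param start 1-based implant start position.
#' @param seed Integer seed.
#' @return A string with attributes `implant_start`, `implant_end`.
#' @export
synthesize_motif_sequence <- function(pattern, length = 60L, start = 25L, seed = 1L) {
  cp <- compile_pattern(pattern)
  with_seed(seed, {
    piece <- sample_ast(cp$ast, sQuote(pattern))
    w <- nchar(piece)
    if (start < 1L || start + w - 1L > length) {
      stop_input("implant span does not fit in the requested sequence length")
    }
    cls <- data.frame(identifier = "QUERY_PATTERN", pattern = pattern)
    for (attempt in seq_len(1000L)) {
      seq <- splice_at(random_protein(length), piece, start)
      hits <- scan_sequence(seq, cls)
      if (nrow(hits) == 1L && hits$start == start && hits$end == start + w - 1L) {
        return(structure(seq, implant_start = start, implant_end = start + w - 1L))
      }
    }
    stop_validation(sprintf(
      "could not synthesize a sequence with a unique occurrence of %s", sQuote(pattern)
    ))
  })
}
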