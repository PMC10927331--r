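# Motif-class pattern compilation and exhaustive (overlap-reporting) scanning.
#
# Supported pattern dialect (a POSIX-ERE subset, the constructs curated
# motif-class patterns actually use):
#   literal residue letters; "." wildcard; character classes "[...]" and
#   "[^...]" with letter ranges; quantifiers "{m}", "{m,n}", "{m,}", "*",
#   "+", "?"; grouping "(...)"; alternation "|"; "^" as first character
#   (match must start at residue 1) and "$" as last character (match must
#   end at the final residue).
# Backreferences, escapes, lookaround and interior anchors are rejected at
# compile time.  Matching uses leftmost-longest (POSIX) semantics: at each
# query offset the longest possible extent is reported.

#' @keywords internal
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## ---- pattern parser ------------------------------------------------------

# Recursive-descent parse of the supported dialect into an AST used for
# validation, minimal-length computation and fixture sampling.  Node types:
#   alt(branches), concat(items), lit(char), any, class(chars, negated),
#   quant(node, min, max)
parse_pattern_body <- function(body, label) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 0L

  peek <- function() if (pos < n) chars[pos + 1L] else NA_character_
  take <- function() {
    pos <<- pos + 1L
    chars[pos]
  }
  perr <- function(msg) {
    stop_compile(sprintf("pattern %s: %s at position %d", label, msg, pos + 1L))
  }

  parse_alt <- function() {
    branches <- list(parse_concat())
    while (identical(peek(), "|")) {
      take()
      branches[[length(branches) + 1L]] <- parse_concat()
    }
    if (length(branches) == 1L) branches[[1L]] else list(type = "alt", branches = branches)
  }

  parse_concat <- function() {
    items <- list()
    repeat {
      p <- peek()
      if (is.na(p) || p == "|" || p == ")") break
      items[[length(items) + 1L]] <- parse_term()
    }
    if (length(items) == 1L) items[[1L]] else list(type = "concat", items = items)
  }

  parse_term <- function() {
    atom <- parse_atom()
    p <- peek()
    if (is.na(p) || !p %in% c("*", "+", "?", "{")) return(atom)
    take()
    if (p == "*") return(list(type = "quant", node = atom, min = 0L, max = Inf))
    if (p == "+") return(list(type = "quant", node = atom, min = 1L, max = Inf))
    if (p == "?") return(list(type = "quant", node = atom, min = 0L, max = 1L))
    # "{m}", "{m,}", "{m,n}"
    digits <- function() {
      d <- ""
      while (!is.na(peek()) && grepl("[0-9]", peek())) d <- paste0(d, take())
      d
    }
    m <- digits()
    if (m == "") perr("malformed quantifier: expected digits after '{'")
    mi <- as.integer(m)
    mx <- mi
    if (identical(peek(), ",")) {
      take()
      nn <- digits()
      mx <- if (nn == "") Inf else as.integer(nn)
    }
    if (!identical(peek(), "}")) perr("malformed quantifier: missing '}'")
    take()
    if (is.finite(mx) && mx < mi) perr("malformed quantifier: max repeat below min")
    list(type = "quant", node = atom, min = mi, max = mx)
  }

  parse_atom <- function() {
    p <- peek()
    if (is.na(p)) perr("unexpected end of pattern")
    if (p == "(") {
      take()
      if (identical(peek(), "?")) {
        perr("unsupported construct '(?...': lookaround and special groups")
      }
      inner <- parse_alt()
      if (!identical(peek(), ")")) perr("unbalanced '('")
      take()
      return(inner)
    }
    if (p == "[") return(parse_class())
    if (p == ".") {
      take()
      return(list(type = "any"))
    }
    if (p == "\\") perr("unsupported construct: escape sequences and backreferences")
    if (p == "^") perr("unsupported construct: '^' anchor in interior position")
    if (p == "$") perr("unsupported construct: '$' anchor in interior position")
    if (p %in% c("*", "+", "?", "{")) perr(sprintf("quantifier '%s' with no preceding atom", p))
    if (p == ")") perr("unbalanced ')'")
    if (grepl("[A-Za-z]", p)) {
      take()
      return(list(type = "lit", char = toupper(p)))
    }
    perr(sprintf("unsupported character '%s'", p))
  }

  parse_class <- function() {
    take() # "["
    negated <- FALSE
    if (identical(peek(), "^")) {
      take()
      negated <- TRUE
    }
    members <- character()
    if (identical(peek(), "]")) perr("empty character class")
    while (!identical(peek(), "]")) {
      p <- peek()
      if (is.na(p)) perr("unterminated character class")
      if (!grepl("[A-Za-z]", p)) perr(sprintf("unsupported character '%s' in class", p))
      a <- toupper(take())
      if (identical(peek(), "-") && !identical(chars[pos + 2L], "]") && pos + 2L <= n) {
        take() # "-"
        b <- peek()
        if (is.na(b) || !grepl("[A-Za-z]", b)) perr("malformed range in character class")
        b <- toupper(take())
        if (utf8ToInt(b) < utf8ToInt(a)) perr("reversed range in character class")
        members <- c(members, strsplit(intToUtf8(utf8ToInt(a):utf8ToInt(b), multiple = TRUE), "")[[1]])
      } else {
        members <- c(members, a)
      }
    }
    take() # "]"
    list(type = "class", chars = unique(members), negated = negated)
  }

  ast <- parse_alt()
  if (pos < n) {
    if (identical(peek(), ")")) perr("unbalanced ')'")
    perr(sprintf("unexpected '%s'", peek()))
  }
  ast
}

# Shortest string length the AST can match.
ast_min_length <- function(node) {
  switch(node$type,
    lit = 1L,
    any = 1L,
    class = 1L,
    quant = node$min * ast_min_length(node$node),
    concat = sum(vapply(node$items, ast_min_length, integer(1))),
    alt = min(vapply(node$branches, ast_min_length, integer(1))),
    stop_contract("unknown AST node type")
  )
}

## ---- compilation ---------------------------------------------------------

#' Compile a motif-class pattern
#'
#' Validates a pattern against the supported POSIX-ERE subset and prepares
#' it for offset-anchored scanning.  `^` is only meaningful as the first
#' character (the motif must start at residue 1) and `$` only as the last
#' (the motif must end at the final residue); anywhere else both are
#' rejected, as are backreferences, escape sequences and lookaround.
#'
#' @param source Pattern string, e.g. `"....WF.L"`.
#' @param identifier Optional motif-class identifier used in error messages.
#' @return An object of class `slim_pattern` with fields `source`, `body`
#'   (source with terminal anchors stripped), `anchored_n`, `anchored_c`,
#'   `ast` (parse tree) and `min_length` (shortest matchable string).
#' @examples
#' p <- compile_pattern("....WF.L")
#' p$min_length # 8
#' @export
compile_pattern <- function(source, identifier = NULL) {
  if (!is.character(source) || length(source) != 1L || is.na(source) || !nzchar(source)) {
    stop_input("pattern source must be a single non-empty string")
  }
  label <- if (is.null(identifier)) sQuote(source) else sprintf("%s (%s)", identifier, sQuote(source))

  body <- source
  anchored_n <- startsWith(body, "^")
  if (anchored_n) body <- substring(body, 2L)
  anchored_c <- endsWith(body, "$")
  if (anchored_c) body <- substring(body, 1L, nchar(body) - 1L)
  if (!nzchar(body)) stop_compile(sprintf("pattern %s: empty pattern body", label))

  ast <- parse_pattern_body(body, label)
  structure(
    list(
      source = source,
      body = toupper(body),
      anchored_n = anchored_n,
      anchored_c = anchored_c,
      ast = ast,
      min_length = ast_min_length(ast)
    ),
    class = "slim_pattern"
  )
}

#' @export
print.slim_pattern <- function(x, ...) {
  cat(sprintf(
    "<slim_pattern> %s  (min length %d%s%s)\n",
    x$source, x$min_length,
    if (x$anchored_n) ", N-anchored" else "",
    if (x$anchored_c) ", C-anchored" else ""
  ))
  invisible(x)
}

## ---- scanning ------------------------------------------------------------

# Uppercase and validate an amino-acid sequence; any character outside A-Z
# is an input error naming the first offending position.  Non-canonical
# letters (B, J, O, U, X, Z) are legal: real database sequences contain
# them.
validate_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop_input(sprintf("%s must be a single string", what))
  }
  seq <- toupper(seq)
  bad <- regexpr("[^A-Z]", seq)
  if (bad != -1L) {
    stop_input(sprintf(
      "%s contains illegal character '%s' at position %d",
      what, substr(seq, bad, bad), as.integer(bad)
    ))
  }
  seq
}

# All (start, end) spans of one compiled pattern in `query` (already
# validated/uppercased).  One leftmost-longest match is attempted at every
# offset, so overlapping occurrences are all reported.
scan_pattern_spans <- function(query, cp) {
  n <- nchar(query)
  if (n < cp$min_length) {
    return(data.frame(start = integer(), end = integer()))
  }
  offs <- if (cp$anchored_n) 1L else seq_len(n - cp$min_length + 1L)
  regex <- paste0("^(", cp$body, ")", if (cp$anchored_c) "$" else "")
  m <- regexpr(regex, substring(query, offs, n), perl = FALSE)
  len <- attr(m, "match.length")
  ok <- m == 1L & len > 0L # zero-length matches are not motif occurrences
  data.frame(start = offs[ok], end = offs[ok] + len[ok] - 1L)
}

#' Scan a query sequence against a set of motif classes
#'
#' Attempts an anchored leftmost-longest match of every class pattern at
#' every query offset and reports each distinct (class, start, end) span,
#' so overlapping matches of the same or different classes are all
#' reported.  N-anchored patterns (`^...`) are only tried at offset 1;
#' C-anchored patterns (`...$`) must extend to the final residue.
#'
#' @param query Amino-acid sequence (case-insensitive; letters A-Z only).
#' @param classes Motif-class table as returned by [load_motif_classes()],
#'   i.e. a data frame with at least `identifier` and `pattern` columns.
#' @return A data frame with columns `class_identifier`,
#'   `matched_sequence`, `start`, `end` (1-based inclusive residue
#'   coordinates), ordered by class identifier, then start, then end.
#' @examples
#' cls <- data.frame(identifier = "LIG_PALB2_WD40_1", pattern = "....WF.L")
#' scan_sequence("MAAAWFALKK", cls)
#' @export
scan_sequence <- function(query, classes) {
  query <- validate_sequence(query, "query sequence")
  if (is.null(classes$identifier) || is.null(classes$pattern)) {
    stop_schema("classes must have 'identifier' and 'pattern' columns")
  }
  out <- vector("list", nrow(classes))
  for (k in seq_len(nrow(classes))) {
    cp <- compile_pattern(classes$pattern[k], classes$identifier[k])
    spans <- scan_pattern_spans(query, cp)
    if (nrow(spans)) {
      out[[k]] <- data.frame(
        class_identifier = classes$identifier[k],
        matched_sequence = substring(query, spans$start, spans$end),
        start = spans$start,
        end = spans$end,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(
      class_identifier = character(), matched_sequence = character(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$class_identifier, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## ---- output table --------------------------------------------------------

REGEX_TABLE_COLS <- c(
  "motif_class_accession", "motif_class_identifier", "functional_site_name",
  "description", "motif_type", "probability", "matched_sequence",
  "motif_start_in_query", "motif_end_in_query"
)

#' Annotate regex matches with motif-class metadata
#'
#' Joins each match record from [scan_sequence()] with its class
#' annotation, producing the candidate-motif ("regex") result table.
#'
#' @param records Match records from [scan_sequence()].
#' @param classes Motif-class table ([load_motif_classes()]).
#' @return A data frame with columns `motif_class_accession`,
#'   `motif_class_identifier`, `functional_site_name`, `description`,
#'   `motif_type`, `probability`, `matched_sequence`,
#'   `motif_start_in_query`, `motif_end_in_query`.
#' @export
build_regex_table <- function(records, classes) {
  empty <- data.frame(
    motif_class_accession = character(), motif_class_identifier = character(),
    functional_site_name = character(), description = character(),
    motif_type = character(), probability = numeric(),
    matched_sequence = character(), motif_start_in_query = integer(),
    motif_end_in_query = integer(), stringsAsFactors = FALSE
  )
  if (is.null(records) || nrow(records) == 0L) return(empty)
  idx <- match(records$class_identifier, classes$identifier)
  if (anyNA(idx)) {
    stop_contract(sprintf(
      "match records reference unknown motif class(es): %s",
      paste(unique(records$class_identifier[is.na(idx)]), collapse = ", ")
    ))
  }
  data.frame(
    motif_class_accession = classes$accession[idx],
    motif_class_identifier = records$class_identifier,
    functional_site_name = classes$functional_site_name[idx],
    description = classes$description[idx],
    motif_type = classes$motif_type[idx],
    probability = classes$probability[idx],
    matched_sequence = records$matched_sequence,
    motif_start_in_query = records$start,
    motif_end_in_query = records$end,
    stringsAsFactors = FALSE
  )
}
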