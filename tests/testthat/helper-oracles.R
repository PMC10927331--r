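# Independent oracles used to cross-check the package's scanner, aligner
# and projection.  These deliberately use different machinery than the
# implementation: the scan oracle enumerates whole substrings with PCRE
# boolean matches, the alignment oracle is a naive unbounded-gap DP, and
# the projection oracle is an explicit column-by-column walk.

# All (start, end) spans of `source` in `query`: for every start offset,
# test every candidate end with a fully anchored PCRE match and keep the
# longest matching end.  Zero-length matches are not spans.
oracle_scan_spans <- function(query, source) {
  query <- toupper(query)
  n <- nchar(query)
  body <- source
  anch_n <- startsWith(body, "^")
  if (anch_n) body <- substring(body, 2L)
  anch_c <- endsWith(body, "$")
  if (anch_c) body <- substring(body, 1L, nchar(body) - 1L)
  pat <- paste0("^(?:", body, ")$")
  starts <- if (anch_n) 1L else seq_len(n)
  out <- list()
  for (i in starts) {
    if (i > n) next
    ends <- if (anch_c) n else i:n
    ok <- grepl(pat, substring(query, i, ends), perl = TRUE)
    if (any(ok)) {
      out[[length(out) + 1L]] <- c(start = i, end = ends[ok][sum(ok)])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Random pattern from the supported dialect (biased toward motif-like
# shapes), for property tests.
random_dialect_pattern <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_class <- function() {
    members <- paste(sample(aa, sample(2:4, 1)), collapse = "")
    if (runif(1) < 0.25) paste0("[^", members, "]") else paste0("[", members, "]")
  }
  rand_atom <- function() {
    u <- runif(1)
    if (u < 0.40) sample(aa, 1)
    else if (u < 0.65) "."
    else if (u < 0.90) rand_class()
    else paste0("(", sample(aa, 1), "|", paste(sample(aa, sample(1:2, 1)), collapse = ""), ")")
  }
  rand_quant <- function() {
    if (runif(1) < 0.7) return("")
    sample(c("*", "+", "?", "{2}", "{1,3}", "{2,}"), 1)
  }
  n_el <- sample(2:6, 1)
  body <- paste(vapply(seq_len(n_el), function(i) paste0(rand_atom(), rand_quant()), character(1)),
    collapse = ""
  )
  paste0(
    if (runif(1) < 0.15) "^" else "",
    body,
    if (runif(1) < 0.15) "$" else ""
  )
}

random_aa_sequence <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTWYV", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Naive affine-gap local-alignment score: unbounded-gap recurrence
# H(i,j) = max(0, H(i-1,j-1)+s, max_k H(i,k) - open - ext*(j-k),
#              max_k H(k,j) - open - ext*(i-k))
# A gap of length L costs open + L*ext, matching the package convention.
oracle_sw_score <- function(q, s, scheme) {
  qc <- strsplit(toupper(q), "")[[1]]
  sc <- strsplit(toupper(s), "")[[1]]
  n <- length(qc)
  m <- length(sc)
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      diag <- H[i - 1L, j - 1L] + scheme$matrix[qc[i - 1L], sc[j - 1L]]
      gap_in_q <- max(H[i, 1:(j - 1L)] - (open + ext * ((j - 1L):1)))
      gap_in_s <- max(H[1:(i - 1L), j] - (open + ext * ((i - 1L):1)))
      H[i, j] <- max(0, diag, gap_in_q, gap_in_s)
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Explicit column-walk projection of a subject interval onto the query:
# advances residue counters one column at a time and records the first /
# last query residue seen between the subject start and end columns.
oracle_project <- function(trace, q_start, s_start, inst_start, inst_end) {
  ops <- strsplit(trace, "")[[1]]
  qp <- q_start - 1L
  sp <- s_start - 1L
  col_s <- integer(0)
  col_q <- integer(0)
  for (op in ops) {
    if (op %in% c("M", "I")) qp <- qp + 1L
    if (op %in% c("M", "D")) sp <- sp + 1L
    col_s <- c(col_s, if (op %in% c("M", "D")) sp else NA_integer_)
    col_q <- c(col_q, if (op %in% c("M", "I")) qp else NA_integer_)
  }
  cs <- match(inst_start, col_s)
  ce <- match(inst_end, col_s)
  if (is.na(cs) || is.na(ce)) return(NULL)
  qs <- NA_integer_
  for (k in cs:length(ops)) {
    if (!is.na(col_q[k])) {
      qs <- col_q[k]
      break
    }
  }
  qe <- NA_integer_
  for (k in ce:1) {
    if (!is.na(col_q[k])) {
      qe <- col_q[k]
      break
    }
  }
  if (is.na(qs) || is.na(qe) || qs > qe) return(NULL)
  c(qs, qe)
}
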