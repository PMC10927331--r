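---
title: "How slimscan finds candidate short linear motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How slimscan finds candidate short linear motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

## The problem and the two-table design

Short linear motifs (SLiMs) are 3–15 residue protein segments, mostly in
disordered regions, that mediate protein–protein interactions,
modifications, targeting and degradation. Curated motif databases
describe each motif **class** by a regular-expression pattern plus
annotation, and record validated **instances** of classes on specific
proteins with 1-based inclusive coordinates.

For a query sequence, `slimscan` produces two tables and deliberately
never merges them, because they answer different questions with
different error profiles:

- the **regex table** asks "which class patterns occur anywhere in this
  sequence?" — high sensitivity, pattern-level specificity only;
- the **ortholog table** asks "which *validated* instances sit on
  proteins demonstrably similar to this sequence, and where do they land
  on it?" — evidence-backed, but dependent on a homolog being curated.

Either table may be empty while the other is not; `run_query()` computes
them independently, and a parameter of one side never influences the
other (this independence is asserted by a test).

## Pattern dialect and matching semantics

Motif-class patterns use a POSIX-ERE subset: residue literals, `.`,
character classes (including negation and letter ranges), quantifiers
(`*`, `+`, `?`, `{m}`, `{m,}`, `{m,n}`), grouping, alternation, and
terminal anchors. Choices that needed making:

- **Anchors are terminal only.** `^` is honoured as the first pattern
  character (the motif must start at residue 1) and `$` as the last;
  anywhere else they are rejected at compile time. Protein sequences are
  single-line entities, so line-anchor semantics would be meaningless,
  and interior anchors inside alternations would make the offset-anchored
  scan ill-defined. Curated motif patterns only use terminal anchors.
- **Backreferences, escapes and lookaround are rejected**, with an error
  naming the construct and the motif class. Patterns are data loaded
  from a table; failing loudly at compile time beats engine-dependent
  behaviour at scan time.
- **Every offset is tried, so overlaps are all reported.** Iterating a
  regex engine's non-overlapping matches silently drops biologically
  real overlapping sites (two classes, or two occurrences of one class,
  frequently share residues). `scan_sequence()` instead attempts one
  anchored match at every query offset and de-duplicates spans.
- **One leftmost-longest extent per offset.** At a given offset a
  variable-length pattern may admit several extents; reporting all of
  them would inflate output quadratically for `X+`-style patterns.
  One span per (class, offset) with POSIX longest-match semantics is the
  bounded, reproducible choice; base R's TRE engine provides exactly
  these semantics, and the test suite verifies span sets against an
  exhaustive substring oracle run under PCRE, a genuinely independent
  route.
- **Zero-length matches are dropped**: a motif occurrence must span at
  least one residue.
- **Non-canonical residues (B, J, O, U, X, Z) are legal input.** Real
  sequence databases contain them; they match `.` and any class that
  does not exclude them, and a literal only if identical. Rejecting
  whole sequences over one ambiguity code would be worse. Characters
  outside A–Z are an error naming the position.

## The aligner

Homology search uses a built-in Smith–Waterman implementation (Gotoh
three-matrix recurrence, affine gaps) in C++, so the package is fully
self-contained and works offline; the fast seed-and-extend aligners used
for database-scale search solve the same problem approximately, and
their tabular fields (identity %, coverage %, aligned spans) are what
the ortholog table reports. Parameters, with defaults chosen to mirror
the conventions of those tools:

| parameter | default | meaning |
|---|---|---|
| substitution matrix | BLOSUM62 | 26×26 extension, see below |
| `gap_open` | 11 | gap of length L costs `gap_open + L * gap_extend` |
| `gap_extend` | 1 | |
| `min_score` | 50 | raw-score floor for reported hits |
| `prefilter_k` | 0 (off) | shared k-mer subject prefilter |
| `threads` | 1 | per-subject alignment workers |

Numerical and tie-break choices:

- **Raw score floor, not E-values.** Karlin–Altschul statistics need
  database-scale calibration parameters that a small curated instance
  set does not provide; a transparent raw threshold is testable and easy
  to reason about. The floor (50) is roughly two chance 4-mer matches
  above background and in practice separates genuine homologs from
  noise on 150–250 aa fixtures; it is surfaced in the CLI `--help`.
- **Ambiguity scoring**: the 20×20 BLOSUM62 core is extended so `B`,
  `Z`, `J` average their constituent rows (N/D, E/Q, I/L) and `X`, `O`,
  `U` score 0 against everything — neutral rather than penalised,
  because an unknown residue is not evidence against homology.
- **Deterministic traceback**: at an `H` cell, diagonal beats a gap in
  the subject beats a gap in the query; inside a gap state, closing the
  gap (an `H` origin) beats extending it; among equal-scoring end
  cells the smallest query end, then subject end, wins. Any consistent
  order would do — what matters is that output is byte-identical across
  runs and thread counts, which a test asserts.
- **One optimal alignment per query–subject pair** (no sub-optimal
  HSPs): bounded output, and motif transfer needs the region of clear
  homology, not every repeat copy.
- **Identity denominator = all alignment columns including gaps**,
  matching the `pident` convention of tabular alignment output, so the
  numbers are comparable with those tools. Coverage is computed per
  side: aligned span length over full sequence length.
- The k-mer prefilter is a pure subset filter (a subject is dropped only
  if it shares no length-k substring with the query); with `k = 0` it is
  off, and a test asserts that enabling it never changes retained hits'
  order or content.

The aligner's scores are verified against a naive affine-gap DP oracle
written independently in R, and cross-checked against
`Biostrings::pairwiseAlignment()` under the same matrix and gap
convention; the implementation itself never calls either.

## Coordinate projection

For a contained instance, coordinates are projected onto the query by
walking alignment columns: the projected start is the query position of
the first query-consuming column at or after the column holding the
instance's subject start; the end symmetrically, scanning backward.
Offset arithmetic would be wrong whenever an indel falls inside or
before the motif. When the motif's subject span aligns entirely to a
query gap the projection is undefined and the row keeps `NA`
coordinates with its containment flag — the row is still evidence, even
when the site has no query image. Partial overlaps are likewise reported
with `motif_in_overlap = FALSE` rather than filtered: downstream users
can decide.

Instances whose curation logic is "false positive" or "true negative"
are loaded (for provenance) but never emitted in the ortholog table:
the table proposes candidate interaction sites, and negative-logic rows
would read as candidates while meaning the opposite.

## What the synthetic generator emulates — and what it does not

`generate_database()` builds a complete database cache with known ground
truth: classes drawn from fixed-length, motif-shaped pattern templates;
background proteins with residues uniform over the 20 canonical amino
acids; per protein, implants sampled from class patterns (quantifiers at
their minimum count, so spans are unambiguous) spliced into disjoint
blocks and recorded as true-positive instances. `derive_query()` then
emulates an ortholog: independent per-residue substitutions at a given
divergence (default 0.05), drawing replacements from the 19 other
residues, with implant spans optionally conserved — mimicking the strong
conservation of functional motifs in otherwise diverged orthologs.
`synthesize_motif_sequence()` produces a background sequence whose
*only* occurrence of a pattern is the implant (re-drawing the background
deterministically until uniqueness holds), which is the setting needed
to demonstrate motif loss under a single point mutation.

Deliberately not emulated: real residue composition and disorder
context, motif class frequencies and taxonomy, and — most importantly —
**indel divergence** (`derive_query` substitutes only). Passing the
recovery tests therefore shows that scanning, alignment, containment and
projection are internally correct under substitution-style divergence;
it does not show that the default `min_score` or the alignment defaults
are well-tuned for remote homologs, compositionally biased regions, or
gappy ortholog pairs. Gapped projection is instead exercised directly
with hand-constructed and randomly generated traces checked against an
independent column-walk oracle.

Reference study conditions, fixed once and used by the test suite and
the acceptance script: 5 classes, 10 proteins of 150–250 residues, 2
implants per protein, divergence 0.05; scanner oracle comparisons on
1,000 random pattern/sequence pairs (sequences ≤ 50 aa), aligner oracle
comparisons on 200 random pairs (≤ 30 aa). These sizes give each
property enough random cases to be convincing while keeping the whole
suite fast enough to run habitually.

## Database cache and degenerate inputs

The cache is one directory with fixed names (`classes.tsv`,
`instances.tsv`, `instance_sequences.fasta`, `meta.json`), making
discovery deterministic and the layout trivial for the generator to
emulate. `setup_database()` stages into a temporary directory, validates
by a full load, then swaps atomically — a failed fetch can never corrupt
an existing cache. Loading is order-insensitive (instances are
canonically sorted and de-duplicated), row-level problems (reversed or
non-integer coordinates, spans beyond the protein length, unknown
classes) reject the row with a warning and a count in the load report
rather than aborting, and instance proteins without a sequence are kept
for metadata but excluded from alignment targets, with a logged count —
silent dropping hides data problems. Header-only tables and empty
databases are valid.

## Known limitations

- No disorder-context filtering: every pattern match is reported, and
  most regex matches in folded regions are biologically implausible. A
  disorder predictor can be applied downstream on the reported spans.
- No alignment statistics (E-values), no sub-optimal HSPs, no
  low-complexity masking; a compositionally biased query will produce
  spurious high-scoring hits that `min_score` alone does not remove.
- One greedy extent per (class, offset): a shorter alternative extent at
  the same offset is not separately reported.
- The remote accession provider in the CLI is a convenience for online
  use; everything tested works from the local database and offline
  fixtures.
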