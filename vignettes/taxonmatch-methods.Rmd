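---
title: "Resolving misspelled plant species names: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving misspelled plant species names: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxonmatch)
```

## The problem

Plant species mentions in text and in data repositories are noisy: the same
taxon appears under synonyms, with or without authority strings, and very
often with spelling or typographical errors. Linking such strings to a
single accepted scientific name (taxonomic name resolution) is a
prerequisite for aggregating biodiversity and biomedical information by
species. `taxonmatch` implements a two-stage resolution engine and a
species-level text tagger on top of a user-supplied dictionary of accepted
names and synonyms.

## The pipeline

Resolution of a query string `q` against a dictionary of canonical
binomials proceeds in four steps:

1. **Normalization.** Lowercase, collapse whitespace, remove the hybrid
   sign, and strip trailing authority or infraspecific-rank tokens
   (`normalize_name()`). Authorities are stripped, never matched: a token
   after the genus position opens the stripped tail when it contains a
   period, contains an uppercase letter, or is a rank marker
   (`var`, `subsp`, `ssp`, `f`, `cv`).
2. **Candidate retrieval.** A character trigram inverted index
   (`build_index()`, boundary-padded with `#`) pre-filters the dictionary
   by gram overlap with the query, keeping the top `10 * k` records; those
   are rescored by normalized restricted Damerau-Levenshtein similarity
   `1 - DL(q, name) / max(len)`, and the top `k = 10` are kept
   (`query_candidates()`). This emulates the behaviour of a search-server
   fuzzy query while remaining fully auditable against an exhaustive
   distance scan.
3. **Alignment rescoring.** Each candidate's canonical name is aligned to
   the normalized query with Smith-Waterman local alignment
   (`smith_waterman()`, linear gaps). Names are aligned as whole strings;
   the space character participates like any letter.
4. **Constraints and decision.** A candidate survives only if (a) the
   aligned region covers **strictly more than 80%** of the *record* string
   ("greater than" is taken literally), and (b) the first characters of
   the query's genus and epithet tokens equal the record's initials.
   Among survivors the maximum alignment score wins; ties break by higher
   retrieval score, then lexicographic name, then record id. No survivor
   means `no_match`; there is no additional score floor by default (an
   optional `min_score` exists but is 0).

Reading "coverage" on the record side is deliberate: it is what rejects
partial, genus-only alignments, which are the dominant false-positive mode
for this kind of matcher. The initials constraint is applied to the query's
*tokens* (not to the aligned substring) — the simplest deterministic
reading; single-token queries therefore always fail it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n` (gram size) | 3 | retrieval index granularity; 3 balances selectivity and typo tolerance for 10–25 character names |
| `k` | 10 | candidates passed to alignment rescoring |
| `match / mismatch / gap` | +2 / −1 / −1 | alignment weights; unstated upstream, so standard small-alphabet string-matching weights were chosen and left configurable |
| `coverage_threshold` | 0.8 | strict lower bound on record coverage |
| `min_score` | 0 | optional extra alignment-score floor |

## Determinism

Every ranking uses a total order: retrieval ties break by gram overlap,
then C-locale (radix) lexicographic name, then record id; the
Smith-Waterman traceback starts at the maximal cell with the smallest
(end-row, end-col) and prefers diagonal over vertical over horizontal
moves. Identical inputs give byte-identical outputs across platforms and
locales.

## Text annotation

Documents are split into sentences at terminal punctuation followed by
whitespace and a capital, except after single-letter abbreviations (so
"Q. alba" survives intact). Candidate mention spans are a deterministic
shape heuristic — a capitalized alphabetic token (never an all-caps
acronym) or an abbreviated genus `X.`, followed by one or two lowercase
tokens — because species binomials in running text have exactly this
shape. The heuristic deliberately over-runs the true name (followers like
"grows" are included); the alignment stage both validates the span and
trims it. A mention's reported offsets cover the candidate tokens whose
characters are majority-covered (strictly more than half) by the aligned
query region: a one-character gap extension of a local alignment into a
follower word must not drag that word into the mention. Single
capitalized words never become mentions — species-level tagging only —
which is also why an optional stop-list (negative word lexicon) is empty
by default.

An abbreviated genus is expanded using the genus of the most recent
preceding *matched* mention in the same document with the same initial;
documents share no expansion state.

## Synthetic data: what it emulates and what it does not

`generate_taxonomy()` builds pronounceable latinate dictionaries
(alternating consonant–vowel syllables; genus 6–10 characters, epithet
4–9), with a configurable synonym fraction; `make_benchmark()` emulates a
misspelling benchmark by corrupting sampled names under a `typo_model()`
(uniform over substitution / deletion / insertion / transposition by
default — real typo distributions are not characterized, so uniform is the
neutral choice); `make_documents()` plants names into fixed filler
sentences and records gold offsets.

Three generator choices matter for interpreting green tests:

* **Token initials are protected by default** because the pipeline's
  initials constraint makes initial-character typos unresolvable *by
  design*; a flag generates such hard cases to test `no_match` behaviour.
* **Spaces are never edited**, so corruption preserves the binomial token
  structure; merged-token errors are out of the emulated error model.
* **Corruptions are re-drawn until the measured restricted
  Damerau-Levenshtein distance equals the edit budget** — independent
  edits can collide or compound (the restricted distance violates the
  triangle inequality), and the benchmark's contract is "a query at
  distance exactly e".

Synthetic names are uniformly random, so they are better separated than
real congeneric epithets (real dictionaries contain near-identical sibling
names); recovery rates on synthetic benchmarks are therefore an upper
bound, not an estimate of accuracy on real checklists. Synthetic filler
text likewise lacks the capitalized non-taxon vocabulary (place names,
person names) that drives false positives in real abstracts.

## Evaluation accounting

`evaluate()` classifies each query as `TRUE` (match with the gold accepted
id, after synonym resolution on both sides), `FALSE` (any other match,
including matches on items with no valid gold), or `NOT FOUND` (every
no-match, including correct rejections). Metrics follow the accounting
used in published comparison tables for this task:
`precision = TRUE/(TRUE+FALSE)`, `recall = TRUE/TOTAL`,
`F = 2PR/(P+R)`. The recall denominator being the *total* (not
`TRUE + NOT FOUND`) is pinned by recomputing both published tables from
their printed counts. Two display conventions are likewise pinned by those
tables and verified in the test suite: rounding uses base R `round()`
(half-to-even at exact decimal midpoints — a printed recall of 0.74 from
745/1000 rules out half-up), and the displayed F-score is recomputed from
the rounded precision and recall. Raw unrounded values are always kept.
One printed F-score cell in the misspelling-benchmark table (0.67 for one
comparison system) is not derivable from that column's own printed counts
under any definition and is treated as a typo; the suite asserts the value
the pinned definitions produce (0.76).

## Numerical and degenerate-input choices

* Queries shorter than 4 characters are rejected (cannot form a binomial).
* A zero-score alignment has empty spans and coverage 0.
* `precision`, `recall`, `f_score` are 0 on zero denominators.
* Synonym chains longer than one hop are rejected at load time, keeping
  `resolve_accepted()` a single table lookup.
* The trigram postings keep one entry per gram occurrence (a bag, not a
  set), so the index satisfies an exact conservation law — total posting
  mass equals the sum of per-record gram counts — used as a build check.

## Known limitations

Authorities are stripped, never matched, so homonyms differing only by
authority cannot be distinguished. Only species-rank binomials are
indexed; genus-only and infraspecific mentions are out of scope. The
candidate-span heuristic is a stand-in for a proper noun-phrase chunker
and will miss mentions with unusual casing or intervening punctuation.
Retrieval quality is only guaranteed (and only tested) for queries within
two edits of an indexed name.
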