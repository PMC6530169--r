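#' Alignment scoring parameters
#'
#' Linear-gap Smith-Waterman weights. The defaults (+2 match, -1
#' mismatch, -1 gap) are conventional small-alphabet string-matching
#' weights; all three are configurable.
#'
#' @param match Positive integer score for a character match.
#' @param mismatch Non-positive integer penalty for a mismatch.
#' @param gap Non-positive integer penalty per gapped position.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = -1L, gap = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  stopifnot(match > 0L, mismatch <= 0L, gap <= 0L)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_params")
}

#' Smith-Waterman local alignment
#'
#' Computes the maximal local alignment between two strings under linear
#' gap penalties, with a deterministic traceback: among cells tying for
#' the maximum score the one with the smallest (end-row, end-col) is
#' used, and the traceback prefers diagonal over vertical over horizontal
#' moves. Comparison is case-folded; the space character participates
#' like any other character.
#'
#' @param a Query string (non-empty).
#' @param b Record string (non-empty).
#' @param params An [align_params()] object.
#' @return An object of class `alignment_result` with fields `score`
#'   (non-negative integer), `query_span` and `record_span` (0-based
#'   half-open `c(start, end)` character intervals; empty `c(0, 0)` when
#'   score is 0), and `aligned_pairs` (number of match/mismatch columns).
#' @export
smith_waterman <- function(a, b, params = align_params()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("smith_waterman: empty string", call. = FALSE)
  stopifnot(inherits(params, "align_params"))
  r <- cpp_sw_align(tolower(a), tolower(b),
                    params$match, params$mismatch, params$gap)
  structure(list(
    score = r$score,
    query_span = c(r$a_start, r$a_end),
    record_span = c(r$b_start, r$b_end),
    aligned_pairs = r$aligned_pairs
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", x$score,
      ", query [", x$query_span[1], ",", x$query_span[2], ")",
      ", record [", x$record_span[1], ",", x$record_span[2], ")\n", sep = "")
  invisible(x)
}

#' Coverage of the dictionary record by an alignment
#'
#' Fraction of the record string spanned by the best local alignment:
#' `(record_span end - start) / nchar(record_name)`. A zero-score
#' alignment has empty spans and coverage 0. The ratio penalizes partial
#' (e.g. genus-only) alignments.
#'
#' @param aln An [smith_waterman()] result computed against `record_name`.
#' @param record_name The record string the alignment was computed against.
#' @return A number in `[0, 1]`.
#' @export
record_coverage <- function(aln, record_name) {
  stopifnot(inherits(aln, "alignment_result"))
  (aln$record_span[2] - aln$record_span[1]) / nchar(record_name)
}

#' Initial-character constraint
#'
#' TRUE iff the query's first token starts with the record's genus
#' initial and the query has a second token starting with the record's
#' epithet initial. Single-token queries always fail.
#'
#' @param q Normalized query string.
#' @param record_name Normalized two-token binomial.
#' @return Logical scalar.
#' @export
initials_constraint <- function(q, record_name) {
  rt <- strsplit(record_name, " ", fixed = TRUE)[[1]]
  stopifnot(length(rt) == 2L)
  qt <- strsplit(q, " ", fixed = TRUE)[[1]]
  if (length(qt) < 2L) return(FALSE)
  substr(qt[1], 1, 1) == substr(rt[1], 1, 1) &&
    substr(qt[2], 1, 1) == substr(rt[2], 1, 1)
}

#' Resolve one name string against the dictionary
#'
#' Full resolution pipeline: the query is normalized, the top-`k`
#' candidates are retrieved from the trigram index, each candidate's
#' canonical name is rescored by Smith-Waterman local alignment, and
#' candidates are discarded unless the aligned coverage of the record
#' strictly exceeds `coverage_threshold` and the genus/epithet initial
#' characters agree. Among survivors the maximum alignment score wins
#' (ties: higher retrieval score, then lexicographic name, then id); the
#' winner is reported as a `match` together with its accepted record. No
#' survivor means `no_match`.
#'
#' @param index A [build_index()] result over `table`.
#' @param table The [taxonomy_table()] the index was built from.
#' @param raw_query Raw query string (normalized internally).
#' @param params [align_params()].
#' @param coverage_threshold Strict lower bound on record coverage
#'   (default 0.8, i.e. coverage must exceed 80%).
#' @param k Number of retrieval candidates to rescore (default 10).
#' @param min_score Optional minimum alignment score a match must reach
#'   (default 0: no extra floor beyond the two constraints).
#' @return A list of class `resolution_result`: `query`,
#'   `normalized_query`, `decision` (`"match"`/`"no_match"`),
#'   `matched_id`, `matched_name`, `accepted_id`, `accepted_name`,
#'   `alignment` ([smith_waterman()] result or `NULL`), `coverage`,
#'   `retrieval_score`, and `constraints_passed` (named logical
#'   `coverage_ok`, `initials_ok`; for a `no_match` these describe the
#'   best-aligning candidate, or are both FALSE when none was retrieved).
#' @export
resolve_name <- function(index, table, raw_query, params = align_params(),
                         coverage_threshold = 0.8, k = 10L, min_score = 0L) {
  stopifnot(inherits(index, "fuzzy_index"), inherits(table, "taxonomy_table"))
  nq <- normalize_name(raw_query)
  cand <- query_candidates(index, nq, k = k)

  no_match <- function(flags) {
    structure(list(
      query = raw_query, normalized_query = nq, decision = "no_match",
      matched_id = NULL, matched_name = NULL,
      accepted_id = NULL, accepted_name = NULL,
      alignment = NULL, coverage = NULL, retrieval_score = NULL,
      constraints_passed = flags
    ), class = "resolution_result")
  }
  if (!nrow(cand)) {
    return(no_match(c(coverage_ok = FALSE, initials_ok = FALSE)))
  }

  m <- nrow(cand)
  score <- integer(m); cov <- numeric(m); init_ok <- logical(m)
  alns <- vector("list", m)
  for (i in seq_len(m)) {
    alns[[i]] <- smith_waterman(nq, cand$canonical_name[i], params)
    score[i] <- alns[[i]]$score
    cov[i] <- record_coverage(alns[[i]], cand$canonical_name[i])
    init_ok[i] <- initials_constraint(nq, cand$canonical_name[i])
  }
  cov_ok <- cov > coverage_threshold
  ok <- cov_ok & init_ok & score >= min_score

  if (!any(ok)) {
    best <- order(-score, cand$canonical_name, method = "radix")[1L]
    return(no_match(c(coverage_ok = cov_ok[best], initials_ok = init_ok[best])))
  }
  surv <- which(ok)
  w <- surv[order(-score[surv], -cand$retrieval_score[surv],
                  cand$canonical_name[surv], cand$record_id[surv],
                  method = "radix")[1L]]
  acc <- resolve_accepted(table, cand$record_id[w])
  structure(list(
    query = raw_query, normalized_query = nq, decision = "match",
    matched_id = cand$record_id[w], matched_name = cand$canonical_name[w],
    accepted_id = acc$record_id, accepted_name = acc$canonical_name,
    alignment = alns[[w]], coverage = cov[w],
    retrieval_score = cand$retrieval_score[w],
    constraints_passed = c(coverage_ok = TRUE, initials_ok = TRUE)
  ), class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution_result> '", x$query, "' -> ", x$decision, sep = "")
  if (x$decision == "match") {
    cat(": ", x$matched_name, " [", x$matched_id, "] accepted ",
        x$accepted_name, " [", x$accepted_id, "], score ",
        x$alignment$score, ", coverage ", round(x$coverage, 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Resolve many queries to a results table
#'
#' Batch wrapper around [resolve_name()] returning one row per query in
#' the column layout used by the TSV/JSON-lines resolution output.
#'
#' @inheritParams resolve_name
#' @param queries Character vector of raw query strings.
#' @return A data.frame with columns `query`, `normalized_query`,
#'   `matched_id`, `matched_name`, `accepted_id`, `accepted_name`,
#'   `alignment_score`, `coverage`, `decision`.
#' @export
resolve_names <- function(index, table, queries, params = align_params(),
                          coverage_threshold = 0.8, k = 10L, min_score = 0L) {
  rows <- lapply(queries, function(q) {
    r <- resolve_name(index, table, q, params = params,
                      coverage_threshold = coverage_threshold,
                      k = k, min_score = min_score)
    data.frame(
      query = r$query,
      normalized_query = r$normalized_query,
      matched_id = r$matched_id %||% NA_character_,
      matched_name = r$matched_name %||% NA_character_,
      accepted_id = r$accepted_id %||% NA_character_,
      accepted_name = r$accepted_name %||% NA_character_,
      alignment_score = if (is.null(r$alignment)) NA_integer_ else r$alignment$score,
      coverage = r$coverage %||% NA_real_,
      decision = r$decision,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write resolution results
#'
#' @param results A data.frame from [resolve_names()].
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"` (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_resolutions <- function(results, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(results))) {
      writeLines(jsonlite::toJSON(as.list(results[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
    }
  }
  invisible(path)
}
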