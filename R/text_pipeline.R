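# Text annotation: sentence splitting, candidate span detection, and
# dictionary-backed species mention tagging. All spans are 0-based
# half-open character intervals on the original document, matching the
# JSON-lines output convention.

#' Split a document into sentence spans
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and a capital letter, except when the period terminates a
#' single-letter abbreviation (so "Q. alba" stays inside one sentence).
#' Spans are trimmed of surrounding whitespace and cover all non-blank
#' content in order.
#'
#' @param text A single document string.
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `text`, `sentence_index` (1-based). Zero rows for blank input.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), sentence_index = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.!?](?=\\s+[A-Z])", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1L] != -1L) {
    for (p in as.integer(m)) {
      if (substr(text, p, p) == ".") {
        prev <- if (p >= 2L) substr(text, p - 1L, p - 1L) else ""
        prev2 <- if (p >= 3L) substr(text, p - 2L, p - 2L) else ""
        # single-letter abbreviation like "Q." — not a sentence end
        if (grepl("[A-Za-z]", prev) && !grepl("[A-Za-z]", prev2)) next
      }
      bounds <- c(bounds, p)
    }
  }
  n <- nchar(text)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  rows <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    while (s <= e && grepl("^\\s$", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    if (s > e) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, end = e, text = substr(text, s, e),
      sentence_index = length(rows) + 1L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Pattern for a candidate species mention: a capitalized alphabetic token
# (not all-caps) or an abbreviated genus "X." followed by 1-2 lowercase
# alphabetic tokens; greedy, so the maximal span is taken.
candidate_pattern <- paste0(
  "(?:(?<![A-Za-z])[A-Z][a-z]+|(?<![A-Za-z.])[A-Z]\\.)",
  "(?:\\s+[a-z]+(?![A-Za-z])){1,2}")

#' Candidate name spans within a sentence
#'
#' Emits maximal spans shaped like a species mention: a capitalized token
#' (or single capital + period, the abbreviated-genus form) followed by
#' one or two lowercase alphabetic tokens. All-caps tokens (acronyms)
#' never start a span; spans do not overlap and come in document order.
#' Spans deliberately over-run the true name (up to two followers); the
#' alignment stage trims them.
#'
#' @param sentence One row of [split_sentences()] output.
#' @param document The document string the sentence came from.
#' @return A data.frame with columns `start`, `end` (0-based half-open on
#'   the document), `text`, `sentence_index`.
#' @export
candidate_spans <- function(sentence, document) {
  stopifnot(is.data.frame(sentence), nrow(sentence) == 1L)
  stext <- substr(document, sentence$start + 1L, sentence$end)
  m <- gregexpr(candidate_pattern, stext, perl = TRUE)[[1]]
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), sentence_index = integer(0),
                      stringsAsFactors = FALSE)
  if (m[1L] == -1L) return(empty)
  pos <- as.integer(m)
  len <- attr(m, "match.length")
  start0 <- sentence$start + pos - 1L
  data.frame(
    start = start0,
    end = start0 + len,
    text = substring(stext, pos, pos + len - 1L),
    sentence_index = rep.int(sentence$sentence_index, length(pos)),
    stringsAsFactors = FALSE
  )
}

#' Annotate species mentions in a document
#'
#' Runs the full tagging pipeline: sentence splitting, candidate span
#' detection, abbreviated-genus expansion, and [resolve_name()] on each
#' candidate. Only `match` decisions become mentions; the reported span
#' covers the candidate tokens that are majority-covered (strictly more
#' than half their characters) by the aligned query region, so a span
#' like "Quercus alba grows" yields a mention over exactly
#' "Quercus alba".
#'
#' An abbreviated genus ("Q. alba") is expanded to the genus of the most
#' recent preceding matched mention in the same document whose genus
#' starts with the same letter; candidates with an unexpandable
#' abbreviation are skipped.
#'
#' @inheritParams resolve_name
#' @param document A single document string.
#' @param stoplist Optional character vector of lowercased first tokens
#'   that never start a mention (negative word lexicon); empty by default.
#' @return A data.frame of class `mentions` with columns `start`, `end`
#'   (0-based half-open on `document`), `text`, `sentence_index`,
#'   `matched_id`, `matched_name`, `accepted_id`, `accepted_name`,
#'   `score`, `coverage`.
#' @export
annotate <- function(document, index, table, params = align_params(),
                     coverage_threshold = 0.8, k = 10L,
                     stoplist = character()) {
  stopifnot(is.character(document), length(document) == 1L)
  sents <- split_sentences(document)
  out <- list()
  # abbreviation expansion state: initial letter -> genus of the most
  # recent full-genus match in this document
  expansions <- character(0)

  if (nrow(sents)) for (si in seq_len(nrow(sents))) {
    spans <- candidate_spans(sents[si, ], document)
    if (!nrow(spans)) next
    for (ci in seq_len(nrow(spans))) {
      sp <- spans[ci, ]
      tk <- gregexpr("\\S+", sp$text)[[1]]
      tok_start <- as.integer(tk)
      tok_len <- attr(tk, "match.length")
      toks <- substring(sp$text, tok_start, tok_start + tok_len - 1L)
      if (tolower(toks[1L]) %in% tolower(stoplist)) next

      abbreviated <- grepl("^[A-Z]\\.$", toks[1L])
      qtoks <- tolower(toks)
      if (abbreviated) {
        init <- tolower(substr(toks[1L], 1L, 1L))
        genus <- expansions[init]
        if (is.na(genus) || !length(genus)) next
        qtoks[1L] <- genus
      }
      query <- paste(qtoks, collapse = " ")
      res <- tryCatch(
        resolve_name(index, table, query, params = params,
                     coverage_threshold = coverage_threshold, k = k),
        error = function(e) NULL)
      if (is.null(res) || res$decision != "match") next
      # offset bookkeeping assumes normalization left the query unchanged
      if (!identical(res$normalized_query, query)) next

      # which query tokens belong to the mention? a token counts only if
      # strictly more than half of its characters lie in the aligned
      # query span, so a one-character gap extension into a follower
      # word does not drag the whole word into the mention
      qlen <- nchar(qtoks)
      qstart <- cumsum(c(0L, qlen[-length(qlen)] + 1L)) # 0-based in query
      qend <- qstart + qlen
      qs <- res$alignment$query_span[1L]; qe <- res$alignment$query_span[2L]
      inside <- pmax(0L, pmin(qend, qe) - pmax(qstart, qs))
      touched <- which(inside * 2L > qlen)
      if (!length(touched)) next
      d_start <- sp$start + tok_start[min(touched)] - 1L
      d_end <- sp$start + tok_start[max(touched)] + tok_len[max(touched)] - 1L

      if (!abbreviated) {
        g_init <- tolower(substr(res$matched_name, 1L, 1L))
        expansions[g_init] <- strsplit(res$matched_name, " ", fixed = TRUE)[[1]][1L]
      }
      out[[length(out) + 1L]] <- data.frame(
        start = d_start, end = d_end,
        text = substr(document, d_start + 1L, d_end),
        sentence_index = sp$sentence_index,
        matched_id = res$matched_id, matched_name = res$matched_name,
        accepted_id = res$accepted_id, accepted_name = res$accepted_name,
        score = res$alignment$score, coverage = res$coverage,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), sentence_index = integer(0),
                      matched_id = character(0), matched_name = character(0),
                      accepted_id = character(0), accepted_name = character(0),
                      score = integer(0), coverage = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, out)
    # candidate spans never overlap, but guard anyway: on overlap keep
    # the higher alignment score (then the earlier start)
    o <- order(-out$score, out$start)
    chosen <- integer(0)
    for (r in o) {
      if (!any(out$start[r] < out$end[chosen] & out$end[r] > out$start[chosen])) {
        chosen <- c(chosen, r)
      }
    }
    out <- out[sort(chosen), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mentions", "data.frame")
  out
}

#' Write mentions as JSON-lines
#'
#' One JSON object per mention: `doc_id`, `start`, `end`, `text`,
#' `matched_name`, `accepted_name`, `accepted_id`, `score` (offsets are
#' 0-based half-open on the document).
#'
#' @param mentions An [annotate()] result.
#' @param path Output file path.
#' @param doc_id Document identifier stored with each mention.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path, doc_id = "doc1") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(mentions))) {
    writeLines(jsonlite::toJSON(list(
      doc_id = doc_id,
      start = mentions$start[i], end = mentions$end[i],
      text = mentions$text[i],
      matched_name = mentions$matched_name[i],
      accepted_name = mentions$accepted_name[i],
      accepted_id = mentions$accepted_id[i],
      score = mentions$score[i]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write mentions as BRAT standoff annotations
#'
#' Emits `T<n>\tSpecies <start> <end>\t<text>` lines.
#'
#' @inheritParams write_mentions
#' @export
write_mentions_brat <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    sprintf("T%d\tSpecies %d %d\t%s", i, mentions$start[i], mentions$end[i],
            mentions$text[i])
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
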