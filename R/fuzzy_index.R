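#' Character n-grams of a name
#'
#' Pads the string with one boundary marker `#` at each end and emits all
#' contiguous substrings of length `n` (with multiplicity), so that a
#' string of length L yields `L + 2 - n + 1` grams.
#'
#' @param s A single non-empty string (normally a normalized name).
#' @param n Gram size in characters, at least 2.
#' @return Character vector of n-grams in positional order.
#' @examples
#' ngrams("alba", 3)  # "#al" "alb" "lba" "ba#"
#' @export
ngrams <- function(s, n = 3L) {
  stopifnot(length(s) == 1L, is.character(s), nzchar(s), n >= 2L)
  padded <- paste0("#", s, "#")
  L <- nchar(padded)
  if (n > L) stop("ngrams: name too short for n-gram size", call. = FALSE)
  substring(padded, 1:(L - n + 1L), n:L)
}

#' Build a fuzzy retrieval index over a taxonomy
#'
#' Constructs an inverted index from character n-grams of the canonical
#' names to record positions. Posting lists keep one entry per gram
#' occurrence, so the total posting mass equals the sum of per-record
#' gram counts. The index is treated as immutable once built.
#'
#' @param table A [taxonomy_table()].
#' @param n Gram size (default 3, i.e. trigrams).
#' @return An object of class `fuzzy_index`.
#' @export
build_index <- function(table, n = 3L) {
  stopifnot(inherits(table, "taxonomy_table"))
  if (!nrow(table$records)) stop("build_index: empty table", call. = FALSE)
  canonical <- table$records$canonical_name
  gl <- lapply(canonical, ngrams, n = n)
  lens <- lengths(gl)
  rec <- rep.int(seq_along(gl), lens)
  postings <- split(rec, unlist(gl, use.names = FALSE))
  structure(list(
    n = as.integer(n),
    postings = list2env(postings, hash = TRUE, size = max(64L, length(postings))),
    gram_counts = lens,
    record_ids = table$records$record_id,
    canonical = canonical
  ), class = "fuzzy_index")
}

#' @export
print.fuzzy_index <- function(x, ...) {
  cat("<fuzzy_index> ", length(x$record_ids), " records, n = ", x$n,
      ", ", length(ls(x$postings)), " distinct grams\n", sep = "")
  invisible(x)
}

# Damerau-Levenshtein (optimal string alignment) distances from one query
# to many names.
#' Restricted Damerau-Levenshtein distance
#'
#' Unit-cost edit distance counting insertions, deletions, substitutions
#' and adjacent transpositions (optimal string alignment variant).
#'
#' @param a A single string.
#' @param b Character vector of strings to compare against.
#' @return Integer vector of distances, one per element of `b`.
#' @export
dl_distance <- function(a, b) {
  stopifnot(length(a) == 1L, is.character(a), is.character(b))
  cpp_osa(a, b)
}

#' Retrieve ranked candidate records for a query string
#'
#' Two-stage approximate lookup standing in for a search-server fuzzy
#' query: (a) records are pre-filtered by n-gram overlap with the query
#' (sum of posting-list hits over the query's distinct grams) and the top
#' `10 * k` kept; (b) survivors are rescored by normalized
#' Damerau-Levenshtein similarity `1 - DL(q, name) / max(len)`, and the
#' top `k` returned. Ties break by higher gram overlap, then C-locale
#' lexicographic canonical name, then record id, so results are identical
#' across runs and platforms.
#'
#' @param index A [build_index()] result.
#' @param q Normalized query string (lowercased internally); must be at
#'   least 4 characters.
#' @param k Number of candidates to return (default 10).
#' @return A data.frame with columns `rank`, `record_id`,
#'   `canonical_name`, `retrieval_score`, `overlap`; fewer than `k` rows
#'   only when fewer records share any gram with the query.
#' @export
query_candidates <- function(index, q, k = 10L) {
  stopifnot(inherits(index, "fuzzy_index"), k >= 1L)
  q <- tolower(trimws(q))
  if (!nzchar(q)) stop("query_candidates: empty query", call. = FALSE)
  if (nchar(q) < 4L) {
    stop("query_candidates: query shorter than 4 characters", call. = FALSE)
  }
  qg <- unique(ngrams(q, index$n))
  hits <- unlist(mget(qg, envir = index$postings,
                      ifnotfound = list(integer(0))), use.names = FALSE)
  if (!length(hits)) {
    return(data.frame(rank = integer(0), record_id = character(0),
                      canonical_name = character(0),
                      retrieval_score = numeric(0), overlap = integer(0),
                      stringsAsFactors = FALSE))
  }
  ov <- tabulate(hits, nbins = length(index$canonical))
  cand <- which(ov > 0L)
  o <- order(-ov[cand], index$canonical[cand], index$record_ids[cand],
             method = "radix")
  cand <- cand[o][seq_len(min(10L * k, length(cand)))]

  d <- cpp_osa(q, index$canonical[cand])
  sim <- 1 - d / pmax(nchar(q), nchar(index$canonical[cand]))
  o2 <- order(-sim, -ov[cand], index$canonical[cand], index$record_ids[cand],
              method = "radix")
  keep <- o2[seq_len(min(k, length(cand)))]
  data.frame(
    rank = seq_along(keep),
    record_id = index$record_ids[cand[keep]],
    canonical_name = index$canonical[cand[keep]],
    retrieval_score = sim[keep],
    overlap = ov[cand[keep]],
    stringsAsFactors = FALSE
  )
}

index_magic <- "taxonmatch_fuzzy_index"
index_format_version <- 1L

#' Persist / reload a fuzzy index
#'
#' The on-disk artifact is a single serialized file with a magic header
#' and format version; [load_index()] refuses files that do not carry
#' them.
#'
#' @param index A `fuzzy_index`.
#' @param path File path.
#' @return `path` (write) or the reloaded `fuzzy_index` (load).
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fuzzy_index"))
  payload <- list(
    magic = index_magic,
    version = index_format_version,
    n = index$n,
    postings = as.list(index$postings, sorted = TRUE),
    gram_counts = index$gram_counts,
    record_ids = index$record_ids,
    canonical = index$canonical
  )
  saveRDS(payload, path, version = 2L)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(payload) || !identical(payload$magic, index_magic)) {
    stop("load_index: not a taxonmatch index file: ", path, call. = FALSE)
  }
  if (!identical(payload$version, index_format_version)) {
    stop("load_index: unsupported index format version ", payload$version,
         call. = FALSE)
  }
  structure(list(
    n = payload$n,
    postings = list2env(payload$postings, hash = TRUE,
                        size = max(64L, length(payload$postings))),
    gram_counts = payload$gram_counts,
    record_ids = payload$record_ids,
    canonical = payload$canonical
  ), class = "fuzzy_index")
}
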