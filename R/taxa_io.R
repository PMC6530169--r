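#' Normalize a scientific name string
#'
#' Canonicalizes a raw name to the lowercase `"genus epithet"` form used
#' throughout the package: whitespace is collapsed, the hybrid sign
#' (`×` or a standalone `x` marker) is removed, and trailing
#' authority or infraspecific-rank tokens are stripped. Authorities are
#' stripped, never matched: a token after the genus position starts the
#' stripped tail when it contains a period, contains an uppercase letter,
#' or is one of `var`, `subsp`, `ssp`, `f`, `cv` (rank markers take all
#' following tokens with them).
#'
#' @param raw Character vector of raw name strings.
#' @return Character vector of normalized names. Note the result is not
#'   guaranteed to be a two-token binomial; callers that require one
#'   (e.g. the dictionary loader) must check.
#' @examples
#' normalize_name("Quercus alba L.")        # "quercus alba"
#' normalize_name("Rosa × damascena Mill.") # "rosa damascena"
#' normalize_name("  Poa   annua ")         # "poa annua"
#' @export
normalize_name <- function(raw) {
  stopifnot(is.character(raw))
  vapply(raw, normalize_name_one, character(1), USE.NAMES = FALSE)
}

rank_markers <- c("var", "subsp", "ssp", "f", "cv")

normalize_name_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    stop("normalize_name: no name content", call. = FALSE)
  }
  s <- gsub("×", " ", raw, fixed = TRUE)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[tolower(toks) != "x"] # hybrid marker
  if (length(toks) >= 2L) {
    authority_like <- vapply(toks, function(tk) {
      grepl(".", tk, fixed = TRUE) || grepl("[A-Z]", tk) ||
        tolower(tk) %in% rank_markers
    }, logical(1))
    authority_like[1L] <- FALSE # genus keeps its capital
    hit <- which(authority_like)
    if (length(hit)) toks <- toks[seq_len(hit[1L] - 1L)]
  }
  if (!length(toks)) stop("normalize_name: no name content", call. = FALSE)
  paste(tolower(toks), collapse = " ")
}

is_binomial <- function(x) {
  grepl("^[a-z]+ [a-z]+$", x)
}

#' Construct a validated taxonomy table
#'
#' Low-level constructor used by [load_taxonomy()] and
#' [generate_taxonomy()]. Validates all record invariants: unique record
#' ids, two-token alphabetic canonical binomials, species rank, accepted
#' records pointing at themselves, and synonyms pointing (in exactly one
#' hop) at an existing accepted record.
#'
#' @param records A data.frame with character columns `record_id`,
#'   `raw_name`, `canonical_name`, `status` (`"accepted"`/`"synonym"`),
#'   `accepted_id`, `rank` (`"species"`), `kingdom`, `sources`.
#' @return An object of class `taxonomy_table`: the validated `records`
#'   data.frame plus an id lookup.
#' @export
taxonomy_table <- function(records) {
  req <- c("record_id", "raw_name", "canonical_name", "status",
           "accepted_id", "rank", "kingdom", "sources")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("taxonomy_table: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)[req]
  for (cl in req) records[[cl]] <- as.character(records[[cl]])
  if (!nrow(records)) stop("taxonomy_table: empty table", call. = FALSE)

  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup)) {
    stop("taxonomy_table: duplicate record_id: ", dup[1L], call. = FALSE)
  }
  bad <- !is_binomial(records$canonical_name)
  if (any(bad)) {
    stop("taxonomy_table: canonical_name not a two-token binomial: ",
         records$canonical_name[which(bad)[1L]], call. = FALSE)
  }
  if (any(records$rank != "species")) {
    stop("taxonomy_table: only rank 'species' is supported", call. = FALSE)
  }
  if (!all(records$status %in% c("accepted", "synonym"))) {
    stop("taxonomy_table: status must be 'accepted' or 'synonym'", call. = FALSE)
  }
  acc <- records$status == "accepted"
  if (any(acc & records$accepted_id != records$record_id)) {
    i <- which(acc & records$accepted_id != records$record_id)[1L]
    stop("taxonomy_table: accepted record '", records$record_id[i],
         "' has accepted_id != record_id", call. = FALSE)
  }
  idx <- match(records$accepted_id, records$record_id)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1L]
    stop("taxonomy_table: synonym '", records$record_id[i],
         "' points at absent accepted_id '", records$accepted_id[i], "'",
         call. = FALSE)
  }
  chain <- !acc & records$status[idx] != "accepted"
  if (any(chain)) {
    i <- which(chain)[1L]
    stop("taxonomy_table: synonym chain at '", records$record_id[i],
         "' (accepted_id must reference an accepted record)", call. = FALSE)
  }
  structure(list(records = records), class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  n <- nrow(x$records)
  n_acc <- sum(x$records$status == "accepted")
  cat("<taxonomy_table> ", n, " species records (",
      n_acc, " accepted, ", n - n_acc, " synonyms)\n", sep = "")
  print(utils::head(x$records, 5L))
  if (n > 5L) cat("... and", n - 5L, "more rows\n")
  invisible(x)
}

#' Number of records in a taxonomy table
#' @param x A `taxonomy_table`.
#' @export
length.taxonomy_table <- function(x) nrow(x$records)

#' Load a taxonomic dictionary from a TSV file
#'
#' Reads a tab-separated dictionary with header columns `record_id`,
#' `name`, `status`, `accepted_id`, `rank`, `kingdom` and (optionally)
#' `sources` (comma-joined labels). Each surviving row becomes a record
#' with `canonical_name = normalize_name(name)`.
#'
#' Rows are dropped (with one summary warning giving the count) when the
#' normalized name is not a two-token alphabetic binomial or the rank is
#' not `species`. Duplicated `record_id`s, synonyms whose `accepted_id`
#' is absent (or itself a synonym), and accepted rows whose `accepted_id`
#' names a different record are hard errors. Empty `accepted_id` on an
#' accepted row is filled with the row's own id.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A [taxonomy_table()].
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("load_taxonomy: no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("record_id", "name", "status", "accepted_id", "rank", "kingdom")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("load_taxonomy: header lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$sources)) raw$sources <- ""
  dup <- raw$record_id[duplicated(raw$record_id)]
  if (length(dup)) {
    stop("load_taxonomy: duplicate record_id: ", dup[1L], call. = FALSE)
  }

  canonical <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    canonical[i] <- tryCatch(normalize_name_one(raw$name[i]),
                             error = function(e) NA_character_)
  }
  keep <- !is.na(canonical) & is_binomial(canonical) & raw$rank == "species"
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning("load_taxonomy: excluded ", n_dropped,
            " row(s) (not a species-rank two-token binomial)", call. = FALSE)
  }
  raw <- raw[keep, , drop = FALSE]
  canonical <- canonical[keep]
  if (!nrow(raw)) stop("load_taxonomy: no valid rows", call. = FALSE)

  acc <- raw$status == "accepted"
  blank <- !nzchar(trimws(raw$accepted_id))
  raw$accepted_id[acc & blank] <- raw$record_id[acc & blank]

  taxonomy_table(data.frame(
    record_id = raw$record_id,
    raw_name = raw$name,
    canonical_name = canonical,
    status = raw$status,
    accepted_id = raw$accepted_id,
    rank = raw$rank,
    kingdom = raw$kingdom,
    sources = raw$sources,
    stringsAsFactors = FALSE
  ))
}

#' Write a taxonomy table to TSV
#'
#' Inverse of [load_taxonomy()]: writes the raw names and record fields so
#' that reloading reproduces an equivalent record set.
#'
#' @param table A `taxonomy_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(table, path) {
  stopifnot(inherits(table, "taxonomy_table"))
  out <- data.frame(
    record_id = table$records$record_id,
    name = table$records$raw_name,
    status = table$records$status,
    accepted_id = table$records$accepted_id,
    rank = table$records$rank,
    kingdom = table$records$kingdom,
    sources = table$records$sources,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve a record to its accepted record
#'
#' Follows `accepted_id` exactly once: accepted records return themselves,
#' synonyms return the accepted record they point to.
#'
#' @param table A `taxonomy_table`.
#' @param record_id A single record id present in the table.
#' @return A one-row data.frame (the accepted record).
#' @export
resolve_accepted <- function(table, record_id) {
  stopifnot(inherits(table, "taxonomy_table"), length(record_id) == 1L)
  i <- match(record_id, table$records$record_id)
  if (is.na(i)) stop("resolve_accepted: unknown record_id: ", record_id, call. = FALSE)
  j <- match(table$records$accepted_id[i], table$records$record_id)
  table$records[j, , drop = FALSE]
}

# Vectorized id -> accepted_id map (NA passes through); internal.
accepted_id_of <- function(table, ids) {
  i <- match(ids, table$records$record_id)
  bad <- !is.na(ids) & is.na(i)
  if (any(bad)) {
    stop("unknown record_id: ", ids[which(bad)[1L]], call. = FALSE)
  }
  out <- table$records$accepted_id[i]
  out[is.na(ids)] <- NA_character_
  out
}
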