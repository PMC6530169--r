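# Seeded synthetic data: latinate taxonomies, typo-corrupted query
# benchmarks, and planted-mention documents. Everything is deterministic
# under a seed (R's default Mersenne-Twister via set.seed), so tests and
# the acceptance script are reproducible without external downloads.

syll_consonants <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
syll_vowels <- c("a", "e", "i", "o", "u")

# One pronounceable lowercase word of length in [min_len, max_len]:
# alternating consonant-vowel syllables, optional trailing consonant.
latinate_word <- function(min_len, max_len) {
  len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
  n_pairs <- len %/% 2L
  chars <- character(0)
  for (i in seq_len(n_pairs)) {
    chars <- c(chars, sample(syll_consonants, 1L), sample(syll_vowels, 1L))
  }
  if (len %% 2L == 1L) chars <- c(chars, sample(syll_consonants, 1L))
  paste(chars, collapse = "")
}

sample_unique_words <- function(k, min_len, max_len, taken = character(0)) {
  out <- character(0)
  attempts <- 0L
  while (length(out) < k) {
    if (attempts > 200L * k + 200L) {
      stop("generate_taxonomy: requested count exceeds unique-name capacity",
           call. = FALSE)
    }
    w <- latinate_word(min_len, max_len)
    if (!(w %in% taken) && !(w %in% out)) out <- c(out, w)
    attempts <- attempts + 1L
  }
  out
}

#' Generate a synthetic species taxonomy
#'
#' Builds a seeded random dictionary of pronounceable latinate binomials:
#' `n_genera` genera (6-10 characters) each with `species_per_genus`
#' accepted species (epithets 4-9 characters), plus
#' `round(synonym_fraction * n_accepted)` synonym records, each a fresh
#' unique binomial pointing at a uniformly chosen accepted record. The
#' same seed always yields a byte-identical table.
#'
#' @param n_genera Number of genera (>= 1).
#' @param species_per_genus Accepted species per genus (>= 1).
#' @param synonym_fraction Synonyms as a fraction of accepted records, in
#'   `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A [taxonomy_table()]; raw names carry a capitalized genus.
#' @export
generate_taxonomy <- function(n_genera, species_per_genus,
                              synonym_fraction = 0, seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            synonym_fraction >= 0, synonym_fraction < 1)
  with_seed(seed, {
    genera <- sample_unique_words(n_genera, 6L, 10L)
    binomials <- character(0)
    for (g in genera) {
      eps <- sample_unique_words(species_per_genus, 4L, 9L)
      binomials <- c(binomials, paste(g, eps))
    }
    n_acc <- length(binomials)
    n_syn <- round(synonym_fraction * n_acc)
    syn_binomials <- character(0)
    if (n_syn > 0L) {
      syn_genera <- sample_unique_words(n_syn, 6L, 10L, taken = genera)
      syn_eps <- vapply(seq_len(n_syn), function(i) latinate_word(4L, 9L),
                        character(1))
      syn_binomials <- paste(syn_genera, syn_eps)
    }
    all_names <- c(binomials, syn_binomials)
    ids <- sprintf("ub%d", seq_along(all_names))
    status <- c(rep("accepted", n_acc), rep("synonym", n_syn))
    accepted_id <- c(ids[seq_len(n_acc)],
                     if (n_syn > 0L) sample(ids[seq_len(n_acc)], n_syn,
                                            replace = TRUE))
    raw <- paste0(toupper(substr(all_names, 1L, 1L)), substr(all_names, 2L,
                                                             nchar(all_names)))
    taxonomy_table(data.frame(
      record_id = ids,
      raw_name = raw,
      canonical_name = all_names,
      status = status,
      accepted_id = accepted_id,
      rank = "species",
      kingdom = "Plantae",
      sources = "synthetic",
      stringsAsFactors = FALSE
    ))
  })
}

#' Typo model for name corruption
#'
#' @param n_edits Number of independent edits to apply (>= 0).
#' @param weights Named probabilities over `substitution`, `deletion`,
#'   `insertion`, `transposition`; must sum to 1.
#' @param alphabet Characters used for substitutions/insertions.
#' @param protect_first_chars If TRUE (default), token-initial characters
#'   are never edited, so the pipeline's initials constraint remains
#'   satisfiable; set FALSE to generate "hard" no-match cases.
#' @return A list of class `typo_model`.
#' @export
typo_model <- function(n_edits = 1L,
                       weights = c(substitution = 0.25, deletion = 0.25,
                                   insertion = 0.25, transposition = 0.25),
                       alphabet = letters,
                       protect_first_chars = TRUE) {
  stopifnot(n_edits >= 0L)
  need <- c("substitution", "deletion", "insertion", "transposition")
  stopifnot(setequal(names(weights), need))
  weights <- weights[need]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("typo_model: edit weights must sum to 1", call. = FALSE)
  }
  structure(list(n_edits = as.integer(n_edits), weights = weights,
                 alphabet = alphabet,
                 protect_first_chars = isTRUE(protect_first_chars)),
            class = "typo_model")
}

# Apply one random edit to a character vector representation of a name.
# Token-initial positions (and spaces) are protected when asked; spaces
# are never edited so the binomial token structure survives.
apply_one_edit <- function(chars, model) {
  protected <- rep(FALSE, length(chars))
  is_space <- chars == " "
  if (model$protect_first_chars) {
    starts <- which(!is_space & (seq_along(chars) == 1L |
                                   c(FALSE, is_space[-length(chars)])))
    protected[starts] <- TRUE
  }
  editable <- which(!is_space & !protected)
  type <- sample(names(model$weights), 1L, prob = model$weights)
  if (type == "substitution") {
    if (!length(editable)) return(NULL)
    p <- if (length(editable) == 1L) editable else sample(editable, 1L)
    repl <- setdiff(model$alphabet, chars[p])
    chars[p] <- if (length(repl) == 1L) repl else sample(repl, 1L)
    chars
  } else if (type == "deletion") {
    if (!length(editable)) return(NULL)
    p <- if (length(editable) == 1L) editable else sample(editable, 1L)
    chars[-p]
  } else if (type == "insertion") {
    # insert AFTER an editable-or-protected letter (never at a token
    # start, so initials stay intact)
    anchors <- which(!is_space)
    if (!length(anchors)) return(NULL)
    p <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
    newc <- if (length(model$alphabet) == 1L) model$alphabet else
      sample(model$alphabet, 1L)
    append(chars, newc, after = p)
  } else { # transposition of adjacent distinct letters
    ok <- which(seq_along(chars) < length(chars) &
                  !is_space & !c(is_space[-1L], TRUE) &
                  !protected & !c(protected[-1L], TRUE) &
                  chars != c(chars[-1L], ""))
    if (!length(ok)) return(NULL)
    p <- if (length(ok) == 1L) ok else sample(ok, 1L)
    tmp <- chars[p]
    chars[p] <- chars[p + 1L]
    chars[p + 1L] <- tmp
    chars
  }
}

#' Corrupt a name with a fixed number of typos
#'
#' Applies exactly `model$n_edits` independent edits at uniformly chosen
#' eligible positions. Spaces are never edited (token structure is
#' preserved) and, with `protect_first_chars`, neither are token-initial
#' characters. The result is guaranteed to sit at restricted
#' Damerau-Levenshtein distance exactly `n_edits` from the input;
#' corruptions whose edits collide or compound to a different measured
#' distance are re-drawn (at most 100 attempts, then an error).
#'
#' @param name A binomial (or any non-empty lowercase string).
#' @param model A [typo_model()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used
#'   (so callers can batch under their own seed).
#' @return The corrupted string.
#' @export
corrupt <- function(name, model = typo_model(), seed = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(inherits(model, "typo_model"))
  if (model$n_edits >= nchar(name) / 2) {
    stop("corrupt: n_edits must be below half the name length", call. = FALSE)
  }
  run <- function() {
    if (model$n_edits == 0L) return(name)
    for (attempt in seq_len(100L)) {
      chars <- strsplit(name, "")[[1]]
      ok <- TRUE
      for (e in seq_len(model$n_edits)) {
        nxt <- apply_one_edit(chars, model)
        if (is.null(nxt)) { ok <- FALSE; break }
        chars <- nxt
      }
      if (!ok) next
      out <- paste(chars, collapse = "")
      # edits can collide or compound (e.g. two edits measuring as three
      # under the restricted distance); re-draw until the measured
      # distance equals the edit budget
      if (out != name &&
          dl_distance(name, out) == model$n_edits) {
        return(out)
      }
    }
    stop("corrupt: could not produce a distinct string in 100 attempts",
         call. = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Build a misspelled-query benchmark
#'
#' Emulates a misspelling benchmark: samples records (accepted or
#' synonym) with replacement, corrupts each canonical name under the typo
#' model, and pairs the query with the gold accepted id. A
#' `distractor_fraction` of the items are fresh latinate binomials absent
#' from the table, with gold `NA`. Deterministic under `seed`.
#'
#' @param table A [taxonomy_table()].
#' @param n_queries Number of benchmark items.
#' @param model A [typo_model()].
#' @param distractor_fraction Fraction of items that are distractors, in
#'   `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A list of class `benchmark_set`: `items` (data.frame `query`,
#'   `gold_id` with `NA` for distractors), `seed`, `config`.
#' @export
make_benchmark <- function(table, n_queries, model = typo_model(),
                           distractor_fraction = 0, seed = 1L) {
  stopifnot(inherits(table, "taxonomy_table"), n_queries >= 1L,
            distractor_fraction >= 0, distractor_fraction <= 1)
  with_seed(seed, {
    n_dis <- round(distractor_fraction * n_queries)
    is_dis <- rep(FALSE, n_queries)
    if (n_dis > 0L) is_dis[sample.int(n_queries, n_dis)] <- TRUE
    known <- table$records$canonical_name
    queries <- character(n_queries)
    gold <- rep(NA_character_, n_queries)
    for (i in seq_len(n_queries)) {
      if (is_dis[i]) {
        repeat {
          w <- paste(latinate_word(6L, 10L), latinate_word(4L, 9L))
          if (!(w %in% known)) break
        }
        queries[i] <- w
      } else {
        r <- sample.int(nrow(table$records), 1L)
        queries[i] <- corrupt(known[r], model)
        gold[i] <- table$records$accepted_id[r]
      }
    }
    # present queries the way users type them: capitalized genus
    queries <- paste0(toupper(substr(queries, 1L, 1L)),
                      substr(queries, 2L, nchar(queries)))
    structure(list(
      items = data.frame(query = queries, gold_id = gold,
                         stringsAsFactors = FALSE),
      seed = as.integer(seed),
      config = list(n_queries = n_queries, model = model,
                    distractor_fraction = distractor_fraction)
    ), class = "benchmark_set")
  })
}

filler_sentences <- c(
  "The experimental plots were sampled twice during the growing season.",
  "Soil moisture declined steadily over the observation period.",
  "Seed dispersal distances were recorded for each individual.",
  "Canopy cover was estimated from hemispherical photographs.",
  "Rainfall during the study year was close to the long-term mean."
)

planted_templates <- c(
  "Populations of %s increased at most sites.",
  "Seedlings of %s were transplanted into the common garden.",
  "Flowering in %s began earlier at low elevation.",
  "Herbivory on %s was measured weekly.",
  "Leaf samples of %s were collected for analysis."
)

#' Generate documents with planted species mentions
#'
#' Builds synthetic abstracts by interleaving fixed filler sentences with
#' template sentences carrying a planted dictionary name (optionally
#' corrupted under a typo model), and records the gold character offsets
#' of each planted name. Useful for end-to-end annotation tests.
#'
#' @param table A [taxonomy_table()].
#' @param n_docs Number of documents.
#' @param mentions_per_doc Planted names per document.
#' @param model Optional [typo_model()] applied to planted names
#'   (`NULL` = plant names verbatim).
#' @param seed Integer RNG seed.
#' @return A list of class `planted_docs`: `documents` (character
#'   vector) and `gold` (data.frame `doc`, `start`, `end`, `text`,
#'   `record_id`, `accepted_id`; offsets 0-based half-open).
#' @export
make_documents <- function(table, n_docs, mentions_per_doc = 3L,
                           model = NULL, seed = 1L) {
  stopifnot(inherits(table, "taxonomy_table"), n_docs >= 1L,
            mentions_per_doc >= 1L)
  with_seed(seed, {
    docs <- character(n_docs)
    gold <- list()
    for (d in seq_len(n_docs)) {
      text <- ""
      for (mi in seq_len(mentions_per_doc)) {
        filler <- sample(filler_sentences, 1L)
        text <- if (nzchar(text)) paste(text, filler) else filler
        r <- sample.int(nrow(table$records), 1L)
        nm <- table$records$canonical_name[r]
        if (!is.null(model)) nm <- corrupt(nm, model)
        nm <- paste0(toupper(substr(nm, 1L, 1L)), substr(nm, 2L, nchar(nm)))
        template <- sample(planted_templates, 1L)
        prefix <- sub("%s.*$", "", template)
        sentence <- sprintf(template, nm)
        start0 <- nchar(text) + 1L + nchar(prefix) # +1 for joining space
        text <- paste(text, sentence)
        gold[[length(gold) + 1L]] <- data.frame(
          doc = d, start = start0, end = start0 + nchar(nm), text = nm,
          record_id = table$records$record_id[r],
          accepted_id = table$records$accepted_id[r],
          stringsAsFactors = FALSE)
      }
      docs[d] <- text
    }
    structure(list(documents = docs, gold = do.call(rbind, gold)),
              class = "planted_docs")
  })
}
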