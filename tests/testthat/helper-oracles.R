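# Independent reference implementations used as oracles. These are
# deliberately naive, pure-R, and share no code with the package's
# production paths (which are C++).

# Restricted Damerau-Levenshtein (optimal string alignment) distance.
oracle_osa <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (A[i] == B[j]) 0L else 1L
      v <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L, D[i, j] + cost)
      if (i > 1L && j > 1L && A[i] == B[j - 1L] && A[i - 1L] == B[j]) {
        v <- min(v, D[i - 1L, j - 1L] + 1L)
      }
      D[i + 1L, j + 1L] <- v
    }
  }
  D[n + 1L, m + 1L]
}

# Brute-force Smith-Waterman maximum local-alignment score.
oracle_sw_score <- function(a, b, match = 2L, mismatch = -1L, gap = -1L) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0L, n + 1L, m + 1L)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      v <- max(H[i, j] + s, H[i, j + 1L] + gap, H[i + 1L, j] + gap, 0L)
      H[i + 1L, j + 1L] <- v
      if (v > best) best <- v
    }
  }
  best
}

random_string <- function(min_len = 4L, max_len = 30L,
                          alphabet = c(letters, " ")) {
  len <- sample(min_len:max_len, 1L)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A three-record dictionary used across modules.
tiny_table <- function() {
  taxonomy_table(data.frame(
    record_id = c("ub1", "ub2", "ub3"),
    raw_name = c("Quercus alba", "Quercus rubra", "Poa annua"),
    canonical_name = c("quercus alba", "quercus rubra", "poa annua"),
    status = c("accepted", "accepted", "synonym"),
    accepted_id = c("ub1", "ub2", "ub1"),
    rank = "species",
    kingdom = "Plantae",
    sources = "test",
    stringsAsFactors = FALSE
  ))
}

write_tiny_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  header <- "record_id\tname\tstatus\taccepted_id\trank\tkingdom\tsources"
  writeLines(c(header, lines), path)
  path
}
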