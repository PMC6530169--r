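# TRUE / FALSE / NOT-FOUND accounting and precision/recall/F-score, with
# the display conventions of published comparison tables.

#' Score resolution results against gold ids
#'
#' Classifies each item: `true` when the decision is a match and the
#' matched accepted id equals the gold accepted id; `false` when a match
#' disagrees with gold (including any match on a gold-`NA` distractor);
#' `not_found` for every no-match decision (correct rejections of
#' distractors included). Comparison is on accepted ids after synonym
#' resolution on both sides.
#'
#' @param results A data.frame from [resolve_names()] (columns `decision`,
#'   `accepted_id`).
#' @param gold Character vector of gold record ids (`NA` = no valid
#'   answer), same length as `results`.
#' @param table The [taxonomy_table()] the ids live in.
#' @return A list of class `eval_counts`: `true_count`, `false_count`,
#'   `not_found`, `total`.
#' @export
evaluate <- function(results, gold, table) {
  stopifnot(is.data.frame(results), inherits(table, "taxonomy_table"))
  if (nrow(results) != length(gold)) {
    stop("evaluate: results and gold have different lengths", call. = FALSE)
  }
  gold_acc <- accepted_id_of(table, gold)
  res_acc <- accepted_id_of(table, results$accepted_id)
  matched <- results$decision == "match"
  true_count <- sum(matched & !is.na(gold_acc) & res_acc == gold_acc,
                    na.rm = TRUE)
  false_count <- sum(matched) - true_count
  not_found <- sum(!matched)
  structure(list(true_count = true_count, false_count = false_count,
                 not_found = not_found, total = nrow(results)),
            class = "eval_counts")
}

#' Construct evaluation counts directly
#'
#' @param true_count,false_count,not_found Non-negative integers; their
#'   sum is the total.
#' @return A list of class `eval_counts`.
#' @export
eval_counts <- function(true_count, false_count, not_found) {
  stopifnot(true_count >= 0, false_count >= 0, not_found >= 0)
  structure(list(true_count = as.integer(true_count),
                 false_count = as.integer(false_count),
                 not_found = as.integer(not_found),
                 total = as.integer(true_count + false_count + not_found)),
            class = "eval_counts")
}

#' Precision / recall / F-score report
#'
#' Computes `precision = true / (true + false)` and
#' `recall = true / total` (0 on a zero denominator), and the harmonic
#' mean F-score. Raw values are kept at full precision; the display
#' values round at `decimals` places (base R rounding, which resolves
#' exact decimal midpoints like 0.745 downward to even, as the published
#' tables do), and the displayed F-score is recomputed from the *rounded*
#' precision and recall, matching how published comparison tables derive
#' it.
#'
#' @param counts An [eval_counts()] / [evaluate()] result.
#' @param decimals Display rounding (default 2).
#' @return A list of class `eval_report`: `counts`, raw `precision`,
#'   `recall`, `f_score`, and `display` (named numeric vector of rounded
#'   `precision`, `recall`, `f_score`).
#' @export
report_metrics <- function(counts, decimals = 2L) {
  stopifnot(inherits(counts, "eval_counts"))
  tc <- counts$true_count; fc <- counts$false_count; tot <- counts$total
  precision <- if (tc + fc > 0) tc / (tc + fc) else 0
  recall <- if (tot > 0) tc / tot else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  p_d <- display_round(precision, decimals)
  r_d <- display_round(recall, decimals)
  f_d <- if (p_d + r_d > 0) {
    display_round(2 * p_d * r_d / (p_d + r_d), decimals)
  } else 0
  structure(list(
    counts = counts,
    precision = precision, recall = recall, f_score = f_score,
    display = c(precision = p_d, recall = r_d, f_score = f_d)
  ), class = "eval_report")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("%-10s %d\n", "TRUE", x$true_count))
  cat(sprintf("%-10s %d\n", "FALSE", x$false_count))
  cat(sprintf("%-10s %d\n", "NOT FOUND", x$not_found))
  cat(sprintf("%-10s %d\n", "TOTAL", x$total))
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$counts)
  cat(sprintf("%-10s %.2f\n", "PRECISION", x$display["precision"]))
  cat(sprintf("%-10s %.2f\n", "RECALL", x$display["recall"]))
  cat(sprintf("%-10s %.2f\n", "F-SCORE", x$display["f_score"]))
  invisible(x)
}

#' Score mentions against gold planted offsets
#'
#' Exact-span, species-level mention scoring: a predicted mention is
#' `true` when some gold mention in the same document has identical
#' `[start, end)` offsets and the same accepted id; anything else
#' (including partial genus overlaps) is `false`. Gold mentions with no
#' exact-span prediction count as `not_found`.
#'
#' @param mentions_by_doc List of [annotate()] results, one per document.
#' @param gold Gold data.frame with columns `doc`, `start`, `end`,
#'   `accepted_id` (as produced by [make_documents()]).
#' @return An `eval_counts` object over gold mentions and predictions.
#' @export
evaluate_mentions <- function(mentions_by_doc, gold) {
  true_count <- 0L; false_count <- 0L
  matched_gold <- rep(FALSE, nrow(gold))
  for (d in seq_along(mentions_by_doc)) {
    m <- mentions_by_doc[[d]]
    gd <- which(gold$doc == d)
    for (i in seq_len(nrow(m))) {
      hit <- gd[gold$start[gd] == m$start[i] & gold$end[gd] == m$end[i] &
                  gold$accepted_id[gd] == m$accepted_id[i]]
      if (length(hit)) {
        true_count <- true_count + 1L
        matched_gold[hit[1L]] <- TRUE
      } else {
        false_count <- false_count + 1L
      }
    }
  }
  structure(list(true_count = true_count, false_count = false_count,
                 not_found = sum(!matched_gold),
                 total = true_count + false_count + sum(!matched_gold)),
            class = "eval_counts")
}
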