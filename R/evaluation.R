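# Scoring against gold labels at note and hit level, plus bucketing of
# misclassifications into the recurring error families of rule-based
# housing extraction: resource-list false positives, third-party and
# family-member mentions, and negation-scope false negatives.

eval_result <- function(tp, fp, tn, fn, level, recall_defined = TRUE) {
  precision <- if ((tp + fp) > 0L) tp / (tp + fp) else NA_real_
  recall <- if (recall_defined && (tp + fn) > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1,
                 level = level),
            class = "eval_result")
}

fmt_metric <- function(x) if (is.na(x)) "N/A" else format(round(x, 4))

#' @export
print.eval_result <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Render an evaluation result as a plain-text report
#'
#' Undefined ratios are printed as `"N/A"`, never as 0 — e.g. recall in a
#' precision-only review where no gold negatives exist.
#'
#' @param x An `eval_result`.
#' @return Character vector of report lines.
#' @export
format_eval_report <- function(x) {
  stopifnot(inherits(x, "eval_result"))
  c(sprintf("Evaluation level: %s", x$level),
    sprintf("TP: %d  FP: %d  TN: %d  FN: %d", x$tp, x$fp, x$tn, x$fn),
    sprintf("Precision: %s", fmt_metric(x$precision)),
    sprintf("Recall: %s", fmt_metric(x$recall)),
    sprintf("F1: %s", fmt_metric(x$f1)))
}

check_labels <- function(labels, what) {
  if (!all(labels %in% c("positive", "negative"))) {
    abort_data(paste0(what, " labels must be 'positive' or 'negative'"))
  }
}

#' Note-level evaluation against gold labels
#'
#' Standard confusion-matrix computation over exactly-matched note ids.
#' `tp + fp + tn + fn` equals the number of scored notes.
#'
#' @param predictions Data frame `note_id`, `label`.
#' @param gold Data frame `note_id`, `label`.
#' @return An `eval_result` (level `"note"`).
#' @export
#' @examples
#' p <- data.frame(note_id = c("a", "b"), label = c("positive", "negative"))
#' evaluate_notes(p, p)
evaluate_notes <- function(predictions, gold) {
  stopifnot(is.data.frame(predictions), is.data.frame(gold))
  miss_gold <- setdiff(predictions$note_id, gold$note_id)
  miss_pred <- setdiff(gold$note_id, predictions$note_id)
  if (length(miss_gold) > 0L || length(miss_pred) > 0L) {
    abort_data(paste0(
      "note ids do not align between predictions and gold",
      if (length(miss_gold)) paste0("; missing from gold: ",
                                    paste(miss_gold, collapse = ", ")),
      if (length(miss_pred)) paste0("; missing from predictions: ",
                                    paste(miss_pred, collapse = ", "))))
  }
  if (anyDuplicated(predictions$note_id) || anyDuplicated(gold$note_id)) {
    abort_data("duplicate note_id in predictions or gold")
  }
  check_labels(predictions$label, "prediction")
  check_labels(gold$label, "gold")
  g <- gold$label[match(predictions$note_id, gold$note_id)]
  p <- predictions$label
  eval_result(tp = sum(p == "positive" & g == "positive"),
              fp = sum(p == "positive" & g == "negative"),
              tn = sum(p == "negative" & g == "negative"),
              fn = sum(p == "negative" & g == "positive"),
              level = "note")
}

#' Hit-level evaluation against gold mention annotations
#'
#' Predicted and gold mentions are aligned when they share a note, their
#' spans overlap by at least one character, and concepts agree. A predicted
#' mention wrongly negated against an affirmed gold mention counts as a
#' hit-level false negative. When several predictions align to one gold
#' mention, the leftmost is scored and the rest are ignored (not false
#' positives). In `precision_only` mode — mirroring review settings where
#' extracted hits are checked for correctness but no exhaustive gold
#' annotation exists — the scored units are the predicted positive hits
#' (`positive` in gold flags a reviewed-correct hit) and recall is
#' undefined.
#'
#' @param predicted Asserted mentions ([assert_corpus()] output).
#' @param gold_mentions Data frame `note_id`, `start`, `end`, `concept`,
#'   `positive` (logical).
#' @param precision_only Reviewed-hits mode, see above.
#' @param historical_positive Passed to [positive_hit()].
#' @return An `eval_result` (level `"hit"`).
#' @export
evaluate_hits <- function(predicted, gold_mentions, precision_only = FALSE,
                          historical_positive = TRUE) {
  stopifnot(is.data.frame(predicted), is.data.frame(gold_mentions))
  need <- c("note_id", "start", "end", "concept", "positive")
  if (!all(need %in% names(gold_mentions))) {
    abort_data(paste0("gold mentions need columns: ",
                      paste(need, collapse = ", ")))
  }
  pred_pos <- positive_hit(predicted, historical_positive)

  if (precision_only) {
    tp <- 0L; fp <- 0L
    for (k in which(pred_pos)) {
      hit <- gold_mentions$note_id == predicted$note_id[k] &
        gold_mentions$concept == predicted$concept[k] &
        spans_overlap(gold_mentions$start, gold_mentions$end,
                      predicted$start[k], predicted$end[k])
      if (any(hit) && any(gold_mentions$positive[hit])) tp <- tp + 1L
      else fp <- fp + 1L
    }
    return(eval_result(tp, fp, 0L, 0L, level = "hit", recall_defined = FALSE))
  }

  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  matched_pred <- logical(nrow(predicted))
  for (g in seq_len(nrow(gold_mentions))) {
    idx <- which(predicted$note_id == gold_mentions$note_id[g] &
                   predicted$concept == gold_mentions$concept[g] &
                   spans_overlap(predicted$start, predicted$end,
                                 gold_mentions$start[g], gold_mentions$end[g]))
    idx <- idx[order(predicted$start[idx])]
    matched_pred[idx] <- TRUE
    any_pos <- length(idx) > 0L && any(pred_pos[idx])
    if (gold_mentions$positive[g]) {
      if (any_pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (any_pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  fp <- fp + sum(pred_pos & !matched_pred)
  eval_result(tp, fp, tn, fn, level = "hit")
}

error_buckets <- function() {
  c("resource_list_fp", "third_party_fp", "family_member_fp",
    "negation_scope_fn", "other")
}

third_party_cue <- paste0(
  "(?i)\\b(a|an|another)\\s+(homeless|unhoused)\\s+",
  "(person|man|woman|individual|gentleman|lady|veteran)\\b")

#' Bucket misclassifications into an error taxonomy
#'
#' Assigns each error to one of `resource_list_fp` (false positive inside a
#' patient-education/resource section), `family_member_fp` (sentence names
#' a family-member experiencer), `third_party_fp` (sentence describes an
#' unrelated third person), `negation_scope_fn` (false negative with a
#' negation trigger in the sentence — the concept being negated was
#' misidentified), or `other`.
#'
#' @param errors Data frame with columns `type` (`"fp"` or `"fn"`),
#'   `sentence_text`, and optionally `section_header` and `note_id`.
#' @param rules Context rules used to spot experiencer / negation triggers.
#' @return Named list mapping every bucket to its (possibly empty) subset
#'   of `errors`.
#' @export
bucket_errors <- function(errors, rules = load_context_rules()) {
  stopifnot(is.data.frame(errors),
            all(c("type", "sentence_text") %in% names(errors)))
  if (!all(errors$type %in% c("fp", "fn"))) {
    abort_data("error type must be 'fp' or 'fn'")
  }
  r <- rules_df(rules)
  exp_rules <- r[r$dimension == "experiencer" & r$value != "none", , drop = FALSE]
  neg_rules <- r[r$dimension == "negation" & r$value != "none", , drop = FALSE]
  has_trigger <- function(txt, tr) {
    any(vapply(tr$compiled, function(p) grepl(p, txt, perl = TRUE), TRUE))
  }
  header <- if ("section_header" %in% names(errors)) {
    errors$section_header
  } else {
    rep(NA_character_, nrow(errors))
  }

  bucket <- character(nrow(errors))
  for (k in seq_len(nrow(errors))) {
    txt <- errors$sentence_text[k]
    if (errors$type[k] == "fp") {
      bucket[k] <- if (!is.na(header[k]) &&
                       grepl("(?i)patient education|resource", header[k],
                             perl = TRUE)) {
        "resource_list_fp"
      } else if (nrow(exp_rules) > 0L && has_trigger(txt, exp_rules)) {
        "family_member_fp"
      } else if (grepl(third_party_cue, txt, perl = TRUE)) {
        "third_party_fp"
      } else {
        "other"
      }
    } else {
      bucket[k] <- if (nrow(neg_rules) > 0L && has_trigger(txt, neg_rules)) {
        "negation_scope_fn"
      } else {
        "other"
      }
    }
  }
  out <- lapply(error_buckets(), function(b) errors[bucket == b, , drop = FALSE])
  names(out) <- error_buckets()
  out
}
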