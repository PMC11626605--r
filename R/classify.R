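# Note-level labeling and concept distributions. A note is positive iff at
# least one of its hits is positive; a hit is positive when it is not
# negated and the experiencer is the patient. Historical mentions count as
# positive by default (housing history stays clinically relevant), with an
# override flag.

#' Positive-hit predicate
#'
#' @param asserted Asserted-mention data frame ([assert_corpus()] output).
#' @param historical_positive Do historical (resolved) mentions still count
#'   as positive hits? Default `TRUE`.
#' @return Logical vector, one element per mention.
#' @export
positive_hit <- function(asserted, historical_positive = TRUE) {
  ok <- !asserted$negated & asserted$experiencer == "patient"
  if (!historical_positive) ok <- ok & !asserted$historical
  ok
}

#' Label a single note from its asserted mentions
#'
#' `"positive"` iff at least one positive hit; a note with no mentions, or
#' whose mentions are all negated or about another experiencer, is
#' `"negative"`.
#'
#' @inheritParams positive_hit
#' @return `"positive"` or `"negative"`.
#' @export
#' @examples
#' classify_note(data.frame(note_id = "a", negated = TRUE,
#'                          historical = FALSE, experiencer = "patient"))
classify_note <- function(asserted, historical_positive = TRUE) {
  if (nrow(asserted) == 0L) return("negative")
  if (length(unique(asserted$note_id)) > 1L) {
    abort_data("classify_note: mentions from multiple note_ids")
  }
  if (any(positive_hit(asserted, historical_positive))) "positive" else "negative"
}

#' Label every note of a corpus
#'
#' @param asserted Asserted mentions for the whole corpus.
#' @param note_ids All note ids (zero-mention notes are labeled negative).
#' @inheritParams positive_hit
#' @return Data frame `note_id`, `label`, `n_mentions`, `n_positive_hits`.
#' @export
classify_corpus <- function(asserted, note_ids, historical_positive = TRUE) {
  ph <- positive_hit(asserted, historical_positive)
  n_mentions <- as.integer(table(factor(asserted$note_id, levels = note_ids)))
  n_pos <- as.integer(table(factor(asserted$note_id[ph], levels = note_ids)))
  data.frame(
    note_id = note_ids,
    label = ifelse(n_pos > 0L, "positive", "negative"),
    n_mentions = n_mentions,
    n_positive_hits = n_pos,
    stringsAsFactors = FALSE
  )
}

#' Distribution of identified concepts
#'
#' Counts asserted mentions per concept category, either over all hits or
#' only over positive hits (the default: affirmed patient-experienced
#' concepts are what cohort-level interpretation rests on).
#'
#' @inheritParams positive_hit
#' @param basis `"positive_hits"` (default) or `"all_hits"`.
#' @return Data frame `concept`, `count`, `basis` covering all six
#'   categories; counts sum to the number of basis-filtered mentions.
#' @export
concept_distribution <- function(asserted,
                                 basis = c("positive_hits", "all_hits"),
                                 historical_positive = TRUE) {
  basis <- match.arg(basis)
  sel <- if (basis == "positive_hits") {
    positive_hit(asserted, historical_positive)
  } else {
    rep(TRUE, nrow(asserted))
  }
  counts <- table(factor(asserted$concept[sel], levels = housing_concepts()))
  data.frame(concept = housing_concepts(),
             count = as.integer(counts),
             basis = basis,
             stringsAsFactors = FALSE)
}
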