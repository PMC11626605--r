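# Dictionary matching: find all lexicon hits inside each sentence and emit
# mentions with note-relative spans. Matching is sentence-local (patterns
# never cross a sentence boundary) and overlaps are resolved
# leftmost-longest, ties between entries at the same span broken by lexicon
# file order. A span yields exactly one mention.

empty_mentions <- function() {
  data.frame(note_id = character(0), sentence_index = integer(0),
             concept = character(0), matched_text = character(0),
             start = integer(0), end = integer(0), entry_id = integer(0),
             stringsAsFactors = FALSE)
}

#' Match lexicon concepts inside one sentence
#'
#' @param sentence One sentence: a list or one-row data frame with fields
#'   `note_id`, `index`, `start`, `text` (as produced by
#'   [segment_sentences()]).
#' @param lexicon A [load_lexicon()] result.
#' @return Data frame of mentions: `note_id`, `sentence_index`, `concept`,
#'   `matched_text`, `start`, `end` (note-relative, 0-based half-open),
#'   `entry_id`. Maximal non-overlapping matches in left-to-right order.
#' @export
#' @examples
#' lex <- load_lexicon()
#' s <- segment_sentences("Patient is homeless.")[1, ]
#' match_concepts(s, lex)
match_concepts <- function(sentence, lexicon) {
  stopifnot(inherits(lexicon, "compiled_lexicon"))
  sentence <- as.list(sentence)
  txt <- sentence$text
  if (is.null(txt) || !nzchar(txt)) return(empty_mentions())
  entries <- lexicon$entries

  starts <- integer(0); lens <- integer(0); eids <- integer(0)
  for (i in seq_len(nrow(entries))) {
    g <- gregexpr(entries$compiled[i], txt, perl = TRUE)[[1L]]
    if (g[1L] == -1L) next
    ml <- attr(g, "match.length")
    starts <- c(starts, as.integer(g))
    lens <- c(lens, as.integer(ml))
    eids <- c(eids, rep.int(i, length(g)))
  }
  if (length(starts) == 0L) return(empty_mentions())

  ord <- order(starts, -lens, eids)
  starts <- starts[ord]; lens <- lens[ord]; eids <- eids[ord]

  keep <- logical(length(starts))
  last_end <- 0L  # local 1-based end of last accepted match
  for (k in seq_along(starts)) {
    if (starts[k] > last_end) {
      keep[k] <- TRUE
      last_end <- starts[k] + lens[k] - 1L
    }
  }
  starts <- starts[keep]; lens <- lens[keep]; eids <- eids[keep]

  data.frame(
    note_id = sentence$note_id,
    sentence_index = sentence$index,
    concept = entries$concept[eids],
    matched_text = substring(txt, starts, starts + lens - 1L),
    start = sentence$start + starts - 1L,
    end = sentence$start + starts + lens - 1L,
    entry_id = entries$entry_id[eids],
    stringsAsFactors = FALSE
  )
}

#' Match lexicon concepts over a whole corpus
#'
#' Equivalent to running [match_concepts()] over every sentence of every
#' note; output is ordered by (note order, sentence order, offset).
#'
#' @param notes Data frame with `note_id`, `text`; ids must be unique.
#' @param lexicon A [load_lexicon()] result.
#' @param sentences Optional precomputed [segment_corpus()] output (must
#'   cover `notes` in the same order); segmented on the fly if `NULL`.
#' @return Data frame of mentions (see [match_concepts()]).
#' @export
match_corpus <- function(notes, lexicon, sentences = NULL) {
  stopifnot(is.data.frame(notes), all(c("note_id", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id)) {
    abort_data(paste0("duplicate note_id: ",
                      paste(unique(notes$note_id[duplicated(notes$note_id)]),
                            collapse = ", ")))
  }
  if (is.null(sentences)) sentences <- segment_corpus(notes)
  if (nrow(sentences) == 0L) return(empty_mentions())
  parts <- lapply(seq_len(nrow(sentences)), function(k) {
    match_concepts(sentences[k, ], lexicon)
  })
  out <- do.call(rbind, c(parts, list(empty_mentions())))
  rownames(out) <- NULL
  out
}
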