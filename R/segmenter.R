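# Deterministic rule-based sentence segmentation with exact character
# offsets. Assertion scope downstream is sentence-bounded, so offsets must
# be reproducible to the character: 0-based, half-open [start, end),
# counted in Unicode code points. Sentence text always equals the note
# substring at its span; terminal punctuation stays inside the sentence and
# inter-sentence gaps are whitespace only.

# Lower-cased abbreviations whose trailing period never ends a sentence.
# Single-letter tokens ("F.", the pieces of "b.i.d.") are protected by a
# separate rule.
clinical_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "vs",
    "pt", "pts", "hx", "dx", "tx", "rx", "fx", "sx",
    "etc", "approx", "appt", "dept", "wt", "ht", "neg", "pos",
    "resp", "abd", "ext", "gen", "psych", "neuro")
}

empty_sentences <- function(note_id) {
  data.frame(note_id = character(0), index = integer(0),
             start = integer(0), end = integer(0), text = character(0),
             stringsAsFactors = FALSE)
}

#' Split a clinical note into sentences with exact offsets
#'
#' Rule-based splitting on sentence terminators (`.`, `!`, `?` followed by
#' whitespace or end of text), every line break, and section headers
#' (`"Patient Education:"` at line start ends a sentence at the colon).
#' A period is protected — does not split — after a common clinical
#' abbreviation or a single letter, and inside decimal numbers.
#'
#' @param text Note text (length-1 character; may be empty).
#' @param note_id Identifier copied into the output rows.
#' @return Data frame with columns `note_id`, `index` (0-based ordinal),
#'   `start`, `end` (0-based, half-open, code points), `text`. Sentences
#'   are ordered, non-overlapping, and `text` equals
#'   `substr(note, start + 1, end)`.
#' @export
#' @examples
#' segment_sentences("Patient is homeless. Denies chest pain.")
segment_sentences <- function(text, note_id = "note") {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_sentences(note_id))
  n <- nchar(text)
  cuts <- integer(0)

  # Terminator runs: cut after the run when followed by whitespace/EOF.
  term <- gregexpr("[.!?]+", text, perl = TRUE)[[1L]]
  if (term[1L] != -1L) {
    lens <- attr(term, "match.length")
    for (k in seq_along(term)) {
      p <- term[k]
      last <- p + lens[k] - 1L
      nxt <- if (last < n) substr(text, last + 1L, last + 1L) else ""
      if (nzchar(nxt) && !grepl("^\\s$", nxt)) next
      if (lens[k] == 1L && substr(text, p, p) == ".") {
        before <- substr(text, max(1L, p - 15L), p - 1L)
        w <- regmatches(before, regexpr("[A-Za-z]+$", before))
        if (length(w) == 1L &&
            (nchar(w) == 1L || tolower(w) %in% clinical_abbreviations())) {
          next
        }
      }
      cuts <- c(cuts, last)
    }
  }

  # Every line break ends a sentence (list items, paragraph breaks).
  nl <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  if (nl[1L] != -1L) cuts <- c(cuts, as.integer(nl))

  # Section headers terminate a sentence at the colon.
  hd <- gregexpr("(?m)^[ \t]*[A-Za-z][A-Za-z0-9 /()'&-]{0,60}:", text,
                 perl = TRUE)[[1L]]
  if (hd[1L] != -1L) {
    cuts <- c(cuts, as.integer(hd) + attr(hd, "match.length") - 1L)
  }

  cuts <- sort(unique(cuts))
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, n)
  keep <- starts <= stops
  starts <- starts[keep]
  stops <- stops[keep]

  rows <- vector("list", length(starts))
  m <- 0L
  for (k in seq_along(starts)) {
    seg <- substr(text, starts[k], stops[k])
    lead <- attr(regexpr("^\\s*", seg), "match.length")
    trail <- attr(regexpr("\\s*$", seg, perl = TRUE), "match.length")
    a <- starts[k] + lead
    b <- stops[k] - trail
    if (a > b) next
    m <- m + 1L
    rows[[m]] <- data.frame(note_id = note_id, index = 0L,
                            start = a - 1L, end = b,
                            text = substr(text, a, b),
                            stringsAsFactors = FALSE)
  }
  if (m == 0L) return(empty_sentences(note_id))
  out <- do.call(rbind, rows[seq_len(m)])
  out$index <- seq_len(m) - 1L
  out
}

#' Segment every note in a corpus
#'
#' @param notes Data frame with columns `note_id`, `text`.
#' @return Row-bound [segment_sentences()] output, notes in input order.
#' @export
segment_corpus <- function(notes) {
  stopifnot(is.data.frame(notes), all(c("note_id", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id)) {
    abort_data(paste0("duplicate note_id: ",
                      paste(unique(notes$note_id[duplicated(notes$note_id)]),
                            collapse = ", ")))
  }
  parts <- lapply(seq_len(nrow(notes)), function(i) {
    segment_sentences(notes$text[i], notes$note_id[i])
  })
  out <- do.call(rbind, c(parts, list(empty_sentences(""))))
  rownames(out) <- NULL
  out
}
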