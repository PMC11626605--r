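# Shared fixtures: tiny lexicon/rule files written on the fly, cached
# shipped resources, a naive literal-scan matcher used as an independent
# oracle, and small random-text generators.

.fixtures <- new.env(parent = emptyenv())

shipped_lexicon <- function() {
  if (is.null(.fixtures$lex)) .fixtures$lex <- load_lexicon()
  .fixtures$lex
}

shipped_rules <- function() {
  if (is.null(.fixtures$rules)) .fixtures$rules <- load_context_rules()
  .fixtures$rules
}

lexicon_header <- "concept\tpattern\tsource_phrases\tcase_sensitive\tnotes"

lex_row <- function(concept, pattern, phrases, case_sensitive = "false",
                    notes = "") {
  paste(concept, pattern, paste(phrases, collapse = "|"), case_sensitive,
        notes, sep = "\t")
}

make_lexicon_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(lexicon_header, rows), path)
  path
}

rules_header <- paste("rule_id", "trigger", "dimension", "value", "direction",
                      "max_scope_tokens", "enabled", sep = "\t")

rule_row <- function(rule_id, trigger, dimension, value, direction,
                     max_scope_tokens = "", enabled = "true") {
  paste(rule_id, trigger, dimension, value, direction, max_scope_tokens,
        enabled, sep = "\t")
}

make_rules_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(rules_header, rows), path)
  path
}

# Literal-only lexicon for oracle-equivalence tests (pattern == phrase).
oracle_lexicon <- function() {
  if (is.null(.fixtures$oracle_lex)) {
    phrases <- oracle_phrases()
    rows <- vapply(seq_len(nrow(phrases)), function(i) {
      lex_row(phrases$concept[i], phrases$phrase[i], phrases$phrase[i])
    }, "")
    .fixtures$oracle_lex <- load_lexicon(make_lexicon_file(rows))
  }
  .fixtures$oracle_lex
}

oracle_phrases <- function() {
  data.frame(
    concept = c("homeless", "homeless", "emergency_housing",
                "unstable_housing", "temporary_housing", "homeless",
                "emergency_housing"),
    phrase = c("homeless", "homelessness", "homeless shelter",
               "housing", "temporary housing", "lack of housing",
               "shelter"),
    stringsAsFactors = FALSE
  )
}

# Naive case-folded literal scan with word boundaries, resolved
# leftmost-longest (shorter overlapping matches suppressed, ties by entry
# order). Intentionally avoids regular expressions for the scan itself.
naive_literal_mentions <- function(txt, phrases) {
  low <- tolower(txt)
  n <- nchar(low)
  is_word <- function(ch) nzchar(ch) && grepl("[a-z0-9_]", ch)
  starts <- integer(0); lens <- integer(0); eids <- integer(0)
  for (i in seq_len(nrow(phrases))) {
    p <- tolower(phrases$phrase[i])
    np <- nchar(p)
    pos <- 1L
    while (pos + np - 1L <= n) {
      hit <- regexpr(p, substr(low, pos, n), fixed = TRUE)
      if (hit == -1L) break
      st <- pos + as.integer(hit) - 1L
      before <- if (st > 1L) substr(low, st - 1L, st - 1L) else ""
      after <- if (st + np - 1L < n) substr(low, st + np, st + np) else ""
      if (!is_word(before) && !is_word(after)) {
        starts <- c(starts, st); lens <- c(lens, np); eids <- c(eids, i)
      }
      pos <- st + 1L
    }
  }
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), len = integer(0),
                      concept = character(0), stringsAsFactors = FALSE))
  }
  ord <- order(starts, -lens, eids)
  starts <- starts[ord]; lens <- lens[ord]; eids <- eids[ord]
  keep <- logical(length(starts)); last_end <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] > last_end) {
      keep[k] <- TRUE
      last_end <- starts[k] + lens[k] - 1L
    }
  }
  data.frame(start = starts[keep], len = lens[keep],
             concept = phrases$concept[eids[keep]], stringsAsFactors = FALSE)
}

random_word_sentences <- function(n, seed) {
  vocab <- c("patient", "reports", "the", "a", "stable", "pain", "follow",
             "up", "housing", "homeless", "homelessness", "shelter", "lack",
             "of", "street", "denies", "and", "with", "temporary", "crisis",
             "visit", "today", "plan", "rest", "fluids", "exam", "normal")
  withr_seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(4:12, 1L), replace = TRUE), collapse = " ")
  }, "")
}

random_clinical_texts <- function(n, seed) {
  units <- c("Patient is doing well", "Dr. Smith reviewed the chart",
             "Temp was 98.6 today", "pt. seen and examined",
             "Take 2 tablets b.i.d. as needed", "Plan", "Patient Education",
             "Follow up in 3 days", "No acute distress", "Wound is healing")
  seps <- c(". ", "! ", "? ", "\n", "\n\n", ": ")
  withr_seed(seed)
  vapply(seq_len(n), function(i) {
    k <- sample(2:6, 1L)
    paste0(paste0(sample(units, k, replace = TRUE),
                  sample(seps, k, replace = TRUE), collapse = ""), "End")
  }, "")
}

withr_seed <- function(seed) set.seed(seed)

# Quick single-sentence wrapper used throughout the matcher tests.
first_sentence <- function(text) segment_sentences(text, "probe")[1L, ]

mentions_for <- function(text, lexicon = shipped_lexicon()) {
  match_concepts(first_sentence(text), lexicon)
}
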