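# ConText-style assertion classification. Each mention is assigned, per
# dimension (negation, temporality, experiencer), the value of any enabled
# trigger whose directional scope covers the mention. Scopes never cross the
# sentence boundary; termination terms ("but", "however") end a scope early;
# pseudo-triggers (value "none") block real triggers they overlap; a trigger
# overlapping the mention itself is ignored (so "no fixed address" does not
# self-negate). Default status: not negated, not historical, experiencer
# "patient".

context_dimensions <- function() {
  c("negation", "temporality", "experiencer", "termination")
}

# dimension -> admissible non-pseudo value
context_value_map <- function() {
  c(negation = "negated", temporality = "historical",
    experiencer = "other_experiencer", termination = "terminate")
}

#' Load ConText-style assertion trigger rules
#'
#' Reads a TSV with columns `rule_id`, `trigger` (dialect pattern),
#' `dimension` (`negation`, `temporality`, `experiencer`, `termination`),
#' `value` (`negated`, `historical`, `other_experiencer`, `terminate`, or
#' `none` for pseudo-triggers that only block real triggers), `direction`
#' (`forward`, `backward`, `bidirectional`), `max_scope_tokens` (empty =
#' unbounded within the sentence), `enabled`. Disabled rows — e.g. the
#' pruned test-result negation `did_not_demonstrate`, inappropriate because
#' housing is not something patients test positive or negative for — are
#' retained in an audit list but never fire.
#'
#' @param path Rule file; defaults to the shipped rule set.
#' @return Object of class `context_rules`: list with `rules` (enabled,
#'   compiled), `audit` (disabled rows), `source_path`, `version`.
#' @export
#' @examples
#' rls <- load_context_rules()
#' head(rls$rules[, c("rule_id", "trigger", "dimension")])
load_context_rules <- function(path = default_context_rules_path()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_config(paste0("context-rule file not found: ", path))
  }
  raw <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = NULL, blank.lines.skip = TRUE,
                           fileEncoding = "UTF-8")
  required <- c("rule_id", "trigger", "dimension", "value", "direction",
                "max_scope_tokens", "enabled")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort_config(paste0("context-rule file lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(raw$rule_id)) {
    abort_data(paste0("duplicate rule_id: ",
                      paste(unique(raw$rule_id[duplicated(raw$rule_id)]),
                            collapse = ", ")))
  }
  bad_dim <- which(!raw$dimension %in% context_dimensions())
  if (length(bad_dim) > 0L) {
    abort_data(sprintf("rule '%s': unknown dimension '%s'",
                       raw$rule_id[bad_dim[1L]], raw$dimension[bad_dim[1L]]))
  }
  vmap <- context_value_map()
  ok_value <- raw$value == "none" | raw$value == vmap[raw$dimension]
  if (!all(ok_value)) {
    i <- which(!ok_value)[1L]
    abort_data(sprintf("rule '%s': value '%s' inconsistent with dimension '%s'",
                       raw$rule_id[i], raw$value[i], raw$dimension[i]))
  }
  bad_dir <- which(!raw$direction %in% c("forward", "backward", "bidirectional"))
  if (length(bad_dir) > 0L) {
    abort_data(sprintf("rule '%s': unknown direction '%s'",
                       raw$rule_id[bad_dir[1L]], raw$direction[bad_dir[1L]]))
  }
  msc <- trimws(raw$max_scope_tokens)
  scope <- ifelse(msc == "" | tolower(msc) == "unbounded", Inf,
                  suppressWarnings(as.numeric(msc)))
  if (anyNA(scope) || any(is.finite(scope) & scope < 1)) {
    abort_data("max_scope_tokens must be empty/'unbounded' or a positive integer")
  }
  enabled <- parse_flag(raw$enabled, "context-rule column enabled")

  compiled <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    regex <- compile_pattern(raw$trigger[i], case_sensitive = FALSE)
    err <- compile_error(regex)
    if (!is.null(err)) {
      abort_data(sprintf("rule '%s': trigger does not compile: %s",
                         raw$rule_id[i], err))
    }
    compiled[i] <- regex
  }

  df <- data.frame(rule_id = raw$rule_id, trigger = raw$trigger,
                   dimension = raw$dimension, value = raw$value,
                   direction = raw$direction, max_scope_tokens = scope,
                   enabled = enabled, compiled = compiled,
                   stringsAsFactors = FALSE)
  structure(
    list(rules = df[df$enabled, , drop = FALSE],
         audit = df[!df$enabled, , drop = FALSE],
         source_path = normalizePath(path), version = file_version(path)),
    class = "context_rules"
  )
}

#' @export
print.context_rules <- function(x, ...) {
  cat(sprintf("<context_rules> %d enabled, %d disabled (version %s)\n",
              nrow(x$rules), nrow(x$audit), x$version))
  print(table(x$rules$dimension))
  invisible(x)
}

rules_df <- function(rules) {
  if (inherits(rules, "context_rules")) return(rules$rules)
  stopifnot(is.data.frame(rules))
  if (!"enabled" %in% names(rules)) rules$enabled <- TRUE
  rules[rules$enabled, , drop = FALSE]
}

# All occurrences of every rule trigger inside a sentence, note coordinates.
trigger_occurrences <- function(txt, sentence_start, r) {
  rule_idx <- integer(0); ts <- integer(0); te <- integer(0)
  for (i in seq_len(nrow(r))) {
    g <- gregexpr(r$compiled[i], txt, perl = TRUE)[[1L]]
    if (g[1L] == -1L) next
    ml <- attr(g, "match.length")
    rule_idx <- c(rule_idx, rep.int(i, length(g)))
    ts <- c(ts, sentence_start + as.integer(g) - 1L)
    te <- c(te, sentence_start + as.integer(g) + as.integer(ml) - 1L)
  }
  data.frame(rule_idx = rule_idx, start = ts, end = te)
}

#' Classify the assertion status of one mention
#'
#' Applies the trigger-and-scope algorithm within the mention's sentence.
#' Forward scope runs from the trigger's end to the sentence end, backward
#' from the sentence start to the trigger's start, both clipped at the
#' nearest termination term and at `max_scope_tokens` whitespace-delimited
#' tokens when finite.
#'
#' @param mention One mention (list or one-row data frame with note-relative
#'   `start`, `end`).
#' @param sentence The owning sentence (with `start`, `end`, `text`).
#' @param rules A [load_context_rules()] object (or plain rule data frame).
#' @return List with `negated`, `historical` (logicals), `experiencer`
#'   (`"patient"` or `"other"`), and `firing_rules` (sorted rule ids).
#' @export
classify_context <- function(mention, sentence, rules) {
  mention <- as.list(mention)
  sentence <- as.list(sentence)
  if (mention$start < sentence$start || mention$end > sentence$end) {
    abort_data("mention lies outside its sentence span")
  }
  r <- rules_df(rules)
  status <- list(negated = FALSE, historical = FALSE,
                 experiencer = "patient", firing_rules = character(0))
  if (nrow(r) == 0L) return(status)

  txt <- sentence$text
  occ <- trigger_occurrences(txt, sentence$start, r)
  if (nrow(occ) == 0L) return(status)

  is_term <- r$dimension[occ$rule_idx] == "termination"
  is_pseudo <- r$value[occ$rule_idx] == "none"
  term_occ <- occ[is_term, , drop = FALSE]
  pseudo_occ <- occ[is_pseudo, , drop = FALSE]
  real_occ <- occ[!is_term & !is_pseudo, , drop = FALSE]
  if (nrow(real_occ) == 0L) return(status)

  # token spans (note coordinates) for max_scope_tokens clipping
  tok <- gregexpr("\\S+", txt, perl = TRUE)[[1L]]
  tok_start <- sentence$start + as.integer(tok) - 1L
  tok_end <- tok_start + attr(tok, "match.length")

  ms <- mention$start; me <- mention$end
  fired <- character(0)

  for (k in seq_len(nrow(real_occ))) {
    i <- real_occ$rule_idx[k]
    os <- real_occ$start[k]; oe <- real_occ$end[k]
    # trigger inside/overlapping the mention never scopes it
    if (spans_overlap(os, oe, ms, me)) next
    # blocked by a pseudo-trigger of the same dimension
    if (nrow(pseudo_occ) > 0L) {
      same_dim <- r$dimension[pseudo_occ$rule_idx] == r$dimension[i]
      if (any(same_dim &
              spans_overlap(pseudo_occ$start, pseudo_occ$end, os, oe))) next
    }
    dir <- r$direction[i]
    w <- r$max_scope_tokens[i]
    covered <- FALSE

    if (dir %in% c("forward", "bidirectional")) {
      e0 <- sentence$end
      if (nrow(term_occ) > 0L) {
        after <- term_occ$start[term_occ$start >= oe]
        if (length(after) > 0L) e0 <- min(e0, min(after))
      }
      if (is.finite(w)) {
        sel <- which(tok_start >= oe)
        if (length(sel) > w) e0 <- min(e0, tok_end[sel[w]])
      }
      if (ms >= oe && me <= e0) covered <- TRUE
    }
    if (!covered && dir %in% c("backward", "bidirectional")) {
      s0 <- sentence$start
      if (nrow(term_occ) > 0L) {
        before <- term_occ$end[term_occ$end <= os]
        if (length(before) > 0L) s0 <- max(s0, max(before))
      }
      if (is.finite(w)) {
        sel <- which(tok_end <= os)
        if (length(sel) > w) s0 <- max(s0, tok_start[sel[length(sel) - w + 1L]])
      }
      if (ms >= s0 && me <= os) covered <- TRUE
    }
    if (!covered) next

    val <- r$value[i]
    if (val == "negated") status$negated <- TRUE
    if (val == "historical") status$historical <- TRUE
    if (val == "other_experiencer") status$experiencer <- "other"
    fired <- c(fired, r$rule_id[i])
  }
  status$firing_rules <- sort(unique(fired))
  status
}

#' Assert every mention of a corpus
#'
#' Joins each mention to its sentence and applies [classify_context()];
#' mention order is preserved.
#'
#' @param mentions [match_corpus()] output.
#' @param sentences [segment_corpus()] output covering every mention.
#' @param rules A [load_context_rules()] object.
#' @return `mentions` with added columns `negated`, `historical`,
#'   `experiencer`, `firing_rules` (comma-joined rule ids).
#' @export
assert_corpus <- function(mentions, sentences, rules) {
  out <- mentions
  out$negated <- logical(nrow(mentions))
  out$historical <- logical(nrow(mentions))
  out$experiencer <- rep("patient", nrow(mentions))
  out$firing_rules <- rep("", nrow(mentions))
  if (nrow(mentions) == 0L) return(out)

  key <- paste(sentences$note_id, sentences$index, sep = "\r")
  mkey <- paste(mentions$note_id, mentions$sentence_index, sep = "\r")
  idx <- match(mkey, key)
  if (anyNA(idx)) {
    bad <- mentions$note_id[is.na(idx)][1L]
    abort_data(paste0("missing sentence for a mention in note ", bad))
  }
  for (k in seq_len(nrow(mentions))) {
    st <- classify_context(mentions[k, ], sentences[idx[k], ], rules)
    out$negated[k] <- st$negated
    out$historical[k] <- st$historical
    out$experiencer[k] <- st$experiencer
    out$firing_rules[k] <- paste(st$firing_rules, collapse = ",")
  }
  out
}
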