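# Lexicon loading, validation, and pattern compilation.
#
# Patterns are written in a PCRE-compatible subset: literals, alternation,
# optional groups, character classes. Two conventions are layered on at
# compile time because clinical text is messy:
#   * a literal space matches one or more whitespace characters;
#   * compiled patterns are anchored at word boundaries on both ends.

#' The six housing concept categories
#'
#' Every lexicon entry and every mention carries exactly one of these labels.
#'
#' @return Character vector of the six concept names, in canonical order.
#' @export
#' @examples
#' housing_concepts()
housing_concepts <- function() {
  c("homeless", "unstable_housing", "recovery_housing",
    "emergency_housing", "temporary_housing", "exposure")
}

#' Paths to the shipped default lexicon and context-rule files
#'
#' @return Absolute path to the packaged TSV file.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "housing_lexicon.tsv", package = "housenlp",
              mustWork = TRUE)
}

#' @rdname default_lexicon_path
#' @export
default_context_rules_path <- function() {
  system.file("extdata", "context_rules.tsv", package = "housenlp",
              mustWork = TRUE)
}

# Escape a literal string for use inside a pattern. Spaces stay literal;
# compile_pattern() turns them into whitespace runs.
escape_literal <- function(x) {
  gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)
}

#' Compile a dialect pattern into a PCRE regular expression
#'
#' Dialect conventions: a literal space matches any whitespace run; an
#' optional group written with a preceding space (`"the (the)? street"`)
#' absorbs that space so the group can be dropped entirely; the whole
#' pattern is anchored at word boundaries unless `word_boundaries = FALSE`.
#'
#' @param pattern Pattern string in the dialect.
#' @param case_sensitive Match case exactly? Default `FALSE`.
#' @param word_boundaries Anchor at `\\b` on both ends? Default `TRUE`.
#' @param whole_string Anchor at `^...$` instead (used for round-trip
#'   validation and exact-membership tests).
#' @return A PCRE pattern string for use with `perl = TRUE` matching.
#' @export
#' @examples
#' grepl(compile_pattern("lack of (shelter|housing)"),
#'       "Pt has lack of housing.", perl = TRUE)
compile_pattern <- function(pattern, case_sensitive = FALSE,
                            word_boundaries = TRUE, whole_string = FALSE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  # " (x)?" -> "( x)?" so the optional group swallows its separator space
  pat <- gsub(" \\(([^()]*[^ ()])\\)\\?", "( \\1)?", pattern)
  pat <- gsub(" +", "\\\\s+", pat)
  core <- paste0("(?:", pat, ")")
  if (whole_string) {
    core <- paste0("^", core, "$")
  } else if (word_boundaries) {
    core <- paste0("\\b", core, "\\b")
  }
  if (!case_sensitive) core <- paste0("(?i)", core)
  core
}

# NULL if the compiled regex is usable, otherwise the compiler message.
compile_error <- function(regex) {
  tryCatch({
    regexpr(regex, "probe", perl = TRUE)
    NULL
  },
  error = function(e) conditionMessage(e),
  warning = function(w) conditionMessage(w))
}

#' Test whole-string acceptance of a dialect pattern
#'
#' Accepts a string only if the pattern matches it end to end (the
#' membership semantics used to verify [compress_phrases()] output).
#'
#' @param pattern Dialect pattern string.
#' @param strings Character vector of candidate strings.
#' @param case_sensitive Default `TRUE`: literal compression preserves case.
#' @return Logical vector, one element per candidate.
#' @export
pattern_accepts <- function(pattern, strings, case_sensitive = TRUE) {
  regex <- compile_pattern(pattern, case_sensitive = case_sensitive,
                           whole_string = TRUE)
  grepl(regex, strings, perl = TRUE)
}

common_prefix <- function(x) {
  if (length(x) == 1L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)
  k <- 0L
  repeat {
    if (any(lengths(chars) <= k)) break
    nxt <- vapply(chars, function(ch) ch[k + 1L], "")
    if (length(unique(nxt)) > 1L) break
    k <- k + 1L
  }
  substr(x[1L], 1L, k)
}

str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

common_suffix <- function(x) str_rev(common_prefix(str_rev(x)))

#' Compress literal phrases into one alternation pattern
#'
#' Factors a shared prefix and suffix out of the phrase list and joins the
#' remainders with alternation, e.g. `c("lack of housing", "lack of
#' shelter")` becomes `"lack of (housing|shelter)"`. The result accepts
#' exactly the input phrases under whole-string matching (see
#' [pattern_accepts()]).
#'
#' @param phrases Non-empty character vector of non-empty literal phrases.
#' @return A single dialect pattern string.
#' @export
#' @examples
#' compress_phrases(c("lack of housing", "lack of shelter"))
compress_phrases <- function(phrases) {
  phrases <- as.character(phrases)
  if (length(phrases) == 0L) {
    abort_data("compress_phrases: phrase list must be non-empty")
  }
  if (anyNA(phrases) || any(!nzchar(phrases))) {
    abort_data("compress_phrases: phrases must be non-empty literal strings")
  }
  phrases <- unique(phrases)
  if (length(phrases) == 1L) return(escape_literal(phrases))
  pre <- common_prefix(phrases)
  rest <- substring(phrases, nchar(pre) + 1L)
  suf <- common_suffix(rest)
  mid <- substring(rest, 1L, nchar(rest) - nchar(suf))
  paste0(escape_literal(pre), "(",
         paste(vapply(mid, escape_literal, "", USE.NAMES = FALSE),
               collapse = "|"),
         ")", escape_literal(suf))
}

read_lexicon_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = NULL, blank.lines.skip = TRUE,
                    fileEncoding = "UTF-8")
}

read_lexicon_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$entries)) doc$entries else doc
  rows <- lapply(entries, function(e) {
    data.frame(
      concept = as.character(e$concept %||% ""),
      pattern = as.character(e$pattern %||% ""),
      source_phrases = paste(unlist(e$source_phrases), collapse = "|"),
      case_sensitive = as.character(isTRUE(e$case_sensitive)),
      notes = as.character(e$notes %||% ""),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_version <- function(path) {
  head_lines <- readLines(path, n = 20L, warn = FALSE, encoding = "UTF-8")
  m <- regmatches(head_lines,
                  regexpr("^#\\s*version[:=]\\s*(\\S+)", head_lines, perl = TRUE))
  if (length(m) == 0L) return("unversioned")
  sub("^#\\s*version[:=]\\s*", "", m[1L])
}

#' Load and compile a housing lexicon
#'
#' Reads a TSV (columns `concept`, `pattern`, `source_phrases`
#' (`|`-separated), `case_sensitive`, `notes`; `#` lines are comments) or a
#' YAML file, validates every row, compiles each pattern, and verifies the
#' round-trip invariant that every source phrase is matched end-to-end by
#' its own pattern. Loading is deterministic: entries keep file order and
#' `entry_id` is the row number.
#'
#' @param path Lexicon file; defaults to the shipped housing lexicon.
#' @param dialect Pattern dialect identifier; only `"pcre"` is defined.
#' @param require_coverage If `TRUE`, fail unless every one of the six
#'   concept categories has at least one entry (the shipped lexicon must
#'   satisfy this; small task-specific lexicons need not).
#' @return An object of class `compiled_lexicon`: list with `entries`
#'   (data frame incl. compiled regexes), `version`, `source_path`,
#'   `dialect`.
#' @export
#' @examples
#' lex <- load_lexicon()
#' table(lex$entries$concept)
load_lexicon <- function(path = default_lexicon_path(), dialect = "pcre",
                         require_coverage = FALSE) {
  dialect <- match.arg(dialect, "pcre")
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_config(paste0("lexicon file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    read_lexicon_yaml(path)
  } else {
    read_lexicon_tsv(path)
  }
  required <- c("concept", "pattern", "source_phrases", "case_sensitive", "notes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort_config(paste0("lexicon file ", path, " lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  if (is.null(n) || n == 0L) abort_data("lexicon file has no entries")

  bad_concept <- which(!raw$concept %in% housing_concepts())
  if (length(bad_concept) > 0L) {
    abort_data(sprintf("lexicon row %d: unknown concept '%s'",
                       bad_concept[1L], raw$concept[bad_concept[1L]]))
  }
  cs <- parse_flag(raw$case_sensitive, "lexicon column case_sensitive")

  compiled <- character(n)
  for (i in seq_len(n)) {
    regex <- compile_pattern(raw$pattern[i], case_sensitive = cs[i])
    err <- compile_error(regex)
    if (!is.null(err)) {
      abort_data(sprintf("lexicon row %d ('%s'): pattern does not compile: %s",
                         i, raw$pattern[i], err))
    }
    compiled[i] <- regex
  }

  phrase_lists <- strsplit(raw$source_phrases, "|", fixed = TRUE)
  for (i in seq_len(n)) {
    phrases <- trimws(phrase_lists[[i]])
    if (length(phrases) == 0L || any(!nzchar(phrases))) {
      abort_data(sprintf("lexicon row %d: source_phrases must be non-empty", i))
    }
    full <- compile_pattern(raw$pattern[i], case_sensitive = cs[i],
                            whole_string = TRUE)
    hit <- grepl(full, phrases, perl = TRUE)
    if (!all(hit)) {
      abort_data(sprintf(
        "lexicon row %d: source phrase '%s' is not matched by its pattern '%s'",
        i, phrases[!hit][1L], raw$pattern[i]))
    }
    phrase_lists[[i]] <- phrases
  }

  entries <- data.frame(
    entry_id = seq_len(n),
    concept = raw$concept,
    pattern = raw$pattern,
    source_phrases = vapply(phrase_lists, paste, "", collapse = "|"),
    case_sensitive = cs,
    notes = raw$notes,
    compiled = compiled,
    stringsAsFactors = FALSE
  )

  if (require_coverage) {
    missing_cat <- setdiff(housing_concepts(), entries$concept)
    if (length(missing_cat) > 0L) {
      abort_data(paste0("lexicon lacks entries for concept(s): ",
                        paste(missing_cat, collapse = ", ")))
    }
  }

  structure(
    list(entries = entries, version = file_version(path),
         source_path = normalizePath(path), dialect = dialect),
    class = "compiled_lexicon"
  )
}

#' @export
print.compiled_lexicon <- function(x, ...) {
  cat(sprintf("<compiled_lexicon> %d entries, %d concepts (version %s)\n",
              nrow(x$entries), length(unique(x$entries$concept)), x$version))
  tab <- table(factor(x$entries$concept, levels = housing_concepts()))
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Probe an entry's pattern against candidate strings
#'
#' Reports, per probe, whether the entry's pattern fires anywhere inside the
#' probe under the usual matching conventions (word boundaries, whitespace
#' flexibility, case folding). Used to pin optional-token behavior of
#' flexible patterns in tests.
#'
#' @param entry A lexicon entry (a list or one-row data frame with
#'   `pattern` and optionally `case_sensitive`), or a bare pattern string.
#' @param probes Character vector of probe strings.
#' @return Data frame with columns `probe` and `matched`.
#' @export
#' @examples
#' validate_flexibility("living on the (the)? streets?",
#'                      c("living on the street", "living in the street"))
validate_flexibility <- function(entry, probes) {
  if (is.character(entry)) entry <- list(pattern = entry)
  regex <- compile_pattern(as.character(entry$pattern),
                           case_sensitive = isTRUE(entry$case_sensitive))
  err <- compile_error(regex)
  if (!is.null(err)) abort_data(paste0("entry pattern does not compile: ", err))
  data.frame(probe = as.character(probes),
             matched = grepl(regex, probes, perl = TRUE),
             stringsAsFactors = FALSE)
}
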