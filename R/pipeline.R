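# End-to-end orchestration and standard I/O. Outputs are standoff JSONL
# annotations (one object per asserted mention), a note-label CSV, and a
# concept-distribution CSV; a manifest records configuration, input hashes,
# and counts. (config, inputs) -> outputs is a pure function: no timestamps
# inside data files.

read_text_file <- function(path) {
  size <- file.info(path)$size
  x <- readChar(path, size, useBytes = TRUE)
  Encoding(x) <- "UTF-8"
  if (!all(validUTF8(x))) {
    abort_data(paste0("note file is not valid UTF-8: ", path))
  }
  x
}

#' Read a corpus of clinical notes
#'
#' Accepts a directory of `.txt` files (note_id = filename stem, notes in
#' lexicographic order) or a CSV with columns `note_id`, `text` (RFC-4180
#' quoting; embedded newlines preserved).
#'
#' @param input Directory or CSV path.
#' @return Data frame with `note_id`, `text`.
#' @export
read_notes <- function(input) {
  if (length(input) != 1L || !is.character(input)) {
    abort_config("input must be a single path")
  }
  if (dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.txt$", full.names = TRUE),
                  method = "radix")
    notes <- data.frame(
      note_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, read_text_file, "", USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  } else if (file.exists(input)) {
    df <- utils::read.csv(input, colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (!all(c("note_id", "text") %in% names(df))) {
      abort_config(paste0("note CSV must have columns note_id, text: ", input))
    }
    notes <- df[, c("note_id", "text")]
  } else {
    abort_config(paste0("input not found: ", input))
  }
  if (anyDuplicated(notes$note_id)) {
    abort_data(paste0("duplicate note_id: ",
                      paste(unique(notes$note_id[duplicated(notes$note_id)]),
                            collapse = ", ")))
  }
  notes
}

#' Annotate a corpus in memory
#'
#' Runs segmentation, concept matching, assertion classification, and
#' note-level labeling; this is the in-process core that [run_pipeline()]
#' wraps with file I/O.
#'
#' @param notes Data frame `note_id`, `text`.
#' @param lexicon A [load_lexicon()] result (default: shipped lexicon).
#' @param rules A [load_context_rules()] result (default: shipped rules).
#' @param historical_positive Do historical mentions count as positive
#'   hits? Default `TRUE`.
#' @return Object of class `annotated_corpus`: list with `notes`,
#'   `sentences`, `mentions` (asserted), `labels`.
#' @export
#' @examples
#' notes <- data.frame(note_id = "a", text = "Patient is homeless.")
#' annotate_corpus(notes)$labels
annotate_corpus <- function(notes, lexicon = load_lexicon(),
                            rules = load_context_rules(),
                            historical_positive = TRUE) {
  sentences <- segment_corpus(notes)
  mentions <- match_corpus(notes, lexicon, sentences)
  asserted <- assert_corpus(mentions, sentences, rules)
  labels <- classify_corpus(asserted, notes$note_id, historical_positive)
  structure(
    list(notes = notes, sentences = sentences, mentions = asserted,
         labels = labels, historical_positive = historical_positive),
    class = "annotated_corpus"
  )
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat(sprintf("<annotated_corpus> %d notes, %d mentions, %d positive notes\n",
              nrow(x$notes), nrow(x$mentions),
              sum(x$labels$label == "positive")))
  invisible(x)
}

check_span_fidelity <- function(ann) {
  m <- ann$mentions
  if (nrow(m) == 0L) return(invisible(TRUE))
  note_text <- ann$notes$text[match(m$note_id, ann$notes$note_id)]
  got <- substr(note_text, m$start + 1L, m$end)
  if (!identical(got, m$matched_text)) {
    abort_data("span fidelity violation: mention text does not equal note substring")
  }
  invisible(TRUE)
}

#' Write annotation outputs
#'
#' Writes `annotations.jsonl` (one JSON object per asserted mention with
#' 0-based half-open code-point offsets), `note_labels.csv`, and
#' `concept_distribution.csv`. Every mention span is re-validated against
#' the note text before writing.
#'
#' @param ann An [annotate_corpus()] result.
#' @param outdir Output directory (created if needed).
#' @param distribution_basis `"positive_hits"` or `"all_hits"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_annotations <- function(ann, outdir,
                              distribution_basis = c("positive_hits",
                                                     "all_hits")) {
  stopifnot(inherits(ann, "annotated_corpus"))
  distribution_basis <- match.arg(distribution_basis)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_config(paste0("cannot create output directory: ", outdir))
  }
  check_span_fidelity(ann)

  ann_path <- file.path(outdir, "annotations.jsonl")
  labels_path <- file.path(outdir, "note_labels.csv")
  dist_path <- file.path(outdir, "concept_distribution.csv")
  m <- ann$mentions
  lines <- vapply(seq_len(nrow(m)), function(k) {
    as.character(jsonlite::toJSON(list(
      note_id = m$note_id[k], sentence_index = m$sentence_index[k],
      concept = m$concept[k], matched_text = m$matched_text[k],
      start = m$start[k], end = m$end[k], entry_id = m$entry_id[k],
      negated = m$negated[k], historical = m$historical[k],
      experiencer = m$experiencer[k], firing_rules = m$firing_rules[k]
    ), auto_unbox = TRUE))
  }, "")
  writeLines(lines, ann_path)
  utils::write.csv(ann$labels, labels_path, row.names = FALSE)
  dist <- concept_distribution(m, basis = distribution_basis,
                               historical_positive = ann$historical_positive)
  utils::write.csv(dist, dist_path, row.names = FALSE)
  invisible(c(ann_path, labels_path, dist_path))
}

#' Run the full extraction pipeline over files
#'
#' load lexicon -> load rules -> read notes -> segment -> match -> assert
#' -> classify -> write outputs. Identical configuration and inputs yield
#' byte-identical outputs; partial outputs are removed on failure.
#'
#' @param input Notes directory or CSV (see [read_notes()]).
#' @param output_dir Where outputs and `manifest.json` are written.
#' @param lexicon_path,rules_path Lexicon / context-rule files; default to
#'   the shipped versions.
#' @param historical_positive See [annotate_corpus()].
#' @param distribution_basis See [write_annotations()].
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(input, output_dir,
                         lexicon_path = default_lexicon_path(),
                         rules_path = default_context_rules_path(),
                         historical_positive = TRUE,
                         distribution_basis = c("positive_hits", "all_hits"),
                         log_level = c("info", "quiet")) {
  distribution_basis <- match.arg(distribution_basis)
  log_level <- match.arg(log_level)
  say <- function(...) if (log_level == "info") message(...)

  lexicon <- load_lexicon(lexicon_path)
  rules <- load_context_rules(rules_path)
  notes <- read_notes(input)
  say(sprintf("loaded %d lexicon entries, %d context rules, %d notes",
              nrow(lexicon$entries), nrow(rules$rules), nrow(notes)))
  if (nrow(notes) == 0L) warning("no input notes found; writing empty outputs")

  ann <- annotate_corpus(notes, lexicon, rules, historical_positive)
  say(sprintf("%d sentences, %d mentions, %d positive notes",
              nrow(ann$sentences), nrow(ann$mentions),
              sum(ann$labels$label == "positive")))

  written <- character(0)
  manifest_path <- file.path(output_dir, "manifest.json")
  tryCatch({
    written <- write_annotations(ann, output_dir, distribution_basis)
    input_hashes <- if (dir.exists(input)) {
      f <- sort(list.files(input, pattern = "\\.txt$", full.names = TRUE),
                method = "radix")
      stats::setNames(as.list(tools::md5sum(f)), basename(f))
    } else {
      stats::setNames(as.list(tools::md5sum(input)), basename(input))
    }
    manifest <- list(
      package = "housenlp",
      package_version = as.character(utils::packageVersion("housenlp")),
      config = list(
        input = input, output_dir = output_dir,
        lexicon = lexicon$source_path, lexicon_version = lexicon$version,
        context_rules = rules$source_path, rules_version = rules$version,
        historical_positive = historical_positive,
        distribution_basis = distribution_basis
      ),
      inputs = list(n_notes = nrow(notes), md5 = input_hashes),
      counts = list(
        n_sentences = nrow(ann$sentences),
        n_mentions = nrow(ann$mentions),
        n_positive_hits = sum(positive_hit(ann$mentions,
                                           historical_positive)),
        n_positive_notes = sum(ann$labels$label == "positive")
      )
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say(sprintf("wrote outputs to %s", output_dir))
    invisible(manifest)
  }, error = function(e) {
    unlink(c(written, manifest_path))
    stop(e)
  })
}
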