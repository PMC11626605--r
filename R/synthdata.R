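# Template-based generator of labeled synthetic emergency-department
# discharge notes. Emulates a formulaic LLM-written test cohort: positive
# notes where the hypothetical patient has housing problems, negative notes
# with no housing concern, plus adversarial classes (family-member,
# third-party, resource-list mentions) that are designed to stress the
# assertion and classification rules. Class allocation is deterministic
# (largest-remainder apportionment); randomness, all driven by the spec
# seed, only picks templates and phrases.

#' Synthetic note classes
#'
#' `affirmed`: patient-context positive phrase (gold positive).
#' `negated`: phrase under a negation trigger. `absent`: no housing
#' language. `family_member`: phrase about a relative (experiencer other).
#' `third_party`: phrase about an unrelated person — a designed false
#' positive for rule-based methods. `resource_list`: housing phrase inside
#' a patient-education resource list — likewise adversarial. All classes
#' except `affirmed` are gold-negative.
#'
#' @return Character vector of class names in canonical order.
#' @export
synth_classes <- function() {
  c("affirmed", "negated", "absent", "family_member", "third_party",
    "resource_list")
}

largest_remainder <- function(n, props) {
  q <- n * props
  base <- floor(q + 1e-9)
  r <- n - sum(base)
  if (r > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(props))
    base[ord[seq_len(r)]] <- base[ord[seq_len(r)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# Deterministic balanced sequence holding counts[j] copies of each name:
# the k-th copy of item j gets key (k - 0.5) / counts[j] and the pooled
# occurrences are sorted by key, interleaving classes/concepts instead of
# emitting them in blocks.
interleave_counts <- function(counts) {
  items <- rep(names(counts), counts)
  group <- rep(seq_along(counts), counts)
  keys <- unlist(lapply(seq_along(counts), function(j) {
    if (counts[j] == 0L) return(numeric(0))
    (seq_len(counts[j]) - 0.5) / counts[j]
  }))
  items[order(keys, group)]
}

#' Specify a synthetic corpus
#'
#' @param n_notes Number of notes to generate.
#' @param class_mix Named proportions over [synth_classes()] (unnamed
#'   classes get 0); must sum to 1 within 1e-9. Default mirrors a formulaic
#'   positive/negative test cohort: 40% affirmed, 30% negated, 30% absent.
#' @param concept_mix Named proportions over [housing_concepts()]; default
#'   uniform. Applies to classes that inject a concept (the two adversarial
#'   classes always use the homeless concept).
#' @param seed Integer seed; the same spec yields a byte-identical corpus.
#' @param style `"formulaic"` (clean templated prose) or `"noisy"` (extra
#'   filler sentences and irregular spacing).
#' @param unrealistic_negations Include the implausible
#'   "no visible signs of ..." negation template (off by default; such
#'   phrasing does not occur in real notes).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_notes,
                           class_mix = c(affirmed = 0.4, negated = 0.3,
                                         absent = 0.3),
                           concept_mix = NULL,
                           seed = 42L,
                           style = c("formulaic", "noisy"),
                           unrealistic_negations = FALSE) {
  style <- match.arg(style)
  if (!is.numeric(n_notes) || length(n_notes) != 1L || n_notes < 1) {
    abort_data("n_notes must be a positive integer")
  }
  full_mix <- stats::setNames(numeric(length(synth_classes())), synth_classes())
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% synth_classes())) {
    abort_data(paste0("class_mix names must be among: ",
                      paste(synth_classes(), collapse = ", ")))
  }
  full_mix[names(class_mix)] <- class_mix
  if (any(full_mix < 0) || abs(sum(full_mix) - 1) > 1e-9) {
    abort_data("class_mix must be non-negative and sum to 1")
  }
  if (is.null(concept_mix)) {
    concept_mix <- stats::setNames(rep(1 / 6, 6), housing_concepts())
  }
  full_cmix <- stats::setNames(numeric(6), housing_concepts())
  if (is.null(names(concept_mix)) ||
      !all(names(concept_mix) %in% housing_concepts())) {
    abort_data(paste0("concept_mix names must be among: ",
                      paste(housing_concepts(), collapse = ", ")))
  }
  full_cmix[names(concept_mix)] <- concept_mix
  if (any(full_cmix < 0) || abs(sum(full_cmix) - 1) > 1e-9) {
    abort_data("concept_mix must be non-negative and sum to 1")
  }
  structure(
    list(n_notes = as.integer(n_notes), class_mix = full_mix,
         concept_mix = full_cmix, seed = as.integer(seed), style = style,
         unrealistic_negations = isTRUE(unrealistic_negations)),
    class = "generator_spec"
  )
}

# --- phrase banks: every phrase here must be hit by the shipped lexicon
#     with the recorded concept (asserted by the ledger-soundness tests) ---
synth_phrase_bank <- function() {
  list(
    homeless = c("homelessness", "lack of housing", "lack of shelter",
                 "living on the streets", "sleeping rough"),
    unstable_housing = c("housing instability", "housing insecurity",
                         "unstable housing", "couch surfing"),
    recovery_housing = c("recovery housing", "sober living",
                         "staying at a halfway house"),
    emergency_housing = c("emergency housing", "emergency shelter",
                          "staying in a homeless shelter"),
    temporary_housing = c("temporary housing", "transitional housing",
                          "living in a motel"),
    exposure = c("sleeping outside", "sleeping outdoors",
                 "exposure to the elements", "cold exposure")
  )
}

synth_pools <- function() {
  list(
    cc = c("chest pain", "shortness of breath", "headache",
           "abdominal pain", "ankle injury", "cough and congestion",
           "back pain", "dizziness"),
    hpi1 = c("The patient presented to the emergency department with {CC} beginning earlier today.",
             "The patient arrived with a chief concern of {CC} that started this morning.",
             "The patient was brought in for evaluation of {CC} of two days duration."),
    hpi2 = c("Symptoms were moderate in severity and intermittent.",
             "The patient rated the discomfort as mild to moderate.",
             "Associated symptoms were minimal."),
    exam = c("Vital signs stable.",
             "Vital signs within normal limits.",
             "Heart rate and blood pressure within normal limits."),
    exam2 = c("Physical examination was unremarkable.",
              "The remainder of the examination was benign."),
    course = c("The patient was monitored and symptoms improved with supportive care.",
               "Laboratory studies and imaging were unremarkable.",
               "The patient received symptomatic treatment with good effect."),
    dispo = c("Discharged in stable condition with return precautions.",
              "Discharged in improved condition.",
              "The patient was discharged with follow-up instructions."),
    edu = c("Return to the emergency department if symptoms worsen.",
            "Follow up with a primary care provider within one week.",
            "Medication instructions were reviewed with the patient."),
    noise = c("The patient was accompanied by a friend.",
              "The patient tolerated oral intake well.",
              "A work note was provided."),
    aff = c("The patient reports {PHRASE}.",
            "Social history is notable for {PHRASE}.",
            "The patient has been dealing with {PHRASE} for several months.",
            "Social work was consulted because the patient is experiencing {PHRASE}."),
    neg = c("The patient denies {PHRASE}.",
            "No {PHRASE} was reported during the visit.",
            "The patient is without {PHRASE}."),
    neg_unrealistic = "There were no visible signs of {PHRASE}.",
    fam = c("The patient's {REL} has been experiencing {PHRASE}.",
            "The patient reports that her {REL} is dealing with {PHRASE}.",
            "The patient's {REL} has a history of {PHRASE}."),
    rel = c("brother", "sister", "mother", "father")
  )
}

# third-party templates carry their own ledger phrase
synth_third_party_templates <- function() {
  data.frame(
    text = c("The patient came to the emergency department after finding a homeless person sleeping in her bathroom.",
             "A homeless man was found resting near the patient's vehicle and police were notified.",
             "The patient was startled by a homeless person sleeping in the stairwell of her building."),
    phrase = c("a homeless person sleeping in her bathroom",
               "A homeless man",
               "a homeless person"),
    stringsAsFactors = FALSE
  )
}

synth_resource_lines <- function() {
  c("Community resources available to all patients: Homeless Veterans Center, Riverside Food Pantry, Neighborhood Legal Aid.",
    "These listings are provided as general information at discharge.")
}

pick1 <- function(x) x[sample.int(length(x), 1L)]

fill_slots <- function(template, cc = NULL, phrase = NULL, rel = NULL) {
  out <- template
  if (!is.null(cc)) out <- gsub("{CC}", cc, out, fixed = TRUE)
  if (!is.null(phrase)) out <- gsub("{PHRASE}", phrase, out, fixed = TRUE)
  if (!is.null(rel)) out <- gsub("{REL}", rel, out, fixed = TRUE)
  out
}

build_synth_note <- function(note_id, class, concept, spec, pools, bank) {
  phrase <- NA_character_
  injection <- NULL

  if (class %in% c("affirmed", "negated", "family_member")) {
    phrase <- pick1(bank[[concept]])
  }
  if (class == "affirmed") {
    injection <- fill_slots(pick1(pools$aff), phrase = phrase)
  } else if (class == "negated") {
    tmpl <- if (spec$unrealistic_negations) {
      pick1(c(pools$neg, pools$neg_unrealistic))
    } else {
      pick1(pools$neg)
    }
    injection <- fill_slots(tmpl, phrase = phrase)
  } else if (class == "family_member") {
    injection <- fill_slots(pick1(pools$fam), phrase = phrase,
                            rel = pick1(pools$rel))
  } else if (class == "third_party") {
    tp <- synth_third_party_templates()
    i <- sample.int(nrow(tp), 1L)
    injection <- tp$text[i]
    phrase <- tp$phrase[i]
    concept <- "homeless"
  } else if (class == "resource_list") {
    phrase <- "Homeless Veterans Center"
    concept <- "homeless"
  }

  cc <- pick1(pools$cc)
  hpi <- c(fill_slots(pick1(pools$hpi1), cc = cc), pick1(pools$hpi2))
  if (spec$style == "noisy") hpi <- c(hpi, pick1(pools$noise))
  if (!is.null(injection)) hpi <- c(hpi, injection)

  edu_lines <- if (class == "resource_list") {
    synth_resource_lines()
  } else {
    pick1(pools$edu)
  }

  lines <- c("EMERGENCY DEPARTMENT DISCHARGE NOTE", "",
             paste0("Chief Complaint: ", cc),
             paste0("HPI: ", hpi[1L]), hpi[-1L],
             "",
             paste0("Physical Exam: ", pick1(pools$exam)),
             pick1(pools$exam2),
             "",
             paste0("ED Course: ", pick1(pools$course)),
             "",
             paste0("Disposition: ", pick1(pools$dispo)),
             "",
             "Patient Education:", edu_lines)
  if (spec$style == "noisy" && sample.int(2L, 1L) == 1L) {
    lines <- sub("emergency department", "emergency  department", lines,
                 fixed = TRUE)
  }
  text <- paste(lines, collapse = "\n")

  ledger <- NULL
  if (class != "absent") {
    sents <- segment_sentences(text, note_id)
    hit <- which(vapply(sents$text, function(s) grepl(phrase, s, fixed = TRUE),
                        TRUE))
    ledger <- data.frame(note_id = note_id, phrase = phrase,
                         concept = concept, class = class,
                         sentence_index = if (length(hit)) sents$index[hit[1L]] else NA_integer_,
                         stringsAsFactors = FALSE)
  }
  list(text = text, ledger = ledger)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a labeled synthetic ED-note corpus
#'
#' Builds `spec$n_notes` formulaic emergency-department discharge notes
#' (chief complaint, HPI, exam, course, disposition, patient-education
#' section). Class counts follow deterministic largest-remainder
#' apportionment of `class_mix`; concepts are apportioned the same way over
#' the concept-bearing notes. Each non-absent note records its injection in
#' a ledger; gold label is positive iff the note carries an affirmed-class
#' injection.
#'
#' @param spec A [generator_spec()].
#' @return Object of class `synth_corpus`: list with `notes` (data frame
#'   `note_id`, `text`), `gold` (`note_id`, `label`), `ledger` (`note_id`,
#'   `phrase`, `concept`, `class`, `sentence_index`), `assignment`
#'   (`note_id`, `class`, `concept`), and `spec`.
#' @export
#' @examples
#' corpus <- generate_corpus(generator_spec(6, seed = 1))
#' corpus$gold
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_notes
  class_counts <- largest_remainder(n, spec$class_mix)
  classes <- interleave_counts(class_counts)

  needs_concept <- !classes %in% "absent"
  m <- sum(needs_concept)
  concepts <- rep(NA_character_, n)
  if (m > 0L) {
    concept_counts <- largest_remainder(m, spec$concept_mix)
    concepts[needs_concept] <- interleave_counts(concept_counts)
  }

  ids <- sprintf("note_%04d", seq_len(n))
  pools <- synth_pools()
  bank <- synth_phrase_bank()

  with_seed(spec$seed, {
    texts <- character(n)
    ledgers <- vector("list", n)
    for (i in seq_len(n)) {
      built <- build_synth_note(ids[i], classes[i], concepts[i], spec,
                                pools, bank)
      texts[i] <- built$text
      ledgers[[i]] <- built$ledger
    }
    ledger <- do.call(rbind, c(ledgers[!vapply(ledgers, is.null, TRUE)],
                               list(data.frame(note_id = character(0),
                                               phrase = character(0),
                                               concept = character(0),
                                               class = character(0),
                                               sentence_index = integer(0),
                                               stringsAsFactors = FALSE))))
    rownames(ledger) <- NULL
    structure(
      list(
        notes = data.frame(note_id = ids, text = texts,
                           stringsAsFactors = FALSE),
        gold = data.frame(note_id = ids,
                          label = ifelse(classes == "affirmed",
                                         "positive", "negative"),
                          stringsAsFactors = FALSE),
        ledger = ledger,
        assignment = data.frame(note_id = ids, class = classes,
                                concept = concepts,
                                stringsAsFactors = FALSE),
        spec = spec
      ),
      class = "synth_corpus"
    )
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus> %d notes (seed %d, style %s)\n",
              nrow(x$notes), x$spec$seed, x$spec$style))
  print(table(x$assignment$class))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes one UTF-8 `.txt` file per note, `gold.csv`, `ledger.jsonl`, and a
#' `manifest.json` recording the generating spec (incl. seed) and an MD5
#' hash per file, so a recorded spec regenerates identical files.
#'
#' @param corpus A [generate_corpus()] result.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
corpus_to_files <- function(corpus, outdir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_config(paste0("cannot create output directory: ", outdir))
  }
  if (file.access(outdir, mode = 2L) != 0L) {
    abort_config(paste0("output directory is not writable: ", outdir))
  }
  note_files <- file.path(outdir, paste0(corpus$notes$note_id, ".txt"))
  for (i in seq_len(nrow(corpus$notes))) {
    con <- file(note_files[i], open = "wb")
    writeChar(enc2utf8(corpus$notes$text[i]), con, eos = NULL)
    close(con)
  }
  gold_path <- file.path(outdir, "gold.csv")
  utils::write.csv(corpus$gold, gold_path, row.names = FALSE)
  ledger_path <- file.path(outdir, "ledger.jsonl")
  writeLines(vapply(seq_len(nrow(corpus$ledger)), function(i) {
    as.character(jsonlite::toJSON(as.list(corpus$ledger[i, ]),
                                  auto_unbox = TRUE))
  }, ""), ledger_path)

  files <- c(note_files, gold_path, ledger_path)
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(files)
  manifest <- list(
    spec = unclass(corpus$spec),
    n_notes = nrow(corpus$notes),
    files = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
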