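assert_one <- function(text, rules = shipped_rules(),
                       lexicon = shipped_lexicon()) {
  notes <- data.frame(note_id = "t", text = text)
  sentences <- segment_corpus(notes)
  mentions <- match_corpus(notes, lexicon, sentences)
  assert_corpus(mentions, sentences, rules)
}

test_that("shipped rule file keeps pruned test-result triggers disabled but auditable", {
  rls <- load_context_rules()
  expect_false("did_not_demonstrate" %in% rls$rules$rule_id)
  expect_true("did_not_demonstrate" %in% rls$audit$rule_id)
  expect_true(all(!rls$audit$enabled))
  expect_true(all(rls$rules$enabled))
})

test_that("a minimal two-rule file loads and duplicate rule ids are fatal", {
  path <- make_rules_file(c(
    rule_row("r_denies", "denies", "negation", "negated", "forward"),
    rule_row("r_hist", "history of", "temporality", "historical", "forward")
  ))
  rls <- load_context_rules(path)
  expect_equal(nrow(rls$rules), 2L)

  dup <- make_rules_file(c(
    rule_row("same", "no", "negation", "negated", "forward"),
    rule_row("same", "not", "negation", "negated", "forward")
  ))
  expect_error(load_context_rules(dup), "duplicate rule_id",
               class = "housenlp_data_error")

  bad <- make_rules_file(rule_row("broken", "no (evidence", "negation",
                                  "negated", "forward"))
  expect_error(load_context_rules(bad), "broken.*does not compile")

  mismatch <- make_rules_file(rule_row("m", "no", "negation", "historical",
                                       "forward"))
  expect_error(load_context_rules(mismatch), "inconsistent with dimension")
})

test_that("the documented negation-scope limitation is reproduced verbatim", {
  a <- assert_one(paste("Patient is not safe candidate for home IV abx",
                        "therapy given active IVDA and homelessness"))
  expect_equal(nrow(a), 1L)
  expect_identical(a$matched_text, "homelessness")
  expect_true(a$negated)
})

test_that("a plain affirmation gets the default status", {
  a <- assert_one("Patient is homeless")
  expect_false(a$negated)
  expect_false(a$historical)
  expect_identical(a$experiencer, "patient")
  expect_identical(a$firing_rules, "")
})

test_that("termination terms clip forward scope; experiencer triggers fire", {
  a <- assert_one("Patient denies being homeless but her brother is homeless")
  expect_equal(nrow(a), 2L)
  expect_true(a$negated[1])
  expect_false(a$negated[2])
  expect_identical(a$experiencer[2], "other")
})

test_that("temporality, backward negation, and pseudo-trigger blocking work", {
  h <- assert_one("Patient has a history of homelessness.")
  expect_true(h$historical)
  expect_false(h$negated)

  b <- assert_one("Housing instability was ruled out.")
  expect_true(b$negated)

  p <- assert_one("No change in housing instability since last visit.")
  expect_false(p$negated)
})

test_that("a negation trigger inside the mention itself does not self-negate", {
  a <- assert_one("Patient has no fixed address.")
  expect_equal(nrow(a), 1L)
  expect_identical(a$matched_text, "no fixed address")
  expect_false(a$negated)
})

test_that("scope never crosses the sentence boundary", {
  a <- assert_one("Patient denies chest pain.\nHomelessness was documented.")
  expect_equal(nrow(a), 1L)
  expect_false(a$negated)
})

test_that("max_scope_tokens bounds the trigger window", {
  rules2 <- load_context_rules(make_rules_file(
    rule_row("neg_short", "denies", "negation", "negated", "forward",
             max_scope_tokens = "2")
  ))
  near <- assert_one("Patient denies any homelessness today", rules = rules2)
  expect_true(near$negated)
  far <- assert_one("Patient denies chest pain and also reports homelessness",
                    rules = rules2)
  expect_false(far$negated)
})

test_that("with every rule disabled all statuses are the default", {
  off <- load_context_rules(make_rules_file(c(
    rule_row("neg_no", "no", "negation", "negated", "forward", enabled = "false"),
    rule_row("neg_denies", "denies", "negation", "negated", "forward",
             enabled = "false")
  )))
  a <- assert_one("Patient denies homelessness and reports no housing issues",
                  rules = off)
  expect_true(all(!a$negated))
  expect_true(all(!a$historical))
  expect_true(all(a$experiencer == "patient"))
})

test_that("assertion is deterministic and independent of rule order", {
  texts <- c("Patient denies being homeless but her brother is homeless",
             "No evidence of housing instability.",
             "The patient's sister has a history of couch surfing.",
             "Patient is homeless. Denies chest pain.")
  notes <- data.frame(note_id = paste0("o", seq_along(texts)), text = texts)
  sentences <- segment_corpus(notes)
  mentions <- match_corpus(notes, shipped_lexicon(), sentences)

  base <- assert_corpus(mentions, sentences, shipped_rules())
  shuffled <- shipped_rules()
  set.seed(405)
  shuffled$rules <- shuffled$rules[sample.int(nrow(shuffled$rules)), ]
  again <- assert_corpus(mentions, sentences, shuffled)
  cols <- c("negated", "historical", "experiencer")
  expect_identical(base[, cols], again[, cols])
  expect_identical(base, assert_corpus(mentions, sentences, shipped_rules()))
})

test_that("assert_corpus matches per-mention classification and validates inputs", {
  notes <- data.frame(note_id = "pc", text = "Patient denies homelessness.")
  sentences <- segment_corpus(notes)
  mentions <- match_corpus(notes, shipped_lexicon(), sentences)
  corpus_status <- assert_corpus(mentions, sentences, shipped_rules())
  solo <- classify_context(mentions[1, ], sentences[1, ], shipped_rules())
  expect_identical(corpus_status$negated[1], solo$negated)
  expect_identical(corpus_status$firing_rules[1],
                   paste(solo$firing_rules, collapse = ","))

  expect_equal(nrow(assert_corpus(mentions[0, ], sentences, shipped_rules())), 0L)
  expect_error(assert_corpus(mentions, sentences[0, ], shipped_rules()),
               "missing sentence")
  bad_mention <- mentions[1, ]
  bad_mention$start <- 1000L
  bad_mention$end <- 1010L
  expect_error(classify_context(bad_mention, sentences[1, ], shipped_rules()),
               "outside its sentence")
})
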