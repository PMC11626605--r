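test_that("shipped lexicon loads, covers all six concepts, and is deterministic", {
  lex <- load_lexicon(require_coverage = TRUE)
  expect_s3_class(lex, "compiled_lexicon")
  expect_setequal(unique(lex$entries$concept), housing_concepts())
  expect_identical(lex$entries$entry_id, seq_len(nrow(lex$entries)))

  again <- load_lexicon(require_coverage = TRUE)
  expect_identical(lex$entries, again$entries)
})

test_that("round-trip validation passes for every shipped source phrase", {
  # load_lexicon() already enforces this fatally; re-check explicitly so a
  # regression reports the offending phrase
  lex <- shipped_lexicon()
  for (i in seq_len(nrow(lex$entries))) {
    phrases <- strsplit(lex$entries$source_phrases[i], "|", fixed = TRUE)[[1]]
    full <- compile_pattern(lex$entries$pattern[i],
                            case_sensitive = lex$entries$case_sensitive[i],
                            whole_string = TRUE)
    expect_true(all(grepl(full, phrases, perl = TRUE)),
                info = lex$entries$pattern[i])
  }
})

test_that("compressed phrase alternation accepts exactly the input phrases", {
  pat <- compress_phrases(c("lack of housing", "lack of shelter"))
  expect_true(all(pattern_accepts(pat, c("lack of housing", "lack of shelter"))))
  expect_false(any(pattern_accepts(pat, c("lack of food", "lack of",
                                          "lack of sheltering",
                                          "a lack of housing"))))
  # behaviorally equivalent to the hand-written alternation
  probes <- c("lack of housing", "lack of shelter", "lack of shelters",
              "lackof housing", "lack  of housing", "LACK OF HOUSING")
  expect_identical(pattern_accepts(pat, probes),
                   pattern_accepts("lack of (shelter|housing)", probes))
})

test_that("singleton compression is equivalent to the literal", {
  pat <- compress_phrases("homeless")
  expect_true(pattern_accepts(pat, "homeless"))
  expect_false(any(pattern_accepts(pat, c("homelessness", "home less", ""))))
})

test_that("compression is sound against a brute-force membership oracle", {
  members <- c("sleeping outside", "sleeping outdoors")
  pat <- compress_phrases(members)
  set.seed(401)
  alphabet <- c(letters, " ")
  perturb <- function(s) {
    ch <- strsplit(s, "")[[1]]
    op <- sample(c("sub", "del", "ins"), 1L)
    i <- sample(length(ch), 1L)
    if (op == "sub") ch[i] <- sample(alphabet, 1L)
    if (op == "del") ch <- ch[-i]
    if (op == "ins") ch <- append(ch, sample(alphabet, 1L), after = i)
    paste(ch, collapse = "")
  }
  probes <- c(members, vapply(1:20, function(i) perturb(sample(members, 1L)), ""))
  expect_identical(pattern_accepts(pat, probes), probes %in% members)
})

test_that("compression of several phrase families round-trips", {
  cases <- list(
    c("recovery housing", "recovery residence", "recovery home"),
    c("housing instability", "housing insecurity"),
    c("ab", "b"),
    c("unhoused")
  )
  for (members in cases) {
    pat <- compress_phrases(members)
    expect_true(all(pattern_accepts(pat, members)), info = pat)
  }
  expect_error(compress_phrases(character(0)), "non-empty")
  expect_error(compress_phrases(c("ok", "")), "non-empty")
})

test_that("flexible pattern matches optional article and plural forms", {
  res <- validate_flexibility("living on the (the)? streets?",
                              c("living on the streets",
                                "living on the street",
                                "living on the the street",
                                "living in the street"))
  expect_identical(res$matched, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("misspelling and stem variants are covered by the shipped homeless entry", {
  res <- validate_flexibility("homeless(ness|s)?",
                              c("homeless", "homelessness", "homelesss",
                                "homelessnesss", "home"))
  expect_identical(res$matched, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("matching is case-insensitive by default and case-sensitive on request", {
  path <- make_lexicon_file(c(
    lex_row("homeless", "homeless", "homeless"),
    lex_row("exposure", "COLD exposure", "COLD exposure", case_sensitive = "true")
  ))
  lex <- load_lexicon(path)
  expect_true(validate_flexibility(as.list(lex$entries[1, ]), "HOMELESS")$matched)
  expect_false(validate_flexibility(as.list(lex$entries[2, ]), "cold exposure")$matched)
  expect_true(validate_flexibility(as.list(lex$entries[2, ]), "COLD exposure")$matched)
})

test_that("load errors name the offending row", {
  bad_concept <- make_lexicon_file(lex_row("housing_problem", "x", "x"))
  expect_error(load_lexicon(bad_concept), "row 1.*unknown concept")

  bad_pattern <- make_lexicon_file(lex_row("homeless", "lack of (shelter|housing", "lack of shelter"))
  expect_error(load_lexicon(bad_pattern), "row 1.*does not compile")

  bad_phrase <- make_lexicon_file(lex_row("homeless", "homeless", "unhoused"))
  expect_error(load_lexicon(bad_phrase), "not matched by its pattern")

  expect_error(load_lexicon(tempfile()), "not found",
               class = "housenlp_config_error")
})

test_that("a yaml lexicon loads to the same entries as its tsv twin", {
  ypath <- tempfile(fileext = ".yaml")
  writeLines(c(
    "entries:",
    "  - concept: homeless",
    "    pattern: lack of (shelter|housing)",
    "    source_phrases: [lack of shelter, lack of housing]",
    "  - concept: exposure",
    "    pattern: sleeping outside",
    "    source_phrases: [sleeping outside]"
  ), ypath)
  tpath <- make_lexicon_file(c(
    lex_row("homeless", "lack of (shelter|housing)",
            c("lack of shelter", "lack of housing")),
    lex_row("exposure", "sleeping outside", "sleeping outside")
  ))
  ylex <- load_lexicon(ypath)
  tlex <- load_lexicon(tpath)
  cols <- c("concept", "pattern", "source_phrases", "case_sensitive", "compiled")
  expect_identical(ylex$entries[, cols], tlex$entries[, cols])
})
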