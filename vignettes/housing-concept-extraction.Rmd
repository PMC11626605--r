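---
title: "Extracting housing instability concepts from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting housing instability concepts from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(housenlp)
```

## The problem

Housing instability — from precarious housing up to literal homelessness —
is strongly linked to mortality, readmission, and reliance on emergency
care, yet it is systematically underdocumented in structured EHR fields.
Diagnosis codes capture only part of the affected population; the rest is
visible only in free text. `housenlp` is a rule-based engine for finding
housing concepts in clinical notes and classifying each note as positive
or negative for housing issues, built so that every step is deterministic,
auditable, and editable by a non-programmer (the lexicon and trigger rules
are plain TSV files).

Rule-based extraction is the right tool here for the same reasons it
remains standard for negation handling in clinical NLP: the target
vocabulary is small and stable, errors must be explainable, and the
pipeline must run inside the firewall on modest hardware with no model
weights or network access.

## The pipeline and its assumptions

### Lexicon

Six concept categories cover the clinically useful spectrum: `homeless`,
`unstable_housing`, `recovery_housing`, `emergency_housing`,
`temporary_housing`, and `exposure`. Each lexicon row maps a concept to a
pattern in a small PCRE-compatible dialect (literals, alternation,
optional groups). Three conventions are applied at compile time:

* **Whitespace flexibility** — a literal space matches one or more
  whitespace characters; clinical text has irregular spacing.
* **Word-boundary anchoring** — every pattern is anchored at `\b` on both
  ends, so `homeless` never fires inside an unrelated longer token.
  Morphological variants are therefore encoded in-pattern: the stem entry
  is `homeless(ness|s)?`, which also covers the common trailing-s
  misspelling observed in real notes.
* **Case-insensitive by default** — notes mix `Homeless`, `HOMELESS`, and
  `homeless`; an entry can opt into case sensitivity.

Phrase lists are compressed into alternations by factoring shared
prefixes/suffixes (`compress_phrases()`), and every row carries its
`source_phrases` so the loader can verify, fatally, that each phrase
round-trips through its own compiled pattern. This round-trip check is
what keeps a hand-edited lexicon honest.

```{r}
compress_phrases(c("lack of housing", "lack of shelter"))
validate_flexibility("living on the (the)? streets?",
                     c("living on the street", "living in the street"))
```

### Sentence segmentation

Assertion scope is sentence-bounded, so segmentation offsets must be
exact. The splitter is rule-based: terminators (`.`, `!`, `?` followed by
whitespace), every line break, and section headers (`Plan:` at line
start) end a sentence; periods after common clinical abbreviations
(`Dr.`, `pt.`, `b.i.d.`) and inside decimals are protected. Offsets are
0-based, half-open, counted in code points, and the invariant *sentence
text equals the note substring at its span* is asserted throughout the
test suite. Sentence-local matching and assertion follow directly: a
negation in one sentence can never scope a mention in the next, which is
the failure mode that motivates sentence windowing in the first place.

### Matching

All lexicon patterns are run against each sentence; overlapping candidate
matches are resolved **leftmost-longest**, ties at the same span broken by
lexicon file order, and a span yields exactly one mention (so concept
distributions never double-count). This is the conventional
dictionary-matching rule and, unlike "all matches", it keeps
`staying in a homeless shelter` a single `emergency_housing` hit instead
of an additional spurious `homeless` hit.

The matcher is cross-checked in the tests against an independent naive
literal-scan oracle (case-folded fixed-string search with word-boundary
checks) on 1,000 random sentences.

### Assertion (ConText-style)

Three dimensions are assigned per mention: `negated`, `historical`, and
`experiencer` (patient vs. other). Triggers are plain rows in
`context_rules.tsv`; each has a direction (`forward`, `backward`,
`bidirectional`), an optional token-count scope bound (default: unbounded
within the sentence), and an enabled flag. Termination terms (`but`,
`however`, `except`) clip scopes early; pseudo-triggers (`no change`,
`not only`) block the real triggers they overlap; and a trigger occurrence
overlapping the mention itself is ignored — otherwise the lexicon phrase
`no fixed address` would negate itself.

Two design choices deserve justification:

* **Pruned test-result triggers.** Negation phrases of the
  "did not demonstrate" family are shipped *disabled* (kept in an audit
  list): housing issues are not findings a patient tests positive or
  negative for, and such triggers wrongly negate genuine mentions. Note
  that the bare trigger `not` remains enabled, which deliberately
  preserves a documented failure mode of sentence-scoped assertion:

```{r}
ann <- annotate_corpus(data.frame(
  note_id = "iv",
  text = "Patient is not safe candidate for home IV abx therapy given active IVDA and homelessness"))
ann$mentions[, c("matched_text", "negated", "firing_rules")]
```

  The clinician negated "safe candidate", not the housing status; a
  trigger-and-scope algorithm cannot know that. This false negative is
  part of the method's specification, reproduced as a golden test, and
  bucketed as `negation_scope_fn` by the error taxonomy.

* **Historical mentions count as positive hits by default.** Positivity
  is defined through negation and experiencer only; a history of
  homelessness remains clinically relevant for cohort discovery. The
  `historical_positive = FALSE` flag flips this for use cases that need
  strictly current status. Temporality across notes is out of scope.

Family-member mentions are handled by the experiencer dimension
(`brother`, `mother`, `family member`, … as forward triggers): the
mention is kept but marked `experiencer = "other"` and is not a positive
hit. Third-party mentions with no lexical marker of the experiencer
("a homeless person sleeping in her bathroom") are *not* fixable by
trigger rules; they remain designed false positives.

### Note classification

A note is positive iff at least one mention is a positive hit (not
negated, experiencer patient). Zero mentions, or all mentions
negated/other-experiencer, give a negative. Concept distributions are
reported over positive hits by default (`basis = "all_hits"` available):
affirmed, patient-experienced concepts are what cohort interpretation
rests on.

### Evaluation

`evaluate_notes()` computes the note-level confusion matrix;
`evaluate_hits()` aligns predicted to gold mentions by note, ≥1-character
span overlap, and concept agreement — overlap rather than exact-span
because offset conventions differ across annotation tools, and the choice
is pinned in tests. When several predictions align to one gold mention,
the leftmost scores and the rest are ignored rather than penalized.
Undefined ratios are reported as `NA` and rendered `N/A`, never `0`: in a
precision-only review setting (extracted hits reviewed for correctness,
no exhaustive gold), recall is simply unknowable.

## The synthetic-data generator

`generate_corpus()` emulates a formulaic, LLM-style test cohort of
emergency-department discharge notes: templated chief complaint, HPI,
exam, course, disposition, and patient-education sections, with one
housing injection per non-absent note. Six classes drive the injection:

| class | injection | gold label | pipeline outcome (formulaic) |
|---|---|---|---|
| `affirmed` | positive phrase in patient context | positive | positive |
| `negated` | phrase under a negation trigger | negative | negative |
| `absent` | no housing language | negative | negative |
| `family_member` | phrase about a relative | negative | negative |
| `third_party` | phrase about an unrelated person | negative | **false positive** |
| `resource_list` | phrase inside an education resource list | negative | **false positive** |

The last two classes are adversarial by design and the ledger marks them
as such; they reproduce the two canonical real-world error families
(generic community-resource lists naming e.g. a "Homeless Veterans
Center", and notes describing an unhoused person who is not the patient).

Defaults were chosen once as the benchmark study conditions: 200 notes,
`affirmed = 0.4, negated = 0.3, absent = 0.3` (a formulaic
positive/negative test cohort; the adversarial classes are opt-in),
uniform concept mix, seed 42. Class and concept allocation use
largest-remainder apportionment and a balanced deterministic
interleaving, so class counts are exact and concepts are uncorrelated
with classes; the seed only selects templates and phrases. The same spec
is therefore byte-identical across runs and platforms, which the tests
assert via file hashes.

The implausible negation "no visible signs of homelessness" — the kind of
phrasing a generative model produces but a clinician would not write — is
available behind `unrealistic_negations = TRUE` and excluded by default.

**What passing the benchmark does and does not show.** On formulaic
templated notes the shipped lexicon and rules are exhaustive by
construction, so note-level precision and recall are 1.0 (the
`scripts/acceptance.R` run recomputes this end to end). That validates
the plumbing — segmentation, offsets, scoping, labeling — not real-world
accuracy: real notes carry vocabulary drift, typos beyond the encoded
misspellings, copy-forward artifacts, and the third-party/resource-list
traps above, all of which degrade performance in ways synthetic templates
cannot measure.

## Numerical and degenerate-input choices

* Offsets: 0-based, half-open, code points; every output record is
  re-validated against the note text before writing (span-fidelity gate).
* Empty note → zero sentences; zero mentions → negative label; empty
  input directory → empty outputs with a warning, exit code 0.
* Scope token counting uses whitespace-delimited tokens; `max_scope_tokens`
  empty means unbounded within the sentence.
* Proportions must sum to 1 within 1e-9; class counts come from
  largest-remainder apportionment with ties broken by canonical class
  order.
* Problem sizes used by the test suite — 200-note benchmark corpus,
  1,000 oracle sentences, 100 random segmentation texts — keep the whole
  suite in the tens of seconds on a single CPU while exercising every
  invariant.

## Known limitations

* The lexicon is finite and English-only; phrasing of housing status
  drifts over time and across sites. The TSV format is the extension
  point.
* Assertion is trigger-and-scope; it cannot resolve *what* is being
  negated (the IV-abx example) nor experiencers without a lexical marker
  (the bathroom example). Both behaviors are frozen in golden tests as
  documented limitations.
* No cross-note temporality, no detection of explicitly *stable* housing,
  no statistical or embedding-based term expansion, no patient-level
  rollup in the core metrics (note-level is primary).
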