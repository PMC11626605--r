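# housenlp

Rule-based extraction of housing instability concepts from clinical notes.

Housing is a social determinant of health that is chronically underreported
in structured EHR data: billing codes alone miss a large share of patients
experiencing housing instability or homelessness, and much of the signal
lives only in free-text notes. `housenlp` is a small, fully deterministic
NLP engine for surfacing that signal. It identifies six housing concepts —
`homeless`, `unstable_housing`, `recovery_housing`, `emergency_housing`,
`temporary_housing`, `exposure` — in unstructured notes and rolls them up
to note-level positive/negative labels suitable for cohort discovery and
phenotyping.

The pipeline is the classic dictionary-plus-assertion design used by
clinical IE systems:

1. **Lexicon** — an editable TSV maps each concept to flexible,
   word-boundary-anchored patterns. Literal phrase lists are compressed to
   alternations (`lack of housing` + `lack of shelter` →
   `lack of (shelter|housing)`), optional tokens make matching tolerant
   (`living on the (the)? streets?`), and known misspellings
   (`homelesss`) are covered explicitly.
2. **Sentence segmentation** — deterministic rule-based splitting with
   exact 0-based half-open character offsets; assertion scope is strictly
   sentence-bounded because cross-sentence negation windows are a known
   source of spurious negations.
3. **Matching** — all lexicon hits per sentence; overlaps resolved
   leftmost-longest, one concept per span.
4. **Assertion (ConText-style)** — trigger terms assign each mention a
   negation flag, a historical flag, and an experiencer
   (patient vs. other). Scopes run forward/backward from the trigger to
   the sentence boundary, clipped by termination terms (`but`,
   `however`) and blocked by pseudo-triggers (`no change`). Test-result
   negation triggers such as `did not demonstrate` are shipped disabled:
   housing is not something a patient tests positive or negative for.
5. **Classification** — a note is **positive** iff any mention is a
   positive hit (not negated, experiencer = patient); otherwise negative.
6. **Evaluation** — note-level and hit-level confusion matrices with
   precision/recall/F1 (undefined ratios reported as `N/A`, never 0) and
   an error taxonomy (resource-list, third-party, family-member false
   positives; negation-scope false negatives).
7. **Synthetic data** — a template-based generator of labeled,
   PHI-free emergency-department discharge notes (affirmed / negated /
   absent plus adversarial family-member, third-party, and resource-list
   classes) so the whole pipeline can be benchmarked with zero data
   downloads.

## Worked example

```r
library(housenlp)

note <- data.frame(
  note_id = "ed_001",
  text = paste("Patient is not safe candidate for home IV abx therapy",
               "given active IVDA and homelessness.",
               "Her brother is staying in a homeless shelter.")
)
ann <- annotate_corpus(note)
ann$mentions[, c("matched_text", "concept", "start", "end",
                 "negated", "experiencer")]
#>       matched_text           concept start end negated experiencer
#> 1     homelessness          homeless    76  88    TRUE     patient
#> 2 homeless shelter emergency_housing   118 134   FALSE       other

ann$labels
#>   note_id    label n_mentions n_positive_hits
#> 1  ed_001 negative          2               0
```

Both mentions are found with exact offsets, but neither is a positive hit:
`homelessness` falls in the forward scope of the negation trigger `not`
(a documented limitation of sentence-scoped assertion — the clinician
negated "safe candidate", not the housing status), and the shelter mention
belongs to the patient's brother (experiencer = other), so the note is
labeled negative.

Benchmarking the full pipeline on the synthetic corpus:

```r
corpus <- generate_corpus(generator_spec(200, seed = 42))
ann <- annotate_corpus(corpus$notes)
evaluate_notes(ann$labels[, c("note_id", "label")], corpus$gold)
#> Evaluation level: note
#> TP: 80  FP: 0  TN: 120  FN: 0
#> Precision: 1
#> Recall: 1
#> F1: 1
```

On formulaic templated notes the rules are exhaustive, so performance is
perfect; the adversarial generator classes (`third_party`,
`resource_list`) exist precisely to break this — see the vignette.

## Command line

A thin CLI ships in `inst/exec/housenlp`:

```sh
housenlp extract  --in notes_dir --out results_dir
housenlp evaluate --pred results_dir/note_labels.csv --gold gold.csv
housenlp synth    --n 200 --seed 42 --out synth_dir
```

Outputs are standoff JSONL annotations (one object per asserted mention),
a note-label CSV, a concept-distribution CSV, and a run manifest.

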