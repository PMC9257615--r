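---
title: "Identifying disease categories in medical crowdfunding text"
author: "crowddx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying disease categories in medical crowdfunding text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Medical crowdfunding campaigns describe illness in unstructured lay text:
misspelled diagnoses ("brain aneruism", "myeloid lukemia"), informal
synonyms ("heart attack" rather than "myocardial infarction"), and
campaigns that never state a diagnosis at all but mention a treatment
that implies one ("having to start dialysis"). Researchers who want to
ask questions about specific conditions — how much is raised for cancer
versus injuries, how often categories co-occur — need those free texts
turned into structured, per-campaign disease labels.

crowddx implements a disease identification pipeline for this setting.
Each campaign is summarized as present/absent over eleven **mutually
inclusive** disease categories (cardiovascular, endocrine,
gastrointestinal, genitourinary, infections, injuries and external
causes, mental health, musculoskeletal, neoplasms, nervous system,
respiratory); a campaign mentioning both a tumor and a heart condition
carries both labels. Anything outside the eleven (pregnancy, eye/ear,
blood/immune, symptom and encounter codes, ...) maps to `OTHER` and is
dropped from the final summary.

## The pipeline

Two paths feed each campaign's label set:

1. **NER path.** A spell-tolerant dictionary detector finds candidate
   diagnosis mentions ([`detect_mentions()`]); each mention is linked to
   its best-matching ICD-10-CM code by character-trigram similarity
   ([`resolve_mentions()`]); codes that lack an exact match in the
   grouping lexicon are aligned by iterative prefix trimming
   ([`recode()`]); each code's disease category comes from a CCSR-style
   grouping scheme.
2. **Keyword path.** A word search over treatment/procedure terms
   ([`apply_keyword_rules()`]) flags categories implied without any
   stated diagnosis.

`identify_diseases()` merges the two paths, records per-category
provenance (`ner`, `keyword`, or `both`), and
`contribution_breakdown()` / `cooccurrence_matrix()` summarize how much
each path contributes corpus-wide.

The original production systems behind this design used pretrained
clinical NER and embedding-based entity-resolution models. Those are
proprietary and not reproducible at desk scale, so both stages here are
deliberately simple, fully specified, and **pluggable**: the detector is
fuzzy dictionary matching over an explicit term index, and the resolver
is trigram-cosine scoring. Users with access to learned models can
substitute either stage; every downstream contract (mention table in,
ranked code table out) is unchanged.

## The mention detector

`build_term_index()` extracts matchable terms from the lexicon: each
normalized description, any synonyms, and every contiguous token
subsequence of a description that is at least 4 characters, does not
start or end with a connective ("of", "with", ...), and is not a bare
generic qualifier (`generic_terms()`: "unspecified", "right",
"disease", ...). Sub-phrases matter because lay text rarely quotes a
full ICD description; generic-qualifier filtering keeps "right" or
"chronic" from becoming mentions on their own.

Matching is token-boundary aligned and case-insensitive. A token window
of the text matches a term when their **optimal string alignment**
distance (substitutions, insertions, deletions, adjacent
transpositions, implemented in C++ with early abandoning) is at most
`floor(max_edit_fraction * nchar(term))`, capped at 2. Transpositions
are essential: "aneruism" is 2 edits from "aneurysm" under OSA but 3
under plain Levenshtein, and swapped letters are among the most common
lay misspellings.

Tunable parameters, with defaults and rationale:

* `max_edit_fraction = 0.3` (edits per term character, range 0–0.4).
  At 0.3 a 7-character term tolerates 2 edits while a 6-character term
  tolerates 1; 0 reduces the detector to exact dictionary matching.
* Fuzzy matching is disabled for terms under 6 characters, and the edit
  cap never exceeds 2. Short terms ("copd", "burn") otherwise generate
  rampant false positives against ordinary vocabulary.
* Overlap resolution is deterministic: earliest start, then longest
  span, then smallest edit distance, then lexicographically smallest
  term. Longest-match preference means that raising the tolerance can
  *replace* two exact fragments by one wider fuzzy span that subsumes
  them ("Non ST elevatino myocardial infarction" as a single mention
  rather than "non st" + "myocardial infarction"); detection coverage
  is monotone in the tolerance even though span identity is not.
* Negation and hedging are not modeled: "does not have cancer" still
  yields a mention. This mirrors the behavior being emulated, which
  also could not distinguish incidental mentions.

## The code resolver

`trigram_similarity()` is the cosine of character-trigram count vectors
over normalized text; an entry scores as the best of its description
and synonyms, and ties break by shorter code then lexicographic code,
so resolution is invariant to lexicon row order. Only the rank-1 code
flows into categorization — each detected diagnosis is assigned one
best code. Trigram profiles degrade gracefully under the same
misspellings the detector tolerates, which is what makes the two-stage
chain robust end to end.

## Category scheme and recoding

`category_scheme()` bundles the closed category set with a chapter map
(`inst/extdata/chapter_categories.csv`) assigning a default category to
each three-character code stem range (A00–B99 infections, C00–D49
neoplasms, I00–I99 cardiovascular, S00–T98 and V00–Y99 injuries and
external causes, ...), plus optional per-CCSR-category reassignments
(e.g. routing congenital cardiovascular malformations into
`cardiovascular`). The shipped chapter map is an approximation built
from ICD-10-CM chapter conventions — the exact production assignment
table is not publicly available — and is deliberately data, not code:
users with the authoritative table supply it as CSV.

`recode()` handles resolver output codes absent from the grouping
lexicon. For k = 0, 1, 2, ... it takes the code minus its last k
characters and collects lexicon codes beginning with that prefix,
stopping at the smallest k with a match; the code inherits the modal
category of the matches. Two decisions were genuinely open:

* **k starts at 0** (the untrimmed code is tried as a prefix before any
  trimming). The canonical example — "C5091" matching C50911/C50912/
  C50919 — already succeeds untrimmed, and starting at 0 subsumes
  trim-first behavior whenever trimming would actually be needed.
* **Ties** in the majority vote are broken by the fixed category
  priority order (`disease_categories()`, then `OTHER`) and flagged in
  the result, keeping the pipeline deterministic. Codes that exhaust
  every prefix are dropped downstream with a warning.

## The keyword word search

The shipped rule set (`default_keyword_rules()`,
`inst/extdata/keyword_rules.csv`) expands to 21 patterns over six
categories: *accident*, *injury/injuries/injured*, *crash*,
*collision*, *burn/burns/burned* (injuries and external causes); *heart
transplant*, *heart surgery* (cardiovascular); *chemo/chemotherapy*,
*radiation/radiotherapy*, *bone marrow transplant* (neoplasms);
*dialysis*, *kidney/renal transplant* (genitourinary); *liver
transplant* (gastrointestinal); *lung transplant* (respiratory).

Matching is case-insensitive, word-boundary aligned, literal (no
stemming: "crashing" does not fire "crash", "burnout" does not fire
"burn"), and multi-word phrases tolerate whitespace runs but not
intervening words ("kidney and liver transplant" fires only "liver
transplant"). The alternates are enumerated rather than stemmed
because the rule set is a curated artifact; users extend it via CSV.

## Evaluation

`evaluate_assignments()` reproduces the validation methodology:
per-category binary confusion counts against an expert-labeled
reference, precision/recall/F1/accuracy, 95% **Wald** intervals, and
count-weighted averages (weights = reference campaigns mentioning the
category). Two details are load-bearing:

* Wald intervals are **not clipped** to [0, 1]. A precision of 28/29 on
  29 predicted positives reports an upper bound of 1.03; only the
  unclipped normal approximation produces such bounds, which pins the
  method.
* Each interval uses the n its proportion is based on: predicted
  positives for precision, reference positives for recall, all
  evaluated campaigns for accuracy. With 35 reference positives and
  recall 0.80 this yields exactly (0.67, 0.93).

Inter-rater reliability between the two annotators who build the
reference is Cohen's kappa (`cohen_kappa()`), with
`annotator_discrepancies()` producing the reconciliation listing for
adjudication — a report, not an algorithm, since disagreements are
resolved by discussion.

## The synthetic corpus generator

No scraped campaign text can be redistributed, so `generate_corpus()`
builds labeled corpora with the structure the pipeline assumes: true
category sets drawn from per-category prevalences, one planted surface
form per true category (a lexicon description or synonym, possibly
misspelled by `corrupt_term()`, or a keyword phrase with no diagnosis),
embedded in first-person filler sentences written for this package in
crowdfunding register.

Defaults, chosen once:

* `prevalence`: the per-category rates implied by a 400-campaign
  expert-labeled reference set (0.045 gastrointestinal to 0.405
  neoplasms) — the best available description of category frequencies
  in this domain.
* `cooccurrence_boost = 1.5`: campaigns frequently mention several
  categories; the boost multiplies a category's odds once another is
  present.
* `misspelling_rate = 0.5` expected edits per planted term (drawn as
  Binomial(2, rate/2) per term, edits never touching the first
  character); `keyword_only_prob = 0.1`, within the observed 2.6–25.2%
  range of keyword-only category detections.

`corrupt_term()` verifies that its composed edits measure within the
requested budget under OSA (interacting edits can otherwise measure one
more) and redraws if not, so "edit distance to source ≤ n_edits" is a
hard guarantee.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: the diversity of genuinely lay phrasings
(the generator only plants lexicon descriptions, synonyms, and keyword
phrases; real campaigns paraphrase freely), vague or indirect condition
descriptions ("a sternum issue"), negated or incidental mentions,
fundraising metadata, and the long tail of codes beyond the bundled
60-code demonstration lexicon (itself a synthetic miniature, not the
official CCSR tables). Perfect recovery on a noise-free synthetic
corpus validates the plumbing, not real-world accuracy.

## Numerical choices and problem sizes

All matching happens on a single normal form (lowercase, punctuation to
single spaces). Degenerate inputs are defined rather than accidental:
empty text yields no mentions; an empty lexicon loads but cannot be
indexed or resolved against; a zero denominator omits a co-occurrence
cell rather than reporting 0; a category with no predicted positives
has undefined (`NA`) precision rather than 0; prefix queries returning
nothing are valid. Every stochastic component runs from one seeded
stream per corpus, and two runs of `identify_diseases()` on the same
inputs are byte-identical.

The test suite and the acceptance script exercise end-to-end recovery
at 500 synthetic campaigns (noise-free and at one expected edit per
planted term), property checks against brute-force oracles at 100–200
random cases per operation, and the published-table recomputations at
their exact printed sizes. On one CPU the whole suite runs in a few
minutes.

## Known limitations

The eleven categories exclude pregnancy, ocular/otologic, hematologic/
immune and chromosomal conditions by design. The dictionary detector
only finds what the lexicon (plus synonyms) can express; with the
small demonstration lexicon, coverage of real campaign text would be
poor — production use requires a full ICD-10-CM/CCSR-scale lexicon
supplied by the user. Incidental and negated mentions are counted as
present. Accuracy figures on imbalanced reference sets should be read
with the usual caution: a category absent almost everywhere yields high
accuracy for trivial reasons.
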