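# crowddx

Disease category identification in medical crowdfunding text.

Web-based medical crowdfunding campaigns describe illness in
unstructured lay prose: misspelled diagnoses ("brain aneruism",
"myeloid lukemia"), informal synonyms, and campaigns that state a
treatment ("having to start dialysis") but never a diagnosis.
Researchers studying who crowdfunds for what — health-services and
health-policy groups working with scraped campaign corpora — need those
free texts converted into structured per-campaign disease labels.

crowddx implements a disease identification pipeline for exactly this
task. Each campaign is labeled present/absent for eleven **mutually
inclusive** disease categories (cardiovascular, endocrine,
gastrointestinal, genitourinary, infections, injuries and external
causes, mental health, musculoskeletal, neoplasms, nervous system,
respiratory) via two merged paths:

* **NER path** — a spell-tolerant dictionary detector finds diagnosis
  mentions (optimal-string-alignment edit distance
  `d(w, t) <= min(2, floor(0.3 |t|))` over token windows `w` and
  indexed terms `t`); each mention links to its best ICD-10-CM code by
  character-trigram cosine similarity; codes missing from the grouping
  lexicon are aligned by iterative prefix trimming (drop the last
  character until some lexicon code starts with the prefix, inherit
  the modal disease category of the matches); codes grouping to
  `OTHER` are removed.
* **Keyword path** — a word-boundary search over 21 treatment/procedure
  terms (*chemo/chemotherapy*, *dialysis*, *accident*, *liver
  transplant*, ...) flags the categories they imply.

Evaluation mirrors the validation-study methodology: per-category
precision, recall, F1 and accuracy with unclipped 95% Wald intervals
(`p ± 1.96 sqrt(p(1-p)/n)`, each on the n its proportion is based on),
count-weighted averages, and Cohen's κ `(p_o − p_e)/(1 − p_e)` for
inter-rater agreement. A synthetic-corpus generator plants ground-truth
diagnosis phrases (with controlled misspellings) and keyword-only
mentions so the whole pipeline is testable without any scraped data.

## Worked example

```r
library(crowddx)

lex <- load_lexicon(system.file("extdata", "demo_lexicon.csv",
                                package = "crowddx"))
camp <- data.frame(
  campaign_id = "c1",
  text = paste("Last month he suffered a brain aneruism.",
               "This disease resulted in my kidneys failing and",
               "having to start dialysis."))
a <- identify_diseases(camp, lex)
subset(a$assignments, present)
#>   campaign_id disease_category present source      evidence
#> 1          c1   cardiovascular    TRUE    ner          I671
#> 4          c1    genitourinary    TRUE   both N200;dialysis
```

The misspelled "brain aneruism" (2 edits from "brain aneurysm") is
detected, resolved to the cerebral-aneurysm code I671, and grouped as
cardiovascular; "kidneys" reaches genitourinary through the NER path
while "dialysis" fires the keyword rule, so the provenance is `both`,
with the supporting code and pattern retained as evidence.

The stages are usable on their own:

```r
recode("C5091", lex)   # breast-cancer stem absent from the lexicon
#> recode(C5091): prefix, trims=0, 3 match(es) -> neoplasms

m <- detect_mentions(list(campaign_id = "c1",
                          text = "diagnosed with myeloid lukemia"),
                     build_term_index(lex))
m
#>   campaign_id start end         surface     matched_term edit_distance
#> 1          c1    15  30 myeloid lukemia myeloid leukemia             1
resolve_mentions(m, lex)[, c("surface", "code", "score", "rank")]
#>           surface  code     score rank
#> 1 myeloid lukemia C9200 0.8153742    1
```

C5091 ("malignant neoplasm of breast, unspecified site") has no exact
lexicon entry, but the untrimmed prefix already matches C50911, C50912
and C50919, so it inherits `neoplasms`. The mention/resolution tables
show the 0-based half-open offsets, the matched dictionary term with
its edit distance, and the trigram-cosine score of the rank-1 code.

`evaluate_assignments(a, reference)` then produces the per-category
metric table (confusion counts, the four metrics, Wald intervals) with
the count-weighted summary attached as `attr(, "weighted")`, and
`contribution_breakdown()` / `cooccurrence_matrix()` summarize how the
two paths divide the detections corpus-wide.

A thin CLI over the same functions ships at `inst/cli/crowddx.R` with
subcommands `identify`, `evaluate`, `summarize` and `simulate`.

The bundled `demo_lexicon.csv` is a synthetic 60-code miniature for
demonstration and testing — production use requires a full
ICD-10-CM/CCSR-scale grouping table, supplied as a CSV with columns
`code,description,ccsr_category[,disease_category][,synonyms]`.

## Package layout

* `R/` — lexicon/scheme store, term index and detector, trigram
  resolver, prefix-trimming recoder, keyword rules, pipeline
  orchestration, evaluation metrics, synthetic generator.
* `src/` — optimal-string-alignment edit distance (Rcpp).
* `inst/extdata/` — chapter→category map, default keyword rules, demo
  lexicon (all editable CSVs).
* `vignettes/crowddx-methods.Rmd` — the model, its parameters, design
  decisions and limitations.
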