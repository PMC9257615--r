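Package: crowddx
Title: Disease Category Identification in Medical Crowdfunding Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects diagnosis mentions in free-text medical crowdfunding
    campaign descriptions with tolerance to misspellings, links them to
    ICD-10-CM codes by character-trigram similarity, groups codes into
    eleven mutually inclusive disease categories via a CCSR-style lexicon
    with iterative prefix-trimming recoding, augments detection with a
    treatment/procedure keyword search, and evaluates the resulting
    multi-label classification (per-category precision, recall, F1,
    accuracy with Wald confidence intervals, count-weighted averages, and
    Cohen's kappa). Includes a synthetic-corpus generator with planted
    ground truth so the whole pipeline is testable without scraped data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
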