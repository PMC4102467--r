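Package: varpharm
Title: Exome Variant and Drug-Response Association Screening for Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacogenomic analysis of annotated exome variants on
    cancer cell line panels such as the NCI-60. Classifies variants by
    amino-acid-changing type and predicted protein-function effect (SIFT and
    PolyPhen-2 criteria), compares panel allele frequencies against a
    non-cancerous reference to flag enriched and depleted variants, converts
    GI50 drug screening data to per-compound z-scores with per-line
    resistance:sensitivity profiling, screens gene-drug pairs by searching
    variant subsets that maximize the Matthews correlation coefficient against
    binarized drug response, sums per-gene variant burden under an
    independence model, and correlates arbitrary per-line patterns against a
    compound activity matrix with pathway-target enrichment testing. A
    synthetic panel generator with planted variant-drug effects supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
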