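Package: clonodyn
Title: Longitudinal T Cell Receptor Beta Repertoire Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of longitudinal bulk T cell receptor beta (TCRbeta)
    repertoire studies of the kind used to follow tumour-infiltrating and
    peripheral-blood T cells through immune checkpoint therapy. Provides a
    clonotype data model with AIRR-C rearrangement TSV input/output and
    CDR3 length/alphabet filtering; rarefaction to a common depth;
    diversity and clonality statistics (normalized Shannon entropy, Renyi
    profiles, Gini index, rank-abundance bands, large-clone counts);
    Morisita-Horn repertoire overlap with within/between-subject
    stratification; longitudinal clone trajectory tracking; exact matching
    of public antigen-associated clonotype panels; a transparent
    frequency-weighted linear multiple-instance repertoire classifier with
    sample-level cross-validation and label-permutation nulls; a
    ground-truthed synthetic study simulator (bilateral tumours, serial
    blood draws, responder/non-responder expansion schedules); and the
    group-comparison statistics and report bundle that tie the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
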