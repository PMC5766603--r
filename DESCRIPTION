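Package: moietypath
Title: Moiety-Balanced Reaction Rules and De Novo Pathway Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts elementally balanced reaction rules from a database of
    metabolic reactions by canonical atom labeling with prime-number moiety
    identifiers, and designs mass-, moiety- and energy-balanced bioconversion
    pathways with a mixed-integer linear program that blends known reactions
    with de novo rule steps. Includes a molecular-graph model with SMILES and
    MDL molfile input, signature-level instantiation of rules on concrete
    substrates, synthetic benchmark networks with planted routes, and
    command-line front ends for rule extraction and pathway design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
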