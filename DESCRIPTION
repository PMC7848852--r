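Package: lipidpath
Title: Lipid Reaction Networks and Pathway Activity from Quantitative Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pathway-level analysis of two-condition quantitative lipidomics
    data. Lipid species names in common shorthand dialects are normalised to
    sum compositions, mapped onto a curated database of mammalian lipid
    reactions (94 reactions over 41 subclasses), and each reaction and
    reaction chain is scored with a Z-statistic comparing a condition of
    interest against a control. Significantly active or suppressed pathways
    are reported together with the human gene symbols annotated to their
    reactions. Includes a synthetic-data generator with planted reaction
    effects, graph and table exporters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
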