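Package: icongr
Title: Protein-Content Phenograms and Tree Congruence Testing with the Icong Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds species phenograms from protein-family count matrices by
    Pearson-correlation distances and average-linkage (UPGMA) clustering, and
    tests topological congruence between trees with the Icong index based on
    exact maximum agreement subtree (MAST) sizes. Includes rooted and unrooted
    MAST dynamic programming with a brute-force oracle, regression and
    Monte-Carlo calibrations of the expected MAST size under Yule and PDA null
    models, curation of rare protein families, a seeded gene-family gain-loss
    simulator for end-to-end validation, and a pipeline that produces pairwise
    congruence tables in TSV and Markdown form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
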