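Package: lexmantel
Title: Lexical Distances, Mantel Tests and Distance-Based Trees for
    Cultural Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether a bounded cultural trait measured on
    groups (e.g. the proportion of cultivated land devoted to rice per
    Chinese province) tracks the historical relatedness of those groups as
    measured through language. Computes normalized Levenshtein distances
    (LDN), doubly normalized edit distances (LDND) and shared-cognate
    distances between language varieties from long-format wordlists,
    aggregates variety-level distances to group (province) level, compares
    the lexical distance matrix with a trait-difference matrix by a
    permutation Mantel test, and estimates a rooted tree of historical
    relations by average-linkage (UPGMA) clustering with Newick export.
    Includes a generator of synthetic datasets in which a lexicon and a
    continuous trait co-evolve on the same tree of descent, with optional
    horizontal borrowing, so that phylogenetic non-independence (Galton's
    problem) can be demonstrated and every pipeline stage tested without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
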