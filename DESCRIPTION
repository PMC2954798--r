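Package: fitchkit
Title: Maximum Parsimony Analysis of Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete maximum-parsimony toolkit for discrete morphological
    (osteological) character matrices: NEXUS matrix input/output with
    missing, inapplicable and polymorphic codings; Fitch-length scoring of
    unordered multistate characters (bitset representation, multifurcation
    support) with ensemble consistency and retention indices; heuristic tree
    search by random addition sequences and tree bisection-reconnection
    (TBR) with monophyly and backbone constraints and zero-length-branch
    collapsing; strict, Adams and majority-rule consensus; nonparametric
    bootstrap proportions and Bremer decay; the incongruence length
    difference (partition homogeneity) test; paired-sites topology tests
    (winning-sites, Templeton, Kishino-Hasegawa with the halved-p bound);
    most-parsimonious character-state reconstruction (ACCTRAN/DELTRAN) and
    unambiguous-synapomorphy reporting; and a simulator for Mk-style
    morphological evolution with partitioned rates and fossil-style
    missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
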