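Package: rankmedian
Title: Exact Generalized Rank-Distance Medians of Three Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the generalized median of three genomes under the rank
    distance on genomic (binary, symmetric, orthogonal) matrices. Genomes are
    involutions on gene extremities; the median attaining the lower bound
    beta = (d(A,B)+d(B,C)+d(C,A))/2 is built exactly from the five-subspace
    decomposition of R^n induced by the inputs, acting as the majority input
    on the four agreement subspaces and as the identity on the disagreement
    subspace. When the resulting matrix is not itself a genome, two recovery
    heuristics (maximum-weight matching, and exhaustive closest-genome search
    over the fractional block) extract a bona-fide genome. A single cut-or-join
    (SCJ) and double cut-and-join (DCJ) simulator generates benchmark triples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
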