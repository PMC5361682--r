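Package: adaptconv
Title: Detection of Adaptive Sequence Convergence in Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting convergent amino-acid and nucleotide
    substitutions between independent branches of a phylogeny. Implements
    Felsenstein pruning likelihoods under reversible substitution models with
    discrete-gamma rate heterogeneity, marginal maximum-likelihood ancestral
    state reconstruction, observed and posterior-expected convergent and
    divergent substitution counts for branch pairs, a divergence-versus-
    convergence empirical null with outlier ranking, a Zhang-Kumar style
    significance test, a physicochemical-property positive-selection scan,
    site-wise log-likelihood topology comparison with the approximately
    unbiased (AU) test, a gene-tree monophyly screen, allometric longevity
    residuals, and a sequence simulator that can plant convergent
    substitutions on focal branches with full ground-truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
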