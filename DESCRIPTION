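Package: paleorate
Title: Paleovirological Dating and Substitution-Rate Inference from Endogenous Viral Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for treating endogenous viral elements (EVEs) as genomic
    fossils. Dates endogenization events from ortholog presence/absence
    patterns on a dated host phylogeny, estimates long-term viral
    substitution-rate bounds from host-corrected nucleotide distances
    (p, JC69, TN93 with optional gamma rate variation, pairwise deletion),
    quantifies gene rate heterogeneity between viral genes with an exact
    Wilcoxon signed-rank test, fits log10-log10 time-dependent rate-decay
    regressions, and runs counting-based neutrality tests (Tajima's D,
    Fu and Li's D*/F*, modified Nei-Gojobori dN/dS with a codon-based
    Fisher exact test). Includes a synthetic endogenization simulator that
    generates sequence data with known ground truth for end-to-end
    validation of the inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
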