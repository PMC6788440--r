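Package: elevdiv
Title: Small-Mammal Diversity Along Elevational Gradients
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of small, non-volant mammal communities surveyed by
    live-trapping along tropical elevational gradients. Reads and filters
    capture-level trap-survey data, computes per-site alpha diversity
    (richness, Shannon, Simpson, Pielou), contrasts observed richness against
    a mid-domain-effect null model built by shuffling discretized species
    ranges within the mountain's elevational domain, partitions Sorensen
    beta diversity into turnover and nestedness components (pairwise and
    multiple-site) with neighbor-joining clustering of sites, quantifies
    endemism with bootstrap confidence envelopes, and tests the contribution
    of endemic species to beta diversity with a subset-permutation test.
    Includes a synthetic trap-survey generator with known ground truth and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'survey.R'
    'tables.R'
    'alpha.R'
    'mde.R'
    'beta.R'
    'endemism.R'
    'synthetic.R'
    'pipeline.R'
    'elevdiv-package.R'
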