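Package: nemosim
Title: Neutral Agent-Based Models of Host-Associated Microbiome Evolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time neutral simulation of microbiome evolution in a
    Wright-Fisher population of hosts. Offspring hosts fill a fixed number of
    microbiome slots by multinomial sampling from their parent's microbiome
    (with per-slot probability x) or from an environmental pool (probability
    1 - x); the environment itself is a mixture of a fixed pool and the pooled
    microbiomes of the previous host generation (weight y). The package
    computes scaled Shannon-Wiener alpha- and gamma-diversity and mean
    pairwise Bray-Curtis beta-diversity along simulation trajectories,
    characterises emergent taxon-abundance distributions with log-normal and
    Dirichlet-multinomial maximum-likelihood fits, reconstructs diversities
    from fitted Dirichlet-multinomial parameters, sweeps the acquisition by
    environment parameter plane with replicated grids, and analyses HMP-style
    community-profile tables (rank collapse, subject deduplication,
    per-body-site diversity summaries) with a matching synthetic-fixture
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vegan
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, PopulationGenetics, Software
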