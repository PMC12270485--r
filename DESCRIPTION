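Package: meiophos
Title: Quantitative Phosphoproteomics of Oocyte Meiotic Maturation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for multiplexed (TMT) phosphoproteomic time
    courses of oocyte meiotic maturation. Aggregates peptide-level reporter-ion
    measurements into posterior channel-share trends with credible intervals
    using a Dirichlet-multinomial model, estimates absolute phosphosite
    occupancy (stoichiometry) from phosphatase-treated anchor channels,
    classifies protein accumulation trends and phosphosite dynamics classes
    from stage fold changes, clusters trajectories by cosine k-means, estimates
    absolute protein concentrations from precursor ion current, scans sequences
    for degrons and kinase consensus motifs with PSSM percentile scoring, and
    matches phosphosites across species by pairwise protein alignment. Includes
    a seeded synthetic-data generator emulating the plex design (nine
    timepoints, two phosphatase anchor channels, three replicates) so that the
    whole pipeline is testable end to end without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
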