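Package: plext
Title: Membrane Analysis for E. coli Polar Lipid Extract Bilayer Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing lipid bilayer trajectories of E. coli
    polar lipid extract (PLE) membrane models. Provides the lipid species
    and tail-chemistry registry of the four PLE model compositions,
    structural metrics (area per lipid by periodic Voronoi tessellation,
    curved-area ratio, volume per lipid, gridded bilayer and hydrophobic
    thickness, interleaflet tail interdigitation, fluctuation-based area
    compressibility), tail ordering statistics (trans-dihedral fraction
    and P2 bond order parameters), lateral lipid diffusion from restarted
    mean squared displacements with Arrhenius activation-energy fits,
    transmembrane water permeation event counting, headgroup neighbour
    enrichment and cluster-size distributions, and lipid-protein shell,
    binding and local-thinning analyses. A seeded synthetic bilayer
    generator with recorded ground truth supports validation of every
    metric. All user-facing functions return tibbles and compose with the
    pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
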