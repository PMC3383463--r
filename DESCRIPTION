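Package: karyoanc
Title: Ancestral Karyotype Reconstruction from Comparative Chromosome Painting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns cross-species chromosome painting (Zoo-FISH) homology maps
    into phylogenetic characters and reconstructs ancestral karyotypes on a
    fixed species tree. Painting maps record which human chromosome segments
    paint each target chromosome; the package extracts syntenic-association
    and fragment-count characters, reconstructs ancestral states by Fitch,
    Dollo and ordered (Wagner) parsimony with full enumeration of most
    parsimonious reconstructions, assembles inferred blocks and adjacencies
    into an ancestral karyotype with a diploid number, and classifies
    characters as synapomorphies, symplesiomorphies or homoplasy. Ships the
    published painting maps for eight xenarthran species (sloths, anteaters,
    armadillos) and the ancestral Eutherian karyotype, together with a
    fusion/fission simulator that generates painting maps with ground-truth
    event logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
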