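Package: corelattice
Title: Steric-Exclusion Occupancy and Assembly Models for Polyhedral
    Protein-Cage Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric and combinatorial analysis of interior-protein
    occupancy on polyhedral enzyme-core lattices, motivated by the fungal
    pyruvate dehydrogenase complex (PDC).  The icosahedral 60-mer E2 core is
    modelled as a dodecahedral graph of trimer sites; trimeric interior
    binders (protein X core-binding domains) occupy vertices subject to a
    steric-exclusion rule on graph distance.  The package enumerates and
    canonically classifies valid and jammed occupancy configurations under
    the proper rotation group, derives binding-stoichiometry bounds, computes
    exact and Monte Carlo jamming distributions of random sequential
    attachment (including a co-assembly variant), and provides a synthetic
    particle-population generator with a classification-confusion model plus
    a maximum-likelihood estimator of the true saturation fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
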