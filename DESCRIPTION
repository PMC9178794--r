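Package: bilayr
Title: Membrane Bilayer Trajectory Analysis: Surface Fitting, Elasticity,
    and Pore Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for lipid-bilayer molecular trajectories,
    oriented at the analysis of antimicrobial-peptide binding and
    tension-driven poration of anionic membranes. Fits smooth periodic height
    fields to each leaflet's phosphorus atoms and derives local thickness,
    surface order-parameter and curvature-corrected density maps; estimates
    the area compressibility modulus from area fluctuations and converts
    relative area dilation to surface tension; counts water molecules in the
    bilayer-centre slab and sizes trans-membrane pores with a cylindrical
    water-census model; and computes peptide-lipid interaction statistics
    (contacts, hydrogen bonds, residue distance maps, centre-of-mass tracks,
    diffusion coefficients, charge bookkeeping). Includes a synthetic bilayer
    trajectory generator with analytic ground truth so every stage can be
    validated at desk scale, plus readers and writers for GRO and PDB
    structures and multi-frame trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
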