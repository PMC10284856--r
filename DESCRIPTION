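Package: foldtrap
Title: Kinetics and Topology of Long-Lived Misfolded Protein States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying soluble misfolded protein subpopulations that
    escape chaperone-mediated refolding. Fits two-pathway biexponential
    refolding kinetics with slow-rate measurability rules and envelope bounds,
    integrates a single-ring GroEL/GroES ATP-cycle reaction network and fits
    its folding/misfolding partition coefficients, estimates chaperone-client
    dissociation constants and binding odds ratios from contact trajectories,
    evaluates a coarse-grained C-alpha 12-10-6 potential, detects non-covalent
    lasso entanglements via discrete Gauss linking numbers (fraction of native
    contacts, windowed-mode classification, crossing localisation, clustering,
    Shrake-Rupley solvent accessibility), and tests the consistency of
    predicted entanglements against limited-proteolysis mass-spectrometry
    peptides with a permutation null built on a theoretical proteinase-K
    cut-site distribution. Includes synthetic-data generators with known
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    bio3d,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
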