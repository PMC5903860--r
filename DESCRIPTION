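Package: memflex
Title: Membrane Trajectory Metrics for Lipid Bilayer Flexibility and Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the acyl-chain profile of phospholipids shapes the
    mechanics and permeability of lipid bilayers from molecular-dynamics
    trajectories and from wet-lab assay traces. Reads GRO, multi-model PDB and
    a plain-text frame-sequence format; annotates atoms with membrane roles
    (phosphate, glycerol, sn1/sn2 acyl carbons, water oxygens) from lipid
    templates; computes per-frame bilayer reference geometry and density
    profiles; detects and classifies water permeation events (crossings versus
    same-side rebounds through the hydrophobic slab); measures terminal-methyl
    velocities, acyl-chain torsion frequencies and chain protrusion events;
    scans leaflet interfaces for shallow and deep lipid packing defects;
    extracts tube length and radius from tether-pulling configurations and
    infers relative bending rigidity from length-to-radius ratios; and
    implements fluorescence-quenching, vesicle permeability/shrinkage,
    apparent-radius and GTPase-rate quantification formulas. A synthetic-data
    generator plants ground-truth events so every analysis is testable without
    running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
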