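Package: ttmd
Title: Thermal Titration Molecular Dynamics Analysis of Protein-Ligand Binding Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thermal titration molecular dynamics (TTMD), a
    temperature-ramp protocol that probes how long a ligand's native binding
    mode survives as simulation temperature rises. Provides residue-resolved
    protein-ligand interaction fingerprints scored by cosine similarity
    against an equilibrated reference (IFP_CS), the progressive
    temperature-ramp driver with its early-termination rule, the MS
    binding-stability slope statistic with trimmed-mean replicate aggregation
    and tight/weak classification, per-residue nonbonded interaction-energy
    decomposition, RMSD trajectory analysis, diagnostic plots, and a
    deterministic synthetic trajectory engine for testing the full pipeline
    without running molecular dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
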