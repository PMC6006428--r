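Package: npcfit
Title: Synthetic Cryo-Electron Tomography and Systematic Density Fitting
    for Nuclear Pore Complex Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale reimplementation of the computational chain used to
    infer the scaffold architecture of the nuclear pore complex (NPC) from
    in situ cryo-electron tomography: missing-wedge-aware subtomogram
    alignment and averaging with imposed rotational symmetry, exhaustive
    rigid-body fitting of subcomplex models into ring densities with
    empirical-null significance assessment and multiple-testing correction,
    difference-map and copy-number analysis, ring geometry measurements,
    and a nucleoporin co-expression analysis.  All stages run on synthetic
    C8-symmetric phantoms with known ground truth, so every claim the
    pipeline makes can be checked against planted copy numbers and poses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
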