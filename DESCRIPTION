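Package: protonplan
Title: Proton Plan Robustness and Variable-RBE Analysis on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward planning and uncertainty analysis for intensity modulated
    proton therapy (IMPT) of base-of-skull and pediatric craniopharyngioma-like
    geometries. Generates seeded synthetic voxel phantoms (clinical target
    volume abutting or overlapping the optic chiasm, adjacent brainstem and
    optic nerves), computes analytical spread-out Bragg peak dose and
    dose-averaged linear energy transfer (LET) maps, weights dose with either
    the clinical constant relative biological effectiveness (RBE) of 1.1 or
    the McNamara phenomenological variable-RBE model, runs a twelve-scenario
    worst-case physical robustness analysis (setup shifts of 3 mm combined
    with 3.5 percent range scaling), converts dose constraints between
    fractionation schemes with the isoeffective biologically effective dose
    formula, and reports dose-volume-histogram metrics against clinical
    organ-at-risk constraints, including a rotational photon-arc surrogate
    comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
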