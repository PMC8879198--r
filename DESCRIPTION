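Package: mapfitr
Title: Template Detection, Rigid and Flexible Fitting, and Validation of
    Atomic Models in Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for cryo-EM template-based model building.
    Provides correlation-scored profile-profile alignment with Z-score
    calibration for template detection, simulated density from atomic models
    by exact Gaussian voxel integration, exhaustive FFT-accelerated
    rigid-body docking ranked by the cross-correlation coefficient,
    CCC-biased flexible fitting with contact-preserving structure-based
    restraints, the CCmask/CCvolume/CCpeaks/CCbox and per-residue SMOC
    map-model agreement metrics, and a candidate filtering/ranking/assembly
    pipeline. Includes a deterministic synthetic fixture generator (ideal
    helices, dimers, hinged domains, sampled MSAs, noisy maps) so the whole
    toolkit is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
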