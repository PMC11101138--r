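Package: mepfield
Title: Inverse Mapping of TMS-Induced Cortical E-Fields from Multi-Muscle MEPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the transcranial magnetic stimulation (TMS) induced
    cortical electric-field volume from a vector of motor evoked potential
    (MEP) amplitudes recorded over multiple muscles. Implements five 3D
    convolutional inverse-imaging network variants (plain and variational),
    the two training regimes (two-stage autoencoding then mapper refinement,
    and single-stage direct training), min-max preprocessing with cortical
    masking, stratified cross-validation, and the reconstruction metrics
    (NRMSE, R-squared, centre-of-gravity error). Ships a synthetic motor-strip
    phantom generator so the whole pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
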