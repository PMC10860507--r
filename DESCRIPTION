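Package: adcboost
Title: DWI-Guided Boost Target Delineation and Radiotherapy Plan Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating dose-escalated radiotherapy of locally
    advanced rectal cancer guided by diffusion-weighted MRI. Delineates
    restricted-diffusion boost subvolumes from apparent diffusion
    coefficient (ADC) maps by intra-tumoural percentile thresholding,
    grows anisotropic boost target margins, computes cumulative
    dose-volume histograms and SBRT conformality indices (Paddick and
    RTOG conformity, modified gradient index, R50, non-target tissue
    spillage), audits plans against single-fraction boost and combined
    long-course constraint sets, and compares dose distributions with a
    3-D gamma index. A seeded synthetic pelvis phantom with analytic
    dose fields supports validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
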