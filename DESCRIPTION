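Package: suturemech
Title: Cranial Suture Biomechanics from Labeled Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the mechanics of the developing calvaria
    from labeled micro-CT-style volumes. Builds bone-plus-suture models
    from disarticulated bone segmentations by morphological suture
    synthesis, extracts the intracranial volume (endocast) and seals
    large openings with cover material, generates conforming multi-region
    tetrahedral meshes, solves small-strain linear-elastic point-loading
    problems with per-suture strain summaries, estimates suture strain
    from unloaded/loaded surface pairs via per-bone rigid registration,
    measures suture gaps slice by slice with ANOVA-based comparison of
    loading states, and calibrates the bone Young's modulus against
    experimental suture strains with Lin's concordance statistics.
    Includes a synthetic skull phantom generator so every stage can be
    exercised without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, Rcpp, RNifti, car, stats, utils, graphics, grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
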