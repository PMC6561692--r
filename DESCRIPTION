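Package: cordmap
Title: Template-Based Quantification of Corticospinal Sprouting,
    Microglial Activation and Expression Time Courses in Spinal Cord
    Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying anatomical plasticity in transverse
    spinal cord sections after cortical injury. Sections are registered
    onto a predefined gray-matter template by landmark-driven affine
    moving-least-squares deformation, traced axon crossings are counted
    along a 20 x 20 template-anchored sampling grid by extended-minima
    (h-minima) detection on gray-value line profiles, and counts are
    normalized, summed over Rexed laminae, binned along the midline and
    assembled into group heat maps and difference maps. Companion modules
    score microglial activation (longest process over soma diameter) with
    semi-random even-coverage sampling and level-set definition of the
    corticospinal projection area, compute threshold-based densitometric
    scores (in situ signal fractions, lesion-completeness ratios, neurite
    outgrowth per cell), score behavioral trial logs (cylinder paw drags,
    horizontal ladder success and foot faults), and call time-course
    differentially expressed genes from count matrices with
    Benjamini-Hochberg control followed by hierarchical clustering into
    temporal patterns. A synthetic-data module generates every input with
    exact ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    limma,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
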