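Package: cbpkit
Title: Connectivity-Based Parcellation of Primate Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connectivity-based parcellation (CBP) of primate brain
    regions from diffusion-tractography connectivity profiles. Implements
    multi-atlas brain extraction by majority voting and joint label fusion
    with a leave-one-out evaluation protocol; segmentation accuracy metrics
    (Dice, surface distances, relative volume difference); registration
    quality-control similarity metrics; thresholding, down-sampling and
    cross-correlation of streamline-count connectivity matrices; spectral
    clustering of seed voxels over a range of cluster numbers; group-level
    label harmonization by linear assignment, probabilistic maps, maximum
    probability maps and neighborhood smoothing; cluster-validity indices
    with leave-one-out and split-half resampling; and PCA-based criteria
    (cumulative variance, Kaiser, scree elbow) for choosing the number of
    clusters. Seeded synthetic generators with planted ground truth make the
    whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
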