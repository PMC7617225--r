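Package: h2axprofiler
Title: Texture-Based Profiling of DNA Damage in 3D Histology Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling DNA damage in thick 3D fluorescence
    histology volumes. Starting from a nuclei instance segmentation and
    multi-channel image stacks (DAPI, gamma-H2AX, CD8), the package
    identifies marker-positive cells by threshold-and-superimpose rules,
    represents each gamma-H2AX positive nucleus by gray-level
    co-occurrence matrix (GLCM) texture features and by latent codes from
    a VAE-GAN trained on 64x64 nucleus patches, clusters representations
    into pseudo texture classes, and profiles local spherical
    neighborhoods (class co-occurrence heatmaps, CD8 proximity counts at
    multiple radii) to compare control and treated tissue regions. A
    seedable synthetic-data generator provides fully annotated 3D
    fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
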