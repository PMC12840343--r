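Package: adiffi
Title: Voxel-Wise Spatial Lesion Mapping with Permutation Cluster Inference
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise analysis of differential involvement (ADIFFI) for
    cohorts of brain-tumor segmentations co-registered to a common atlas
    grid. Provides lesion frequency and differential frequency maps,
    per-voxel Fisher's exact tests with max-statistic permutation
    cluster-size correction, compartment volumetrics with rank-based group
    comparisons, center-of-mass laterality statistics, a synthetic
    lesion-cohort generator with known ground truth for validation, and a
    minimal NIfTI-1 reader/writer so segmentation volumes and statistical
    maps round-trip without external imaging dependencies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
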