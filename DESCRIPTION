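Package: vesseltort
Title: Arterial Tortuosity from 3-D Angiography via Minimal-Cost-Path Centerlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the tortuosity of arteries in segmented 3-D angiographic
    volumes. Provides numeric tube phantoms (helix, comb, branching Y) with
    known ground-truth centerlines; median-filter background subtraction and
    Fourier (sinc) upsampling; Z-buffer segmentation with percentile-threshold
    region growing, bubble filling and directional hole filling; per-voxel
    centerline cost fields (distance-from-edge, modified DFE, center-of-mass
    collapse, and DFE-weighted COM); Dijkstra minimal-cost-path centerline tree
    extraction; distance-factor-metric (DFM = L/d) tortuosity curves with peak
    and end-point readouts; and validation metrics (centerline RMSE against
    ground truth, goal-node stability) together with group-comparison
    statistics (Wilcoxon, ANOVA, F-test, Bonferroni thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
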