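Package: tractometry
Title: Diffusion MRI Tractometry with Synthetic Phantoms and Two-Group
    Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale diffusion MRI tractometry pipeline: multi-shell
    phantom and cohort simulation with known ground truth, voxelwise fitting
    of the diffusion tensor, constant-solid-angle Q-ball orientation
    distribution functions and the NODDI three-compartment microstructure
    model, regularized probabilistic streamline tractography, atlas-based
    bundle labeling by pairwise streamline distance, per-bundle volumetry
    (raw and normalized to total brain and white matter volume) and
    along-tract metric means, and Bonferroni-controlled two-group effect-size
    statistics (Student's t, Cohen's d, relative differences, per-sex
    regression and ANCOVA). Reads and writes NIfTI-1, FSL bval/bvec, TCK/TRK
    tractograms and TSV cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'streamlines.R'
    'bundles.R'
    'cohort.R'
    'gradient.R'
    'io.R'
    'stats.R'
    'csa.R'
    'tracking.R'
    'signal.R'
    'noddi.R'
    'dti.R'
    'phantom.R'
    'pipeline.R'
    'cli.R'
    'tractometry-package.R'
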