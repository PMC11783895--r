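Package: flexfrag
Title: Flexible Protein Fragment Datasets, Featurization and Classification Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for building and benchmarking 3D classification datasets of
    flexible molecular fragments. Harvests single-residue and dipeptide fragments
    from PDB structures (or generates synthetic conformer ensembles from ideal
    amino-acid templates by dihedral sampling), chemically completes them to a
    homogeneous neutral form, featurizes them as point clouds, molecular
    surface meshes, Gaussian density voxel grids and locality-preserving 2D
    Hilbert-curve images, builds conformation-blocked train/test splits by
    RMSD-based two-step clustering, stores features in an indexed HDF5 schema
    with constant-time random access, and trains/evaluates baseline point-cloud,
    voxel and image classifiers with a fixed protocol on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    Rtsne,
    bio3d,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
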