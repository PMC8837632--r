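Package: spatlo
Title: Spatial Transcriptomics Analysis of Tertiary Lymphoid Organs in
    Inflamed Synovium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multi-section spatial
    transcriptomics (ST) of inflamed synovial tissue. Provides spot-level
    quality filtering and normalization, variable-gene selection by the
    squared coefficient of variation, PCA with permutation-based dimension
    selection, tSNE embedding and Ward (ward.D2) hierarchical clustering of
    spots, negative-binomial likelihood-ratio differential expression,
    marker-signature cell-type scoring with a co-expression validity filter,
    tertiary lymphoid organ (TLO) detection from cell-density percentiles,
    point-set registration and piecewise-linear interpolation of serial
    sections into a 3D volume, receptor-ligand interaction permutation
    statistics, hypergeometric gene-set over-representation, and Monte-Carlo
    power simulation under a nested mixed-effects design. A synthetic-data
    generator emulating radially organized lymphoid infiltrates with known
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rtsne,
    interp,
    irlba,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    vegan,
    lme4,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
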