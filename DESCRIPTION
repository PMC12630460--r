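Package: phytodiv
Title: Phytochemical Diversity Metrics for Species-Compound-Region Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes compound-level and biosynthetic-pathway-level measures of
    phytochemical diversity for groups of plant compounds assembled by
    botanical region. Compound-level disparity is measured on Tanimoto
    (Jaccard) distances between binary molecular fingerprints via functional
    attribute diversity (FAD), its size-corrected form MFAD and the average
    pairwise distance APWD. Pathway-level diversity uses Shannon entropy, a
    bias-controlled Shannon estimator based on sample coverage, the
    Gini-Simpson index and Pielou evenness, with rarefaction by repeated
    fixed-size subsampling to control for uneven sampling effort. Faith's
    phylogenetic diversity is computed for the species of each region and
    residualized against species richness with a robust LOWESS fit.
    Association analysis relates the chemical and phylogenetic axes through
    Yeo-Johnson normalisation, Spearman rank correlations and LOWESS-residual
    outlier flagging. A synthetic-data generator produces realistic
    species-compound-region scenarios (skewed compounds-per-species
    distributions, uneven pathway mixtures, Yule trees) so the full pipeline
    can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    vegan,
    car,
    optparse,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
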