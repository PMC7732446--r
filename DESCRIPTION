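Package: snpcluster
Title: Population Structure Inference for Inbred-Line SNP Panels via
    Autoencoder and Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers population genetic structure from panels of fully
    homozygous (inbred-line) SNP genotypes. Nucleotide calls are read from
    VCF, HapMap or plain matrix files, filtered on minor allele frequency
    and missingness, encoded numerically (one-hot or label encoding), and
    compressed with a symmetric deep autoencoder or principal component
    analysis. Samples are then grouped by K-means or agglomerative
    hierarchical clustering; the number of clusters is chosen with the
    silhouette coefficient and the Davies-Bouldin index, and cluster
    assignments are scored against known subpopulations by cross-tab
    accuracy. A Balding-Nichols simulator of differentiated inbred
    subpopulations supports end-to-end verification, and t-SNE/PCA scatter
    exports visualise the recovered structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
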