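Package: landcnn
Title: Simulation-Based Landscape Model Selection with Convolutional
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation-based model selection for landscape genetics.
    Candidate isolation-by-resistance hypotheses are expressed as weighted
    composites of spatial predictor rasters (geographic distance, slope,
    rivers, historical habitat shifts, and environmental niche suitability),
    converted into deme-to-deme migration matrices via least-cost resistance
    distances and a cubic decay, and used to simulate unlinked biallelic
    SNPs under a structured coalescent with an ancestral island split.
    Simulated genotype matrices are encoded as deterministic binary images
    and a small convolutional neural network is trained to assign empirical
    data to one of twelve landscape models, with confusion-matrix,
    precision/recall, and softmax-calibration reporting, plus a
    sampling-design sensitivity experiment and population-genetic summary
    statistics (Hudson's pairwise FST, heterozygosity, and a PCA
    plausibility check of simulated against observed differentiation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
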