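Package: nitroRF
Title: Nitrotyrosine Site Prediction from Sequence Evolutionary Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein tyrosine nitration (3-nitrotyrosine) sites from
    sequence evolutionary information. Fixed-length peptide windows centered
    on tyrosines are encoded with profile-based k-spaced amino-acid-pair
    composition (pbCKSAAP) computed from PSI-BLAST position-specific scoring
    matrices, alongside k-spaced pair counts, binary one-hot and AAindex
    physicochemical encodings. Features are ranked by Wilcoxon rank-sum
    tests (with information-gain and mRMR alternatives), a random-forest
    classifier is trained and thresholded at a target specificity, and
    human-readable decision rules are extracted from the forest by greedy
    set cover. Positional residue enrichment statistics and profile
    conservation comparisons, a deterministic synthetic benchmark generator,
    and an end-to-end train/predict pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    randomForest,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, Classification, FeatureExtraction, SequenceMatching
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aaindex.R'
    'encoders.R'
    'featureSelection.R'
    'model.R'
    'nitroRF-package.R'
    'pipeline.R'
    'positionAnalysis.R'
    'pssm.R'
    'rules.R'
    'seqio.R'
    'synthetic.R'
    'utils.R'
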