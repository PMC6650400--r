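Package: repelscore
Title: Phylogenetic Distance and Odor Similarity Scoring for Non-Host
    Repellency Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate non-host plants for their potential to repel a
    specialist herbivore by combining two predictors: phylogenetic distance
    (PD) of each candidate taxon to a focal host plant, computed as the
    branch-length sum from the candidate's tip to its most recent common
    ancestor with the host on a distance tree built from barcode-gene
    alignments, and physicochemical similarity (PS) of the candidate's
    volatile blend to the host's kairomone compounds, computed from atom-pair
    fingerprints compared with the Tanimoto coefficient. Includes the
    behavioral-assay statistics used to relate those scores to insect
    responses (negative-binomial no-choice oviposition models, weighted
    one-sample Hotelling T-squared choice tests, choice odds ratios, exact
    binomial olfactometer tests, and PD/PS predictor regressions) and a
    synthetic-data generator that emulates the full study design with known
    ground-truth parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
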