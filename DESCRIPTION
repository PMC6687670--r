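Package: specdelim
Title: Integrative Species Delimitation for Cryptic Frog Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative species delimitation in cryptic anuran
    radiations. Computes uncorrected p-distances with pairwise deletion and
    site-bootstrap standard errors from 16S alignments, identifies candidate
    lineages by single-linkage threshold clustering of group-mean distances,
    performs allometric size correction, rank tests and discriminant
    classification on morphometric data, extracts the ten standard
    advertisement-call parameters from recordings, runs correlation-matrix PCA
    of environmental variables with Kaiser retention after spatial thinning of
    occurrence records, estimates Extent of Occurrence and Area of Occupancy
    with IUCN criterion-B Red List categorization, and combines the evidence
    into confirmed/unconfirmed candidate species or deep conspecific lineage
    decisions. Includes seeded simulators for every input type so the whole
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    geosphere,
    jsonlite,
    seqinr,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
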