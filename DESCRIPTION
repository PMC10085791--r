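Package: linkscaf
Title: Linkage-Map-Guided Genome Curation and Scaffolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chromosome-scale pseudomolecules from draft contigs using an
    F2-intercross genetic linkage map. Provides marker quality-control filters,
    two-point recombination-fraction and LOD estimation under F2 and backcross
    models, LOD-threshold linkage grouping and marker ordering; chimeric-contig
    detection from genetic/physical inconsistencies with breakpoint location at
    read-coverage minima; marker-anchored ordering and orienting of contigs with
    overlap-aware joining and guide-assisted placement of markerless contigs;
    AGP 2.1 and FASTA pseudomolecule emission with a fixed 100-N gap convention;
    and an assembly quality-control surface covering N50 and gap statistics,
    telomere and telomere-to-telomere accounting, k-mer-based consensus quality
    values (QV), and physical-versus-genetic marker consistency checks. A
    seeded synthetic-data generator (genomes with telomeric repeats, ZW
    inheritance, Haldane-model F2 crosses, fragmented and chimeric contig sets,
    windowed coverage tracks, and error-bearing k-mer sets) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'curation.R'
    'io.R'
    'linkage.R'
    'pipeline.R'
    'qc.R'
    'scaffolding.R'
    'simulate.R'
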