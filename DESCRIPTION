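Package: its2cbc
Title: ITS-2 Secondary-Structure Barcoding and CBC-Based Species
    Delimitation for Coccoid Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting species of coccoid green algae (such as
    Choricystis and Chlorella-like sponge endosymbionts) from nuclear rDNA
    sequences.  Implements constrained folding of the ITS-2 transcript
    (5.8S/LSU stem, pyrimidine-pyrimidine processing-site mismatch in
    Helix II, GGU motif in Helix III), extraction of the conserved-region
    base-pair barcode as a number code, detection and classification of
    compensatory base changes (CBCs and hemi-CBCs), mapping of SSU rDNA to
    E. coli 16S coordinates with group I intron detection and V4/V9
    variable-region extraction, and statistical-parsimony (TCS) haplotype
    networks with habitat and geographic overlays.  A seeded synthetic-data
    generator produces cassettes, SSU sequences and haplotype samples with
    known ground truth so every analysis stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
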