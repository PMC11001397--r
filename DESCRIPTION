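Package: multiconf
Title: Multi-Conformer Side-Chain Model Building from Electron Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds multi-conformer protein models from crystallographic
    electron density. Samples map density around side-chain chi dihedral
    angles (Ringer-style scans), detects density peaks on the circular
    traces, assembles peak combinations into candidate rotamers, validates
    them against an ideal rotamer library, and builds signal-ranked
    alternate conformations (altlocs) into the model with occupancy
    bookkeeping and flexibility reporting. Reads and writes PDB/mmCIF
    models, CCP4/MRC density maps and MTZ map coefficients, and ships a
    synthetic-fixture generator that plants known rotamer ensembles in
    Gaussian-atom density maps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
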