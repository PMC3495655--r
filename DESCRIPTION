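Package: unismiles
Title: Canonical SMILES from InChI Canonical Labels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates standard canonical SMILES strings by reusing the
    canonical atom labelling of the InChI algorithm.  Two canonical forms
    are provided: Universal SMILES, which keeps the original structure and
    orders its atoms by the canonical labels parsed from the auxiliary
    information of a non-standard (FixedH, RecMet) InChI, and Inchified
    SMILES, which round-trips the structure through the Standard InChI and
    therefore inherits its normalisations (nitro and sulfoxide expansion,
    tautomer collapse, metal disconnection).  Includes an OpenSMILES reader
    and writer, an MDL mol/SDF reader, an InChI auxiliary-information
    parser, order-invariance ("shuffle") and duplicate-detection tests, and
    a command-line interface.  The InChI itself is computed by the Open
    Babel command-line program, never reimplemented.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel) with InChI support on the PATH
Config/testthat/edition: 3
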