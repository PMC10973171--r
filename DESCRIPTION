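Package: rnaMAC
Title: Molar Absorption Coefficients and UV Quantification of
    Nucleoside-Modified mRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes composition-based molar absorption coefficients at
    260 nm (MAC260) for in vitro transcribed mRNA, accounting for the
    hypochromicity of modified nucleosides (pseudouridine,
    N1-methylpseudouridine, 5-methylcytidine) and for 5' cap structures
    (Cap0/Cap1). Converts A260 measurements - single readings or serial
    dilution series fitted by linear regression - into molar and mass
    concentrations and total amounts via the Beer-Lambert law, predicts
    the hypochromicity ratio and concentration under-estimation incurred
    when unmodified coefficients are applied to modified constructs, and
    fits molar absorption coefficients from calibration data. Includes a
    user-overridable photometric registry, synthetic data generators for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'rnaMAC-package.R'
    'AllClasses.R'
    'registry.R'
    'sequence-io.R'
    'photometry.R'
    'quantify.R'
    'synthetic.R'
    'cli.R'
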