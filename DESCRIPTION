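Package: chemoprint
Title: Chemometric Species Classification from Ambient Mass-Spectral
    Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput species identification and
    classification from ambient ionization mass-spectral fingerprints.
    Converts raw or centroided spectra into normalized full-spectrum
    fingerprint matrices ("heat maps") and targeted feature tables,
    classifies samples with linear and kernel Fisher discriminant
    analysis validated by leave-one-out cross-validation, performs
    principal component and kernel principal component ordination, and
    infers sample relatedness by uncentered-correlation single-linkage
    hierarchical clustering with Newick export.  Includes mass
    recalibration, centroiding, spectral averaging, background
    subtraction, and a seeded simulator of species-specific chemotype
    fingerprints for end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    ape,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
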