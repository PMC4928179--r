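Package: rgdflex
Title: Quantifying Protein Conformational Flexibility from SAXS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-free quantification of protein conformational
    flexibility from small-angle X-ray scattering (SAXS) intensity
    profiles. A log-normal distribution over the radius of gyration is
    convolved with the form factor of a homogeneous sphere and fitted to
    the measured low-angle intensity; the differential entropy of the
    fitted distribution is a continuous flexibility metric that separates
    compact, partially folded and intrinsically disordered biopolymers.
    Includes the classical SAXS diagnostics (Guinier analysis, Kratky and
    dimensionless Kratky plots, Porod and Porod-Debye transforms with
    plateau detection), an entropy-quartile flexibility classifier,
    reading and writing of three-column '.dat' scattering files, and a
    synthetic-profile generator for delta, log-normal and mixture Rg
    ensembles with configurable noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
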