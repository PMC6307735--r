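Package: hrmasflux
Title: Synthetic 13C-Tracer HRMAS NMR Cohorts and Isotopomer Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates litter-matched fetal growth restriction (FGR) versus
    appropriate-for-gestational-age (AGA) cohorts infused with 1-13C-glucose or
    2-13C-acetate, renders their 1H-CPMG, 2D 1H-13C HSQC and 31P HRMAS spectra,
    and analyses them: positional 13C label propagation through glycolysis and
    the TCA cycle with explicit carbon atom maps, region-of-interest and
    deconvolution-based spectral quantification, isotopomer-derived enrichment
    and incorporation statistics, relative flux ratios (PC/PDH, PC/ME, GS), and
    littermate case-control comparisons with Shapiro-Wilk gating and Student
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
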