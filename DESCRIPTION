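Package: oxinmr
Title: Quantitative 1H NMR Monitoring of Edible-Oil Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative 1H NMR (qNMR) monitoring of lipid oxidation in
    edible oils rich in omega-6 polyunsaturated acyl groups. Ships a machine-readable
    chemical-shift assignment catalogue for oxylipins and related oxidation products
    (hydroperoxy-, hydroxy-, keto-, epoxy-dienes and -monoenes, oxygenated
    alpha,beta-unsaturated aldehydes, poly-formates, sterol oxides), performs
    signal-window integration with internal-reference quantification against the
    triglyceride glyceryl backbone and ordered overlap-subtraction corrections, and
    estimates stage-wise degradation and formation kinetics on concentration time
    courses. A Lorentzian synthetic-spectrum generator renders concentration tables
    into spectra so that every stage of the pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
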