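Package: switchprint
Title: Photoswitching Fingerprint Analysis for Sub-10-nm Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to infer the number of fluorophores and their
    sub-10-nm interfluorophore distances from single-molecule
    photoswitching statistics.  Implements photoswitching fingerprint
    analysis of localization tables (on-times, off-times, on-events,
    intensity, cumulative localizations and T80), fluorescence intensity
    trajectory analysis with multiple-tau autocorrelation, TCSPC decay
    construction and multiexponential lifetime fitting with instrument
    response reconvolution, fast per-pixel lifetime estimation, and
    photon antibunching coincidence analysis (Nc/Nl,av emitter
    counting).  A distance-coupled stochastic photophysics simulator
    (continuous-time Markov chain with Forster-type energy transfer
    between on- and off-states) generates photon streams and
    localization tables emulating dSTORM and DNA-PAINT experiments on
    DNA origami and membrane-receptor mimics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
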