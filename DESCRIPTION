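Package: iaplung
Title: Intra-Abdominal Pressure and Lung Mechanics During Laparoscopy
Version: 0.1.0
Authors@R: person("OR", "Datafusion", email = "ordatafusion@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the coupling between intra-abdominal
    pressure (IAP) created by CO2 pneumoperitoneum and respiratory
    mechanics during laparoscopic surgery under mechanical ventilation.
    Provides a synthetic multi-device operating-room stream simulator
    (ventilator waveforms at 20 ms, insufflator IAP at 40 ms, ventilation
    settings at 60 s, device clock skew, missing samples), ingestion with
    clock-skew repair and gap flagging, per-breath extraction of peak
    inspiratory pressure, PEEP, tidal volume and dynamic compliance
    Cdyn = VT/(PIP - PEEP), zero-lag FIR low-pass filtering of the IAP,
    and per-subject simple and multiple linear regression correlation
    between IAP and lung mechanics with group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
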