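Package: vlobule
Title: Virtual Hepatic Lobule Simulation of Acetaminophen-Induced Hepatotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic, discrete-time, agent-based model of a hepatic lobule
    for simulating acetaminophen (APAP) toxicity in a virtual mouse. A
    three-zone directed graph of sinusoid segments carries percolating APAP
    objects from the periportal entrance to the central vein; hepatocytes run
    a per-second event cascade (metabolism, NAPQI formation, glutathione
    depletion, mitochondrial damage and its amplification, damage mitigation,
    and delayed necrotic death) whose event probabilities follow configurable
    periportal-to-pericentral gradients. Four competing mechanism hypotheses
    of centrilobular necrosis (NZ, GNZ, MNZ, MGNZ) are provided as presets,
    together with virtual-experiment protocols: single-pass liver perfusion
    (hepatic extraction ratio), 24-hour bolus toxicity time courses with
    regional measurements and death observers, dose-response runs, and
    multi-variant sweeps over mechanism configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
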