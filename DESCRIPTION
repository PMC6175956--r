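Package: curvsense
Title: Entropic Membrane-Curvature Sensing by Disordered Polymers
Version: 0.1.0
Authors@R: person("curvsense", "maintainers", email = "curvsense@example.org",
    role = c("aut", "cre"))
Description: Lattice self-avoiding-walk (SAW) models of intrinsically
    disordered protein domains tethered to curved membrane substrates,
    with absolute conformational entropy estimation by the hypothetical
    scanning Monte Carlo (HSMC) method, conversion of entropy differences
    into relative curvature-sensitivity predictions via a Boltzmann
    relation, and the companion tethered-vesicle analysis pipeline:
    fluorescence calibration of vesicle diameters and bound-protein
    counts, Langmuir isotherm fitting with a geometric binding-capacity
    correction, normalized curvature-sensitivity profiles, filopodia
    partition coefficients, and FCS autocorrelation fitting. Includes
    synthetic-data generators that emulate every input the pipeline
    consumes, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
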