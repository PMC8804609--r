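Package: hvgate
Title: Simulation and Analysis of Voltage-Gated Proton Channel Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the gating and selectivity of voltage-gated
    proton channels (HV1) from whole-cell patch-clamp current families. A
    biophysical simulator generates families of depolarization-evoked proton
    currents under arbitrary step protocols, pH gradients and zinc
    concentrations, including proton-depletion feedback on intracellular pH.
    Analysis functions implement rising-exponential activation fits, tail
    current measurement, threshold detection, both zero-current and
    tail-current reversal-potential methods, conductance-voltage curves and
    their pH and zinc shifts, the voltage dependence of activation kinetics,
    and the threshold-versus-reversal regression describing pH-dependent
    gating. Thermodynamic reference potentials (Nernst, Goldman-Hodgkin-Katz)
    and a sequence-screening module (S4 voltage-sensor motif scan,
    selectivity-filter classification by pairwise alignment, zinc-site
    annotation, ORF translation, in-silico PCR) support mining transcriptome
    assemblies for HV1 homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
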