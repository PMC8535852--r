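Package: wheelnet
Title: Gait Kinematics, Calcium Event Rates, and Direct Functional
    Connectivity for Speed-Controlled Wheel Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motor-learning experiments in which a
    head-fixed mouse runs on a speed-controlled wheel while layer 2/3 and
    layer 5a motor-cortex neurons are imaged with a calcium indicator.
    Provides forelimb stride detection and interlimb coordination scoring
    from paw-trajectory tables, fluorescence-transient (event) detection and
    block-wise event-rate summaries, permutation-based identification of
    neurons responsive to wheel-speed transitions, pairwise Pearson and
    maximum-entropy direct-coupling (partial-correlation) functional
    connectivity with strong-pair and proximity-bias analyses, cross-day
    field-of-view registration with neuron identity matching, and pair
    persistence summaries.  A synthetic-data module generates all input
    kinds with planted ground truth so the full pipeline is testable
    without experimental data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
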