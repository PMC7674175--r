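Package: qinncond
Title: Quantum-Inspired Cortico-Hippocampal Simulation of Classical Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates classical conditioning with a two-module quantum-inspired
    neural network model of the cortico-hippocampal system. Stimulus cues are
    amplitude-encoded as real-valued qubits and rotated through a Hadamard gate;
    a one-qubit autoencoder network (the hippocampal module) compresses each cue
    into an internal representation, and a sixteen-qubit feedforward network
    (the cortical module) maps the cue to a conditioned response, trained online
    with instar, outstar, and Widrow-Hoff rules plus gradient updates of the
    quantum intervals inside each neuron's activation. Intact and lesioned
    (link-severed) variants reproduce a thirteen-task battery of conditioning
    phenomena - acquisition, extinction, blocking, latent inhibition,
    overshadowing, discrimination reversal, context shifts - reporting
    trials-to-criterion per task phase together with full learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
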