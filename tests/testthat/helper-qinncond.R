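# Shared fixtures: everything is generated in code at test time.

default_cfg <- learning_config()

# Fast config for loop-heavy property checks: identical dynamics, smaller cap.
capped_cfg <- function(max_trials = 60L, ...) {
  learning_config(max_trials = max_trials, ...)
}

cue_ax <- function(us, a = 1) stimulus_cue(cs_a = a, ctx = "x", us = us)
cue_bx <- function(us, b = 1) stimulus_cue(cs_b = b, ctx = "x", us = us)
cue_abx <- function(us) stimulus_cue(cs_a = 1, cs_b = 1, ctx = "x", us = us)

random_qubit <- function() {
  ang <- stats::runif(1, 0, 2 * pi)
  qubit(cos(ang), sin(ang))
}

encode_cue_lines <- function(cue) {
  encode_input(c(cue$cs_a, cue$cs_b, cue$ctx_x, cue$ctx_y))$p_tilde
}
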