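# Vectorized forward pass through one layer of quantum-inspired neurons
# (single activation function per neuron). W is R x Q. The raw rotated
# inputs of the first layer are squashed through the log-sigmoid
# (squash_input = TRUE); hidden activities entering a second layer are
# already firing rates and are weighted directly, so the Widrow-Hoff rule's
# presynaptic term is exactly the output unit's regressor. o_extra adds to
# the pre-activations (used by the hippocampo-cortical link).
layer_forward <- function(W, inputs, thetas, delta, o_extra = NULL,
                          squash_input = TRUE) {
  o <- drop(crossprod(W, if (squash_input) .sig(inputs) else inputs))
  if (!is.null(o_extra)) o <- o + o_extra
  y <- .sig(delta * (o - thetas))
  list(o = o, y = y, z = .sig(y), v = y * (1 - y))
}

init_weights <- function(nr, nc, max = 0.1) {
  matrix(stats::runif(nr * nc, 0, max), nr, nc)
}

#' Initialize the hippocampal autoencoder network
#'
#' The hippocampal module is an autoencoder of quantum-inspired neurons: `R`
#' input lines feed `Q` hidden qubits (the internal representation), which
#' reconstruct the `R` lines at the output. Weights are drawn uniformly on
#' \[0, `init_weight_max`\] from the current RNG state; every quantum
#' interval starts at `theta_init`.
#'
#' @param n_inputs Number of input lines `R`.
#' @param n_hidden Number of hidden qubits `Q`.
#' @param theta_init Initial quantum interval.
#' @param init_weight_max Upper bound of the uniform weight initialization.
#' @param rng_seed Optional integer; when supplied, the RNG is seeded before
#'   drawing the weights.
#' @return A list of class `"aqinn"` with weight matrices `W_h1` (`R x Q`),
#'   `W_h2` (`Q x R`) and interval vectors `theta_h1`, `theta_h2`.
#' @examples
#' st <- aqinn_init(rng_seed = 1)
#' dim(st$W_h1)
#' @export
aqinn_init <- function(n_inputs = 4L, n_hidden = 1L, theta_init = 2,
                       init_weight_max = 0.1, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  structure(list(
    W_h1 = init_weights(n_inputs, n_hidden, init_weight_max),
    W_h2 = init_weights(n_hidden, n_inputs, init_weight_max),
    theta_h1 = rep(theta_init, n_hidden),
    theta_h2 = rep(theta_init, n_inputs),
    n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
    rng_seed = rng_seed
  ), class = "aqinn")
}

#' Forward pass through the hippocampal autoencoder
#'
#' Hidden units are quantum-inspired neurons: pre-activations are weighted
#' sums of the sigmoid-squashed rotated inputs, followed by the interval
#' activation `y = sigmoid(delta * (o - theta))` and the squash
#' `z = sigmoid(y)`. The internal representation `a_h1` is the hidden
#' layer's `z`; output units weight `a_h1` directly (it is already a firing
#' rate), and the reconstruction `a_h2` reported for error tracking is the
#' output layer's interval activation `y`, which spans (0, 1).
#'
#' @param state An [aqinn_init()] state.
#' @param p_tilde Rotated-phase input vector, length `R`.
#' @param delta Steepness factor.
#' @return A list with `a_h1`, `a_h2`, and the full per-layer activations
#'   `hidden` and `output` (each with `o`, `y`, `z`, `v`).
#' @export
aqinn_forward <- function(state, p_tilde, delta = 1) {
  if (!inherits(state, "aqinn")) stop("state must be an aqinn", call. = FALSE)
  if (length(p_tilde) != state$n_inputs) {
    stop("dimension mismatch: p_tilde vs AQINN input layer", call. = FALSE)
  }
  hid <- layer_forward(state$W_h1, p_tilde, state$theta_h1, delta)
  out <- layer_forward(state$W_h2, hid$z, state$theta_h2, delta,
                       squash_input = FALSE)
  list(a_h1 = hid$z, a_h2 = out$y, hidden = hid, output = out)
}

#' One online training step of the hippocampal autoencoder
#'
#' Runs the forward pass, then updates the input layer by the instar rule
#' (pattern = the rotated input, gate = the hidden activity), the output
#' layer by the outstar rule toward the teaching signal, and both layers'
#' quantum intervals by the gradient rule. The default teaching signal is
#' the sigmoid-squashed rotated input (`outstar_target_mode = "clamped"`);
#' the self-referential variant uses the network's own reconstruction.
#'
#' @param state An [aqinn_init()] state.
#' @param p_tilde Rotated-phase input vector, length `R`.
#' @param config A [learning_config()].
#' @return A list with the updated `state`, `a_h1`, and `a_h2`.
#' @export
aqinn_train_step <- function(state, p_tilde, config = learning_config()) {
  if (!inherits(config, "learning_config")) {
    stop("config must be a learning_config", call. = FALSE)
  }
  mu <- config$mu_hippocampal
  delta <- config$delta
  fw <- aqinn_forward(state, p_tilde, delta)

  state$W_h1 <- instar_update(state$W_h1, pre = p_tilde, post = fw$a_h1, mu = mu)
  target <- if (config$outstar_target_mode == "clamped") {
    .sig(p_tilde)
  } else {
    fw$a_h2
  }
  state$W_h2 <- outstar_update(state$W_h2, pre = fw$a_h1,
                               target_pattern = target, mu = mu)
  state$theta_h1 <- quantum_interval_update(state$theta_h1, fw$hidden$y,
                                            fw$hidden$v, delta, mu)
  state$theta_h2 <- quantum_interval_update(state$theta_h2, fw$output$y,
                                            fw$output$v, delta, mu)
  list(state = state, a_h1 = fw$a_h1, a_h2 = fw$a_h2)
}
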