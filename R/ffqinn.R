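#' Initialize the cortical feedforward network
#'
#' The cortical module is a single-hidden-layer feedforward network of
#' quantum-inspired neurons: `R` input lines feed `Q` hidden qubits, which
#' feed one output unit producing the conditioned response. Weights are
#' drawn uniformly on \[0, `init_weight_max`\]; every quantum interval
#' starts at `theta_init`.
#'
#' @param n_inputs Number of input lines `R`.
#' @param n_hidden Number of hidden qubits `Q`.
#' @param theta_init Initial quantum interval.
#' @param init_weight_max Upper bound of the uniform weight initialization.
#' @param rng_seed Optional integer; when supplied, the RNG is seeded before
#'   drawing the weights.
#' @return A list of class `"ffqinn"` with `W_c1` (`R x Q`), `W_c2`
#'   (length `Q`), and interval vectors `theta_c1` (length `Q`),
#'   `theta_c2` (length 1).
#' @examples
#' st <- ffqinn_init(rng_seed = 1)
#' length(st$W_c2)
#' @export
ffqinn_init <- function(n_inputs = 4L, n_hidden = 16L, theta_init = 2,
                        init_weight_max = 0.1, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  structure(list(
    W_c1 = init_weights(n_inputs, n_hidden, init_weight_max),
    W_c2 = stats::runif(n_hidden, 0, init_weight_max),
    theta_c1 = rep(theta_init, n_hidden),
    theta_c2 = theta_init,
    n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
    rng_seed = rng_seed
  ), class = "ffqinn")
}

#' Forward pass through the cortical network
#'
#' Hidden pre-activations are `o_j = sum_i W_c1[i,j] * sigmoid(p_tilde_i)`,
#' plus the hippocampal link contribution when one is supplied; hidden
#' activities `a_c1` are the hidden units' `z` values. The output unit
#' weights `a_c1` directly (so the Widrow-Hoff presynaptic term is exactly
#' its regressor), and its interval activation
#' `y = sigmoid(delta * (o - theta))` is the conditioned response, spanning
#' (0, 1) so it can approach both US targets.
#'
#' @param state An [ffqinn_init()] state.
#' @param p_tilde Rotated-phase input vector, length `R`.
#' @param link_input Optional numeric vector of length `Q` added to the
#'   hidden pre-activations (the hippocampo-cortical modulation); `NULL` is
#'   equivalent to all zeros.
#' @param delta Steepness factor.
#' @return A list with `a_c1`, `cr`, and per-layer activations `hidden` and
#'   `output`.
#' @export
ffqinn_forward <- function(state, p_tilde, link_input = NULL, delta = 1) {
  if (!inherits(state, "ffqinn")) stop("state must be an ffqinn", call. = FALSE)
  if (length(p_tilde) != state$n_inputs) {
    stop("dimension mismatch: p_tilde vs FFQINN input layer", call. = FALSE)
  }
  if (!is.null(link_input) && length(link_input) != state$n_hidden) {
    stop("dimension mismatch: link input vs FFQINN hidden layer", call. = FALSE)
  }
  hid <- layer_forward(state$W_c1, p_tilde, state$theta_c1, delta,
                       o_extra = link_input)
  out <- layer_forward(matrix(state$W_c2, ncol = 1L), hid$z, state$theta_c2,
                       delta, squash_input = FALSE)
  list(a_c1 = hid$z, cr = out$y, hidden = hid, output = out)
}

#' One online training step of the cortical network
#'
#' Runs the forward pass, then updates the hidden layer by the instar rule
#' (pattern = the rotated input, gate = each hidden unit's own activity),
#' the output weights by the Widrow-Hoff rule with error `us - cr`, and
#' both layers' quantum intervals by the gradient rule.
#'
#' @param state An [ffqinn_init()] state.
#' @param p_tilde Rotated-phase input vector, length `R`.
#' @param us Desired response (US target) in \[0, 1\].
#' @param link_input Optional hippocampal modulation vector of length `Q`.
#' @param config A [learning_config()].
#' @return A list with the updated `state`, the pre-update `cr`, the signed
#'   error `error = us - cr`, and the hidden activity `a_c1`.
#' @export
ffqinn_train_step <- function(state, p_tilde, us, link_input = NULL,
                              config = learning_config()) {
  if (!inherits(config, "learning_config")) {
    stop("config must be a learning_config", call. = FALSE)
  }
  if (!is.numeric(us) || length(us) != 1L || us < 0 || us > 1) {
    stop("us must be a single value in [0, 1]", call. = FALSE)
  }
  mu <- config$mu_cortical
  delta <- config$delta
  fw <- ffqinn_forward(state, p_tilde, link_input, delta)
  err <- us - fw$cr

  state$W_c1 <- instar_update(state$W_c1, pre = p_tilde, post = fw$a_c1, mu = mu)
  state$W_c2 <- widrow_hoff_update(state$W_c2, pre = fw$a_c1, error = err,
                                   mu = mu)
  state$theta_c1 <- quantum_interval_update(state$theta_c1, fw$hidden$y,
                                            fw$hidden$v, delta, mu)
  state$theta_c2 <- quantum_interval_update(state$theta_c2, fw$output$y,
                                            fw$output$v, delta, mu)
  list(state = state, cr = fw$cr, error = err, a_c1 = fw$a_c1)
}
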