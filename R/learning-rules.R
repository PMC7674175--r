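#' Learning configuration
#'
#' Bundles every tunable hyperparameter of the simulator. The defaults are
#' the published operating point of the model: hippocampal learning rate
#' 0.03, cortical learning rate 0.01, steepness 1, a single activation
#' function per neuron with initial quantum interval 2, and hidden sizes of
#' 1 (hippocampal autoencoder) and 16 (cortical feedforward network).
#'
#' @param mu_hippocampal Learning rate of the hippocampal module (and of the
#'   hippocampo-cortical linking network), in (0, 1).
#' @param mu_cortical Learning rate of the cortical module, in (0, 1).
#' @param delta Steepness factor of the quantum neurons.
#' @param n_f Number of activation functions per neuron (the network layers
#'   require 1; larger values are supported by [neuron_output()] only).
#' @param theta_init Initial quantum interval for every neuron.
#' @param epsilon Convergence tolerance on `|CR - US|`, in (0, 0.5). A phase
#'   ends on the first trial in which every cue's conditioned response lies
#'   within `epsilon` of its US target.
#' @param max_trials Trial cap per phase; reaching it without convergence
#'   reports the cap as a sentinel rather than raising an error.
#' @param hidden_aqinn Hidden qubits in the autoencoder network.
#' @param hidden_ffqinn Hidden qubits in the feedforward network.
#' @param n_inputs Input lines per cue (CS A, CS B, context X, context Y).
#' @param init_weight_max Weights are initialized uniformly on
#'   \[0, `init_weight_max`\].
#' @param padding_mode How the zero-padding rows interleaved with the cues
#'   are treated: `"forward"` presents them to both networks without any
#'   learning, `"skip"` omits them, `"train"` trains on them with US = 0.
#' @param outstar_target_mode Teaching signal of the autoencoder's output
#'   layer: `"clamped"` uses the sigmoid-squashed rotated input (the classic
#'   outstar teaching signal); `"self"` uses the network's own output.
#' @param easy_hard_interpretation Whether graded easy/hard stimulus values
#'   are CS input `"intensity"` (default) or graded US `"target"` values.
#' @param persistence Number of consecutive satisfying trials required
#'   before convergence is declared (default 1: first satisfying trial).
#' @return A list of class `"learning_config"`.
#' @examples
#' cfg <- learning_config()
#' cfg$mu_hippocampal
#' @export
learning_config <- function(mu_hippocampal = 0.03,
                            mu_cortical = 0.01,
                            delta = 1,
                            n_f = 1L,
                            theta_init = 2,
                            epsilon = 0.05,
                            max_trials = 500L,
                            hidden_aqinn = 1L,
                            hidden_ffqinn = 16L,
                            n_inputs = 4L,
                            init_weight_max = 0.1,
                            padding_mode = c("forward", "skip", "train"),
                            outstar_target_mode = c("clamped", "self"),
                            easy_hard_interpretation = c("intensity", "target"),
                            persistence = 1L) {
  padding_mode <- match.arg(padding_mode)
  outstar_target_mode <- match.arg(outstar_target_mode)
  easy_hard_interpretation <- match.arg(easy_hard_interpretation)
  if (mu_hippocampal <= 0 || mu_hippocampal >= 1 ||
      mu_cortical <= 0 || mu_cortical >= 1) {
    stop("learning rates must lie in (0, 1)", call. = FALSE)
  }
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  }
  if (max_trials < 1L) stop("max_trials must be >= 1", call. = FALSE)
  if (n_f < 1L) stop("n_f must be >= 1", call. = FALSE)
  if (hidden_aqinn < 1L || hidden_ffqinn < 1L || n_inputs < 1L) {
    stop("layer sizes must be >= 1", call. = FALSE)
  }
  if (persistence < 1L) stop("persistence must be >= 1", call. = FALSE)
  structure(list(
    mu_hippocampal = mu_hippocampal, mu_cortical = mu_cortical,
    delta = delta, n_f = as.integer(n_f), theta_init = theta_init,
    epsilon = epsilon, max_trials = as.integer(max_trials),
    hidden_aqinn = as.integer(hidden_aqinn),
    hidden_ffqinn = as.integer(hidden_ffqinn),
    n_inputs = as.integer(n_inputs), init_weight_max = init_weight_max,
    padding_mode = padding_mode, outstar_target_mode = outstar_target_mode,
    easy_hard_interpretation = easy_hard_interpretation,
    persistence = as.integer(persistence)
  ), class = "learning_config")
}

#' @export
print.learning_config <- function(x, ...) {
  cat("<learning_config>\n")
  cat(sprintf("  mu (hippocampal / cortical): %.3g / %.3g\n",
              x$mu_hippocampal, x$mu_cortical))
  cat(sprintf("  delta %.3g, theta_init %.3g, n_f %d\n",
              x$delta, x$theta_init, x$n_f))
  cat(sprintf("  hidden sizes (AQINN / FFQINN): %d / %d, inputs %d\n",
              x$hidden_aqinn, x$hidden_ffqinn, x$n_inputs))
  cat(sprintf("  epsilon %.3g, max_trials %d, persistence %d\n",
              x$epsilon, x$max_trials, x$persistence))
  invisible(x)
}

check_conformable <- function(a, b, what) {
  if (length(a) != length(b)) {
    stop(sprintf("dimension mismatch in %s", what), call. = FALSE)
  }
}

#' Instar weight update
#'
#' Grossberg's instar rule moves the incoming weight vector of a unit toward
#' the presynaptic pattern, gated by the unit's own activity:
#' `W' = W + mu * post * (pre - W)`. With `mu * post <= 1` the new weights
#' are a convex combination of the old weights and the pattern, so repeated
#' presentation of a fixed pattern drives `W` to it geometrically.
#'
#' `W` may also be an `R x Q` matrix with `post` a vector of `Q` unit
#' activities; the update is then applied column-wise.
#'
#' @param W Weight vector of one post-synaptic unit (or `R x Q` matrix).
#' @param pre Presynaptic pattern, length `R`.
#' @param post Post-synaptic activity (scalar, or length `Q` for a matrix).
#' @param mu Learning rate.
#' @return Updated weights, same shape as `W`.
#' @examples
#' instar_update(0.5, pre = 0.70711, post = 1, mu = 0.03)  # 0.5062133
#' @export
instar_update <- function(W, pre, post, mu) {
  if (is.matrix(W)) {
    if (nrow(W) != length(pre) || ncol(W) != length(post)) {
      stop("dimension mismatch in instar update", call. = FALSE)
    }
    return(W + mu * (pre - W) * rep(post, each = nrow(W)))
  }
  check_conformable(W, pre, "instar update")
  W + mu * post * (pre - W)
}

#' Outstar weight update
#'
#' Grossberg's outstar rule moves the outgoing weights of a unit toward a
#' target activity pattern, gated by the presynaptic activity:
#' `W' = W + mu * (target - W) * pre`. With no presynaptic activity nothing
#' is learned; with the target equal to the weights the rule is at a fixed
#' point.
#'
#' `W` may also be a `Q x R` matrix fanning out from `Q` units, with `pre` a
#' vector of `Q` activities; the update is applied row-wise.
#'
#' @param W Weight vector fanning out from one pre-synaptic unit (or
#'   `Q x R` matrix).
#' @param pre Pre-synaptic activity (scalar, or length `Q` for a matrix).
#' @param target_pattern Target activity pattern, length `R`.
#' @param mu Learning rate.
#' @return Updated weights, same shape as `W`.
#' @examples
#' outstar_update(c(0.2, 0.2), pre = 1, target_pattern = c(1, 0), mu = 0.03)
#' @export
outstar_update <- function(W, pre, target_pattern, mu) {
  if (is.matrix(W)) {
    if (ncol(W) != length(target_pattern) || nrow(W) != length(pre)) {
      stop("dimension mismatch in outstar update", call. = FALSE)
    }
    return(W + mu * (rep(target_pattern, each = nrow(W)) - W) * pre)
  }
  check_conformable(W, target_pattern, "outstar update")
  W + mu * (target_pattern - W) * pre
}

#' Widrow-Hoff (LMS) weight update
#'
#' The delta rule for the output layer: `W' = W + mu * pre * error`, with the
#' error taken as `desired - actual` so that repeated updates descend the
#' squared output error (stable for `mu < 2 / ||pre||^2` on a fixed input).
#'
#' @param W Output weight vector.
#' @param pre Hidden activity vector, same length as `W`.
#' @param error Scalar output error, `desired - actual`.
#' @param mu Learning rate.
#' @return Updated weight vector.
#' @examples
#' widrow_hoff_update(0.1, pre = 0.5, error = 0.8, mu = 0.01)  # 0.104
#' @export
widrow_hoff_update <- function(W, pre, error, mu) {
  check_conformable(W, pre, "Widrow-Hoff update")
  W + mu * pre * error
}

l2_normalize <- function(x) {
  if (length(x) < 2L) return(x)  # singleton layer: normalization degenerate
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

#' Gradient update of the quantum intervals
#'
#' Each interval moves by
#' `theta' = theta + mu * delta * sigmoid(y_bar - y) * (v_bar - v)`,
#' where `y_bar` and `v_bar` are the L2-normalized layer vectors of interval
#' activations and interval sensitivities. Normalization is degenerate when
#' `y` or `v` has zero norm and for single-unit layers (a normalized scalar
#' is constant, which would turn the rule into an unbounded one-way drift);
#' in both cases the unnormalized vector is used, making the corresponding
#' difference vanish and the update a no-op.
#'
#' @param thetas Interval vector of the layer.
#' @param y Layer vector of interval activations.
#' @param v Layer vector of interval sensitivities.
#' @param delta Steepness factor.
#' @param mu Learning rate.
#' @return Updated interval vector.
#' @examples
#' quantum_interval_update(c(2, 2), y = c(0.6, 0.8), v = c(0.1, 0.2),
#'                         delta = 1, mu = 0.03)
#' @export
quantum_interval_update <- function(thetas, y, v, delta, mu) {
  check_conformable(thetas, y, "quantum interval update")
  check_conformable(thetas, v, "quantum interval update")
  thetas + mu * delta * .sig(l2_normalize(y) - y) * (l2_normalize(v) - v)
}

#' Output error metrics
#'
#' Returns the signed errors `e_j = y_j - d_j`, the half-sum statistic
#' `0.5 * sum(e_j)` used for reporting, and the mean absolute error
#' `mean(|e_j|)` that drives convergence checks.
#'
#' @param y Actual output vector.
#' @param d Desired output vector (US targets), same length.
#' @return A list of class `"error_record"` with elements `signed_errors`,
#'   `half_sum`, and `mean_abs`.
#' @examples
#' error_metrics(c(0.8), c(1))  # half_sum -0.1, mean_abs 0.2
#' @export
error_metrics <- function(y, d) {
  check_conformable(y, d, "error metrics")
  e <- y - d
  structure(list(signed_errors = e, half_sum = 0.5 * sum(e),
                 mean_abs = mean(abs(e))),
            class = "error_record")
}
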