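#' Log-sigmoid activation
#'
#' The logistic function `1 / (1 + exp(-x))`, the activation used throughout
#' the quantum-inspired neuron model. The exponent argument is clamped at
#' +/-700 so the function is numerically stable over the whole double range.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of the same length, strictly inside (0, 1).
#' @examples
#' sigmoid(0)            # 0.5
#' sigmoid(2)            # 0.8807971
#' sigmoid(3) + sigmoid(-3)  # 1
#' @export
sigmoid <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("sigmoid() requires finite numeric input", call. = FALSE)
  }
  x <- pmin(pmax(x, -700), 700)
  1 / (1 + exp(-x))
}

# Unchecked logistic for internal hot paths; arguments there are bounded by
# the weight dynamics, far from overflow.
.sig <- function(x) 1 / (1 + exp(-x))

#' Construct a qubit with real amplitudes
#'
#' A two-level quantum state restricted to the Bloch circle: both probability
#' amplitudes are real and `alpha^2 + beta^2 = 1`.
#'
#' @param alpha Real amplitude of the `|0>` basis state.
#' @param beta Real amplitude of the `|1>` basis state.
#' @param tol Tolerance on the normalization constraint.
#' @return A named numeric vector `c(alpha =, beta =)` of class `"qubit"`.
#' @examples
#' qubit(1, 0)
#' qubit(0.6, 0.8)
#' @export
qubit <- function(alpha, beta, tol = 1e-9) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta)) {
    stop("qubit amplitudes must be single finite real numbers", call. = FALSE)
  }
  if (abs(alpha^2 + beta^2 - 1) > tol) {
    stop("qubit amplitudes must satisfy alpha^2 + beta^2 = 1", call. = FALSE)
  }
  structure(c(alpha = alpha, beta = beta), class = "qubit")
}

as_qubit <- function(q, tol = 1e-9) {
  if (inherits(q, "qubit")) return(q)
  if (is.numeric(q) && length(q) == 2L) return(qubit(q[[1L]], q[[2L]], tol = tol))
  stop("expected a qubit or a numeric vector of two amplitudes", call. = FALSE)
}

#' @export
print.qubit <- function(x, ...) {
  cat(sprintf("<qubit> %.6f|0> %+.6f|1>\n", x[["alpha"]], x[["beta"]]))
  invisible(x)
}

#' Hadamard rotation of a qubit
#'
#' Applies the 2x2 Hadamard (Walsh) gate, mapping amplitudes
#' `(alpha, beta)` to `((alpha + beta)/sqrt(2), (alpha - beta)/sqrt(2))`.
#' The gate takes basis states into equal superpositions and is its own
#' inverse.
#'
#' @param q A [qubit()] or numeric vector of two amplitudes.
#' @return A normalized [qubit()].
#' @examples
#' hadamard(qubit(1, 0))   # (1, 1)/sqrt(2)
#' hadamard(qubit(0, 1))   # (1, -1)/sqrt(2)
#' hadamard(hadamard(qubit(0.6, 0.8)))  # back to (0.6, 0.8)
#' @export
hadamard <- function(q) {
  q <- as_qubit(q)
  s <- 1 / sqrt(2)
  qubit((q[["alpha"]] + q[["beta"]]) * s, (q[["alpha"]] - q[["beta"]]) * s,
        tol = 1e-8)
}

#' Encode a stimulus intensity as a rotated qubit
#'
#' A stimulus line with intensity `x` in \[0, 1\] is amplitude-encoded on the
#' Bloch circle as `(cos(pi*x/2), sin(pi*x/2))`, so that intensity 0 is the
#' basis state `|0>` and intensity 1 is `|1>`, with graded intensities
#' interpolating linearly in angle. The Hadamard gate then rotates the qubit
#' into superposition, and the post-rotation `|1>` amplitude
#' `p_tilde = (cos(pi*x/2) - sin(pi*x/2)) / sqrt(2)` is the scalar fed to the
#' networks. `p_tilde` is strictly decreasing in `x`, bounded in
#' \[-1/sqrt(2), 1/sqrt(2)\], and retains the sign information that the
#' squared amplitude would destroy (both 0 and 1 map to probability 1/2).
#'
#' @param x Stimulus intensity (or vector of intensities) in \[0, 1\].
#' @return For a single intensity, a list with elements `qubit` (the rotated
#'   [qubit()]) and `p_tilde`; for a vector, a list with matrix `qubit`
#'   (columns alpha, beta) and vector `p_tilde`.
#' @examples
#' encode_input(0)$p_tilde    #  0.7071068
#' encode_input(1)$p_tilde    # -0.7071068
#' encode_input(0.5)$p_tilde  #  0
#' @export
encode_input <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    stop("stimulus intensity must be finite numeric", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("stimulus intensity must lie in [0, 1]", call. = FALSE)
  }
  ang <- (pi / 2) * x
  a <- cos(ang)
  b <- sin(ang)
  s <- 1 / sqrt(2)
  alpha_r <- (a + b) * s
  beta_r <- (a - b) * s
  if (length(x) == 1L) {
    list(qubit = qubit(alpha_r, beta_r, tol = 1e-8), p_tilde = beta_r)
  } else {
    list(qubit = cbind(alpha = alpha_r, beta = beta_r), p_tilde = beta_r)
  }
}

#' Parameters of a quantum-inspired neuron
#'
#' @param delta Steepness factor of the interval sigmoid (default 1).
#' @param thetas Numeric vector of quantum intervals, one per activation
#'   function (default 2).
#' @param n_f Number of activation functions; must equal `length(thetas)`.
#' @return A list of class `"quantum_neuron_params"`.
#' @examples
#' quantum_neuron_params()                 # delta = 1, theta = 2
#' quantum_neuron_params(thetas = c(1, 3)) # two-level activation
#' @export
quantum_neuron_params <- function(delta = 1, thetas = 2, n_f = length(thetas)) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("delta must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(thetas) || length(thetas) < 1L || any(!is.finite(thetas))) {
    stop("thetas must be a finite numeric vector", call. = FALSE)
  }
  if (n_f < 1L || n_f != length(thetas)) {
    stop("n_f must be >= 1 and equal length(thetas)", call. = FALSE)
  }
  structure(list(delta = delta, thetas = as.numeric(thetas), n_f = as.integer(n_f)),
            class = "quantum_neuron_params")
}

#' Weighted pre-activation of a quantum-inspired neuron
#'
#' Each input is squashed through the log-sigmoid before weighting:
#' `o = sum_i w_i * sigmoid(p_i)`.
#'
#' @param inputs Numeric vector of inputs `p_i`.
#' @param weights Numeric vector of weights, same length as `inputs`.
#' @return The scalar pre-activation.
#' @examples
#' neuron_preactivation(c(0, 0), c(1, 1))  # 1
#' @export
neuron_preactivation <- function(inputs, weights) {
  if (length(inputs) != length(weights)) {
    stop("inputs and weights must have equal length", call. = FALSE)
  }
  if (length(inputs) < 1L) stop("need at least one input", call. = FALSE)
  sum(weights * sigmoid(inputs))
}

#' Multilevel activation of a quantum-inspired neuron
#'
#' Given a pre-activation `o`, the neuron averages `n_f` shifted sigmoids,
#' one per quantum interval: `y = mean_k sigmoid(delta * (o - theta_k))`,
#' and squashes once more, `z = sigmoid(y)`. The interval sensitivity
#' `v_k = f_k * (1 - f_k)` (the derivative of each shifted sigmoid) is
#' returned alongside; it drives the gradient update of the intervals.
#'
#' @param o Scalar pre-activation.
#' @param params A [quantum_neuron_params()] object.
#' @return A list of class `"neuron_activation"` with elements `o`, `y`, `z`,
#'   and `v` (length `n_f`).
#' @examples
#' act <- neuron_output(2, quantum_neuron_params())
#' act$y  # 0.5
#' act$z  # 0.6224593
#' @export
neuron_output <- function(o, params = quantum_neuron_params()) {
  stopifnot(inherits(params, "quantum_neuron_params"))
  if (!is.numeric(o) || length(o) != 1L || !is.finite(o)) {
    stop("pre-activation must be a single finite number", call. = FALSE)
  }
  fk <- sigmoid(params$delta * (o - params$thetas))
  y <- mean(fk)
  structure(list(o = o, y = y, z = sigmoid(y), v = fk * (1 - fk)),
            class = "neuron_activation")
}

#' Interval sensitivity of a quantum-inspired neuron
#'
#' The derivative of each shifted sigmoid at the current pre-activation:
#' `v_k = f(delta*(o - theta_k)) * (1 - f(delta*(o - theta_k)))`. Each
#' component lies in (0, 0.25\], with the maximum attained exactly at
#' `o = theta_k`.
#'
#' @inheritParams neuron_output
#' @return Numeric vector of length `n_f`.
#' @examples
#' interval_sensitivity(2, quantum_neuron_params())  # 0.25 at o == theta
#' @export
interval_sensitivity <- function(o, params = quantum_neuron_params()) {
  neuron_output(o, params)$v
}
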