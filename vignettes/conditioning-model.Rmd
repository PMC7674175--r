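---
title: "A quantum-inspired cortico-hippocampal model of classical conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantum-inspired cortico-hippocampal model of classical conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qinncond)
```

## The model

`qinncond` simulates classical conditioning with a pair of small neural
networks whose neurons borrow two ideas from quantum computing: inputs are
amplitude-encoded as real-valued qubits and rotated through a Hadamard gate
before they reach the networks, and each neuron's activation contains a
trainable *quantum interval* playing the role of a multi-level threshold.

**Input encoding.** Each cue is four stimulus lines — conditioned stimulus
A, conditioned stimulus B, and two mutually exclusive context lines X and Y.
A line with intensity $x \in [0,1]$ becomes the qubit
$(\cos\frac{\pi x}{2})\,|0\rangle + (\sin\frac{\pi x}{2})\,|1\rangle$, so
intensity 0 is the basis state $|0\rangle$, intensity 1 is $|1\rangle$, and
graded intensities (used by the easy/hard transfer task) interpolate
linearly in Bloch angle. The Hadamard gate rotates the qubit into
superposition; the scalar forwarded to the networks is the post-rotation
$|1\rangle$ amplitude

$$\tilde p = \tfrac{1}{\sqrt 2}\left(\cos\tfrac{\pi x}{2} -
\sin\tfrac{\pi x}{2}\right) \in [-\tfrac{1}{\sqrt2}, \tfrac{1}{\sqrt2}],$$

which is strictly monotone in the intensity. The squared amplitude would
not be usable here: it maps intensity 0 and intensity 1 to the same
probability 1/2, destroying the information the networks must learn from.

**The quantum-inspired neuron.** A neuron with pre-activation $o$ computes

$$y = \frac{1}{n_f}\sum_{k=1}^{n_f} f\!\big(\delta\,(o - \vartheta_k)\big),
\qquad z = f(y), \qquad f(x) = \frac{1}{1+e^{-x}},$$

with steepness $\delta$ and quantum intervals $\vartheta_k$. The model runs
with a single activation function per neuron ($n_f = 1$); the general form
is available through `neuron_output()`. First-layer pre-activations are
$o_j = \sum_i w_{ij}\, f(\tilde p_i)$ — the log-sigmoid turns the signed
rotated amplitude into a firing rate. Hidden activities are already firing
rates, so second layers weight them directly, $o = \sum_j w_j\, a_j$; this
also makes the Widrow–Hoff update below an exact least-mean-squares rule,
whose presynaptic factor must be the output unit's regressor.

**Two modules.** The hippocampal module is an autoencoder (AQINN): four
input lines, one hidden qubit whose activity $a^{h1}$ is the internal
representation of the cue, and four output units that reconstruct the
input. The cortical module (FFQINN) maps the same four lines through
sixteen hidden qubits to one output unit; the output unit's interval
activation $y$ is the conditioned response (CR). In the intact system the
hippocampal representation is forwarded through a trainable linking network
into the cortical hidden layer, where it adds to the hidden
pre-activations; the lesioned system is the identical model with this link
removed — and nothing else changed, a property the test suite checks
bitwise.

**Learning rules.** All learning is online, one update per cue
presentation:

* AQINN input layer — instar: $W \mathrel{+}= \mu\, a^{h1} (\tilde p - W)$;
* AQINN output layer — outstar toward the teaching signal $f(\tilde p)$:
  $W \mathrel{+}= \mu\, (f(\tilde p) - W)\, a^{h1}$;
* FFQINN hidden layer — instar gated by each unit's own activity;
* FFQINN output — Widrow–Hoff: $W \mathrel{+}= \mu\, a^{c1} (d - y)$ with
  the US target $d$;
* link — outstar toward the current cortical hidden pattern;
* every layer's intervals —
  $\vartheta \mathrel{+}= \mu\,\delta\, f(\bar y - y)(\bar v - v)$, where
  $v = y(1-y)$ is the interval sensitivity and $\bar y,\bar v$ are the
  L2-normalized layer vectors.

The learning rates are $\mu = 0.03$ for the hippocampal side (including
the link) and $\mu = 0.01$ for the cortical side, with $\delta = 1$ and
every interval initialized at $\vartheta_0 = 2$. Weights start uniform on
$[0, 0.1]$ from the run seed.

## Design choices where the formulation is open

Several parts of the published formulation do not pin down an executable
model; the package resolves them as follows, and records each choice here
rather than silently.

*Error sign.* The printed error statistic is $e = y - d$, but adding
$+\mu a e$ to the output weights would climb the squared error. The update
therefore uses $(d - y)$, the standard Widrow–Hoff descent direction; the
half-sum statistic $\frac12\sum_j e_j$ is kept verbatim as a reporting
metric in `error_metrics()`.

*The conditioned response is the output unit's $y$, not $z$.* Because
$y \in (0,1)$, the final squash $z = f(y)$ is confined to
$(0.5, 0.731)$; a CR defined as $z$ could never come within the 0.05
criterion of either US target and no task would ever converge. The interval
activation $y$ spans $(0,1)$ and is therefore the reported response (and,
symmetrically, the autoencoder's reported reconstruction).

*Normalization in the interval rule.* $\bar y, \bar v$ are L2-normalized
over the layer. A single-unit layer is degenerate under any normalization
(the normalized scalar is a constant), which would turn the rule into a
one-way drift racing the output learning — measured on the acquisition
task, the CR then stalls near 0.9 and never converges. Singleton layers
therefore receive the same fallback the rule already uses for zero-norm
vectors: the unmodified vector, making their interval update a no-op.

*Outstar teaching signal.* The literal outstar form uses the autoencoder's
own output as its attractor, which exerts no reconstruction pressure. The
default clamps the output-layer activity to $f(\tilde p)$, the classic
Grossberg teaching signal; the literal self-referential form is available
via `outstar_target_mode = "self"`.

*Stimulus layout.* Blocks hold 10 cues cycling through the phase's
contingencies in fixed alternation, each followed by a zero-padding row.
Padding rows are presented forward-only by default (`padding_mode`); they
can be skipped or trained with US = 0. Context bits follow the task table
(AX+ pairs A with context X); compound cues set both CS lines.

*Convergence.* A phase ends on the first trial in which every cue's
$|CR - US| \le \varepsilon$, with $\varepsilon = 0.05$ and a cap of 500
trials reported as a sentinel; a persistence window of $k$ consecutive
satisfying trials is available via `persistence`. One trial is one pass
over the 10-cue block with online updates.

## What the simulated battery does and does not reproduce

The thirteen-task battery (`task_battery()`) covers acquisition (A+),
extinction-style unpaired training (A−), blocking, stimulus discrimination
and its reversal, easy/hard transfer with graded CS intensities (0.9/0.1
and 0.6/0.4), context shift, latent inhibition and its context
sensitivity, sensory and compound preconditioning, and overshadowing, in
intact and/or lesioned modes as applicable.

Single-cue phases behave as expected: the CR converges to its US target in
a few tens of trials, unpaired training converges faster than paired
acquisition, and pre-exposure (latent inhibition) slows subsequent
acquisition. All of this is deterministic given the seed and is measured by
the acceptance suite over 25 seeds.

Two structural properties of the published learning rules limit what the
battery can reproduce, and both are worth understanding before using the
model:

1. **Discrimination phases do not reach criterion.** With instar learning
   on the cortical hidden layer, a block alternating AX+ and BX− drives
   every hidden weight column toward the swap-symmetric average of the two
   cue patterns. At that fixed point the network's response to the A-cue
   and the B-cue is *identical* — the asymmetry needed for discrimination
   decays instead of growing (the gating contrast provides a feedback loop
   gain well below 1). Both cue types settle near the average of their
   targets, and phases that require different responses to A and B
   (stimulus discrimination, reversal, easy/hard transfer, and the
   discriminative halves of overshadowing's and compound preconditioning's
   second phases) run to the trial cap. The package reports the cap
   sentinel honestly rather than a fabricated count.

2. **The quantum intervals ratchet upward.** For any layer of
   $Q \le 16$ units, $\lVert v\rVert_2 \le 0.25\sqrt{Q} \le 1$, so
   $\bar v - v \ge 0$ elementwise and the interval update only ever
   increases $\vartheta$. On task timescales the drift is small relative
   to weight learning, but over long runs it pushes activations into the
   sigmoid tail; the autoencoder's activation-space reconstruction error
   is dominated by this drift, which is why the test suite checks the
   decoder's weight-space convergence instead.

The intact/lesioned contrast produced by the additive link is real but
small (a few trials): the link adds a slowly varying positive drive to the
cortical hidden layer. The large lesion effects reported for this class of
models (substantially faster lesioned acquisition, lesion-abolished
blocking and latent inhibition) do not emerge from these equations at
these hyperparameters; `compare_to_reference()` makes the deviation from
the published counts explicit instead of hiding it.

## Problem sizes and numerics

The simulations are small by construction: networks of 4/1/4 and 4/16/1
units, 10-cue blocks, and at most 500 trials per phase. The full battery —
13 tasks, both applicable modes, 25 seeds — completes in a few minutes on
one CPU, which is the scale at which the acceptance checks and the
worked examples run. The log-sigmoid clamps its argument at ±700 to avoid
overflow; all other quantities stay well inside double range (the test
suite checks weight boundedness over 10,000 updates). Reported aggregates
use the median across seeds with interquartile ranges, which is robust to
occasional non-convergent seeds.

## A worked run

```{r a-plus, fig.width = 6, fig.height = 3, eval = FALSE}
res <- run_task(task_battery()$a_plus, mode = "lesioned", seed = 1)
res$per_phase_trials
tail(subset(res$curves[[1]], cue == "AX+"))
```

A multi-seed battery over a subset of tasks:

```{r battery, eval = FALSE}
report <- run_battery(seeds = 1:25,
                      battery = task_battery()[c("a_plus", "a_minus",
                                                 "latent_inhibition")])
report$summary
compare_to_reference(report)
```
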