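# qinncond

Simulation of classical conditioning with a quantum-inspired neural-network
model of the cortico-hippocampal system, for computational-neuroscience work
on how hippocampal damage reshapes associative learning.

Animals acquire, extinguish, and transfer conditioned responses (CR) to cues
paired or unpaired with reinforcement (US), and hippocampal lesions alter
these phenomena selectively: simple acquisition survives (often speeds up),
while pre-exposure and compound-training effects such as latent inhibition
and blocking are disrupted. `qinncond` implements a two-module simulator of
this system in which every neuron is *quantum-inspired*:

- each stimulus line with intensity $x \in [0,1]$ is amplitude-encoded as a
  real-valued qubit $(\cos\frac{\pi x}{2})|0\rangle +
  (\sin\frac{\pi x}{2})|1\rangle$ and rotated through a Hadamard gate; the
  post-rotation $|1\rangle$ amplitude $\tilde p$ feeds the networks;
- each neuron activates through
  $y = \frac{1}{n_f}\sum_k f(\delta(o - \vartheta_k))$, $z = f(y)$, where
  $f$ is the log-sigmoid, $\delta$ a steepness factor, and the quantum
  intervals $\vartheta_k$ are trained by a normalized gradient rule;
- the hippocampal module is a 4–1–4 autoencoder (instar input layer,
  outstar output layer) whose hidden activity is the cue's internal
  representation; the cortical module is a 4–16–1 feedforward network
  (instar hidden layer, Widrow–Hoff output) whose output unit's interval
  activation is the CR;
- the intact system forwards the hippocampal representation through a
  trainable link into the cortical hidden layer; the lesioned system is the
  same model with that link removed — verified bitwise by the test suite.

A thirteen-task battery (acquisition, extinction, blocking, discrimination
and reversal, easy/hard transfer, context shift, latent inhibition, sensory
and compound preconditioning, overshadowing) runs each task's phases to a
trials-to-criterion measure: the first trial on which every cue's
$|CR - US| \le \varepsilon$ (default 0.05), capped at 500 trials.

The methods vignette (`vignettes/conditioning-model.Rmd`) documents the
model, the places where the published formulation is under-determined and
how the package resolves them, and two structural properties of the
learning rules that limit what the battery reproduces (discrimination
phases cannot reach criterion, and the quantum intervals drift one-way).

## Worked example

```r
library(qinncond)

res <- run_task(task_battery()$a_plus, mode = "lesioned", seed = 1)
res
#> <run_result> a_plus (lesioned, seed 1)
#>   phase 1: 53 trials
tail(subset(res$curves[[1]], cue == "AX+"), 3)
#>     trial cue        cr us
#> 528    53 AX+ 0.9510734  1
#> 529    53 AX+ 0.9511691  1
#> 530    53 AX+ 0.9512645  1
```

The paired cue AX+ needs 53 trials for its CR to climb within 0.05 of the
US target 1. A multi-seed battery aggregates medians per task, phase, and
mode:

```r
report <- run_battery(seeds = 1:5,
                      battery = task_battery()[c("a_plus", "a_minus",
                                                 "latent_inhibition")])
report$summary
#>               task phase     mode median_trials iqr_low iqr_high n_seeds prop_converged
#>            a_minus     1   intact            35      34       35       5              1
#>            a_minus     1 lesioned            36      35       36       5              1
#>             a_plus     1   intact            51      51       51       5              1
#>             a_plus     1 lesioned            53      53       53       5              1
#>  latent_inhibition     1   intact            35      34       35       5              1
#>  latent_inhibition     1 lesioned            36      35       36       5              1
#>  latent_inhibition     2   intact            56      56       56       5              1
#>  latent_inhibition     2 lesioned            58      58       58       5              1
```

Unpaired training (A−) converges faster than acquisition (A+), and
pre-exposure slows subsequent acquisition (latent inhibition phase 2: 56
trials vs. 51 for acquisition without pre-exposure). Learning curves can be
rendered with `plot_curves()`, reports exported/re-imported with
`export_report()` / `read_report()`, and medians compared against the
trial counts reported for the reference implementation of this
architecture with `compare_to_reference()`.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/scripts/qinncond run --task latent_inhibition --mode both \
    --seeds 25 --out li-report
Rscript inst/scripts/qinncond compare --report li-report
```

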