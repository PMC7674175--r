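#' Build an intact or lesioned cortico-hippocampal model
#'
#' Assembles the quantum-input encoding, the hippocampal autoencoder, the
#' cortical feedforward network, and (in the intact system) the linking
#' network that forwards the hippocampal internal representation into the
#' cortical hidden layer. All weights are initialized uniformly on
#' \[0, `init_weight_max`\] from `seed`; lesioning removes the link and
#' nothing else, so an intact model whose link contributes zero behaves
#' identically to the lesioned model.
#'
#' @param config A [learning_config()].
#' @param mode `"intact"` or `"lesioned"`.
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `"ch_model"` with components `aqinn`, `ffqinn`,
#'   `link` (`present`, `frozen`, `W_link`), `config`, `mode`, `seed`.
#'   Setting `link$frozen` to `TRUE` stops the outstar training of the link
#'   while keeping it wired, which (with `W_link` zeroed) pins the link
#'   contribution at exactly zero — the probe used to verify that lesioning
#'   is precisely the removal of this pathway.
#' @examples
#' m <- build_model(seed = 1)
#' m$mode
#' build_model(mode = "lesioned", seed = 1)$link$present
#' @export
build_model <- function(config = learning_config(),
                        mode = c("intact", "lesioned"), seed = 1L) {
  stopifnot(inherits(config, "learning_config"))
  mode <- match.arg(mode)
  set.seed(seed)
  aq <- aqinn_init(config$n_inputs, config$hidden_aqinn, config$theta_init,
                   config$init_weight_max)
  ff <- ffqinn_init(config$n_inputs, config$hidden_ffqinn, config$theta_init,
                    config$init_weight_max)
  link <- if (mode == "intact") {
    list(present = TRUE, frozen = FALSE,
         W_link = init_weights(config$hidden_aqinn, config$hidden_ffqinn,
                               config$init_weight_max))
  } else {
    list(present = FALSE, frozen = TRUE, W_link = NULL)
  }
  structure(list(aqinn = aq, ffqinn = ff, link = link, config = config,
                 mode = mode, seed = as.integer(seed)),
            class = "ch_model")
}

#' @export
print.ch_model <- function(x, ...) {
  cat(sprintf("<ch_model> %s system, seed %d\n", x$mode, x$seed))
  cat(sprintf("  AQINN %d -> %d -> %d | FFQINN %d -> %d -> 1%s\n",
              x$aqinn$n_inputs, x$aqinn$n_hidden, x$aqinn$n_inputs,
              x$ffqinn$n_inputs, x$ffqinn$n_hidden,
              if (x$link$present) " | link present" else ""))
  invisible(x)
}

# Link contribution to the cortical hidden pre-activations: the hippocampal
# representation a_h1 (already a firing rate) mapped through W_link.
link_contribution <- function(model, a_h1) {
  if (!model$link$present) return(NULL)
  drop(crossprod(model$link$W_link, a_h1))
}

#' Run one learning trial (one pass over a stimulus block)
#'
#' For each cue in order: the four stimulus lines are amplitude-encoded and
#' Hadamard-rotated ([encode_input()]); the hippocampal autoencoder takes a
#' training step; its internal representation is forwarded through the link
#' (intact mode) into the cortical hidden layer; the cortical network takes
#' a training step against the cue's US; and the link weights are updated
#' by the outstar rule toward the cortical hidden pattern. Padding rows are
#' handled per `config$padding_mode`. The recorded CR for each cue is the
#' forward-pass response before that cue's weight update.
#'
#' @param model A [build_model()] model.
#' @param block A [make_block()] stimulus block.
#' @return A list with the updated `model` and `record`, a list of class
#'   `"trial_record"` carrying `per_cue_cr`, `per_cue_us`, `labels`, and
#'   the trial `errors` ([error_metrics()] over the block's cues).
#' @export
run_trial <- function(model, block) {
  stopifnot(inherits(model, "ch_model"), inherits(block, "stimulus_block"))
  run_trial_prepared(model, prepare_block(block, model$config))
}

# Rotated-phase encodings and presentation plan for a block, computed once
# per phase so the trial loop does no redundant trigonometry.
prepare_block <- function(block, config) {
  p_mat <- apply(rbind(block$cs_a, block$cs_b, block$ctx_x, block$ctx_y),
                 2, function(col) encode_input(col)$p_tilde)
  list(p_mat = p_mat, us = block$us, labels = block$label,
       is_padding = block$is_padding)
}

run_trial_prepared <- function(model, prep) {
  cfg <- model$config
  n <- length(prep$us)
  keep <- !prep$is_padding
  crs <- numeric(sum(keep))
  k <- 0L
  for (i in seq_len(n)) {
    if (prep$is_padding[i]) {
      if (cfg$padding_mode == "skip") next
      if (cfg$padding_mode == "forward") {
        fw_h <- aqinn_forward(model$aqinn, prep$p_mat[, i], cfg$delta)
        ffqinn_forward(model$ffqinn, prep$p_mat[, i],
                       link_contribution(model, fw_h$a_h1), cfg$delta)
        next
      }
      # padding_mode == "train": fall through and train with US = 0
    }
    p <- prep$p_mat[, i]
    hip <- aqinn_train_step(model$aqinn, p, cfg)
    model$aqinn <- hip$state
    li <- link_contribution(model, hip$a_h1)
    ctx <- ffqinn_train_step(model$ffqinn, p, prep$us[i], li, cfg)
    model$ffqinn <- ctx$state
    if (model$link$present && !model$link$frozen) {
      model$link$W_link <- outstar_update(model$link$W_link, pre = hip$a_h1,
                                          target_pattern = ctx$a_c1,
                                          mu = cfg$mu_hippocampal)
    }
    if (!prep$is_padding[i]) {
      k <- k + 1L
      crs[k] <- ctx$cr
    }
  }
  record <- structure(list(per_cue_cr = crs, per_cue_us = prep$us[keep],
                           labels = prep$labels[keep],
                           errors = error_metrics(crs, prep$us[keep])),
                      class = "trial_record")
  list(model = model, record = record)
}

#' Has a trial reached the learning criterion?
#'
#' True when every non-padding cue's conditioned response lies within
#' `epsilon` of its US target.
#'
#' @param record A `trial_record` from [run_trial()].
#' @param epsilon Convergence tolerance.
#' @return Logical.
#' @examples
#' rec <- structure(list(per_cue_cr = 0.951, per_cue_us = 1),
#'                  class = "trial_record")
#' has_converged(rec, 0.05)  # TRUE: |1 - 0.951| <= 0.05
#' @export
has_converged <- function(record, epsilon = 0.05) {
  stopifnot(inherits(record, "trial_record"))
  all(abs(record$per_cue_cr - record$per_cue_us) <= epsilon)
}

#' Run one learning phase to criterion
#'
#' Presents the phase's stimulus block repeatedly until [has_converged()]
#' holds on `config$persistence` consecutive trials or `config$max_trials`
#' is reached; non-convergence reports the cap as a sentinel, never an
#' error. Weights and intervals persist across trials (and into any
#' following phase).
#'
#' @param model A [build_model()] model.
#' @param contingencies List of [stimulus_cue()] contingencies for the phase.
#' @param config A [learning_config()]; defaults to the model's own.
#' @return A list with the updated `model`, `trials_to_criterion` (first
#'   satisfying trial index, or the `max_trials` sentinel), `converged`,
#'   and `curve` — a data frame with one row per (trial, cue).
#' @export
run_phase <- function(model, contingencies, config = model$config) {
  stopifnot(inherits(model, "ch_model"))
  block <- make_block(contingencies, seed = model$seed)
  prep <- prepare_block(block, config)
  n_cues <- sum(!prep$is_padding)
  cr_curve <- vector("list", config$max_trials)
  streak <- 0L
  trials <- config$max_trials
  converged <- FALSE
  last <- config$max_trials
  for (t in seq_len(config$max_trials)) {
    step <- run_trial_prepared(model, prep)
    model <- step$model
    rec <- step$record
    cr_curve[[t]] <- rec$per_cue_cr
    if (has_converged(rec, config$epsilon)) {
      streak <- streak + 1L
      if (streak >= config$persistence) {
        trials <- t - config$persistence + 1L
        converged <- TRUE
        last <- t
        break
      }
    } else {
      streak <- 0L
    }
  }
  labels <- prep$labels[!prep$is_padding]
  us <- prep$us[!prep$is_padding]
  curve <- data.frame(
    trial = rep(seq_len(last), each = n_cues),
    cue = rep(labels, last),
    cr = unlist(cr_curve[seq_len(last)]),
    us = rep(us, last),
    stringsAsFactors = FALSE)
  list(model = model, trials_to_criterion = trials, converged = converged,
       curve = curve)
}

#' Run a task (all phases, weights carried over)
#'
#' Runs the task's phases in order on one model instance; nothing is reset
#' between phases, which is what lets pre-exposure, blocking, and
#' preconditioning effects build up. `skip_phases` omits the listed phases
#' (used for control runs, e.g. blocking without its pre-training phase).
#'
#' @param task A [task_spec()].
#' @param mode `"intact"` or `"lesioned"`.
#' @param config A [learning_config()].
#' @param seed Integer seed for the model initialization.
#' @param skip_phases Integer indices of phases to omit.
#' @return A list of class `"run_result"` with `task`, `mode`, `seed`,
#'   `phases_run`, `per_phase_trials`, `per_phase_converged`, and `curves`
#'   (one data frame per phase run).
#' @examples
#' \donttest{
#' res <- run_task(task_battery()$a_minus, "intact", seed = 1)
#' res$per_phase_trials
#' }
#' @export
run_task <- function(task, mode = c("intact", "lesioned"),
                     config = learning_config(), seed = 1L,
                     skip_phases = integer(0)) {
  stopifnot(inherits(task, "task_spec"))
  mode <- match.arg(mode)
  if (!mode %in% task$modes) {
    stop(sprintf("task '%s' has no %s-mode condition", task$name, mode),
         call. = FALSE)
  }
  model <- build_model(config, mode, seed)
  phases <- setdiff(seq_along(task$phases), skip_phases)
  trials <- integer(0)
  conv <- logical(0)
  curves <- list()
  for (ph in phases) {
    res <- run_phase(model, task$phases[[ph]], config)
    model <- res$model
    trials <- c(trials, res$trials_to_criterion)
    conv <- c(conv, res$converged)
    curves[[length(curves) + 1L]] <- res$curve
  }
  structure(list(task = task$name, mode = mode, seed = as.integer(seed),
                 phases_run = phases, per_phase_trials = trials,
                 per_phase_converged = conv, curves = curves,
                 model = model),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s (%s, seed %d)\n", x$task, x$mode, x$seed))
  for (i in seq_along(x$phases_run)) {
    cat(sprintf("  phase %d: %d trials%s\n", x$phases_run[i],
                x$per_phase_trials[i],
                if (x$per_phase_converged[i]) "" else " (cap reached)"))
  }
  invisible(x)
}
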