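#' Construct a stimulus cue
#'
#' One four-line input pattern: CS A, CS B, and two mutually exclusive
#' context lines X and Y, with the US target the network should learn to
#' produce. Padding cues are all-zero with US 0.
#'
#' @param cs_a Intensity of conditioned stimulus A in \[0, 1\].
#' @param cs_b Intensity of conditioned stimulus B in \[0, 1\].
#' @param ctx Context line carrying the cue: `"x"`, `"y"`, or `"none"`.
#' @param us US target in \[0, 1\].
#' @param is_padding Whether this is a zero-padding row.
#' @param label Optional cue-type label (used in curves and plots).
#' @return A list of class `"stimulus_cue"`.
#' @examples
#' stimulus_cue(cs_a = 1, ctx = "x", us = 1, label = "AX+")
#' @export
stimulus_cue <- function(cs_a = 0, cs_b = 0, ctx = c("none", "x", "y"),
                         us = 0, is_padding = FALSE, label = NULL) {
  ctx <- match.arg(ctx)
  vals <- c(cs_a, cs_b, us)
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    stop("cue intensities and US must lie in [0, 1]", call. = FALSE)
  }
  if (is_padding && (cs_a != 0 || cs_b != 0 || ctx != "none" || us != 0)) {
    stop("padding cues must be all-zero with US 0", call. = FALSE)
  }
  structure(list(cs_a = cs_a, cs_b = cs_b,
                 ctx_x = as.integer(ctx == "x"),
                 ctx_y = as.integer(ctx == "y"),
                 us = us, is_padding = is_padding,
                 label = if (is.null(label)) cue_label(cs_a, cs_b, ctx, us)
                         else label),
            class = "stimulus_cue")
}

cue_label <- function(cs_a, cs_b, ctx, us) {
  paste0(if (cs_a > 0) if (cs_a == 1) "A" else sprintf("A(%.1f)", cs_a) else "",
         if (cs_b > 0) if (cs_b == 1) "B" else sprintf("B(%.1f)", cs_b) else "",
         switch(ctx, x = "X", y = "Y", none = ""),
         if (us >= 0.5) "+" else "-")
}

cue_lines <- function(cue) {
  c(cue$cs_a, cue$cs_b, cue$ctx_x, cue$ctx_y)
}

#' Replace the CS intensity of a cue template
#'
#' Used for the graded easy/hard transfer stimuli, where the same stimulus
#' line carries different amplitudes (e.g. 0.9 vs 0.1, or 0.6 vs 0.4). The
#' intensity is applied to whichever CS line the template activates (CS A
#' when neither is active).
#'
#' @param base A [stimulus_cue()] template.
#' @param intensity New CS intensity in \[0, 1\].
#' @return The modified [stimulus_cue()].
#' @examples
#' graded_cue(stimulus_cue(cs_a = 1, ctx = "x", us = 1), 0.9)
#' @export
graded_cue <- function(base, intensity) {
  stopifnot(inherits(base, "stimulus_cue"))
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      is.na(intensity) || intensity < 0 || intensity > 1) {
    stop("intensity must lie in [0, 1]", call. = FALSE)
  }
  if (base$cs_b > 0 && base$cs_a == 0) base$cs_b <- intensity
  else base$cs_a <- intensity
  base$label <- cue_label(base$cs_a, base$cs_b,
                          if (base$ctx_x) "x" else if (base$ctx_y) "y" else "none",
                          base$us)
  base
}

padding_cue <- function() {
  stimulus_cue(is_padding = TRUE, label = "pad")
}

#' Build a stimulus block
#'
#' A block is one trial's worth of input: `n_cues` cues cycling through the
#' phase's contingencies in fixed order, each followed by a zero-padding
#' row. Construction is deterministic given its arguments; `seed` is stored
#' for provenance.
#'
#' @param contingencies A list of [stimulus_cue()] templates (cue -> US).
#' @param seed Integer stored as the block's seed.
#' @param n_cues Number of non-padding cues per block.
#' @param padded Whether to interleave a padding row after every cue.
#' @return A data frame of class `"stimulus_block"` with columns `cs_a`,
#'   `cs_b`, `ctx_x`, `ctx_y`, `us`, `is_padding`, `label`.
#' @examples
#' blk <- make_block(list(stimulus_cue(cs_a = 1, ctx = "x", us = 1)))
#' sum(!blk$is_padding)  # 10
#' @export
make_block <- function(contingencies, seed = 0L, n_cues = 10L, padded = TRUE) {
  if (!is.list(contingencies) || length(contingencies) == 0L) {
    stop("at least one contingency is required", call. = FALSE)
  }
  lapply(contingencies, function(cue) stopifnot(inherits(cue, "stimulus_cue")))
  cues <- contingencies[((seq_len(n_cues) - 1L) %% length(contingencies)) + 1L]
  if (padded) {
    rows <- vector("list", 2L * n_cues)
    rows[seq(1L, 2L * n_cues, by = 2L)] <- cues
    rows[seq(2L, 2L * n_cues, by = 2L)] <- list(padding_cue())
  } else {
    rows <- cues
  }
  df <- do.call(rbind, lapply(rows, function(cue) {
    data.frame(cs_a = cue$cs_a, cs_b = cue$cs_b, ctx_x = cue$ctx_x,
               ctx_y = cue$ctx_y, us = cue$us, is_padding = cue$is_padding,
               label = cue$label, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(df, block_seed = as.integer(seed),
            class = c("stimulus_block", "data.frame"))
}

#' Write a stimulus block to CSV
#'
#' One row per cue (padding rows included), columns `cs_a`, `cs_b`, `ctx_x`,
#' `ctx_y`, `us`, `is_padding`, `label`.
#'
#' @param block A [make_block()] block.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_block_csv <- function(block, path) {
  stopifnot(inherits(block, "stimulus_block"))
  utils::write.csv(as.data.frame(block), path, row.names = FALSE)
  invisible(path)
}

#' Define a conditioning task
#'
#' @param name Task identifier.
#' @param phases A list of phases; each phase is a list of [stimulus_cue()]
#'   contingencies presented in fixed alternation within each block.
#' @param modes Which systems the task applies to: `"intact"`,
#'   `"lesioned"`, or both.
#' @return A list of class `"task_spec"`.
#' @export
task_spec <- function(name, phases, modes = c("intact", "lesioned")) {
  stopifnot(is.character(name), length(phases) >= 1L, length(phases) <= 3L)
  modes <- match.arg(modes, several.ok = TRUE)
  lapply(phases, function(ph) lapply(ph, function(cue)
    stopifnot(inherits(cue, "stimulus_cue"))))
  structure(list(name = name, phases = phases, modes = modes),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  phase_txt <- vapply(x$phases, function(ph)
    paste(vapply(ph, `[[`, "", "label"), collapse = ", "), "")
  cat(sprintf("<task_spec> %s [%s]\n", x$name, paste(x$modes, collapse = ", ")))
  for (i in seq_along(phase_txt)) {
    cat(sprintf("  phase %d: %s\n", i, phase_txt[i]))
  }
  invisible(x)
}

cue_AX <- function(us, a = 1) stimulus_cue(cs_a = a, ctx = "x", us = us)
cue_BX <- function(us, b = 1) stimulus_cue(cs_b = b, ctx = "x", us = us)
cue_AY <- function(us) stimulus_cue(cs_a = 1, ctx = "y", us = us)
cue_ABX <- function(us) stimulus_cue(cs_a = 1, cs_b = 1, ctx = "x", us = us)

#' The thirteen-task conditioning battery
#'
#' Returns the standard battery of classical-conditioning tasks the model
#' simulates, each with its phase structure and the modes (intact /
#' lesioned) it applies to. `+` denotes CS-US pairing (US = 1), `-`
#' unpaired (US = 0); A and B are the two conditioned stimuli and X, Y the
#' two contexts. The easy-hard transfer task uses graded CS intensities
#' (0.9 vs 0.1 in the easy phase, 0.6 vs 0.4 in the hard phase).
#'
#' @param easy Intensities `c(plus, minus)` of the easy discrimination.
#' @param hard Intensities `c(plus, minus)` of the hard discrimination.
#' @return A named list of 13 [task_spec()] objects.
#' @examples
#' battery <- task_battery()
#' length(battery)             # 13
#' battery$blocking            # three phases
#' @export
task_battery <- function(easy = c(0.9, 0.1), hard = c(0.6, 0.4)) {
  list(
    a_plus = task_spec("a_plus", list(list(cue_AX(1)))),
    a_minus = task_spec("a_minus", list(list(cue_AX(0)))),
    blocking = task_spec("blocking", list(
      list(cue_AX(1)), list(cue_ABX(1)), list(cue_BX(0)))),
    stimulus_discrimination = task_spec("stimulus_discrimination", list(
      list(cue_AX(1), cue_BX(0)))),
    discrimination_reversal = task_spec("discrimination_reversal", list(
      list(cue_AX(1), cue_BX(0)), list(cue_AX(0), cue_BX(1)))),
    easy_hard_transfer = task_spec("easy_hard_transfer", list(
      list(cue_AX(1, a = easy[1]), cue_AX(0, a = easy[2])),
      list(cue_AX(1, a = hard[1]), cue_AX(0, a = hard[2])))),
    context_shift = task_spec("context_shift", list(
      list(cue_AX(1)), list(cue_AY(1)))),
    context_sensitivity_latent_inhibition = task_spec(
      "context_sensitivity_latent_inhibition",
      list(list(cue_AX(0)), list(cue_AY(1))), modes = "intact"),
    generic_feedforward = task_spec("generic_feedforward", list(
      list(cue_AX(0)), list(cue_AX(1))), modes = "lesioned"),
    sensory_preconditioning = task_spec("sensory_preconditioning", list(
      list(cue_ABX(0)), list(cue_AX(1)), list(cue_BX(0))), modes = "intact"),
    latent_inhibition = task_spec("latent_inhibition", list(
      list(cue_AX(0)), list(cue_AX(1)))),
    overshadowing = task_spec("overshadowing", list(
      list(cue_ABX(1)), list(cue_AX(1), cue_BX(1)))),
    compound_preconditioning = task_spec("compound_preconditioning", list(
      list(cue_ABX(0)), list(cue_AX(1), cue_BX(0))), modes = "intact")
  )
}

#' Serialize the task battery to JSON
#'
#' @param battery A list of [task_spec()]s, as from [task_battery()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
battery_to_json <- function(battery = task_battery(), path = NULL) {
  payload <- lapply(battery, function(task) {
    list(name = task$name, modes = task$modes,
         phases = lapply(task$phases, function(ph)
           lapply(ph, function(cue) cue[c("cs_a", "cs_b", "ctx_x", "ctx_y",
                                          "us", "label")])))
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
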