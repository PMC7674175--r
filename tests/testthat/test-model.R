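test_that("model construction is deterministic and mode-aware", {
  m1 <- build_model(seed = 7)
  m2 <- build_model(seed = 7)
  expect_identical(m1, m2)
  expect_true(m1$link$present)
  expect_equal(dim(m1$link$W_link), c(1, 16))
  les <- build_model(mode = "lesioned", seed = 7)
  expect_false(les$link$present)
  expect_null(les$link$W_link)
  # published hidden sizes
  expect_equal(m1$aqinn$n_hidden, 1L)
  expect_equal(m1$ffqinn$n_hidden, 16L)
  # identical non-link weights across modes at the same seed
  expect_identical(m1$aqinn, les$aqinn)
  expect_identical(m1$ffqinn, les$ffqinn)
})

test_that("a trial with vanishing learning rates leaves the model unchanged", {
  cfg <- learning_config(mu_hippocampal = 1e-300, mu_cortical = 1e-300)
  m <- build_model(cfg, seed = 1)
  blk <- make_block(list(cue_ax(1)))
  out <- run_trial(m, blk)
  expect_equal(out$model$ffqinn$W_c1, m$ffqinn$W_c1, tolerance = 1e-12)
  expect_equal(out$model$aqinn$W_h1, m$aqinn$W_h1, tolerance = 1e-12)
  expect_length(out$record$per_cue_cr, 10)
  expect_true(all(out$record$per_cue_cr > 0 & out$record$per_cue_cr < 1))
})

test_that("intact model with a zeroed link reproduces the lesioned model exactly", {
  blk <- make_block(list(cue_ax(1), cue_bx(0)))
  intact <- build_model(seed = 5)
  intact$link$W_link[] <- 0
  intact$link$frozen <- TRUE
  lesioned <- build_model(mode = "lesioned", seed = 5)
  for (t in 1:5) {
    si <- run_trial(intact, blk)
    sl <- run_trial(lesioned, blk)
    intact <- si$model
    lesioned <- sl$model
    expect_identical(si$record$per_cue_cr, sl$record$per_cue_cr)
    expect_identical(intact$ffqinn, lesioned$ffqinn)
    expect_identical(intact$aqinn, lesioned$aqinn)
  }
})

test_that("run_trial equals the documented composition of module steps", {
  cfg <- learning_config()
  m <- build_model(cfg, mode = "intact", seed = 9)
  blk <- make_block(list(cue_ax(1)))
  out <- run_trial(m, blk)

  ref <- m
  crs <- numeric(0)
  for (i in which(!blk$is_padding)) {
    p <- encode_input(c(blk$cs_a[i], blk$cs_b[i], blk$ctx_x[i],
                        blk$ctx_y[i]))$p_tilde
    hip <- aqinn_train_step(ref$aqinn, p, cfg)
    ref$aqinn <- hip$state
    li <- drop(crossprod(ref$link$W_link, hip$a_h1))
    ctx <- ffqinn_train_step(ref$ffqinn, p, blk$us[i], li, cfg)
    ref$ffqinn <- ctx$state
    ref$link$W_link <- outstar_update(ref$link$W_link, pre = hip$a_h1,
                                      target_pattern = ctx$a_c1,
                                      mu = cfg$mu_hippocampal)
    crs <- c(crs, ctx$cr)
  }
  expect_equal(out$record$per_cue_cr, crs, tolerance = 1e-14)
  expect_equal(out$model$ffqinn, ref$ffqinn, tolerance = 1e-14)
  expect_equal(out$model$link$W_link, ref$link$W_link, tolerance = 1e-14)
})

test_that("padding modes are observationally consistent", {
  blk <- make_block(list(cue_ax(1)))
  m_fwd <- build_model(learning_config(padding_mode = "forward"), seed = 3)
  m_skip <- build_model(learning_config(padding_mode = "skip"), seed = 3)
  r_fwd <- run_trial(m_fwd, blk)
  r_skip <- run_trial(m_skip, blk)
  # forward-only padding has no learning effect
  expect_equal(r_fwd$record$per_cue_cr, r_skip$record$per_cue_cr)
  expect_equal(r_fwd$model$ffqinn$W_c2, r_skip$model$ffqinn$W_c2)
  # training on padding does change the weights
  m_tr <- build_model(learning_config(padding_mode = "train"), seed = 3)
  r_tr <- run_trial(m_tr, blk)
  expect_false(isTRUE(all.equal(r_tr$model$ffqinn$W_c2,
                                r_skip$model$ffqinn$W_c2)))
})

test_that("has_converged applies the per-cue tolerance", {
  rec <- structure(list(per_cue_cr = c(0.96, 0.02), per_cue_us = c(1, 0)),
                   class = "trial_record")
  expect_true(has_converged(rec, 0.05))
  rec$per_cue_cr <- c(0.96, 0.11)
  expect_false(has_converged(rec, 0.05))
  rec2 <- structure(list(per_cue_cr = 0.951, per_cue_us = 1),
                    class = "trial_record")
  expect_true(has_converged(rec2, 0.05))
  expect_false(has_converged(rec2, 0.04))
})

test_that("run_phase reports sentinels and first-trial convergence", {
  # unreachable criterion: sentinel equals the cap, no error
  cfg <- learning_config(epsilon = 1e-4, max_trials = 5L)
  m <- build_model(cfg, seed = 1)
  res <- run_phase(m, list(cue_ax(1)), cfg)
  expect_equal(res$trials_to_criterion, 5L)
  expect_false(res$converged)
  expect_equal(max(res$curve$trial), 5)

  # an effectively converged model reports a single trial
  cfg2 <- learning_config(epsilon = 0.49)
  m2 <- build_model(cfg2, seed = 1)
  res2 <- run_phase(m2, list(cue_ax(0)), cfg2)
  expect_equal(res2$trials_to_criterion, 1L)
  expect_true(res2$converged)
})

test_that("run_task runs phases in order with carried-over weights", {
  bat <- task_battery()
  res <- run_task(bat$a_minus, "intact", capped_cfg(80L), seed = 2)
  expect_length(res$per_phase_trials, 1)
  r1 <- run_task(bat$latent_inhibition, "lesioned", capped_cfg(80L), seed = 2)
  expect_length(r1$per_phase_trials, 2)
  expect_identical(
    r1$per_phase_trials,
    run_task(bat$latent_inhibition, "lesioned", capped_cfg(80L),
             seed = 2)$per_phase_trials)
  # skipping the pre-exposure phase must change phase-2 behaviour
  ctrl <- run_task(bat$latent_inhibition, "lesioned", capped_cfg(80L),
                   seed = 2, skip_phases = 1)
  expect_length(ctrl$per_phase_trials, 1)
  expect_error(run_task(bat$sensory_preconditioning, "lesioned"),
               "no lesioned-mode")
})

test_that("acquisition phases converge across seeds", {
  bat <- task_battery()
  trials <- vapply(1:20, function(s)
    run_task(bat$a_plus, "lesioned", capped_cfg(200L),
             seed = s)$per_phase_trials, 0L)
  expect_gte(mean(trials < 200L), 0.95)
})
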