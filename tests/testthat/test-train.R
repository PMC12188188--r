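# Training machinery: splits, early stopping, reproducibility, ensembles,
# subsampling curves and grid generation.

fast_control <- function(...) {
  defaults <- list(max_epochs = 2, batch_size = 32, learning_rate = 3e-3,
                   weight_decay = 1e-4)
  do.call(camformer_control, utils::modifyList(defaults, list(...)))
}

test_that("train/validation splits are disjoint, sized by rounding, and seed-stable", {
  recs <- data.frame(sequence = rand_seq(100, seed = 1), expression = rnorm(100))
  sp <- split_train_val(recs, 0.10, seed = 4)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$val), 10L)
  expect_length(intersect(sp$train$sequence, sp$val$sequence), 0L)
  expect_setequal(c(sp$train$sequence, sp$val$sequence), recs$sequence)
  sp2 <- split_train_val(recs, 0.10, seed = 4)
  expect_identical(sp, sp2)

  # validation size = round(n * fraction): 7 records at 0.5 -> 4 validation
  recs7 <- recs[1:7, ]
  sp7 <- split_train_val(recs7, 0.5, seed = 1)
  expect_equal(nrow(sp7$val), 4L)
  expect_equal(nrow(sp7$train), 3L)
  expect_error(split_train_val(recs[1, , drop = FALSE], 0.5), "at least 2")
})

test_that("early stopping restores the best epoch and respects max_epochs", {
  lib <- demo_library(300, seed = 2)
  fit <- camformer(lib, preset = "tiny", control = fast_control(), seed = 1)
  h <- fit$history
  expect_equal(h$epochs$val_score[h$best_epoch], max(h$epochs$val_score))
  expect_false(h$stopped_early)
  expect_equal(nrow(h$epochs), 2L)

  fit1 <- camformer(lib, preset = "tiny",
                    control = fast_control(max_epochs = 1), seed = 1)
  expect_equal(nrow(fit1$history$epochs), 1L)
  expect_false(fit1$history$stopped_early)
  # the restored weights reproduce the recorded best validation score
  vr <- correlations(fit$val_y, fit$val_pred)
  expect_equal(vr$r + vr$rho, h$epochs$val_score[h$best_epoch],
               tolerance = 1e-10)
})

test_that("constant labels are degenerate but training completes with r = 0", {
  recs <- data.frame(sequence = rand_seq(80, seed = 3), expression = rep(2, 80))
  fit <- camformer(recs, preset = "tiny",
                   control = fast_control(max_epochs = 1), seed = 1)
  expect_equal(fit$history$epochs$val_r, 0)
  expect_equal(fit$history$epochs$val_rho, 0)
})

test_that("identical data, config and seed reproduce the fit exactly", {
  lib <- demo_library(200, seed = 5)
  f1 <- camformer(lib, preset = "tiny", control = fast_control(), seed = 9)
  f2 <- camformer(lib, preset = "tiny", control = fast_control(), seed = 9)
  expect_identical(f1$history$epochs, f2$history$epochs)
  expect_identical(predict(f1, lib[1:20, ]), predict(f2, lib[1:20, ]))
  f3 <- camformer(lib, preset = "tiny", control = fast_control(), seed = 10)
  expect_false(identical(predict(f1, lib[1:20, ]), predict(f3, lib[1:20, ])))
})

test_that("alternative losses, optimizers and schedulers train without error", {
  lib <- demo_library(150, seed = 6)
  for (ctl in list(fast_control(max_epochs = 1, loss = "MSE"),
                   fast_control(max_epochs = 1, loss = "Huber"),
                   fast_control(max_epochs = 1, optimizer = "Lion",
                                learning_rate = 3e-4),
                   fast_control(scheduler = "step", step_size = 1),
                   fast_control(scheduler = "cosine"))) {
    fit <- camformer(lib, preset = "tiny", control = ctl, seed = 2)
    expect_true(all(is.finite(fit$history$epochs$train_loss)))
  }
  # scheduler closed forms
  ctl <- camformer_control(learning_rate = 0.1, scheduler = "step",
                           step_size = 2, step_gamma = 0.5, max_epochs = 10)
  expect_equal(scheduled_lr(ctl, 1), 0.1)
  expect_equal(scheduled_lr(ctl, 3), 0.05)
  expect_equal(scheduled_lr(ctl, 5), 0.025)
  ctl2 <- camformer_control(learning_rate = 0.1, scheduler = "cosine",
                            max_epochs = 11)
  expect_equal(scheduled_lr(ctl2, 1), 0.1)
  expect_equal(scheduled_lr(ctl2, 6.5), 0.05, tolerance = 0.011)
})

test_that("ensemble averaging is the elementwise mean", {
  expect_identical(ensemble_predict(list(c(1, 2, 3))), c(1, 2, 3))
  v <- rnorm(5)
  expect_equal(ensemble_predict(list(v, -v)), rep(0, 5))
  expect_equal(ensemble_predict(list(rep(1, 4), rep(2, 4), rep(3, 4))),
               rep(2, 4))
  expect_error(ensemble_predict(list(1:3, 1:4)), "same length")
})

test_that("subsampling curves use nested subsets and a fixed holdout", {
  lib <- demo_library(400, seed = 8)
  ctl <- fast_control(max_epochs = 1)
  tab <- subsample_curve(lib, c(0.25, 1), preset = "tiny", control = ctl,
                         seed = 3)
  expect_equal(tab$fraction, c(0.25, 1))
  expect_equal(tab$n_train, c(floor(320 * 0.25), 320L))
  # a run at fraction 1 equals a plain train/eval run on the same pool
  set.seed(3)
  hold_idx <- sample.int(400, 80)
  pool <- lib[-hold_idx, ]
  fit <- camformer(pool, preset = "tiny", control = ctl, seed = 3)
  pred <- predict(fit, lib[hold_idx, ])
  expect_equal(tab$r[2], as.numeric(safe_cor(lib$expression[hold_idx], pred)))
  expect_error(subsample_curve(lib, 0.01, preset = "tiny", control = ctl),
               "batch_size")
})

test_that("grid generation is the full Cartesian product in lexicographic order", {
  g1 <- generate_grid(list(encoding = "onehot"), structures = "tiny")
  expect_equal(nrow(g1), 1L)
  g4 <- generate_grid(list(encoding = c("onehot", "onehotWithN"),
                           loss = c("L1", "MSE")), structures = "tiny")
  expect_equal(nrow(g4), 4L)
  # last axis varies fastest, first (structure) slowest
  expect_equal(g4$encoding, c("onehot", "onehot", "onehotWithN", "onehotWithN"))
  expect_equal(g4$loss, c("L1", "MSE", "L1", "MSE"))

  g <- generate_grid()
  expect_equal(nrow(g), 270L)
  expect_equal(unname(table(g$structure)[unique(g$structure)]),
               array(rep(90L, 3)))
  expect_identical(g, generate_grid()) # deterministic
  expect_error(generate_grid(list(encoding = character(0))), "non-empty")
})
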