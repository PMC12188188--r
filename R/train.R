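# Training: minibatch gradient descent with the L1/MSE/Huber losses, AdamW or
# Lion, optional learning-rate schedules, and early stopping on validation
# r + rho with best-epoch weight restoration. Plus seed ensembles, nested
# subsampling curves and grid-search configuration generation.

#' Training control parameters
#'
#' @param loss one of `"L1"` (mean absolute error, the default used for noisy
#'   binned expression labels), `"MSE"`, `"Huber"`.
#' @param optimizer `"AdamW"` or `"Lion"`.
#' @param learning_rate base learning rate.
#' @param weight_decay decoupled weight decay (applied to weight matrices
#'   only).
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs (default 50).
#' @param val_fraction fraction of the training data held out for validation
#'   and early stopping (default 0.10; 0.08 matches the competition-era
#'   protocol).
#' @param patience epochs without validation `r+rho` improvement before
#'   stopping (default 5).
#' @param scheduler learning-rate schedule: `"none"`, `"step"` (multiply by
#'   `step_gamma` every `step_size` epochs) or `"cosine"` (anneal to 0 over
#'   `max_epochs`).
#' @param step_size,step_gamma step-schedule parameters.
#' @param huber_delta transition point of the Huber loss.
#' @return list of class `camformer_control`.
#' @export
camformer_control <- function(loss = c("L1", "MSE", "Huber"),
                              optimizer = c("AdamW", "Lion"),
                              learning_rate = 1e-3,
                              weight_decay = 1e-2,
                              batch_size = 128L,
                              max_epochs = 50L,
                              val_fraction = 0.10,
                              patience = 5L,
                              scheduler = c("none", "step", "cosine"),
                              step_size = 10L,
                              step_gamma = 0.1,
                              huber_delta = 1) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  scheduler <- match.arg(scheduler)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must be in (0, 1)", call. = FALSE)
  }
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  structure(list(loss = loss, optimizer = optimizer,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 scheduler = scheduler, step_size = as.integer(step_size),
                 step_gamma = step_gamma, huber_delta = huber_delta),
            class = "camformer_control")
}

#' Split records into training and validation sets
#'
#' Disjoint uniform random split, reproducible by seed. The validation size is
#' `round(n * val_fraction)`, clamped so both parts are non-empty.
#'
#' @param records data frame of promoter records.
#' @param val_fraction validation fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `val` (data frames) and the index
#'   vector `val_idx`.
#' @export
split_train_val <- function(records, val_fraction = 0.10, seed = 1L) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must be in (0, 1)", call. = FALSE)
  }
  n_val <- max(1L, min(n - 1L, round(n * val_fraction)))
  set.seed(seed)
  val_idx <- sort(sample.int(n, n_val))
  list(train = records[-val_idx, , drop = FALSE],
       val = records[val_idx, , drop = FALSE],
       val_idx = val_idx)
}

scheduled_lr <- function(control, epoch) {
  base <- control$learning_rate
  switch(control$scheduler,
         none = base,
         step = base * control$step_gamma^((epoch - 1L) %/% control$step_size),
         cosine = base / 2 * (1 + cos(pi * (epoch - 1L) / control$max_epochs)))
}

# Core loop over an already-encoded engine tensor. Assumes the RNG has been
# seeded by the caller; shuffling and dropout draw from it.
train_model <- function(model, x_train, y_train, x_val, y_val, control) {
  n <- length(y_train)
  if (n < 1L) stop("empty training set", call. = FALSE)
  opt <- opt_init(model$par, control$optimizer)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_r = numeric(0), val_rho = numeric(0),
                        val_score = numeric(0), lr = numeric(0))
  best_score <- -Inf
  best_epoch <- 0L
  best_par <- model$par
  best_state <- model$state
  stale <- 0L
  stopped_early <- FALSE

  for (epoch in seq_len(control$max_epochs)) {
    lr <- scheduled_lr(control, epoch)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = control$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, n)]
      xb <- x_train[, idx, , drop = FALSE]
      yb <- y_train[idx]
      fw <- nn_forward(model, xb, train = TRUE, keep_cache = TRUE)
      model$state <- fw$new_state
      lv <- loss_value(fw$pred, yb, control$loss, control$huber_delta)
      if (!is.finite(lv)) {
        stop(sprintf("non-finite %s loss at epoch %d (learning rate %.3g); lower the learning rate",
                     control$loss, epoch, lr), call. = FALSE)
      }
      epoch_loss <- epoch_loss + lv * length(idx)
      dpred <- loss_grad(fw$pred, yb, control$loss, control$huber_delta)
      bw <- nn_backward(model, fw$cache, dpred)
      stepped <- opt_step(model$par, bw$grads, opt, lr,
                          control$weight_decay, control$optimizer,
                          model$trainable)
      model$par <- stepped$par
      opt <- stepped$state
    }
    val_pred <- nn_predict(model, x_val)
    val_r <- as.numeric(safe_cor(y_val, val_pred))
    val_rho <- as.numeric(safe_cor(y_val, val_pred, method = "spearman"))
    score <- val_r + val_rho
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                val_r = val_r, val_rho = val_rho,
                                val_score = score, lr = lr))
    if (score > best_score) {
      best_score <- score
      best_epoch <- epoch
      best_par <- model$par
      best_state <- model$state
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= control$patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  model$par <- best_par
  model$state <- best_state
  list(model = model,
       history = structure(list(epochs = history, best_epoch = best_epoch,
                                stopped_early = stopped_early),
                           class = "train_history"))
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs, best epoch %d (val r+rho = %.4f)%s\n",
              nrow(x$epochs), x$best_epoch,
              x$epochs$val_score[x$best_epoch],
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' Fit a residual convolutional sequence-to-expression model
#'
#' The main fitting function: encodes standardized promoter sequences under
#' the chosen scheme, splits off a validation set, trains the network by
#' minibatch gradient descent on the chosen loss, monitors Pearson + Spearman
#' correlation (`r+rho`) on the validation set each epoch, and restores the
#' weights of the best epoch.
#'
#' @param data data frame with columns `sequence` (length-110 standardized
#'   promoters over A,C,G,T,N) and `expression` (real-valued, e.g. weighted
#'   mean expression bin), plus optional `support` for uncertainty encodings.
#'   Apply [filter_standardize()] first for raw tables.
#' @param preset architecture preset name (see [camformer_preset()]) or a
#'   [model_config()]. A config's `input_channels` must match the encoding.
#' @param encoding encoding scheme name or [encoding_scheme()].
#' @param control a [camformer_control()]; preset-specific training defaults
#'   fill any parameters not explicitly set when `control` is `NULL`.
#' @param seed integer seed governing the split, weight initialization,
#'   shuffling and dropout; identical data + config + seed reproduce the fit
#'   exactly.
#' @param validation optional pre-made validation data frame; when supplied,
#'   no internal split is made and `data` is used for training in full.
#' @return an object of class `camformer` with components `model` (the
#'   trained network), `scheme`, `control`, `history` (per-epoch losses and
#'   validation correlations, best epoch, early-stop flag), `fitted` (in-sample
#'   predictions of the restored model), `y`, and the validation predictions.
#' @examples
#' \donttest{
#' spec <- library_spec(n = 400, motifs = list(
#'   motif_spec("ACT", consensus_pwm("TGACTCA"), effect = 2, plant_prob = 0.5)),
#'   seed = 7)
#' lib <- generate_library(spec)
#' fit <- camformer(lib, preset = "tiny",
#'                  control = camformer_control(max_epochs = 2), seed = 7)
#' print(fit)
#' }
#' @export
camformer <- function(data,
                      preset = "tiny",
                      encoding = "onehot",
                      control = NULL,
                      seed = 1L,
                      validation = NULL) {
  stopifnot(is.data.frame(data),
            all(c("sequence", "expression") %in% names(data)))
  scheme <- as_encoding_scheme(encoding)
  preset_name <- if (is.character(preset)) preset else NULL
  config <- if (is.character(preset)) {
    camformer_preset(preset, input_channels = scheme$channels)
  } else preset
  stopifnot(inherits(config, "model_config"))
  if (config$input_channels != scheme$channels) {
    stop(sprintf("config expects %d input channels but encoding '%s' produces %d",
                 config$input_channels, scheme$name, scheme$channels),
         call. = FALSE)
  }
  if (is.null(control)) {
    defaults <- if (!is.null(preset_name)) preset_train_defaults(preset_name) else list()
    control <- do.call(camformer_control, defaults)
  }
  stopifnot(inherits(control, "camformer_control"))

  if (is.null(validation)) {
    sp <- split_train_val(data, control$val_fraction, seed)
    train_df <- sp$train
    val_df <- sp$val
  } else {
    train_df <- data
    val_df <- validation
  }
  x_train <- batch_to_engine(encode_batch(train_df, scheme,
                                          target_len = config$input_len))
  x_val <- batch_to_engine(encode_batch(val_df, scheme,
                                        target_len = config$input_len))
  model <- build_model(config, seed = seed)
  set.seed(seed + 1L) # independent stream for shuffling/dropout
  res <- train_model(model, x_train, train_df$expression,
                     x_val, val_df$expression, control)
  fitted_vals <- nn_predict(res$model, x_train)
  val_pred <- nn_predict(res$model, x_val)
  structure(list(model = res$model, scheme = scheme, control = control,
                 preset = preset_name %||% "custom", seed = seed,
                 history = res$history,
                 fitted = fitted_vals, y = train_df$expression,
                 val_y = val_df$expression, val_pred = val_pred,
                 call = match.call()),
            class = "camformer")
}

#' Average predictions across ensemble members
#'
#' Elementwise arithmetic mean over k prediction vectors (seed-replicate
#' ensembling).
#'
#' @param prediction_vectors list of k numeric vectors of equal length.
#' @return numeric vector of means.
#' @export
ensemble_predict <- function(prediction_vectors) {
  stopifnot(is.list(prediction_vectors), length(prediction_vectors) >= 1L)
  len <- lengths(prediction_vectors)
  if (length(unique(len)) != 1L) {
    stop("all prediction vectors must have the same length", call. = FALSE)
  }
  Reduce(`+`, prediction_vectors) / length(prediction_vectors)
}

#' Training-set subsampling curve
#'
#' Fixes a held-out evaluation set, then trains one model per fraction on
#' nested subsets of the remaining data (the subset at a smaller fraction is
#' contained in every larger one) and reports held-out correlations.
#'
#' @param data promoter data frame (as for [camformer()]).
#' @param fractions numeric vector of training fractions in (0, 1].
#' @param preset,encoding,control,seed as in [camformer()].
#' @param holdout_fraction fraction held out for evaluation (default 0.2).
#' @return data frame with columns `fraction`, `n_train`, `r`, `rho`.
#' @export
subsample_curve <- function(data, fractions, preset = "tiny",
                            encoding = "onehot", control = NULL, seed = 1L,
                            holdout_fraction = 0.2) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  fractions <- sort(unique(fractions))
  set.seed(seed)
  n <- nrow(data)
  n_hold <- max(2L, round(n * holdout_fraction))
  hold_idx <- sample.int(n, n_hold)
  holdout <- data[hold_idx, , drop = FALSE]
  pool <- data[-hold_idx, , drop = FALSE]
  ord <- sample.int(nrow(pool)) # nested subsets: prefixes of one permutation
  if (is.null(control)) {
    defaults <- if (is.character(preset)) preset_train_defaults(preset) else list()
    control <- do.call(camformer_control, defaults)
  }
  out <- data.frame(fraction = numeric(0), n_train = integer(0),
                    r = numeric(0), rho = numeric(0))
  for (f in fractions) {
    m <- max(1L, floor(nrow(pool) * f))
    if (m < control$batch_size) {
      stop(sprintf("fraction %.3g yields %d examples, fewer than batch_size %d",
                   f, m, control$batch_size), call. = FALSE)
    }
    # the full fraction uses the pool in original order, so a run at
    # fractions = 1 coincides with a plain train/eval run on the pool
    sub <- if (m == nrow(pool)) pool else pool[ord[seq_len(m)], , drop = FALSE]
    fit <- camformer(sub, preset = preset, encoding = encoding,
                     control = control, seed = seed)
    pred <- predict(fit, holdout)
    out <- rbind(out, data.frame(
      fraction = f, n_train = m,
      r = as.numeric(safe_cor(holdout$expression, pred)),
      rho = as.numeric(safe_cor(holdout$expression, pred, method = "spearman"))))
  }
  out
}

#' Generate a hyperparameter grid
#'
#' Full Cartesian product of the option sets for every structure, in
#' deterministic lexicographic order (the last axis varies fastest, with
#' `structures` as the outermost axis). The default axes reproduce the
#' 90-combinations-per-structure design: 5 encodings x 3 losses x 2
#' optimizers x 3 schedulers, over 3 structures = 270 configurations.
#'
#' @param option_sets named list of option vectors; defaults to
#'   `list(encoding = <5 schemes>, loss = c("L1","MSE","Huber"),
#'   optimizer = c("AdamW","Lion"), scheduler = c("none","step","cosine"))`.
#' @param structures character vector of preset names (or list of
#'   [model_config()] objects).
#' @return data frame with one row per configuration: a `structure` column
#'   plus one column per option axis.
#' @export
generate_grid <- function(option_sets = NULL,
                          structures = c("camformer", "camformer_small",
                                         "camformer_mini")) {
  if (is.null(option_sets)) {
    option_sets <- list(encoding = names(ENCODING_CHANNELS),
                        loss = c("L1", "MSE", "Huber"),
                        optimizer = c("AdamW", "Lion"),
                        scheduler = c("none", "step", "cosine"))
  }
  if (!length(option_sets) || any(!lengths(option_sets))) {
    stop("all option sets must be non-empty", call. = FALSE)
  }
  if (!length(structures)) stop("at least one structure required", call. = FALSE)
  if (is.list(structures)) {
    labels <- vapply(seq_along(structures), function(i) {
      paste0("structure", i)
    }, character(1L))
  } else {
    labels <- structures
  }
  axes <- c(list(structure = labels), option_sets)
  # lexicographic over axis order: first axis slowest
  grid <- rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  rownames(grid) <- NULL
  grid
}
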