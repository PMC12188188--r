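# Declarative model configuration, network realization and presets.
#
# A model_config describes the architecture family: a stack of same-length
# (zero-padded) 1-D convolutions with ReLU and optional batch normalization,
# additive identity skips over two-layer blocks (a learned 1x1 projection on
# the skip path where channel counts differ), one optional max pooling along
# positions immediately before flattening, and a fully connected stack with
# dropout ending in a single scalar output per sequence.

#' Describe a residual convolutional architecture
#'
#' @param conv_channels integer vector: output channels of each conv layer.
#' @param kernel_sizes odd integer vector, one kernel width per conv layer
#'   (recycled if length 1).
#' @param residual_after integer vector of conv-layer indices at which an
#'   additive skip terminates; each skip spans exactly the two preceding conv
#'   layers, so indices must be >= 2 and at least 2 apart. A skip whose source
#'   and target channel counts differ gets a learned 1x1 projection.
#' @param batchnorm logical: batch normalization after every convolution.
#' @param maxpool logical: single max pooling along the position axis at the
#'   penultimate position, i.e. immediately before flattening.
#' @param pool_width pooling width (= stride); trailing positions that do not
#'   fill a window are dropped.
#' @param fc_dims integer vector of hidden fully connected widths (the final
#'   width-1 output layer is implicit; `integer(0)` means output directly
#'   from the flattened activations).
#' @param dropout dropout rates for the hidden fully connected layers
#'   (recycled to `length(fc_dims)`).
#' @param activation activation name; `"relu"` is the supported family.
#' @param input_channels number of input channels, matching the encoding
#'   scheme (4, 5 or 6).
#' @param input_len standardized sequence length (default 110).
#' @return an object of class `model_config`.
#' @export
model_config <- function(conv_channels,
                         kernel_sizes,
                         residual_after = integer(0),
                         batchnorm = TRUE,
                         maxpool = TRUE,
                         pool_width = 2L,
                         fc_dims = integer(0),
                         dropout = 0,
                         activation = "relu",
                         input_channels = 4L,
                         input_len = 110L) {
  conv_channels <- as.integer(conv_channels)
  ncv <- length(conv_channels)
  if (ncv < 1L) stop("at least one conv layer is required", call. = FALSE)
  kernel_sizes <- as.integer(rep_len(kernel_sizes, ncv))
  if (any(kernel_sizes %% 2L == 0L)) {
    stop("kernel sizes must be odd (same-length convolutions)", call. = FALSE)
  }
  residual_after <- sort(unique(as.integer(residual_after)))
  if (length(residual_after)) {
    if (any(residual_after < 2L) || any(residual_after > ncv)) {
      stop("residual_after indices must lie in 2..n_conv", call. = FALSE)
    }
    if (any(diff(residual_after) < 2L)) {
      stop("residual skips span two conv layers and may not overlap", call. = FALSE)
    }
  }
  fc_dims <- as.integer(fc_dims)
  if (any(dropout < 0 | dropout >= 1)) stop("dropout rates must be in [0,1)", call. = FALSE)
  dropout <- rep_len(as.numeric(dropout), length(fc_dims))
  if (!identical(activation, "relu")) {
    stop("only the ReLU activation family is supported", call. = FALSE)
  }
  if (!input_channels %in% c(4L, 5L, 6L)) {
    stop("input_channels must be 4, 5 or 6 (one of the encoding schemes)", call. = FALSE)
  }
  pool_width <- as.integer(pool_width)
  if (isTRUE(maxpool) && pool_width < 2L) stop("pool_width must be >= 2", call. = FALSE)
  structure(list(conv_channels = conv_channels, kernel_sizes = kernel_sizes,
                 residual_after = residual_after, batchnorm = isTRUE(batchnorm),
                 maxpool = isTRUE(maxpool), pool_width = pool_width,
                 fc_dims = fc_dims, dropout = dropout, activation = activation,
                 input_channels = as.integer(input_channels),
                 input_len = as.integer(input_len)),
            class = "model_config")
}

# flattened dimension entering the FC stack
flatten_dim <- function(config) {
  h <- if (config$maxpool) config$input_len %/% config$pool_width else config$input_len
  h * config$conv_channels[length(config$conv_channels)]
}

#' Realize a network from a configuration
#'
#' Allocates and initializes all trainable parameters (He initialization for
#' weights, zero biases, unit batch-norm scales) and the batch-norm running
#' statistics.
#'
#' @param config a [model_config()] or preset name (see [camformer_preset()]).
#' @param seed integer seed for the weight initialization.
#' @return an object of class `camformer_model` holding `config`, the named
#'   parameter list `par`, running statistics `state` and per-parameter
#'   `trainable` flags.
#' @export
build_model <- function(config, seed = 1L) {
  if (is.character(config)) config <- camformer_preset(config)
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  par <- list()
  state <- list()
  ncv <- length(config$conv_channels)
  cin <- config$input_channels
  for (i in seq_len(ncv)) {
    cout <- config$conv_channels[i]
    k <- config$kernel_sizes[i]
    fan_in <- k * cin
    par[[paste0("conv", i, ".W")]] <-
      matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
    par[[paste0("conv", i, ".b")]] <- numeric(cout)
    if (config$batchnorm) {
      par[[paste0("conv", i, ".gamma")]] <- rep(1, cout)
      par[[paste0("conv", i, ".beta")]] <- numeric(cout)
      state[[paste0("conv", i, ".rmean")]] <- numeric(cout)
      state[[paste0("conv", i, ".rvar")]] <- rep(1, cout)
    }
    if (i %in% config$residual_after) {
      cs <- skip_channels(config, i)
      if (cs != cout) {
        par[[paste0("proj", i, ".W")]] <-
          matrix(stats::rnorm(cs * cout, sd = sqrt(2 / cs)), cs, cout)
        par[[paste0("proj", i, ".b")]] <- numeric(cout)
      }
    }
    cin <- cout
  }
  din <- flatten_dim(config)
  for (j in seq_along(config$fc_dims)) {
    dout <- config$fc_dims[j]
    par[[paste0("fc", j, ".W")]] <-
      matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
    par[[paste0("fc", j, ".b")]] <- numeric(dout)
    din <- dout
  }
  par[["out.W"]] <- matrix(stats::rnorm(din, sd = sqrt(1 / din)), din, 1L)
  par[["out.b"]] <- 0
  trainable <- stats::setNames(rep(TRUE, length(par)), names(par))
  structure(list(config = config, par = par, state = state,
                 trainable = trainable),
            class = "camformer_model")
}

#' Count trainable parameters
#'
#' Counts every scalar in the trainable parameter arrays of a network (or of
#' the network inside a [camformer()] fit). Frozen parameters (see
#' [freeze_parameters()]) are excluded.
#'
#' @param model a `camformer_model` or `camformer` fit.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "camformer")) model <- model$model
  stopifnot(inherits(model, "camformer_model"))
  sum(vapply(names(model$par), function(nm) {
    if (isTRUE(model$trainable[[nm]])) length(model$par[[nm]]) else 0L
  }, integer(1L)))
}

#' Freeze (or unfreeze) model parameters
#'
#' @param model a `camformer_model`.
#' @param frozen logical; `TRUE` marks all parameters non-trainable.
#' @return the model with updated trainable flags.
#' @export
freeze_parameters <- function(model, frozen = TRUE) {
  stopifnot(inherits(model, "camformer_model"))
  model$trainable[] <- !frozen
  model
}

#' Built-in architecture presets
#'
#' Loads one of the preset configurations shipped with the package:
#' \describe{
#'   \item{camformer}{the full model: six conv layers at 512 channels with
#'     residual skips after layers 2, 4 and 6, penultimate max pooling and
#'     three fully connected layers; 16.6 M trainable parameters.}
#'   \item{camformer_small}{the halved-width variant: the same six-layer
#'     residual trunk at 256 channels with a reduced fully connected head;
#'     3.4 M parameters.}
#'   \item{camformer_mini}{a compact CNN without residual connections;
#'     1.4 M parameters.}
#'   \item{tiny}{a two-layer residual network (~23 k parameters) for
#'     desk-scale training on synthetic libraries.}
#' }
#'
#' @param name preset name.
#' @param input_channels input channel count to instantiate with (4, 5 or 6,
#'   matching the encoding scheme).
#' @return a [model_config()].
#' @export
camformer_preset <- function(name = c("camformer", "camformer_small",
                                      "camformer_mini", "tiny"),
                             input_channels = 4L) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".json"), package = "camformer",
                      mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_config(conv_channels = p$conv_channels,
               kernel_sizes = p$kernel_sizes,
               residual_after = p$residual_after %||% integer(0),
               batchnorm = p$batchnorm,
               maxpool = p$maxpool,
               pool_width = p$pool_width,
               fc_dims = p$fc_dims,
               dropout = p$dropout,
               input_channels = input_channels)
}

# training hyperparameters stored alongside a preset (used as camformer()
# defaults when the caller does not override them)
preset_train_defaults <- function(name) {
  path <- system.file("presets", paste0(name, ".json"), package = "camformer")
  if (!nzchar(path)) return(list())
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$train %||% list()
}

#' Predict expression with an untrained or externally trained network
#'
#' Evaluates the network in eval mode; deterministic given the weights.
#'
#' @param object a `camformer_model`.
#' @param batch an `encoded_batch` from [encode_batch()] (channel count must
#'   match the model), or a character vector of standardized sequences (then
#'   encoded with plain one-hot only if the model takes 4 channels).
#' @param batch_size internal evaluation batch size.
#' @param ... unused.
#' @return numeric vector of predicted expressions, one per sequence.
#' @export
predict.camformer_model <- function(object, batch, batch_size = 512L, ...) {
  if (is.character(batch) || is.data.frame(batch)) {
    scheme <- names(ENCODING_CHANNELS)[match(object$config$input_channels,
                                             ENCODING_CHANNELS)]
    batch <- encode_batch(batch, scheme, target_len = object$config$input_len)
  }
  x <- batch_to_engine(batch)
  nn_predict(object, x, batch_size = batch_size)
}

#' Activations of one convolutional block
#'
#' Returns the post-activation, post-residual output of the indexed conv
#' block in the tensor layout `(n, h, w = 1, c)`.
#'
#' @param model a `camformer_model` or `camformer` fit.
#' @param batch an `encoded_batch` (or sequences, as in
#'   [predict.camformer_model()]).
#' @param layer_index conv block index in `1..n_conv`.
#' @return numeric array `(n, h, 1, c)`.
#' @export
layer_output <- function(model, batch, layer_index) {
  if (inherits(model, "camformer")) {
    if (is.character(batch) || is.data.frame(batch)) {
      batch <- encode_batch(batch, model$scheme,
                            target_len = model$model$config$input_len)
    }
    model <- model$model
  }
  stopifnot(inherits(model, "camformer_model"))
  ncv <- length(model$config$conv_channels)
  if (layer_index < 1L || layer_index > ncv) {
    stop(sprintf("layer_index must be in 1..%d", ncv), call. = FALSE)
  }
  if (is.character(batch) || is.data.frame(batch)) {
    scheme <- names(ENCODING_CHANNELS)[match(model$config$input_channels,
                                             ENCODING_CHANNELS)]
    batch <- encode_batch(batch, scheme, target_len = model$config$input_len)
  }
  x <- batch_to_engine(batch)
  fw <- nn_forward(model, x, train = FALSE, keep_cache = TRUE)
  a <- fw$cache$acts[[layer_index + 1L]] # (L, n, c)
  d <- dim(a)
  out <- aperm(a, c(2L, 1L, 3L))
  dim(out) <- c(d[2L], d[1L], 1L, d[3L])
  out
}

#' @export
print.model_config <- function(x, ...) {
  ncv <- length(x$conv_channels)
  cat("Residual CNN configuration\n")
  cat(sprintf("  input: (%d, 1, %d)\n", x$input_len, x$input_channels))
  for (i in seq_len(ncv)) {
    tag <- if (i %in% x$residual_after) " +skip" else ""
    cat(sprintf("  conv%d: %d channels, kernel %d%s%s\n", i,
                x$conv_channels[i], x$kernel_sizes[i],
                if (x$batchnorm) " +bn" else "", tag))
  }
  if (x$maxpool) cat(sprintf("  maxpool: width %d\n", x$pool_width))
  cat(sprintf("  flatten: %d\n", flatten_dim(x)))
  for (j in seq_along(x$fc_dims)) {
    cat(sprintf("  fc%d: %d units (dropout %.2f)\n", j, x$fc_dims[j], x$dropout[j]))
  }
  cat("  out: 1\n")
  invisible(x)
}

#' @export
print.camformer_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("Trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save a model or fit to a single-file checkpoint
#'
#' The checkpoint holds the configuration and all weights; loading it
#' reconstructs an eval-identical model.
#'
#' @param object a `camformer_model` or `camformer` fit.
#' @param path checkpoint file path.
#' @return invisibly, `path`.
#' @export
save_camformer <- function(object, path) {
  stopifnot(inherits(object, c("camformer_model", "camformer")))
  saveRDS(object, path)
  invisible(path)
}

#' Load a checkpoint written by [save_camformer()]
#'
#' @param path checkpoint file path.
#' @return the saved `camformer_model` or `camformer` fit.
#' @export
load_camformer <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("camformer_model", "camformer"))) {
    stop("file is not a camformer checkpoint", call. = FALSE)
  }
  obj
}
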