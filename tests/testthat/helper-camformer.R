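# Shared fixtures: all built in code at test time.

# uniform random promoter-like sequences
rand_seq <- function(n, L = 110L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L))
}

# a small but structurally complete config (residual + projection skip,
# batchnorm, pooling, one hidden FC layer)
small_config <- function(input_len = 110L, input_channels = 4L) {
  model_config(conv_channels = c(8L, 8L), kernel_sizes = c(5L, 5L),
               residual_after = 2L, batchnorm = TRUE, maxpool = TRUE,
               pool_width = 5L, fc_dims = 16L, dropout = 0,
               input_channels = input_channels, input_len = input_len)
}

# exactly linear sequence model: prediction = sum_p W[base at p, p];
# closed-form oracle for ISM and grouped profiles
linear_predictor <- function(W) {
  force(W)
  function(seqs) {
    vapply(seqs, function(s) {
      b <- strsplit(s, "", fixed = TRUE)[[1L]]
      idx <- match(b, c("A", "C", "G", "T"))
      keep <- !is.na(idx)
      sum(W[cbind(idx[keep], which(keep))])
    }, numeric(1L), USE.NAMES = FALSE)
  }
}

# independent closed-form trainable-parameter count for a model_config,
# mirroring the architecture contract (not the builder's bookkeeping)
closed_form_count <- function(cfg) {
  ncv <- length(cfg$conv_channels)
  total <- 0L
  cin <- cfg$input_channels
  for (i in seq_len(ncv)) {
    cout <- cfg$conv_channels[i]
    total <- total + cfg$kernel_sizes[i] * cin * cout + cout
    if (cfg$batchnorm) total <- total + 2L * cout
    if (i %in% cfg$residual_after) {
      cs <- if (i <= 2L) cfg$input_channels else cfg$conv_channels[i - 2L]
      if (cs != cout) total <- total + cs * cout + cout
    }
    cin <- cout
  }
  h <- if (cfg$maxpool) cfg$input_len %/% cfg$pool_width else cfg$input_len
  d <- h * cfg$conv_channels[ncv]
  for (dd in cfg$fc_dims) {
    total <- total + d * dd + dd
    d <- dd
  }
  total + d + 1L
}

# random valid config generator for property tests
random_config <- function(seed) {
  set.seed(seed)
  ncv <- sample(1:4, 1L)
  channels <- sample(c(4L, 6L, 8L, 12L, 16L), ncv, replace = TRUE)
  kernels <- sample(c(3L, 5L, 7L, 9L), ncv, replace = TRUE)
  resid <- integer(0)
  if (ncv >= 2L && runif(1) < 0.6) {
    cand <- seq(2L, ncv)
    resid <- cand[1L]
    if (length(cand) > 1L) {
      extra <- cand[cand >= resid + 2L]
      if (length(extra) && runif(1) < 0.5) resid <- c(resid, extra[1L])
    }
  }
  maxpool <- runif(1) < 0.7
  model_config(conv_channels = channels, kernel_sizes = kernels,
               residual_after = resid, batchnorm = runif(1) < 0.7,
               maxpool = maxpool,
               pool_width = if (maxpool) sample(2:6, 1L) else 2L,
               fc_dims = if (runif(1) < 0.8) sample(c(4L, 8L, 16L),
                                                    sample(0:2, 1L),
                                                    replace = TRUE) else integer(0),
               dropout = 0.1,
               input_channels = sample(c(4L, 5L, 6L), 1L),
               input_len = sample(c(30L, 110L), 1L))
}

# small synthetic library with one strong activator, reused across tests
demo_library <- function(n = 800L, seed = 42L, ...) {
  spec <- library_spec(
    n = n,
    motifs = list(motif_spec("ACT", consensus_pwm("TGACTCA"), effect = 2,
                             plant_prob = 0.5)),
    cells_per_promoter = 10L, cell_noise_sd = 1, seed = seed, ...)
  generate_library(spec)
}
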