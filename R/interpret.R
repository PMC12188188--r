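# Explainability: in-silico saturation mutagenesis (ISM), ISM-logo entropy,
# Grad-CAM for the 1-D convolutional regression models, saliency averaging
# and flattened activation embeddings.

# A model argument throughout this file may be a camformer fit, a bare
# camformer_model, or any function(sequences) -> numeric. The function form
# admits closed-form oracles (e.g. exactly linear sequence models) in tests.
as_predictor <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "camformer")) {
    return(function(seqs) predict(model, data.frame(sequence = seqs)))
  }
  if (inherits(model, "camformer_model")) {
    return(function(seqs) predict(model, seqs))
  }
  stop("model must be a camformer fit, a camformer_model, or a prediction function",
       call. = FALSE)
}

#' In-silico saturation mutagenesis
#'
#' Evaluates the model on the original promoter plus every single-base
#' substitution within the region (3 variants per non-N position; 240 for an
#' N-free 80-nt variable region) and records `delta[p, b] = f(variant) -
#' f(reference)`. The per-position importance is the negative mean of the
#' three non-reference deltas, so importance is positive where mutating away
#' from the reference lowers predicted expression. `N` positions inside the
#' region are skipped and flagged. Variant evaluation is batched internally;
#' results are independent of the batching.
#'
#' @param model a `camformer` fit, a `camformer_model`, or a function mapping
#'   a character vector of sequences to predictions.
#' @param record one promoter: a single sequence string or a one-row data
#'   frame with a `sequence` column.
#' @param region integer `(from, to)`, 1-based inclusive; default the
#'   variable region `c(18, 97)`.
#' @param batch_size number of variant sequences evaluated per model call.
#' @return object of class `ism_result`: list with `delta` (region-length x 4
#'   matrix, columns A,C,G,T, reference-base entries exactly 0, `NA` rows at
#'   skipped positions), `importance` (named vector over region positions),
#'   `reference` (the sequence), `prediction` (f(reference)), `region`,
#'   `n_variants` and `skipped` (N positions).
#' @export
ism <- function(model, record, region = c(18L, 97L), batch_size = 512L) {
  f <- as_predictor(model)
  seq1 <- if (is.data.frame(record)) record$sequence[1L] else record[1L]
  L <- nchar(seq1)
  if (region[1L] < 1L || region[2L] > L || region[1L] > region[2L]) {
    stop("region out of bounds", call. = FALSE)
  }
  pos <- region[1L]:region[2L]
  np <- length(pos)
  chars <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  ref <- chars[pos]
  skipped <- pos[ref == "N"]

  variants <- character(0)
  vpos <- integer(0)
  vbase <- character(0)
  for (i in seq_len(np)) {
    if (ref[i] == "N") next
    for (b in setdiff(DNA_BASES, ref[i])) {
      v <- chars
      v[pos[i]] <- b
      variants <- c(variants, paste(v, collapse = ""))
      vpos <- c(vpos, pos[i])
      vbase <- c(vbase, b)
    }
  }
  f0 <- f(seq1)
  preds <- numeric(length(variants))
  if (length(variants)) {
    starts <- seq(1L, length(variants), by = batch_size)
    for (s in starts) {
      e <- min(s + batch_size - 1L, length(variants))
      preds[s:e] <- f(variants[s:e])
    }
  }
  delta <- matrix(0, np, 4L, dimnames = list(pos, DNA_BASES))
  if (length(skipped)) delta[as.character(skipped), ] <- NA_real_
  delta[cbind(match(vpos, pos), match(vbase, DNA_BASES))] <- preds - f0
  importance <- stats::setNames(rep(NA_real_, np), pos)
  ok <- !(pos %in% skipped)
  if (any(ok)) {
    nonref <- delta[ok, , drop = FALSE]
    # mean over the 3 non-reference bases; the reference entry is 0 by
    # construction, so sum/3 is exact
    importance[ok] <- -rowSums(nonref) / 3
  }
  structure(list(delta = delta, importance = importance, reference = seq1,
                 prediction = f0, region = region,
                 n_variants = length(variants), skipped = skipped),
            class = "ism_result")
}

#' @export
print.ism_result <- function(x, ...) {
  cat(sprintf("ISM result: %d variants over positions %d-%d%s\n",
              x$n_variants, x$region[1L], x$region[2L],
              if (length(x$skipped)) sprintf(" (%d N positions skipped)",
                                             length(x$skipped)) else ""))
  top <- order(abs(x$importance), decreasing = TRUE)[1:5]
  cat("  top positions by |importance|:",
      paste(sprintf("%s (%.3g)", names(x$importance)[top],
                    x$importance[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Entropy of an ISM importance profile
#'
#' Normalizes the absolute per-position importances to a probability vector
#' and returns its Shannon entropy. Low entropy means the importance is
#' concentrated at few positions, the signature of a sequence carrying
#' distinct regulatory motifs; the maximum, `log(region length)`, corresponds
#' to a perfectly flat profile.
#'
#' @param result an [ism()] result (or a bare numeric importance vector).
#' @param base logarithm base; default natural log.
#' @return entropy (real, >= 0). An all-zero profile returns the maximum
#'   `log(length)` with attribute `flat = TRUE`.
#' @export
ism_entropy <- function(result, base = exp(1)) {
  imp <- if (inherits(result, "ism_result")) result$importance else result
  imp <- imp[!is.na(imp)]
  if (!length(imp)) stop("no non-NA importance values", call. = FALSE)
  a <- abs(imp)
  tot <- sum(a)
  if (tot == 0) {
    return(structure(log(length(a), base = base), flat = TRUE))
  }
  p <- a / tot
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Grad-CAM saliency maps for a convolutional layer
#'
#' For each sequence, the channel weights are the position-averaged gradients
#' of the scalar output with respect to the layer's feature map; the map is
#' the rectified channel-weighted sum of the feature map, linearly
#' interpolated to input coordinates (length 110). For a regression model the
#' raw scalar output plays the role of the class score.
#'
#' @param model a `camformer` fit or `camformer_model` (a differentiable
#'   network is required).
#' @param batch an `encoded_batch`, data frame or character vector of
#'   standardized sequences.
#' @param layer_index conv block index in `1..n_conv`.
#' @return object of class `gradcam_maps`: list with `scores` (matrix
#'   `input_len x n` of nonnegative saliency), `layer`, `ids`.
#' @export
gradcam <- function(model, batch, layer_index) {
  if (is.function(model)) {
    stop("gradcam needs a differentiable network, not a bare prediction function",
         call. = FALSE)
  }
  if (inherits(model, "camformer")) {
    if (!inherits(batch, "encoded_batch")) {
      batch <- encode_batch(batch, model$scheme,
                            target_len = model$model$config$input_len)
    }
    model <- model$model
  }
  stopifnot(inherits(model, "camformer_model"))
  cfg <- model$config
  ncv <- length(cfg$conv_channels)
  if (layer_index < 1L || layer_index > ncv) {
    stop(sprintf("layer_index must be in 1..%d", ncv), call. = FALSE)
  }
  if (!inherits(batch, "encoded_batch")) {
    scheme <- names(ENCODING_CHANNELS)[match(cfg$input_channels,
                                             ENCODING_CHANNELS)]
    batch <- encode_batch(batch, scheme, target_len = cfg$input_len)
  }
  ids <- seq_len(batch$n)
  x <- batch_to_engine(batch)
  n <- dim(x)[2L]
  if (n == 0L) {
    return(structure(list(scores = matrix(0, cfg$input_len, 0L),
                          layer = layer_index, ids = integer(0)),
                     class = "gradcam_maps"))
  }
  fw <- nn_forward(model, x, train = FALSE, keep_cache = TRUE)
  # gradient of the sum of per-sequence outputs: sequences are independent in
  # eval mode, so this yields each sequence's own gradient
  bw <- nn_backward(model, fw$cache, rep(1, n))
  A <- fw$cache$acts[[layer_index + 1L]]   # (L, n, c)
  G <- bw$dact[[layer_index + 1L]]
  L <- dim(A)[1L]; ch <- dim(A)[3L]
  wm <- apply(G, c(2L, 3L), mean)          # (n, c) channel weights
  dim(wm) <- c(n, ch)
  raw <- matrix(0, L, n)
  for (cix in seq_len(ch)) {
    raw <- raw + A[, , cix, drop = TRUE] * rep(wm[, cix], each = L)
  }
  raw[raw < 0] <- 0
  if (L != cfg$input_len) {
    up <- matrix(0, cfg$input_len, n)
    xin <- seq(1, cfg$input_len, length.out = L)
    for (i in seq_len(n)) {
      up[, i] <- stats::approx(xin, raw[, i], xout = seq_len(cfg$input_len))$y
    }
    raw <- up
  }
  structure(list(scores = raw, layer = layer_index, ids = ids),
            class = "gradcam_maps")
}

#' @export
print.gradcam_maps <- function(x, ...) {
  cat(sprintf("Grad-CAM maps: layer %d, %d sequences, length %d\n",
              x$layer, ncol(x$scores), nrow(x$scores)))
  invisible(x)
}

#' Position-wise mean saliency
#'
#' Averages Grad-CAM maps position-wise across sequences. Maps from different
#' layers may not be mixed.
#'
#' @param maps a `gradcam_maps` object or a list of them (same layer).
#' @return numeric vector of length `input_len`.
#' @export
average_saliency <- function(maps) {
  if (inherits(maps, "gradcam_maps")) maps <- list(maps)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1L), "gradcam_maps")))
  layers <- vapply(maps, `[[`, numeric(1L), "layer")
  if (length(unique(layers)) != 1L) {
    stop("cannot average saliency maps from different layers", call. = FALSE)
  }
  all_scores <- do.call(cbind, lapply(maps, `[[`, "scores"))
  if (ncol(all_scores) == 0L) stop("no maps to average", call. = FALSE)
  rowMeans(all_scores)
}

#' Flattened activation embedding of a convolutional layer
#'
#' Flattens each sequence's `(h, w, c)` layer output to a vector of length
#' `d = h * w * c`; rows follow batch order. Feed the matrix to any embedding
#' or clustering routine (e.g. t-SNE, PCA).
#'
#' @param model a `camformer` fit or `camformer_model`.
#' @param batch an `encoded_batch`, data frame or character vector.
#' @param layer_index conv block index.
#' @return numeric matrix `(n, d)`.
#' @export
activation_embedding <- function(model, batch, layer_index) {
  a <- layer_output(model, batch, layer_index) # (n, h, 1, c)
  d <- dim(a)
  out <- matrix(0, d[1L], d[2L] * d[3L] * d[4L])
  for (i in seq_len(d[1L])) out[i, ] <- as.vector(a[i, , , ])
  out
}
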