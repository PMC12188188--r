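# S3 methods for the fitted model object.

#' Predict expression for new promoters
#'
#' @param object a `camformer` fit.
#' @param newdata data frame with a `sequence` column (and `support` for
#'   uncertainty encodings), a character vector of standardized sequences, or
#'   an `encoded_batch` made with the fit's scheme.
#' @param batch_size internal evaluation batch size.
#' @param ... unused.
#' @return numeric vector of predicted expressions.
#' @export
predict.camformer <- function(object, newdata, batch_size = 512L, ...) {
  if (missing(newdata)) return(object$fitted)
  batch <- if (inherits(newdata, "encoded_batch")) {
    if (newdata$scheme$name != object$scheme$name) {
      stop(sprintf("batch encoded with scheme '%s' but the model was fitted with '%s'",
                   newdata$scheme$name, object$scheme$name), call. = FALSE)
    }
    newdata
  } else {
    encode_batch(newdata, object$scheme,
                 target_len = object$model$config$input_len)
  }
  nn_predict(object$model, batch_to_engine(batch), batch_size = batch_size)
}

#' @export
print.camformer <- function(x, ...) {
  h <- x$history
  cat("Residual convolutional sequence-to-expression model\n")
  cat(sprintf("  preset: %s | encoding: %s (%d channels) | %s parameters\n",
              x$preset, x$scheme$name, x$scheme$channels,
              format(count_parameters(x$model), big.mark = ",")))
  cat(sprintf("  loss: %s | optimizer: %s | trained %d epochs (best %d%s)\n",
              x$control$loss, x$control$optimizer, nrow(h$epochs),
              h$best_epoch, if (h$stopped_early) ", early stop" else ""))
  cat(sprintf("  validation: r = %.4f, rho = %.4f\n",
              h$epochs$val_r[h$best_epoch], h$epochs$val_rho[h$best_epoch]))
  invisible(x)
}

#' @export
summary.camformer <- function(object, ...) {
  h <- object$history
  train_cor <- correlations(object$y, object$fitted)
  val_cor <- correlations(object$val_y, object$val_pred)
  out <- list(preset = object$preset, scheme = object$scheme$name,
              n_parameters = count_parameters(object$model),
              n_train = length(object$y), n_val = length(object$val_y),
              epochs = nrow(h$epochs), best_epoch = h$best_epoch,
              stopped_early = h$stopped_early,
              train = train_cor, validation = val_cor,
              history = h$epochs)
  class(out) <- "summary.camformer"
  out
}

#' @export
print.summary.camformer <- function(x, ...) {
  cat("Residual convolutional sequence-to-expression model\n")
  cat(sprintf("  preset %s, encoding %s, %s parameters\n", x$preset, x$scheme,
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  %d training / %d validation sequences, %d epochs (best %d%s)\n",
              x$n_train, x$n_val, x$epochs, x$best_epoch,
              if (x$stopped_early) ", early stop" else ""))
  cat(sprintf("  training:   r = %.4f, r2 = %.4f, rho = %.4f\n",
              x$train$r, x$train$r2, x$train$rho))
  cat(sprintf("  validation: r = %.4f, r2 = %.4f, rho = %.4f\n",
              x$validation$r, x$validation$r2, x$validation$rho))
  invisible(x)
}

#' @export
fitted.camformer <- function(object, ...) object$fitted

#' @export
residuals.camformer <- function(object, ...) object$y - object$fitted

#' Model coefficients (network weights)
#'
#' Returns the named list of trainable parameter arrays; mostly useful for
#' inspection (e.g. viewing first-layer kernels as position weight matrices).
#'
#' @param object a `camformer` fit.
#' @param ... unused.
#' @return named list of numeric arrays.
#' @export
coef.camformer <- function(object, ...) object$model$par

#' Diagnostic plots for a fit
#'
#' Left: predicted vs observed expression on the validation set. Right:
#' validation r and rho per epoch with the restored best epoch marked.
#'
#' @param x a `camformer` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.camformer <- function(x, ...) {
  h <- x$history$epochs
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$val_y, x$val_pred,
                 xlab = "observed expression", ylab = "predicted expression",
                 main = "Validation predictions", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.4), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(h$epoch, h$val_r, type = "b", ylim = range(c(h$val_r, h$val_rho)),
                 xlab = "epoch", ylab = "validation correlation",
                 main = "Training history", col = "steelblue", pch = 16)
  graphics::lines(h$epoch, h$val_rho, type = "b", col = "tomato", pch = 17)
  graphics::abline(v = x$history$best_epoch, lty = 3)
  graphics::legend("bottomright", legend = c("r", "rho"),
                   col = c("steelblue", "tomato"), pch = c(16, 17), bty = "n")
  invisible(x)
}
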