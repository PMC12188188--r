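# Evaluation metrics: Pearson/Spearman correlations with degenerate-variance
# handling, per-category reports with weighted competition-style scores,
# baseline-normalized improvement, and bootstrap model comparison.

#' Pearson and Spearman correlation between truth and prediction
#'
#' Pearson `r` by the product-moment formula, `r2 = r^2`, and Spearman `rho`
#' as the Pearson correlation of average ranks. Zero variance in either
#' vector yields 0 with a `degenerate` flag rather than `NA`.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return list with elements `r`, `r2`, `rho` and logical `degenerate`.
#' @export
correlations <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least 2 observations", call. = FALSE)
  r <- safe_cor(y_true, y_pred)
  rho <- safe_cor(y_true, y_pred, method = "spearman")
  list(r = as.numeric(r), r2 = as.numeric(r)^2, rho = as.numeric(rho),
       degenerate = isTRUE(attr(r, "degenerate")) || isTRUE(attr(rho, "degenerate")))
}

#' Per-category evaluation report with weighted scores
#'
#' Computes `r`, `r2`, `rho` per promoter category and overall, plus the
#' competition-style weighted scores: `pearson_score = sum(w_c * r_c) /
#' sum(w_c)` over categories (and likewise `spearman_score` with `rho_c`).
#' Categories with fewer than 2 observations are excluded from the weighted
#' means and flagged.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param categories character/factor vector of category labels covering all
#'   observations.
#' @param weights named nonnegative weights, one per category present (names
#'   must match category labels); `NULL` means uniform.
#' @return object of class `eval_report`: list with `per_category` (data
#'   frame: category, n, r, r2, rho, weight, excluded), `overall`,
#'   `pearson_score`, `spearman_score`.
#' @export
category_report <- function(y_true, y_pred, categories, weights = NULL) {
  stopifnot(length(y_true) == length(y_pred),
            length(categories) == length(y_true))
  categories <- as.character(categories)
  cats <- unique(categories)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(cats)), cats)
  } else {
    unknown <- setdiff(names(weights), cats)
    if (length(unknown)) {
      stop(sprintf("weight given for unknown category '%s'", unknown[1L]),
           call. = FALSE)
    }
    missing_w <- setdiff(cats, names(weights))
    if (length(missing_w)) {
      stop(sprintf("no weight for category '%s'", missing_w[1L]), call. = FALSE)
    }
    if (any(weights < 0) || all(weights == 0)) {
      stop("weights must be nonnegative and not all zero", call. = FALSE)
    }
  }
  per <- do.call(rbind, lapply(cats, function(cc) {
    idx <- categories == cc
    n <- sum(idx)
    if (n < 2L) {
      data.frame(category = cc, n = n, r = NA_real_, r2 = NA_real_,
                 rho = NA_real_, weight = weights[[cc]], excluded = TRUE)
    } else {
      m <- correlations(y_true[idx], y_pred[idx])
      data.frame(category = cc, n = n, r = m$r, r2 = m$r2, rho = m$rho,
                 weight = weights[[cc]], excluded = FALSE)
    }
  }))
  use <- !per$excluded
  if (!any(use)) stop("no category has 2 or more observations", call. = FALSE)
  wsum <- sum(per$weight[use])
  overall <- correlations(y_true, y_pred)
  structure(list(per_category = per,
                 overall = overall,
                 pearson_score = sum(per$weight[use] * per$r[use]) / wsum,
                 spearman_score = sum(per$weight[use] * per$rho[use]) / wsum),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  overall: r = %.4f, r2 = %.4f, rho = %.4f\n",
              x$overall$r, x$overall$r2, x$overall$rho))
  cat(sprintf("  pearson_score = %.4f, spearman_score = %.4f\n",
              x$pearson_score, x$spearman_score))
  print(x$per_category, row.names = FALSE)
  invisible(x)
}

#' Baseline-normalized improvement in correlation
#'
#' The fraction of the remaining headroom above a baseline correlation that a
#' model closes: `(rho_model - rho_baseline) / (1 - rho_baseline)`. May be
#' negative when the model is worse than the baseline.
#'
#' @param rho_baseline baseline correlation, strictly less than 1.
#' @param rho_model model correlation.
#' @return normalized improvement (real; 1 means a perfect model).
#' @examples
#' delta_norm(0.5, 0.75) # 0.5: half the remaining headroom closed
#' @export
delta_norm <- function(rho_baseline, rho_model) {
  if (any(rho_baseline >= 1)) {
    stop("rho_baseline must be < 1 (no headroom to normalize by)", call. = FALSE)
  }
  (rho_model - rho_baseline) / (1 - rho_baseline)
}

#' Bootstrap comparison of two prediction sets
#'
#' For each of `n_boot` replicates, resamples observation indices with
#' replacement and computes Pearson and Spearman correlations for both
#' prediction vectors on the resample; a degenerate resample (zero variance)
#' is redrawn and counted. The per-replicate differences (`a - b`) are tested
#' with a paired Student's t-test.
#'
#' @param y_true observed values.
#' @param pred_a,pred_b two prediction vectors aligned with `y_true`.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer seed; the replicate index draws are reproducible.
#' @return list with `diff_r`, `diff_rho` (per-replicate differences),
#'   `mean_diff_r`, `mean_diff_rho`, `p_r`, `p_rho` (paired t-test p-values;
#'   `NA` when all differences are identical) and `n_redrawn`.
#' @export
bootstrap_compare <- function(y_true, pred_a, pred_b, n_boot = 10000L,
                              seed = 1L) {
  n <- length(y_true)
  stopifnot(length(pred_a) == n, length(pred_b) == n, n_boot >= 1L)
  set.seed(seed)
  ra <- rb <- sa <- sb <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      yt <- y_true[idx]
      if (stats::sd(yt) > 0 && stats::sd(pred_a[idx]) > 0 &&
          stats::sd(pred_b[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    rk <- rank(yt)
    ra[b] <- stats::cor(yt, pred_a[idx])
    rb[b] <- stats::cor(yt, pred_b[idx])
    sa[b] <- stats::cor(rk, rank(pred_a[idx]))
    sb[b] <- stats::cor(rk, rank(pred_b[idx]))
  }
  diff_r <- ra - rb
  diff_rho <- sa - sb
  p_of <- function(d) {
    if (stats::sd(d) == 0) return(NA_real_)
    stats::t.test(d)$p.value
  }
  list(diff_r = diff_r, diff_rho = diff_rho,
       mean_diff_r = mean(diff_r), mean_diff_rho = mean(diff_rho),
       p_r = p_of(diff_r), p_rho = p_of(diff_rho), n_redrawn = n_redrawn)
}
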