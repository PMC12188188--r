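# PWM motif logic: MEME minimal-format I/O, log-odds scanning on both
# strands, enrichment of motifs in expression extremes, pairwise
# co-occurrence expression matrices, motif feature correlations, and
# overlap-grouped ISM profiles.

#' Construct a position weight matrix
#'
#' @param name motif identifier.
#' @param probs 4 x w probability matrix, rows A,C,G,T, every column summing
#'   to 1.
#' @param background length-4 background base distribution (default uniform).
#' @param pseudocount added to the probabilities (then renormalized) before
#'   taking log-odds, so zero entries stay finite.
#' @return object of class `pwm`.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background must sum to 1", call. = FALSE)
  }
  rownames(probs) <- DNA_BASES
  structure(list(name = name, probs = probs, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$probs, 2L, which.max)], collapse = "")
  cat(sprintf("PWM '%s': width %d, consensus %s\n", x$name, ncol(x$probs), cons))
  invisible(x)
}

# log-odds score matrix (4 x w) with pseudocount regularization
pwm_logodds <- function(p) {
  q <- sweep(p$probs + p$pseudocount, 2L, colSums(p$probs + p$pseudocount), `/`)
  log(q / p$background)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections
#' (rows are positions, columns A C G T). Columns are renormalized to sum to
#' 1 exactly (MEME files round to a few decimals). A `Background letter
#' frequencies` line, when present, sets the scanning background.
#'
#' @param path MEME file path.
#' @param pseudocount pseudocount passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    fl <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fl))
    lab <- fl[is.na(vals)]
    num <- vals[!is.na(vals)]
    if (length(num) == 4L && all(c("A", "C", "G", "T") %in% lab)) {
      background <- num[match(c("A", "C", "G", "T"), lab)]
      background <- background / sum(background)
    }
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found", call. = FALSE)
  out <- list()
  for (m in motif_at) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[m:length(lines)])[1L]
    if (is.na(hdr)) stop(sprintf("motif '%s' has no letter-probability matrix", name),
                         call. = FALSE)
    hdr <- m + hdr - 1L
    wfield <- regmatches(lines[hdr], regexpr("w=\\s*\\d+", lines[hdr]))
    w <- as.integer(sub("w=\\s*", "", wfield))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4])
    }, numeric(4L), USE.NAMES = FALSE)) # w x 4, columns A C G T
    probs <- t(mat)
    cs <- colSums(probs)
    if (any(abs(cs - 1) > 0.02)) {
      stop(sprintf("motif '%s': probability rows do not sum to 1", name),
           call. = FALSE)
    }
    probs <- sweep(probs, 2L, cs, `/`)
    out[[name]] <- pwm(name, probs, background = background,
                       pseudocount = pseudocount)
  }
  out
}

#' Write motifs to a MEME minimal-format file
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, pwms[[1L]]$background),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p$probs)), con)
    for (j in seq_len(ncol(p$probs))) {
      writeLines(paste(sprintf("%.6f", p$probs[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Scan sequences for PWM occurrences
#'
#' Slides the PWM across both strands of every sequence and reports all
#' windows with log-odds score at or above the threshold. The score is the
#' sum over motif positions of `log(p/background)` with pseudocount
#' regularization; `N` positions contribute 0 (zero information). Minus
#' strand hits are windows matching the reverse complement of the motif;
#' their `start` is still the leftmost position on the forward sequence.
#'
#' @param sequences character vector of standardized sequences, a data frame
#'   with a `sequence` column, or a single string. Names (or row names) are
#'   used as sequence ids; unnamed input gets integer ids.
#' @param motif a [pwm()] (or [motif_spec()], whose matrix is used with a
#'   uniform background).
#' @param threshold minimum log-odds score (default 0 = better than
#'   background).
#' @return data frame with columns `seq_id`, `motif`, `start`, `end`,
#'   `strand`, `score`; 1-based inclusive coordinates.
#' @export
scan_pwm <- function(sequences, motif, threshold = 0) {
  if (inherits(motif, "motif_spec")) {
    motif <- pwm(motif$name, motif$pwm)
  }
  stopifnot(inherits(motif, "pwm"))
  if (is.data.frame(sequences)) {
    ids <- rownames(sequences) %||% as.character(seq_len(nrow(sequences)))
    sequences <- stats::setNames(sequences$sequence, ids)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- as.character(seq_along(sequences))
  }
  n <- length(sequences)
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (n == 0L) return(empty)
  L <- nchar(sequences[1L])
  w <- ncol(motif$probs)
  if (w > L) stop("motif is wider than the sequences", call. = FALSE)
  S <- seq_to_int(unname(sequences))
  LO <- pwm_logodds(motif)
  LOrc <- LO[4:1, ncol(LO):1, drop = FALSE] # reverse complement
  npos <- L - w + 1L
  score_strand <- function(lo) {
    sc <- matrix(0, n, npos)
    for (j in seq_len(w)) {
      lut <- c(0, lo[, j]) # N (code 0) scores 0
      sc <- sc + matrix(lut[S[, j:(j + npos - 1L), drop = FALSE] + 1L], n, npos)
    }
    sc
  }
  res <- list()
  for (strand in c("+", "-")) {
    sc <- score_strand(if (strand == "+") LO else LOrc)
    hit <- which(sc >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      res[[strand]] <- data.frame(
        seq_id = names(sequences)[hit[, 1L]], motif = motif$name,
        start = as.integer(hit[, 2L]), end = as.integer(hit[, 2L]) + w - 1L,
        strand = strand, score = sc[hit])
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(match(out$seq_id, names(sequences)), out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Motif enrichment in expression extremes
#'
#' Assigns every record to an expression quantile, then tests each motif for
#' association between hit presence (at least one hit on either strand) and
#' membership in the top vs bottom quantile with Fisher's exact test,
#' adjusting across motifs by Benjamini-Hochberg. Odds ratios above 1 mean
#' the motif is enriched among the highest-expressed promoters.
#'
#' @param records sequences (character vector or data frame with `sequence`).
#' @param expressions numeric expression values aligned with `records`
#'   (taken from an `expression` column when `NULL`).
#' @param pwms list of [pwm()] objects (or a single one).
#' @param quantiles number of expression quantiles (default 10, comparing
#'   Q10 against Q1).
#' @param threshold scan log-odds threshold.
#' @return data frame with columns `motif`, `odds_ratio`, `p`, `p_adj`,
#'   `n_top`, `n_bottom`, `hits_top`, `hits_bottom`.
#' @export
motif_enrichment <- function(records, expressions = NULL, pwms, quantiles = 10L,
                             threshold = 0) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (is.null(expressions)) {
    stopifnot(is.data.frame(records), "expression" %in% names(records))
    expressions <- records$expression
  }
  stopifnot(length(seqs) == length(expressions), quantiles >= 2L)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  breaks <- stats::quantile(expressions, probs = seq(0, 1, length.out = quantiles + 1L))
  if (anyDuplicated(breaks)) {
    stop("empty extreme quantile: expression values do not support the requested number of quantiles",
         call. = FALSE)
  }
  grp <- findInterval(expressions, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  top <- grp == quantiles
  bottom <- grp == 1L
  if (!any(top) || !any(bottom)) {
    stop("empty extreme quantile", call. = FALSE)
  }
  use <- top | bottom
  seqs_use <- seqs[use]
  is_top <- top[use]
  names(seqs_use) <- as.character(seq_along(seqs_use))
  rows <- lapply(pwms, function(p) {
    hits <- scan_pwm(seqs_use, p, threshold = threshold)
    present <- logical(length(seqs_use))
    present[as.integer(unique(hits$seq_id))] <- TRUE
    tab <- matrix(c(sum(present & is_top), sum(!present & is_top),
                    sum(present & !is_top), sum(!present & !is_top)), 2L, 2L)
    ft <- stats::fisher.test(tab)
    data.frame(motif = p$name, odds_ratio = unname(ft$estimate), p = ft$p.value,
               n_top = sum(is_top), n_bottom = sum(!is_top),
               hits_top = sum(present & is_top),
               hits_bottom = sum(present & !is_top))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("motif", "odds_ratio", "p", "p_adj", "n_top", "n_bottom",
          "hits_top", "hits_bottom")]
}

as_prediction_vector <- function(predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("seq_id", "prediction") %in% names(predictions)))
    return(stats::setNames(predictions$prediction,
                           as.character(predictions$seq_id)))
  }
  if (is.null(names(predictions))) {
    names(predictions) <- as.character(seq_along(predictions))
  }
  predictions
}

#' Pairwise motif co-occurrence expression matrices
#'
#' `pair[i, j]` is the mean prediction over sequences carrying at least one
#' hit of motif i and at least one of motif j (the diagonal is the baseline
#' expression of sequences carrying motif i at all); `difference[i, j] =
#' pair[i, j] - pair[i, i]` is the expression shift associated with motif j
#' co-occurring with motif i. Cells supported by fewer than `min_n`
#' sequences are set to `NA`.
#'
#' @param predictions named numeric vector of predicted (or observed)
#'   expression keyed by sequence id, or a data frame with `seq_id` and
#'   `prediction` columns.
#' @param hits scan results ([scan_pwm()] output, possibly concatenated over
#'   motifs).
#' @param min_n minimum supporting sequences per cell (default 5).
#' @return list with matrices `pair`, `difference` and integer matrix
#'   `support`.
#' @export
cooccurrence_expression <- function(predictions, hits, min_n = 5L) {
  pred <- as_prediction_vector(predictions)
  motifs <- sort(unique(hits$motif))
  m <- length(motifs)
  ids_of <- lapply(motifs, function(mm) {
    unique(as.character(hits$seq_id[hits$motif == mm]))
  })
  names(ids_of) <- motifs
  pair <- matrix(NA_real_, m, m, dimnames = list(motifs, motifs))
  support <- matrix(0L, m, m, dimnames = list(motifs, motifs))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      ids <- intersect(ids_of[[i]], ids_of[[j]])
      ids <- ids[ids %in% names(pred)]
      support[i, j] <- length(ids)
      if (length(ids) >= min_n) pair[i, j] <- mean(pred[ids])
    }
  }
  difference <- pair - diag(pair)[row(pair)] # D[i,j] = pair[i,j] - pair[i,i]
  diag(difference) <- 0
  difference[is.na(pair)] <- NA_real_
  list(pair = pair, difference = difference, support = support)
}

#' Correlation of predicted expression with motif features
#'
#' For each motif, over the sequences carrying at least one hit: Pearson
#' correlation of the prediction with the hit count, the best (maximum) hit
#' score and the position (start) of the best hit. A zero-variance feature
#' (e.g. all hits share the consensus score) yields `NA`.
#'
#' @param predictions as in [cooccurrence_expression()].
#' @param hits scan results.
#' @return data frame with columns `motif`, `n`, `count_r`, `score_r`,
#'   `position_r`.
#' @export
feature_correlations <- function(predictions, hits) {
  pred <- as_prediction_vector(predictions)
  motifs <- sort(unique(hits$motif))
  rows <- lapply(motifs, function(mm) {
    h <- hits[hits$motif == mm, , drop = FALSE]
    h$seq_id <- as.character(h$seq_id)
    h <- h[h$seq_id %in% names(pred), , drop = FALSE]
    ids <- unique(h$seq_id)
    feat <- t(vapply(ids, function(id) {
      hh <- h[h$seq_id == id, , drop = FALSE]
      best <- which.max(hh$score)
      c(count = nrow(hh), score = hh$score[best], position = hh$start[best])
    }, numeric(3L)))
    y <- pred[ids]
    cor_or_na <- function(v) {
      if (length(v) < 2L || stats::sd(v) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(y, v)
    }
    data.frame(motif = mm, n = length(ids),
               count_r = cor_or_na(feat[, "count"]),
               score_r = cor_or_na(feat[, "score"]),
               position_r = cor_or_na(feat[, "position"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap-grouped ISM profiles across motif instances
#'
#' For every hit of motif A, extracts the ISM importance profile across the
#' motif window (reversed for minus-strand hits so instances align in motif
#' orientation) and groups instances by whether any hit of motif B shares at
#' least one position on the same sequence. Returns position-wise mean
#' profiles per group, the tool for asking whether a motif's effect changes
#' when a second motif co-occurs with it.
#'
#' @param ism_results named list of [ism()] results keyed by sequence id,
#'   covering every sequence with an A hit.
#' @param hits_a scan results for motif A.
#' @param hits_b scan results for motif B (may be empty).
#' @return list with elements `alone` and `overlap`, each a list holding
#'   `profile` (mean importance per motif position, `NA` where no instance
#'   covers a position), `n` (instances), and `width`.
#' @export
grouped_ism_profile <- function(ism_results, hits_a, hits_b) {
  if (!nrow(hits_a)) stop("no hits of motif A", call. = FALSE)
  w <- hits_a$end[1L] - hits_a$start[1L] + 1L
  hits_a$seq_id <- as.character(hits_a$seq_id)
  if (nrow(hits_b)) hits_b$seq_id <- as.character(hits_b$seq_id)
  profiles <- matrix(NA_real_, nrow(hits_a), w)
  overlap <- logical(nrow(hits_a))
  for (i in seq_len(nrow(hits_a))) {
    id <- hits_a$seq_id[i]
    res <- ism_results[[id]]
    if (is.null(res)) {
      stop(sprintf("no ISM result for sequence '%s'", id), call. = FALSE)
    }
    pos <- hits_a$start[i]:hits_a$end[i]
    imp <- res$importance[as.character(pos)]
    if (hits_a$strand[i] == "-") imp <- rev(imp)
    profiles[i, ] <- imp
    if (nrow(hits_b)) {
      hb <- hits_b[hits_b$seq_id == id, , drop = FALSE]
      overlap[i] <- any(hb$start <= hits_a$end[i] & hb$end >= hits_a$start[i])
    }
  }
  group_mean <- function(mask) {
    if (!any(mask)) {
      return(list(profile = rep(NA_real_, w), n = 0L, width = w))
    }
    sub <- profiles[mask, , drop = FALSE]
    list(profile = colMeans(sub, na.rm = TRUE), n = sum(mask), width = w)
  }
  list(alone = group_mean(!overlap), overlap = group_mean(overlap))
}
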