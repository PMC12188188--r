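# Promoter table I/O, the length/N standardization filters, and the five
# one-hot sequence encodings.
#
# Promoters are exchanged as headerless TSV: sequence<TAB>expression with an
# optional third support column (read/cell support backing the uncertainty
# encodings). Standardized sequences are exactly 110 nt; coordinates are
# 1-based inclusive and the variable region is positions 18-97.

#' Read a promoter-expression table
#'
#' Parses a headerless tab-separated file with columns
#' `sequence<TAB>expression[<TAB>support]`. Sequences are upper-cased;
#' characters outside `A,C,G,T,N` are rejected with the offending line number.
#'
#' @param path file path.
#' @return data frame with columns `sequence`, `expression` and, when a third
#'   column is present, `support`.
#' @export
read_promoter_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)] # tolerate trailing blank lines only
  }
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(sequence = character(0), expression = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts[!nzchar(lines)] <- list(character(0))
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L)) {
    bad <- which(nf < 2L | nf > 3L)[1L]
    stop(sprintf("malformed line %d: expected 2 or 3 tab-separated fields, got %d",
                 bad, nf[bad]), call. = FALSE)
  }
  has_support <- all(nf == 3L)
  if (!has_support && any(nf == 3L)) {
    bad <- which(nf == 3L)[1L]
    stop(sprintf("malformed line %d: inconsistent number of fields", bad),
         call. = FALSE)
  }
  seqs <- toupper(vapply(parts, `[[`, character(1L), 1L))
  ok <- grepl("^[ACGTN]+$", seqs)
  if (!all(ok)) {
    stop(sprintf("invalid sequence character on line %d", which(!ok)[1L]),
         call. = FALSE)
  }
  expr <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1L), 2L)))
  if (anyNA(expr)) {
    stop(sprintf("non-numeric expression on line %d", which(is.na(expr))[1L]),
         call. = FALSE)
  }
  out <- data.frame(sequence = seqs, expression = expr, stringsAsFactors = FALSE)
  if (has_support) {
    supp <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1L), 3L)))
    if (anyNA(supp) || any(supp < 0)) {
      bad <- which(is.na(supp) | supp < 0)[1L]
      stop(sprintf("invalid support value on line %d", bad), call. = FALSE)
    }
    out$support <- supp
  }
  out
}

#' Write a promoter-expression table
#'
#' Inverse of [read_promoter_table()]: headerless, tab-separated, newline
#' terminated.
#'
#' @param records data frame with columns `sequence`, `expression` and
#'   optionally `support`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_promoter_table <- function(records, path) {
  cols <- intersect(c("sequence", "expression", "support"), names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Standardize promoter records to a fixed length
#'
#' Applies the assay's preprocessing rules: sequences with length outside
#' `target_len +/- tol` are discarded; among the survivors, sequences with
#' more than `max_n` `N` symbols (counted before padding) are discarded;
#' shorter survivors are padded with `N` at the 3' end and longer survivors
#' truncated at the 3' end to exactly `target_len`. The length filter is
#' applied first; kept records preserve input order and the operation is
#' idempotent.
#'
#' @param records data frame with a `sequence` column (plus any other columns,
#'   which are carried along).
#' @param target_len standardized length (default 110).
#' @param tol admissible deviation in length (default 3).
#' @param max_n maximum number of `N` symbols (default 3).
#' @return list with elements `records` (the kept, standardized data frame)
#'   and `report` (class `filter_report`: counts `n_in`,
#'   `n_discarded_length`, `n_discarded_n`, `n_kept`).
#' @export
filter_standardize <- function(records, target_len = 110L, tol = 3L, max_n = 3L) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  n_in <- nrow(records)
  len <- nchar(records$sequence)
  ok_len <- len >= target_len - tol & len <= target_len + tol
  n_bad_len <- sum(!ok_len)
  surv <- records[ok_len, , drop = FALSE]
  n_count <- nchar(surv$sequence) - nchar(gsub("N", "", surv$sequence, fixed = TRUE))
  ok_n <- n_count <= max_n
  n_bad_n <- sum(!ok_n)
  kept <- surv[ok_n, , drop = FALSE]
  if (nrow(kept)) {
    klen <- nchar(kept$sequence)
    short <- klen < target_len
    if (any(short)) {
      kept$sequence[short] <- paste0(kept$sequence[short],
                                     strrep("N", target_len - klen[short]))
    }
    long <- klen > target_len
    if (any(long)) {
      kept$sequence[long] <- substr(kept$sequence[long], 1L, target_len)
    }
  }
  rownames(kept) <- NULL
  report <- structure(list(n_in = n_in, n_discarded_length = n_bad_len,
                           n_discarded_n = n_bad_n, n_kept = nrow(kept)),
                      class = "filter_report")
  list(records = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Promoter filter report: %d in, %d discarded by length, %d by N count, %d kept\n",
              x$n_in, x$n_discarded_length, x$n_discarded_n, x$n_kept))
  invisible(x)
}

ENCODING_CHANNELS <- c(onehot = 4L, onehotWithP = 4L, onehotWithN = 5L,
                       onehotWithInt = 5L, onehotWithBoth = 6L)

#' Sequence encoding schemes
#'
#' The five supported encodings. Channels 1-4 are always the one-hot bases in
#' order A,C,G,T:
#' \describe{
#'   \item{onehot}{`N = [0,0,0,0]`; 4 channels.}
#'   \item{onehotWithP}{`N` as the uniform base distribution
#'     `[0.25,0.25,0.25,0.25]`; 4 channels.}
#'   \item{onehotWithN}{a fifth binary channel marks `N` positions; 5 channels.}
#'   \item{onehotWithInt}{a fifth channel carries a per-record uncertainty
#'     scalar `1/sqrt(support)` (1 when support is missing), broadcast across
#'     positions; 5 channels.}
#'   \item{onehotWithBoth}{the `N` channel (5) plus the uncertainty channel
#'     (6); 6 channels.}
#' }
#'
#' @param name one of `onehot`, `onehotWithP`, `onehotWithN`, `onehotWithInt`,
#'   `onehotWithBoth`.
#' @return list with elements `name` and `channels`, class `encoding_scheme`.
#' @export
encoding_scheme <- function(name = names(ENCODING_CHANNELS)) {
  name <- match.arg(name)
  structure(list(name = name, channels = ENCODING_CHANNELS[[name]]),
            class = "encoding_scheme")
}

as_encoding_scheme <- function(scheme) {
  if (inherits(scheme, "encoding_scheme")) scheme else encoding_scheme(scheme)
}

#' One-hot encode standardized promoter records
#'
#' Encodes length-110 sequences into the tensor layout `(n, 110, 1, c)` used
#' by the models, with base channels `A=[1,0,0,0]`, `C=[0,1,0,0]`,
#' `G=[0,0,1,0]`, `T=[0,0,0,1]` and scheme-specific handling of `N` and
#' uncertainty (see [encoding_scheme()]).
#'
#' @param records data frame with a `sequence` column (and optional `support`
#'   for the uncertainty encodings), or a character vector of sequences.
#' @param scheme an [encoding_scheme()] or its name.
#' @param target_len required standardized length (default 110).
#' @return object of class `encoded_batch`: list with `values` (numeric array
#'   `(n, target_len, 1, channels)`), `scheme` and `n`.
#' @export
encode_batch <- function(records, scheme = "onehot", target_len = 110L) {
  scheme <- as_encoding_scheme(scheme)
  if (is.character(records)) {
    records <- data.frame(sequence = records, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  seqs <- records$sequence
  n <- length(seqs)
  ch <- scheme$channels
  if (n > 0L && any(nchar(seqs) != target_len)) {
    stop(sprintf("all sequences must be standardized to length %d (see filter_standardize)",
                 target_len), call. = FALSE)
  }
  vals <- array(0, c(n, target_len, 1L, ch))
  if (n > 0L) {
    S <- seq_to_int(seqs)
    for (b in 1:4) {
      idx <- which(S == b, arr.ind = TRUE)
      if (nrow(idx)) vals[cbind(idx[, 1L], idx[, 2L], 1L, b)] <- 1
    }
    nidx <- which(S == 0L, arr.ind = TRUE)
    if (scheme$name == "onehotWithP" && nrow(nidx)) {
      for (b in 1:4) vals[cbind(nidx[, 1L], nidx[, 2L], 1L, b)] <- 0.25
    }
    if (scheme$name %in% c("onehotWithN", "onehotWithBoth") && nrow(nidx)) {
      vals[cbind(nidx[, 1L], nidx[, 2L], 1L, 5L)] <- 1
    }
    if (scheme$name %in% c("onehotWithInt", "onehotWithBoth")) {
      supp <- records$support %||% rep(NA_real_, n)
      u <- ifelse(is.na(supp) | supp <= 0, 1, 1 / sqrt(supp))
      uch <- if (scheme$name == "onehotWithInt") 5L else 6L
      vals[, , 1L, uch] <- matrix(u, n, target_len)
    }
  }
  structure(list(values = vals, scheme = scheme, n = n), class = "encoded_batch")
}

#' Decode an encoded batch back to sequence strings
#'
#' Exact inverse of [encode_batch()] on the sequence content for all five
#' schemes; slices with no scheme-consistent interpretation raise an error.
#'
#' @param batch an `encoded_batch`.
#' @return character vector of sequences.
#' @export
decode_batch <- function(batch) {
  stopifnot(inherits(batch, "encoded_batch"))
  vals <- batch$values
  n <- dim(vals)[1L]
  L <- dim(vals)[2L]
  if (n == 0L) return(character(0))
  scheme <- batch$scheme$name
  out <- character(n)
  tol <- 1e-9
  for (i in seq_len(n)) {
    slice <- matrix(vals[i, , 1L, 1:4], L, 4L) # positions x base channels
    rs <- rowSums(slice)
    hit <- max.col(slice, ties.method = "first")
    hitval <- slice[cbind(seq_len(L), hit)]
    base <- character(L)
    onehot_pos <- abs(rs - 1) < tol & abs(hitval - 1) < tol
    base[onehot_pos] <- DNA_BASES[hit[onehot_pos]]
    if (scheme == "onehotWithP") {
      npos <- abs(slice[, 1L] - 0.25) < tol & abs(slice[, 2L] - 0.25) < tol &
        abs(slice[, 3L] - 0.25) < tol & abs(slice[, 4L] - 0.25) < tol
    } else {
      npos <- rs < tol
    }
    base[npos] <- "N"
    if (scheme %in% c("onehotWithN", "onehotWithBoth")) {
      flag <- vals[i, , 1L, 5L] > 0.5
      if (any(xor(flag, base == "N"))) {
        stop(sprintf("sequence %d: N channel inconsistent with base channels", i),
             call. = FALSE)
      }
    }
    if (any(base == "")) {
      stop(sprintf("sequence %d: ambiguous slice at position %d under scheme %s",
                   i, which(base == "")[1L], scheme), call. = FALSE)
    }
    out[i] <- paste(base, collapse = "")
  }
  out
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat(sprintf("Encoded batch: %d sequences, scheme %s (%d channels), tensor (%s)\n",
              x$n, x$scheme$name, x$scheme$channels,
              paste(dim(x$values), collapse = ", ")))
  invisible(x)
}
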