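# Shared low-level helpers: DNA alphabet handling and degenerate-safe
# correlations. The integer alphabet is A=1, C=2, G=3, T=4, N=0 throughout.

DNA_BASES <- c("A", "C", "G", "T")

# character vector of sequences -> integer matrix (n x L), N (and anything
# non-ACGT) mapped to 0. All sequences must share one length.
seq_to_int <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[1L])
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  if (any(nchar(sequences) != L)) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  m <- matrix(0L, n, L)
  for (i in seq_len(n)) m[i, ] <- lut[utf8ToInt(sequences[i])]
  m
}

int_to_seq <- function(m) {
  alpha <- c("N", DNA_BASES)
  apply(m, 1L, function(row) paste(alpha[row + 1L], collapse = ""))
}

#' Reverse complement of a DNA string
#'
#' `N` is its own complement. Input may contain only `A`, `C`, `G`, `T`, `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GATTACA")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' GC fraction of a sequence region
#'
#' Fraction of `G`+`C` among the non-`N` bases of the region. Used both by the
#' synthetic expression model and for saliency/GC analyses.
#'
#' @param sequence a single DNA string over `A,C,G,T,N`.
#' @param region integer length-2 vector `(from, to)`, 1-based inclusive;
#'   defaults to the whole sequence.
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("GATTACA")        # 2/7
#' gc_content("NNGCGC", c(3, 6)) # 1
#' @export
gc_content <- function(sequence, region = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.null(region)) region <- c(1L, nchar(sequence))
  if (region[1L] < 1L || region[2L] > nchar(sequence) || region[1L] > region[2L]) {
    stop("region out of bounds", call. = FALSE)
  }
  sub <- substr(sequence, region[1L], region[2L])
  chars <- strsplit(sub, "", fixed = TRUE)[[1L]]
  informative <- chars != "N"
  if (!any(informative)) stop("region contains only N", call. = FALSE)
  sum(chars %in% c("G", "C")) / sum(informative)
}

# Pearson/Spearman with the degenerate-variance rule: zero variance in either
# argument yields 0 with a "degenerate" flag instead of NA. Keeps r + rho
# total-ordered for early stopping and reporting.
safe_cor <- function(x, y, method = "pearson") {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y, method = method), degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
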