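# Synthetic GPRA library simulator.
#
# Emulates the structure of a gigantic parallel reporter assay at desk scale:
# 110-nt promoters built as a fixed 17-nt 5' flank, an 80-nt random insert and
# a fixed 13-nt 3' flank; latent (noise-free) expression as an additive model
# over planted PWM motifs, motif-pair interactions and insert GC content; and
# an observed readout as the mean flow-sorting bin over a configurable number
# of cells with Gaussian cell-level noise. The simulator is the ground-truth
# source for every downstream recovery experiment in the package.

#' Specify a motif to plant in a synthetic library
#'
#' @param name motif identifier.
#' @param pwm 4 x w numeric matrix of per-base probabilities, rows A,C,G,T
#'   (in that order; rownames optional), columns positions; every column must
#'   sum to 1 and w must be at least 4.
#' @param effect latent expression shift contributed by one planted instance.
#' @param plant_prob probability in `[0, 1]` that a library sequence receives
#'   one planted instance of this motif.
#' @return an object of class `motif_spec`.
#' @seealso [consensus_pwm()] for building near-deterministic matrices.
#' @export
motif_spec <- function(name, pwm, effect = 0, plant_prob = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4L) stop("pwm must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(pwm) < 4L) stop("motif width must be at least 4", call. = FALSE)
  if (any(abs(colSums(pwm) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1", call. = FALSE)
  }
  if (any(pwm < 0)) stop("PWM probabilities must be nonnegative", call. = FALSE)
  if (plant_prob < 0 || plant_prob > 1) stop("plant_prob must be in [0,1]", call. = FALSE)
  rownames(pwm) <- DNA_BASES
  structure(list(name = name, pwm = pwm, effect = effect,
                 plant_prob = plant_prob),
            class = "motif_spec")
}

#' Near-deterministic PWM from a consensus sequence
#'
#' Each column puts probability `p` on the consensus base and `(1 - p)/3` on
#' the other three.
#'
#' @param consensus DNA string over A,C,G,T, length >= 4.
#' @param p probability of the consensus base at each position.
#' @return 4 x nchar(consensus) probability matrix with rows A,C,G,T.
#' @export
consensus_pwm <- function(consensus, p = 0.97) {
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  if (!all(bases %in% DNA_BASES)) stop("consensus must be over A,C,G,T", call. = FALSE)
  w <- length(bases)
  m <- matrix((1 - p) / 3, 4L, w, dimnames = list(DNA_BASES, NULL))
  m[cbind(match(bases, DNA_BASES), seq_len(w))] <- p
  m
}

#' Specify a pairwise motif interaction
#'
#' Adds `effect` to the latent expression when both named motifs are planted
#' in the same sequence (the ground-truth analogue of context-dependent
#' repression such as UME6 acting only alongside IME1).
#'
#' @param motif_a,motif_b names of two distinct motifs.
#' @param effect additional latent shift when both are present.
#' @return an object of class `interaction_spec`.
#' @export
interaction_spec <- function(motif_a, motif_b, effect) {
  if (identical(motif_a, motif_b)) stop("interaction requires two distinct motifs", call. = FALSE)
  structure(list(motif_a = motif_a, motif_b = motif_b, effect = effect),
            class = "interaction_spec")
}

# Arbitrary fixed flanks. Only their fixed-ness and lengths (17 and 13 nt)
# matter for the method; the real plasmid flanks are not modelled.
DEFAULT_FLANK5 <- "TGCATTTCTTAGTCAAC"
DEFAULT_FLANK3 <- "GGTTACGGCTGTT"

#' Specify a synthetic promoter library
#'
#' @param n number of promoters to simulate.
#' @param insert_len length of the random variable region (default 80, giving
#'   110-nt promoters with the default flanks).
#' @param flank5 fixed 5' flank, 17 nt.
#' @param flank3 fixed 3' flank, 13 nt.
#' @param baseline latent expression of a motif-free, GC-neutral insert.
#' @param gc_coeff latent shift per unit GC fraction of the variable region.
#' @param motifs list of [motif_spec()] objects.
#' @param interactions list of [interaction_spec()] objects.
#' @param n_bins number of flow-sorting expression bins (default 18).
#' @param cells_per_promoter number of cells sequenced per promoter; the
#'   public training data averaged ~2 cells while test data had >= 100, so
#'   small values emulate noisy training labels.
#' @param cell_noise_sd standard deviation of Gaussian cell-level noise on
#'   the latent expression.
#' @param bin_range numeric `(low, high)` giving the latent range spanned by
#'   the equal-width bin grid, or `NULL` to estimate `mean +/- 2 sd` of the
#'   latent distribution from 10 000 draws at generation time.
#' @param seed integer RNG seed; generation is byte-reproducible given the
#'   spec (seed included).
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(n,
                         insert_len = 80L,
                         flank5 = DEFAULT_FLANK5,
                         flank3 = DEFAULT_FLANK3,
                         baseline = 0,
                         gc_coeff = 0,
                         motifs = list(),
                         interactions = list(),
                         n_bins = 18L,
                         cells_per_promoter = 10L,
                         cell_noise_sd = 1,
                         bin_range = NULL,
                         seed = 1L) {
  if (nchar(flank5) != 17L) stop("flank5 must be 17 nt", call. = FALSE)
  if (nchar(flank3) != 13L) stop("flank3 must be 13 nt", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (cells_per_promoter < 1L) stop("cells_per_promoter must be >= 1", call. = FALSE)
  if (!is.null(bin_range) && bin_range[1L] >= bin_range[2L]) {
    stop("bin_range must satisfy low < high", call. = FALSE)
  }
  if (length(motifs) && inherits(motifs, "motif_spec")) motifs <- list(motifs)
  if (length(interactions) && inherits(interactions, "interaction_spec")) {
    interactions <- list(interactions)
  }
  stopifnot(all(vapply(motifs, inherits, logical(1L), "motif_spec")),
            all(vapply(interactions, inherits, logical(1L), "interaction_spec")))
  known <- vapply(motifs, `[[`, character(1L), "name")
  if (anyDuplicated(known)) stop("duplicated motif names", call. = FALSE)
  for (ia in interactions) {
    if (!all(c(ia$motif_a, ia$motif_b) %in% known)) {
      stop("interaction references an unknown motif", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), insert_len = as.integer(insert_len),
                 flank5 = flank5, flank3 = flank3, baseline = baseline,
                 gc_coeff = gc_coeff, motifs = motifs,
                 interactions = interactions, n_bins = as.integer(n_bins),
                 cells_per_promoter = as.integer(cells_per_promoter),
                 cell_noise_sd = cell_noise_sd, bin_range = bin_range,
                 seed = as.integer(seed)),
            class = "library_spec")
}

# variable region coordinates within the assembled promoter
variable_region <- function(spec) {
  from <- nchar(spec$flank5) + 1L
  c(from, from + spec$insert_len - 1L)
}

# Draw one insert (int vector) and its plant annotations. Non-overlap is
# enforced by rejection sampling, at most 100 attempts per motif.
plant_insert <- function(spec) {
  ins <- sample.int(4L, spec$insert_len, replace = TRUE)
  occupied <- matrix(integer(0), 0L, 2L) # start, end within insert
  ann <- list()
  off <- nchar(spec$flank5)
  for (m in spec$motifs) {
    w <- ncol(m$pwm)
    if (m$plant_prob > 0 && stats::runif(1L) >= m$plant_prob) next
    if (m$plant_prob == 0) next
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      start <- sample.int(spec$insert_len - w + 1L, 1L)
      end <- start + w - 1L
      if (nrow(occupied) == 0L ||
          all(end < occupied[, 1L] | start > occupied[, 2L])) {
        strand <- if (stats::runif(1L) < 0.5) "+" else "-"
        site <- vapply(seq_len(w), function(j) {
          sample.int(4L, 1L, prob = m$pwm[, j])
        }, integer(1L))
        if (strand == "-") site <- rev(5L - site)
        ins[start:end] <- site
        occupied <- rbind(occupied, c(start, end))
        ann[[length(ann) + 1L]] <- list(name = m$name,
                                        start = off + start,
                                        strand = strand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place motif '%s' without overlap after 100 attempts",
                   m$name), call. = FALSE)
    }
  }
  list(insert = ins, planted = ann)
}

planted_to_string <- function(ann) {
  if (!length(ann)) return("")
  paste(vapply(ann, function(a) {
    sprintf("%s:%d:%s", a$name, a$start, a$strand)
  }, character(1L)), collapse = ";")
}

#' Parse planted-motif annotation strings
#'
#' Inverse of the `planted` column written by [generate_library()]:
#' semicolon-separated `name:start:strand` triples with 1-based starts.
#'
#' @param x character vector of annotation strings (`""` = none).
#' @return list of data frames with columns `name`, `start`, `strand`.
#' @export
parse_planted <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(name = character(0), start = integer(0),
                        strand = character(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    data.frame(name = vapply(parts, `[[`, character(1L), 1L),
               start = as.integer(vapply(parts, `[[`, character(1L), 2L)),
               strand = vapply(parts, `[[`, character(1L), 3L))
  })
}

#' Latent (noise-free) expression of a promoter under a library spec
#'
#' `baseline` + sum of planted motif effects + sum of interaction effects for
#' co-planted pairs + `gc_coeff` times the GC fraction of the variable
#' region. Purely deterministic.
#'
#' @param sequence promoter string, length `flank5 + insert_len + flank3`.
#' @param spec a [library_spec()].
#' @param planted plant annotations: a data frame with columns
#'   `name,start,strand`, a list of such annotations, or an annotation string
#'   as written by [generate_library()].
#' @return latent expression (real).
#' @export
latent_expression <- function(sequence, spec, planted = NULL) {
  vr <- variable_region(spec)
  expected_len <- nchar(spec$flank5) + spec$insert_len + nchar(spec$flank3)
  if (nchar(sequence) != expected_len) {
    stop(sprintf("sequence must have length %d", expected_len), call. = FALSE)
  }
  if (is.character(planted)) planted <- parse_planted(planted)[[1L]]
  if (is.null(planted)) {
    planted <- data.frame(name = character(0), start = integer(0),
                          strand = character(0))
  }
  if (is.list(planted) && !is.data.frame(planted)) {
    planted <- data.frame(
      name = vapply(planted, `[[`, character(1L), "name"),
      start = vapply(planted, function(a) as.integer(a$start), integer(1L)),
      strand = vapply(planted, `[[`, character(1L), "strand"))
  }
  eff <- 0
  if (nrow(planted)) {
    effects <- stats::setNames(
      vapply(spec$motifs, `[[`, numeric(1L), "effect"),
      vapply(spec$motifs, `[[`, character(1L), "name"))
    unknown <- setdiff(planted$name, names(effects))
    if (length(unknown)) {
      stop(sprintf("planted motif not in spec: %s", unknown[1L]), call. = FALSE)
    }
    eff <- sum(effects[planted$name])
    for (ia in spec$interactions) {
      if (ia$motif_a %in% planted$name && ia$motif_b %in% planted$name) {
        eff <- eff + ia$effect
      }
    }
  }
  spec$baseline + eff + spec$gc_coeff * gc_content(sequence, vr)
}

# Equal-width bin grid over bin_range; per-cell values are clipped to the
# range, so bin indices run 1..n_bins.
cell_bins <- function(values, spec, bin_range) {
  low <- bin_range[1L]; high <- bin_range[2L]
  width <- (high - low) / spec$n_bins
  v <- pmin(pmax(values, low), high)
  pmin(spec$n_bins, floor((v - low) / width) + 1L)
}

#' Simulated binned flow-sorting readout
#'
#' Draws `cells_per_promoter` cell-level values `latent + N(0, cell_noise_sd)`,
#' assigns each to one of `n_bins` equal-width bins spanning `bin_range`
#' (values clipped to the range) and returns the mean bin index, i.e. the
#' weighted mean expression bin a sequencing readout would report.
#'
#' @param latent latent expression value(s); vectorized.
#' @param spec a [library_spec()]; `spec$bin_range` must be set (it always is
#'   on the spec stored alongside a generated library).
#' @param seed optional integer seed for the cell-level noise.
#' @return mean bin index per latent value (real, in `[1, n_bins]`).
#' @export
binned_readout <- function(latent, spec, seed = NULL) {
  if (is.null(spec$bin_range)) {
    stop("spec$bin_range is not set; generate_library() estimates it, or set it explicitly",
         call. = FALSE)
  }
  if (spec$bin_range[1L] >= spec$bin_range[2L]) {
    stop("degenerate bin_range (low >= high)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent)
  k <- spec$cells_per_promoter
  noise <- matrix(stats::rnorm(n * k, sd = spec$cell_noise_sd), n, k)
  cells <- latent + noise
  bins <- cell_bins(cells, spec, spec$bin_range)
  rowMeans(matrix(bins, n, k))
}

# Estimate the default bin grid: mean +/- 2 sd of the latent distribution
# under the spec, from n_draws simulated inserts (annotations only; no
# readout). Consumes RNG deterministically.
estimate_bin_range <- function(spec, n_draws = 10000L) {
  vr <- variable_region(spec)
  lat <- numeric(n_draws)
  effects <- stats::setNames(
    vapply(spec$motifs, `[[`, numeric(1L), "effect"),
    vapply(spec$motifs, `[[`, character(1L), "name"))
  for (i in seq_len(n_draws)) {
    pl <- plant_insert(spec)
    gc <- mean(pl$insert %in% c(2L, 3L))
    eff <- if (length(pl$planted)) {
      nm <- vapply(pl$planted, `[[`, character(1L), "name")
      e <- sum(effects[nm])
      for (ia in spec$interactions) {
        if (ia$motif_a %in% nm && ia$motif_b %in% nm) e <- e + ia$effect
      }
      e
    } else 0
    lat[i] <- spec$baseline + eff + spec$gc_coeff * gc
  }
  mu <- mean(lat); s <- stats::sd(lat)
  if (s == 0) s <- max(abs(mu), 1) * 0.5 # degenerate spec: fall back to a fixed span
  c(mu - 2 * s, mu + 2 * s)
}

#' Generate a synthetic GPRA promoter library
#'
#' Draws `n` promoters with i.i.d. uniform random inserts, independently
#' plants each motif with its `plant_prob` at a uniform random non-overlapping
#' position on a uniform random strand (site sampled column-wise from the
#' PWM; reverse complement on the minus strand), computes latent expression
#' via [latent_expression()] and the observed readout via [binned_readout()].
#'
#' @param spec a [library_spec()].
#' @return data frame with columns `sequence` (110-nt promoter), `expression`
#'   (observed mean bin), `latent` (noise-free expression) and `planted`
#'   (semicolon-separated `name:start:strand` triples, 1-based starts within
#'   the promoter). The spec actually used (with the estimated `bin_range`
#'   filled in) is attached as attribute `"spec"`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  for (m in spec$motifs) {
    if (ncol(m$pwm) > spec$insert_len) {
      stop(sprintf("motif '%s' (width %d) does not fit in a %d-nt insert",
                   m$name, ncol(m$pwm), spec$insert_len), call. = FALSE)
    }
  }
  set.seed(spec$seed)
  if (is.null(spec$bin_range)) spec$bin_range <- estimate_bin_range(spec)

  n <- spec$n
  seqs <- character(n)
  planted <- character(n)
  latent <- numeric(n)
  alpha <- c("N", DNA_BASES)
  for (i in seq_len(n)) {
    pl <- plant_insert(spec)
    insert <- paste(alpha[pl$insert + 1L], collapse = "")
    seqs[i] <- paste0(spec$flank5, insert, spec$flank3)
    planted[i] <- planted_to_string(pl$planted)
    latent[i] <- latent_expression(seqs[i], spec, planted[i])
  }
  observed <- binned_readout(latent, spec)
  out <- data.frame(sequence = seqs, expression = observed,
                    latent = latent, planted = planted,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Write a synthetic library to disk
#'
#' Writes the two-column promoter table consumed by [read_promoter_table()]
#' (`sequence<TAB>expression`, no header) plus a ground-truth sidecar
#' `<prefix>.truth.tsv` with columns sequence, latent and planted annotations.
#'
#' @param library data frame from [generate_library()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.truth.tsv`.
#' @return invisibly, the two file paths.
#' @export
write_library <- function(library, prefix) {
  main <- paste0(prefix, ".tsv")
  truth <- paste0(prefix, ".truth.tsv")
  utils::write.table(library[, c("sequence", "expression")], main,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(library[, c("sequence", "latent", "planted")], truth,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(library = main, truth = truth))
}
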