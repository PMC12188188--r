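# PWM logic: scanner against brute-force log-odds, strand geometry,
# enrichment calibration, co-occurrence matrices and grouped ISM profiles.

random_pwm <- function(name, w, seed) {
  set.seed(seed)
  p <- matrix(rexp(4 * w), 4, w)
  pwm(name, sweep(p, 2, colSums(p), `/`))
}

test_that("scan scores equal brute-force log-odds on all hexamers, both strands", {
  p <- random_pwm("HEX", 6, 101)
  q <- sweep(p$probs + p$pseudocount, 2,
             colSums(p$probs + p$pseudocount), `/`)
  LO <- log(q / 0.25)
  bases <- c("A", "C", "G", "T")
  hexes <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases, bases,
                                       stringsAsFactors = FALSE))
  hits <- scan_pwm(hexes, p, threshold = -Inf)
  expect_equal(nrow(hits), 2L * length(hexes)) # one window, two strands

  brute_plus <- vapply(hexes, function(s) {
    b <- match(strsplit(s, "")[[1L]], bases)
    sum(LO[cbind(b, 1:6)])
  }, numeric(1L), USE.NAMES = FALSE)
  brute_minus <- vapply(hexes, function(s) {
    b <- match(strsplit(revcomp(s), "")[[1L]], bases)
    sum(LO[cbind(b, 1:6)])
  }, numeric(1L), USE.NAMES = FALSE)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(plus$score[order(as.integer(plus$seq_id))], brute_plus)
  expect_equal(minus$score[order(as.integer(minus$seq_id))], brute_minus)
})

test_that("an embedded consensus gives the maximal plus-strand score at its start", {
  p <- pwm("CONS", consensus_pwm("TGACTCA", 0.9))
  s <- rand_seq(1, seed = 102)
  substr(s, 30, 36) <- "TGACTCA"
  hits <- scan_pwm(s, p, threshold = 0)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$start, 30L)
  expect_equal(best$strand, "+")
  q <- (0.9 + p$pseudocount) / (1 + 4 * p$pseudocount)
  expect_equal(best$score, 7 * log(q / 0.25), tolerance = 1e-12)

  # a GC-only motif never fires on an all-A sequence
  gc_only <- pwm("GC", consensus_pwm("GCGCGC", 0.99))
  expect_equal(nrow(scan_pwm(strrep("A", 110), gc_only, threshold = 0)), 0L)
})

test_that("palindromes hit both strands equally and revcomp mirrors coordinates", {
  pal <- pwm("PAL", consensus_pwm("TGCA", 0.9)) # reverse complement of itself
  s <- paste0(strrep("A", 40), "TGCA", strrep("A", 66))
  hits <- scan_pwm(s, pal, threshold = 0)
  win <- hits[hits$start == 41L, ]
  expect_setequal(win$strand, c("+", "-"))
  expect_equal(win$score[1], win$score[2])

  p <- random_pwm("ASYM", 7, 103)
  s2 <- rand_seq(1, seed = 104)
  h_fwd <- scan_pwm(s2, p, threshold = -Inf)
  h_rev <- scan_pwm(revcomp(s2), p, threshold = -Inf)
  # start' = L - end + 1, strands swap, scores identical
  key_fwd <- paste(110L - h_fwd$end + 1L, chartr("+-", "-+", h_fwd$strand))
  expect_setequal(paste(key_fwd, round(h_fwd$score, 9)),
                  paste(h_rev$start, h_rev$strand, round(h_rev$score, 9)))
})

test_that("N positions contribute zero information to scan scores", {
  p <- pwm("NP", consensus_pwm("TTTT", 0.8))
  lo1 <- scan_pwm("TTTT", p, threshold = -Inf)
  loN <- scan_pwm("TTNT", p, threshold = -Inf)
  per_pos <- lo1$score[lo1$strand == "+"] / 4
  expect_equal(loN$score[loN$strand == "+"], 3 * per_pos, tolerance = 1e-12)
})

test_that("planted motifs are enriched in the top expression quantile", {
  set.seed(105)
  n <- 5000
  seqs <- rand_seq(n)
  expr <- rnorm(n)
  high <- expr > quantile(expr, 0.85)
  plant_at <- sample(which(high), round(sum(high) * 0.8))
  for (i in plant_at) {
    pos <- sample(18:90, 1)
    substr(seqs[i], pos, pos + 6L) <- "TGACTCA"
  }
  p <- pwm("ACT", consensus_pwm("TGACTCA", 0.97))
  enr <- motif_enrichment(seqs, expr, list(p), quantiles = 10, threshold = 3)
  expect_gt(enr$odds_ratio, 1)
  expect_lt(enr$p_adj, 0.05)

  expect_error(motif_enrichment(seqs[1:50], rep(1, 50), list(p)),
               "quantile")
})

test_that("null motifs stay at the nominal false-positive rate after BH", {
  set.seed(106)
  seqs <- rand_seq(1500)
  expr <- rnorm(1500) # expression independent of sequence content
  pwms <- lapply(1:100, function(i) random_pwm(paste0("NULL", i), 6, 200 + i))
  enr <- motif_enrichment(seqs, expr, pwms, quantiles = 10, threshold = 4)
  expect_lte(mean(enr$p_adj < 0.05), 0.05)
})

test_that("co-occurrence matrices match a brute-force enumeration", {
  # composition: singles {A}, {B}, {C} and all pairs, predictions additive
  consensus <- c(A = "TGACTCAT", B = "CACGTGAC", C = "GGGCCCTA")
  effects <- c(A = 1, B = -2, C = 0.5)
  base <- 0.3
  sets <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"))
  seqs <- character(0); pred <- numeric(0); truth <- list()
  idx <- 0
  set.seed(107)
  for (rep_i in 1:6) {
    for (ss in sets) {
      idx <- idx + 1
      s <- rand_seq(1)
      at <- c(20, 50, 80)
      for (j in seq_along(ss)) {
        substr(s, at[j], at[j] + 7L) <- consensus[[ss[j]]]
      }
      seqs[idx] <- s
      pred[idx] <- base + sum(effects[ss])
      truth[[idx]] <- ss
    }
  }
  names(pred) <- as.character(seq_along(pred))
  names(seqs) <- names(pred)
  hits <- do.call(rbind, lapply(names(consensus), function(nm) {
    scan_pwm(seqs, pwm(nm, consensus_pwm(consensus[[nm]], 0.99)),
             threshold = 8)
  }))
  co <- cooccurrence_expression(pred, hits, min_n = 1)
  # brute-force oracle over the known composition
  for (i in names(consensus)) {
    for (j in names(consensus)) {
      in_ij <- vapply(truth, function(ss) all(c(i, j) %in% ss), logical(1))
      expect_equal(co$pair[i, j], mean(pred[in_ij]),
                   info = paste(i, j))
      expect_equal(co$difference[i, j], co$pair[i, j] - co$pair[i, i])
    }
  }
  # constant predictions: pair constant, differences zero
  co0 <- cooccurrence_expression(setNames(rep(2, length(pred)), names(pred)),
                                 hits, min_n = 1)
  expect_true(all(co0$pair == 2))
  expect_true(all(co0$difference == 0))
  # support below min_n is flagged empty
  co5 <- cooccurrence_expression(pred, hits, min_n = 7)
  expect_true(all(is.na(co5$pair[co5$support < 7])))
})

test_that("feature correlations track planted count and score effects", {
  set.seed(108)
  n <- 300
  seqs <- rand_seq(n)
  counts <- sample(0:2, n, replace = TRUE)
  for (i in which(counts > 0)) {
    at <- c(20, 60)[seq_len(counts[i])]
    for (a in at) substr(seqs[i], a, a + 6L) <- "TGACTCA"
  }
  pred <- 0.5 * counts + rnorm(n, sd = 0.1)
  names(pred) <- as.character(seq_len(n))
  names(seqs) <- names(pred)
  p <- pwm("ACT", consensus_pwm("TGACTCA", 0.97))
  hits <- scan_pwm(seqs, p, threshold = 5)
  fc <- feature_correlations(pred, hits)
  expect_gt(fc$count_r, 0)
  # consensus-only planting: every best hit has the same score -> NA
  expect_true(is.na(fc$score_r))

  # graded match quality: weaker sites get weaker effects -> positive score r
  seqs2 <- rand_seq(n)
  strength <- sample(0:2, n, replace = TRUE) # 2 = consensus, 1 = one mismatch
  site <- c("TGACTCA", "TGAGTCA")
  for (i in which(strength > 0)) {
    substr(seqs2[i], 40, 46) <- site[[3L - strength[i]]]
  }
  pred2 <- strength + rnorm(n, sd = 0.1)
  names(pred2) <- names(seqs2) <- as.character(seq_len(n))
  hits2 <- scan_pwm(seqs2, pwm("ACT", consensus_pwm("TGACTCA", 0.9)),
                    threshold = 4)
  fc2 <- feature_correlations(pred2, hits2)
  expect_gt(fc2$score_r, 0)
})

test_that("grouped ISM profiles separate motif instances by overlap", {
  # B ("GGTGACTCACC") embeds the A consensus ("TGACTCA"); a rule-based model
  # scores A alone +2 and the composite B -3, so ISM importance flips sign
  f <- function(seqs) {
    vapply(seqs, function(s) {
      nb <- lengths(regmatches(s, gregexpr("GGTGACTCACC", s)))
      na <- lengths(regmatches(s, gregexpr("TGACTCA", s)))
      2 * (na - nb) - 3 * nb
    }, numeric(1L), USE.NAMES = FALSE)
  }
  set.seed(109)
  seqs <- rand_seq(20)
  for (i in 1:10) substr(seqs[i], 40, 46) <- "TGACTCA"       # A alone
  for (i in 11:20) substr(seqs[i], 38, 48) <- "GGTGACTCACC"  # A inside B
  names(seqs) <- as.character(1:20)
  pa <- pwm("A", consensus_pwm("TGACTCA", 0.99))
  pb <- pwm("B", consensus_pwm("GGTGACTCACC", 0.99))
  hits_a <- scan_pwm(seqs, pa, threshold = 8)
  hits_b <- scan_pwm(seqs, pb, threshold = 8)
  hits_a <- hits_a[hits_a$strand == "+", ]
  ism_results <- lapply(seqs, function(s) ism(f, s))
  prof <- grouped_ism_profile(ism_results, hits_a, hits_b)
  expect_equal(prof$alone$n + prof$overlap$n, nrow(hits_a))
  expect_gt(prof$overlap$n, 0)
  expect_true(all(prof$overlap$profile < prof$alone$profile))

  # no B hits anywhere: overlap group is empty
  prof0 <- grouped_ism_profile(ism_results, hits_a, hits_b[0, ])
  expect_equal(prof0$overlap$n, 0L)
  expect_error(grouped_ism_profile(ism_results, hits_a[0, ], hits_b),
               "no hits")

  # constant model: both group profiles identically zero
  ism0 <- lapply(seqs, function(s) ism(function(x) rep(1, length(x)), s))
  profc <- grouped_ism_profile(ism0, hits_a, hits_b)
  expect_true(all(profc$alone$profile == 0))
})

test_that("MEME minimal format round-trips and parses backgrounds", {
  p1 <- random_pwm("M1", 6, 301)
  p2 <- pwm("M2", consensus_pwm("TGACTCA", 0.9),
            background = c(0.3, 0.2, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p1, p2), path)
  back <- read_meme(path)
  expect_named(back, c("M1", "M2"))
  expect_equal(back$M1$probs, p1$probs, tolerance = 1e-5)
  expect_equal(back$M2$background, p1$background, tolerance = 1e-5)
  expect_error(pwm("bad", matrix(1, 4, 5)), "sum to 1")
})
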