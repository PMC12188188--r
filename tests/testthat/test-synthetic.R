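# The synthetic GPRA generator: determinism, planting geometry, the additive
# latent model and the binned readout noise model.

test_that("library generation is deterministic and respects the construct geometry", {
  spec <- library_spec(n = 50, motifs = list(
    motif_spec("M8", consensus_pwm("TGACTCAG"), effect = 1, plant_prob = 1)),
    seed = 3)
  lib1 <- generate_library(spec)
  lib2 <- generate_library(spec)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 50L)
  expect_true(all(nchar(lib1$sequence) == 110L))
  expect_true(all(startsWith(lib1$sequence, spec$flank5)))
  expect_true(all(endsWith(lib1$sequence, spec$flank3)))

  # forced planting: exactly one instance per record, start within 18..90
  ann <- parse_planted(lib1$planted)
  expect_true(all(vapply(ann, nrow, integer(1L)) == 1L))
  starts <- vapply(ann, function(a) a$start, integer(1L))
  expect_true(all(starts >= 18L & starts <= 90L))
  # the planted site matches the (near-deterministic) motif on the right strand
  for (i in 1:10) {
    a <- ann[[i]]
    site <- substr(lib1$sequence[i], a$start, a$start + 7L)
    if (a$strand == "-") site <- revcomp(site)
    expect_equal(sum(strsplit(site, "")[[1L]] ==
                       strsplit("TGACTCAG", "")[[1L]]) >= 7L, TRUE)
  }
})

test_that("motif-free libraries sit at baseline and planting errors are caught", {
  spec <- library_spec(n = 5, baseline = 1.5, gc_coeff = 0, seed = 1)
  lib <- generate_library(spec)
  expect_equal(lib$latent, rep(1.5, 5))

  too_wide <- motif_spec("WIDE", consensus_pwm(strrep("A", 90)), plant_prob = 1)
  spec_bad <- library_spec(n = 2, motifs = list(too_wide), seed = 1)
  expect_error(generate_library(spec_bad), "WIDE")
})

test_that("latent expression is the stated additive model, exactly", {
  a <- motif_spec("A", consensus_pwm("TGACTCA"), effect = 1, plant_prob = 0)
  b <- motif_spec("B", consensus_pwm("CACGTGAC"), effect = -0.2, plant_prob = 0)
  spec <- library_spec(n = 1, baseline = 0.5, gc_coeff = 0.8,
                       motifs = list(a, b),
                       interactions = list(interaction_spec("A", "B", -3)),
                       seed = 1)
  s <- paste0(spec$flank5, strrep("ACGT", 20), spec$flank3)
  gc <- gc_content(s, c(18, 97))

  expect_equal(latent_expression(s, spec, NULL), 0.5 + 0.8 * gc)
  expect_equal(latent_expression(s, spec, "A:20:+"), 0.5 + 1 + 0.8 * gc)
  expect_equal(latent_expression(s, spec, "A:20:+;B:40:-"),
               0.5 + 1 - 0.2 - 3 + 0.8 * gc)

  # additivity without interactions and GC
  spec0 <- library_spec(n = 1, baseline = 0.5, gc_coeff = 0,
                        motifs = list(a, b), seed = 1)
  la <- latent_expression(s, spec0, "A:20:+")
  lb <- latent_expression(s, spec0, "B:40:-")
  lab <- latent_expression(s, spec0, "A:20:+;B:40:-")
  expect_identical(lab, la + lb - spec0$baseline)
})

test_that("independent planting yields the binomial co-occurrence rate", {
  a <- motif_spec("A", consensus_pwm("TGACTCA"), effect = 0, plant_prob = 0.5)
  b <- motif_spec("B", consensus_pwm("CACGTGAC"), effect = 0, plant_prob = 0.5)
  spec <- library_spec(n = 10000, motifs = list(a, b), cells_per_promoter = 1,
                       seed = 7)
  lib <- generate_library(spec)
  both <- vapply(parse_planted(lib$planted), function(p) {
    all(c("A", "B") %in% p$name)
  }, logical(1L))
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(both) - 0.25), 3 * se)
})

test_that("binned readout centres, clips, and matches the quadrature expectation", {
  spec <- library_spec(n = 1, n_bins = 18, cells_per_promoter = 50,
                       cell_noise_sd = 0, bin_range = c(-3, 3), seed = 1)
  width <- 6 / 18
  centre9 <- -3 + 8.5 * width
  expect_equal(binned_readout(centre9, spec, seed = 1), 9)
  expect_equal(binned_readout(-10, spec, seed = 1), 1)   # clipped low
  expect_equal(binned_readout(10, spec, seed = 1), 18)   # clipped high

  expect_error(binned_readout(0, library_spec(n = 1, bin_range = c(1, 1),
                                              seed = 1)),
               "low < high")

  # quadrature oracle: E[bin] = sum_b b * P(cell in bin b) for Gaussian cells
  spec2 <- library_spec(n = 1, n_bins = 18, cells_per_promoter = 10000,
                        cell_noise_sd = 1, bin_range = c(-3, 3), seed = 1)
  latent <- 0.7
  edges <- seq(-3, 3, length.out = 19)
  pr <- diff(pnorm(edges, mean = latent, sd = 1))
  pr[1] <- pr[1] + pnorm(edges[1], latent, 1)          # clipping mass
  pr[18] <- pr[18] + pnorm(edges[19], latent, 1, lower.tail = FALSE)
  expected <- sum(seq_len(18) * pr)
  obs <- vapply(1:200, function(s) binned_readout(latent, spec2, seed = s),
                numeric(1L))
  expect_lt(abs(mean(obs) - expected), 3 * sd(obs) / sqrt(200))
})

test_that("readout noise shrinks with cell count, emulating the train/test asymmetry", {
  base_spec <- function(cells) {
    library_spec(n = 1, n_bins = 18, cells_per_promoter = cells,
                 cell_noise_sd = 1, bin_range = c(-3, 3), seed = 1)
  }
  latent <- 0.3
  noiseless <- binned_readout(latent, base_spec(1e5), seed = 1)
  obs_at <- function(cells) {
    vapply(1:150, function(s) binned_readout(latent, base_spec(cells), seed = s),
           numeric(1L))
  }
  v2 <- mean((obs_at(2) - noiseless)^2)
  v20 <- mean((obs_at(20) - noiseless)^2)
  v100 <- mean((obs_at(100) - noiseless)^2)
  # 1/cells scaling within a factor of 2, and the strict 2-vs-100 ordering
  expect_gt(v2 / v20, 10 / 2)
  expect_lt(v2 / v20, 10 * 2)
  expect_gt(v2, v100)
})
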