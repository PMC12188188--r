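# Explainability: ISM against a closed-form linear oracle, entropy
# identities, Grad-CAM localization and activation embeddings.

test_that("ISM recovers a linear model's weights exactly, with 240 variants", {
  set.seed(21)
  W <- matrix(rnorm(4 * 110), 4, 110)
  f <- linear_predictor(W)
  s <- rand_seq(1, seed = 22)
  res <- ism(f, s)

  expect_equal(res$n_variants, 240L)
  expect_equal(sum(res$delta != 0), 240L)
  ref <- strsplit(s, "")[[1L]]
  for (p in 18:97) {
    ridx <- match(ref[p], c("A", "C", "G", "T"))
    expect_identical(res$delta[as.character(p), ridx], 0) # reference entry
    for (b in 1:4) {
      expect_lt(abs(res$delta[as.character(p), b] - (W[b, p] - W[ridx, p])),
                1e-9)
    }
    expect_lt(abs(res$importance[as.character(p)] -
                    (-mean(W[-ridx, p] - W[ridx, p]))), 1e-9)
  }
})

test_that("a constant model has zero deltas and N positions are skipped", {
  s <- rand_seq(1, seed = 23)
  res0 <- ism(function(x) rep(1, length(x)), s)
  expect_true(all(res0$delta == 0))
  expect_true(all(res0$importance == 0))

  sN <- s
  substr(sN, 30, 31) <- "NN"
  resN <- ism(function(x) nchar(x) * 0, sN)
  expect_equal(resN$skipped, c(30L, 31L))
  expect_equal(resN$n_variants, 240L - 6L)
  expect_true(all(is.na(resN$delta[c("30", "31"), ])))
})

test_that("ISM results are independent of evaluation batching", {
  m <- build_model(small_config(), 31)
  s <- rand_seq(1, seed = 32)
  r1 <- ism(m, s, batch_size = 1)
  r64 <- ism(m, s, batch_size = 64)
  expect_equal(r1$delta, r64$delta, tolerance = 1e-6)
  expect_equal(r1$importance, r64$importance, tolerance = 1e-6)
})

test_that("ISM-logo entropy has its analytic values", {
  expect_equal(ism_entropy(rep(0.3, 80)), log(80))
  one <- c(rep(0, 40), 5, rep(0, 39))
  expect_equal(ism_entropy(one), 0)
  two <- c(rep(0, 30), 2, rep(0, 30), -2, rep(0, 18)) # sign-blind
  expect_equal(ism_entropy(two), log(2))
  flat <- ism_entropy(rep(0, 80))
  expect_equal(as.numeric(flat), log(80))
  expect_true(attr(flat, "flat"))
  expect_equal(ism_entropy(rep(1, 16), base = 2), 4) # configurable base
})

test_that("Grad-CAM maps are nonnegative, length 110 at every layer, and zero for a constant model", {
  m <- build_model(small_config(), 41)
  seqs <- rand_seq(4, seed = 42)
  for (l in 1:2) {
    g <- gradcam(m, seqs, l)
    expect_equal(dim(g$scores), c(110L, 4L))
    expect_true(all(g$scores >= 0))
    expect_identical(g$scores, gradcam(m, seqs, l)$scores) # eval determinism
  }
  m0 <- m
  m0$par[["out.W"]][] <- 0 # output no longer depends on features
  g0 <- gradcam(m0, seqs, 2)
  expect_true(all(g0$scores == 0))
  expect_error(gradcam(function(x) 1, seqs, 1), "differentiable")
})

test_that("a matched single-filter model localizes a planted 8-mer", {
  target <- "TGACTCAG"
  k <- 9L
  cfg <- model_config(conv_channels = 1, kernel_sizes = k, batchnorm = FALSE,
                      maxpool = FALSE, fc_dims = integer(0),
                      residual_after = integer(0), input_channels = 4)
  m <- build_model(cfg, 1)
  # matched filter: +1 on the consensus base channel at each motif position,
  # bias so only near-perfect matches fire
  W <- matrix(0, k * 4, 1)
  bases <- strsplit(target, "")[[1L]]
  for (j in seq_along(bases)) {
    W[(j - 1L) * 4L + match(bases[j], c("A", "C", "G", "T")), 1] <- 1
  }
  m$par[["conv1.W"]] <- W
  m$par[["conv1.b"]][] <- -7
  m$par[["out.W"]][] <- 1 / 110
  m$par[["out.b"]] <- 0

  set.seed(43)
  hits <- 0L
  for (i in 1:100) {
    s <- rand_seq(1)
    pos <- sample(18:90, 1)
    substr(s, pos, pos + 7L) <- target
    g <- gradcam(m, s, 1)
    peak <- which.max(g$scores[, 1])
    # the filter window is centred, so the response peaks mid-motif
    if (abs(peak - (pos + 3.5)) <= 4) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("saliency averaging is positionwise and refuses mixed layers", {
  m <- build_model(small_config(), 51)
  g1 <- gradcam(m, rand_seq(1, seed = 52), 1)
  g2 <- gradcam(m, rand_seq(1, seed = 53), 1)
  expect_equal(average_saliency(g1), as.numeric(g1$scores[, 1]))
  expect_equal(average_saliency(list(g1, g2)),
               as.numeric((g1$scores[, 1] + g2$scores[, 1]) / 2))
  gL2 <- gradcam(m, rand_seq(1, seed = 54), 2)
  expect_error(average_saliency(list(g1, gL2)), "different layers")
})

test_that("activation embeddings flatten consistently and duplicate inputs", {
  m <- build_model(small_config(), 61)
  s <- rand_seq(1, seed = 62)
  emb <- activation_embedding(m, c(s, s), 2)
  expect_equal(emb[1, ], emb[2, ])
  a <- layer_output(m, c(s, s), 2)
  expect_equal(ncol(emb), prod(dim(a)[-1]))
})

test_that("gc_content counts informative bases only", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GATTACA"), 2 / 7)
  expect_equal(gc_content("GCNNAT", c(1, 6)), 2 / 4)
  expect_error(gc_content("NNN"), "only N")
})
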