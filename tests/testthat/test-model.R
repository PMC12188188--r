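# Architecture realization: parameter accounting against a closed-form
# oracle, residual wiring, layer outputs, analytic gradient verification and
# checkpoint round-trips.

test_that("parameter counts match the closed-form formula on random configs", {
  for (seed in 1:50) {
    cfg <- random_config(seed)
    m <- build_model(cfg, seed = seed)
    expect_identical(count_parameters(m), closed_form_count(cfg),
                     info = paste("config seed", seed))
  }
})

test_that("toy architectures count parameters exactly and freezing zeroes the count", {
  # 1 conv layer 4 -> 8 channels kernel 5, no batchnorm, no pooling, no
  # hidden FC: 4*8*5 + 8 conv + (110*8)*1 + 1 output
  cfg <- model_config(conv_channels = 8, kernel_sizes = 5,
                      batchnorm = FALSE, maxpool = FALSE,
                      fc_dims = integer(0), input_channels = 4)
  m <- build_model(cfg, 1)
  expect_identical(count_parameters(m), 4L * 8L * 5L + 8L + 110L * 8L + 1L)
  expect_identical(count_parameters(freeze_parameters(m)), 0L)
})

test_that("config validation rejects malformed architectures", {
  expect_error(model_config(8, kernel_sizes = 4), "odd")
  expect_error(model_config(c(8, 8), kernel_sizes = 5, residual_after = 1),
               "2..n_conv")
  expect_error(model_config(c(8, 8, 8), kernel_sizes = 5,
                            residual_after = c(2, 3)), "overlap")
  expect_error(model_config(8, kernel_sizes = 5, input_channels = 3L),
               "input_channels")
  expect_error(model_config(8, kernel_sizes = 5, dropout = 1), "dropout")
})

test_that("residual blocks add the identity skip", {
  # zero conv weights with a nonzero bias at layer 1: the block over layers
  # 2-3 must return its input unchanged through the identity skip
  cfg <- model_config(conv_channels = c(8, 8, 8), kernel_sizes = 3,
                      residual_after = 3, batchnorm = FALSE, maxpool = FALSE,
                      fc_dims = integer(0), input_channels = 4,
                      input_len = 20)
  m <- build_model(cfg, 1)
  for (nm in names(m$par)) m$par[[nm]][] <- 0
  m$par[["conv1.b"]][] <- 0.7
  batch <- encode_batch(substr(rand_seq(2, 20, seed = 1), 1, 20),
                        target_len = 20)
  a1 <- layer_output(m, batch, 1)
  a3 <- layer_output(m, batch, 3)
  expect_equal(unique(as.numeric(a1)), 0.7) # stem bias propagates
  expect_equal(a3, a1)                      # block output equals block input
})

test_that("layer outputs have the same-length convolution shape and flatten to h*w*c", {
  cfg <- small_config()
  m <- build_model(cfg, 2)
  batch <- encode_batch(rand_seq(3, seed = 4))
  for (l in 1:2) {
    a <- layer_output(m, batch, l)
    expect_equal(dim(a), c(3L, 110L, 1L, 8L))
    emb <- activation_embedding(m, batch, l)
    expect_equal(dim(emb), c(3L, prod(dim(a)[-1])))
  }
  expect_error(layer_output(m, batch, 3), "layer_index")

  # zero-weight model: all activations are ReLU(0) = 0
  m0 <- m
  for (nm in names(m0$par)) m0$par[[nm]][] <- 0
  m0$par[["conv1.gamma"]][] <- 0
  m0$par[["conv2.gamma"]][] <- 0
  expect_true(all(layer_output(m0, batch, 2) == 0))
})

test_that("forward prediction is deterministic, shape-checked and empty-safe", {
  m <- build_model(small_config(), 5)
  batch <- encode_batch(rand_seq(4, seed = 5))
  p1 <- predict(m, batch)
  p2 <- predict(m, batch)
  expect_identical(p1, p2)
  expect_length(p1, 4L)
  expect_true(all(is.finite(p1)))
  expect_length(predict(m, character(0)), 0L)
  wrong <- encode_batch(rand_seq(2, seed = 6), "onehotWithN")
  expect_error(predict(m, wrong), "channels")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- model_config(conv_channels = c(6, 6, 8), kernel_sizes = c(5, 3, 3),
                      residual_after = 3, batchnorm = TRUE, maxpool = TRUE,
                      pool_width = 4, fc_dims = 7, dropout = 0,
                      input_channels = 4, input_len = 20)
  m <- build_model(cfg, seed = 3)
  set.seed(42)
  n <- 5
  x <- array(rnorm(20 * n * 4), c(20, n, 4))
  y <- rnorm(n)
  lossfn <- function(mm) {
    loss_value(nn_forward(mm, x, train = TRUE)$pred, y, "MSE")
  }
  fw <- nn_forward(m, x, train = TRUE, keep_cache = TRUE)
  bw <- nn_backward(m, fw$cache, loss_grad(fw$pred, y, "MSE"))
  eps <- 1e-6
  for (nm in names(m$par)) {
    idx <- sample(length(m$par[[nm]]), min(3, length(m$par[[nm]])))
    for (i in idx) {
      mp <- m; mp$par[[nm]][i] <- mp$par[[nm]][i] + eps
      mm2 <- m; mm2$par[[nm]][i] <- mm2$par[[nm]][i] - eps
      g_num <- (lossfn(mp) - lossfn(mm2)) / (2 * eps)
      g_ana <- bw$grads[[nm]][i]
      expect_lt(abs(g_num - g_ana), 1e-5 * max(1, abs(g_num)),
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints reconstruct an eval-identical model", {
  m <- build_model(small_config(), 11)
  batch <- encode_batch(rand_seq(3, seed = 7))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_camformer(m, path)
  m2 <- load_camformer(path)
  expect_identical(predict(m2, batch), predict(m, batch))
  expect_identical(m2$config, m$config)
})
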