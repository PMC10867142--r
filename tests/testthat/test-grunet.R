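test_that("analytic gradients match finite differences", {
  cfg <- grunet_config(input_grid = c(14, 12), conv_channels = c(2, 3),
                       gru_units = 4, seed = 3)
  shapes <- bovinecall:::make_shapes(cfg)
  set.seed(5)
  B <- 3
  x <- array(runif(B * 14 * 12), dim = c(B, 14, 12))
  y <- factor(c("a", "b", "a"))
  onehot <- diag(2)[as.integer(y), ]
  params <- bovinecall:::init_params(cfg, 2)
  lossfun <- function(pl) {
    pr <- bovinecall:::net_forward(x, pl, shapes)$probs
    -sum(log(pr[cbind(1:B, as.integer(y))])) / B
  }
  cache <- bovinecall:::net_forward(x, params, shapes, keep = TRUE)
  grads <- bovinecall:::net_backward(cache, onehot, params, shapes)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (trial in 1:3) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4,
                label = paste("gradient of", nm))
    }
  }
})

test_that("spectrogram batches are shaped and normalized to [0, 1]", {
  recs <- tiny_corpus()$recordings[1:10]
  xs <- prepare_spectrogram_batch(recs, grid = c(64, 32))
  expect_equal(dim(xs), c(10, 64, 32))
  expect_gte(min(xs), 0)
  expect_lte(max(xs), 1)
  # silent input: a constant clipped spectrogram, guarded to all zeros
  const <- call_recording(rep(0, 44100), 44100, "const")
  xc <- prepare_spectrogram_batch(list(const), grid = c(64, 32))
  expect_true(all(xc == 0))
  expect_error(prepare_spectrogram_batch(list(), grid = c(64, 32)), "empty")
})

test_that("probability outputs are normalized and configs fail fast", {
  cfg <- grunet_config(input_grid = c(20, 16), conv_channels = c(2, 2),
                       gru_units = 4, epochs = 2, seed = 1)
  set.seed(1)
  x <- array(runif(8 * 20 * 16), dim = c(8, 20, 16))
  y <- factor(rep(c("a", "b"), 4))
  fit <- grunet(x, y, cfg)
  p <- predict(fit, x, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-5))
  expect_error(grunet(x, factor(rep("a", 8)), cfg), "single class")
  expect_error(grunet_config(input_grid = c(4, 4)), "input_grid")
  expect_error(predict(fit, array(0, dim = c(2, 10, 10))), "input_grid")
})

test_that("training loss decreases and the net can overfit a small corpus", {
  corpus <- demo_corpus()
  xs <- demo_spectrograms()
  y <- factor(corpus$ground_truth$call_type)
  # pick 32 calls with both classes present
  lf <- which(y == "LF")[1:6]
  hf <- which(y == "HF")[1:26]
  idx <- c(lf, hf)
  cfg <- grunet_config(input_grid = c(64, 32), conv_channels = c(8, 16),
                       gru_units = 32, epochs = 200, seed = 5)
  fit <- grunet(xs[idx, , , drop = FALSE], y[idx], cfg)
  expect_equal(mean(predict(fit, xs[idx, , , drop = FALSE]) == y[idx]), 1)
  expect_lte(nrow(fit$history), 200)
  h <- fit$history$loss
  expect_lt(h[min(5, length(h))], h[1])
  # determinism under a fixed seed
  cfg2 <- grunet_config(input_grid = c(64, 32), conv_channels = c(4, 4),
                        gru_units = 8, epochs = 3, seed = 9)
  f1 <- grunet(xs[idx, , , drop = FALSE], y[idx], cfg2)
  f2 <- grunet(xs[idx, , , drop = FALSE], y[idx], cfg2)
  expect_identical(f1$history, f2$history)
})
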