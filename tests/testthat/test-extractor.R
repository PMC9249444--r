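test_that("window_split covers the slice and pads by replication", {
  v <- rnorm(250)
  w1 <- window_split(v, 250)
  expect_equal(nrow(w1), 1L)
  expect_equal(as.vector(w1[1, ]), v)

  w <- window_split(v, 25)
  expect_equal(dim(w), c(10L, 25L))
  expect_equal(as.vector(t(w)), v)   # concatenation oracle

  wp <- window_split(v, 32)
  expect_equal(dim(wp), c(8L, 32L))
  cat_v <- as.vector(t(wp))
  expect_equal(cat_v[1:250], v)
  expect_true(all(cat_v[251:256] == v[250]))  # edge-value padding
})

test_that("level-1 encoding shares weights and is stateless across windows", {
  cfg <- tiny_config()
  par <- init_extractor(cfg)
  w <- matrix(rnorm(10), nrow = 1)
  two <- rbind(w, w)
  s <- level1_encode(two, cfg, par)
  expect_equal(s[1, ], s[2, ])                       # weight sharing
  s1 <- level1_encode(w, cfg, par)
  expect_equal(s1[1, ], s[1, ])                      # no cross-window state

  # zero input with zero biases is a fixed point for plainRNN/tanh
  cfg2 <- tiny_config(cell_type = "plainRNN")
  par2 <- init_extractor(cfg2)
  par2$l1$b[] <- 0
  z <- level1_encode(matrix(0, 1, 10), cfg2, par2)
  expect_equal(as.vector(z), rep(0, cfg2$hidden1))
})

test_that("level-2 encoding has the contracted output shape and order sensitivity", {
  for (m in c(8L, 64L)) {
    cfg <- extractor_config(omega = 10, hidden1 = 6, hidden2 = 8, m = m, seed = 5)
    par <- init_extractor(cfg)
    su <- matrix(rnorm(5 * 6), 5, 6)
    f <- level2_encode(su, cfg, par)
    expect_length(f, m)
    expect_identical(f, level2_encode(su, cfg, par))  # determinism
    frev <- level2_encode(su[5:1, ], cfg, par)
    expect_gt(sqrt(sum((f - frev)^2)), 0)             # order matters
  }
  cfg <- tiny_config()
  expect_error(level2_encode(matrix(0, 0, 6), cfg, init_extractor(cfg)),
               "empty")
})

test_that("extract_features equals the manual composition and batches agree", {
  cfg <- tiny_config()
  par <- init_extractor(cfg)
  set.seed(8)
  x <- rnorm(45)
  manual <- level2_encode(level1_encode(window_split(x, cfg$omega), cfg, par),
                          cfg, par)
  expect_equal(extract_features(x, cfg, par), manual, tolerance = 1e-12)

  xb <- matrix(rnorm(5 * 45), 5, 45)
  Fb <- extract_features(xb, cfg, par)
  expect_equal(dim(Fb), c(5L, cfg$m))
  for (i in 1:5) {
    expect_equal(Fb[i, ], extract_features(xb[i, ], cfg, par),
                 tolerance = 1e-12)
  }
})

test_that("input gradients match central finite differences for every cell type", {
  for (ct in c("plainRNN", "GRU", "LSTM", "BiLSTM")) {
    cfg <- extractor_config(omega = 7, cell_type = ct, hidden1 = 4,
                            hidden2 = 5, m = 6, seed = 4)
    par <- init_extractor(cfg)
    set.seed(10)
    x <- rnorm(20)
    entry <- 3L
    g <- feature_input_gradient(x, entry, cfg, par)
    gfd <- fdiff(function(v) extract_features(v, cfg, par)[entry], x)
    expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-4)
  }
})

test_that("parameter count is independent of the slice length (weight sharing)", {
  cfg <- extractor_config()
  par <- init_extractor(cfg)
  n_par <- count_parameters(par)
  # the same parameters process slices of any length
  f1 <- extract_features(rnorm(250), cfg, par)
  f2 <- extract_features(rnorm(500), cfg, par)
  expect_length(f1, cfg$m)
  expect_length(f2, cfg$m)
  expect_identical(count_parameters(par), n_par)
})

test_that("a default trained model serializes under 1 MB", {
  ds <- small_dataset(n = 8, seed = 3)
  parts <- split_dataset(ds, split_spec(seed = 1))
  ens <- train_ensemble(parts$train, parts$val, epochs = 2, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_model(ens, path)
  expect_lt(file.info(path)$size, 1024^2)
  back <- load_model(path)
  expect_identical(predict(back, parts$test$x), predict(ens, parts$test$x))
})
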