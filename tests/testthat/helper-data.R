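# shared fixtures, all generated in code

small_dataset <- function(n = 30, separation = 1, seed = 1) {
  make_dataset(c(N = n, S = n, V = n), separation = separation, seed = seed)
}

# small extractor for fast unit tests
tiny_config <- function(cell_type = "GRU", seed = 2) {
  extractor_config(omega = 10L, cell_type = cell_type, hidden1 = 6L,
                   hidden2 = 8L, m = 12L, seed = seed)
}

# a classifier with reproducible random weights
seeded_classifier <- function(m = 12, h1 = 5, h2 = 4, seed = 3,
                              activation = "tanh") {
  with_seed <- microbeat:::with_seed
  with_seed(seed, init_classifier(m, h1, h2, activation = activation,
                                  class_symbol = "N"))
}

# central finite differences of a scalar function
fdiff <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
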