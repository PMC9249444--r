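# Batched recurrent cells with analytic backpropagation-through-time.
#
# All cells share one calling convention. Sequences are a 3-d array
# X[batch, time, dim]; the forward pass returns the final hidden state
# (batch x H, or batch x 2H for the bidirectional cell) plus a cache; the
# backward pass maps a gradient w.r.t. the final state to gradients w.r.t.
# every parameter and every input sample. Row-vector convention throughout:
# pre-activations are X %*% Wx + H %*% Wh + b.
#
# Gate orders: GRU (r, z, n) with n = tanh(xn + r * hn + bn);
# LSTM (i, f, g, o). Initial states are zero.

CELL_TYPES <- c("plainRNN", "GRU", "LSTM", "BiLSTM")

sigm <- function(x) 1 / (1 + exp(-x))

# parameter shapes for one direction of a cell
cell_param_shapes <- function(cell_type, input_size, hidden) {
  mult <- switch(cell_type, plainRNN = 1L, GRU = 3L, LSTM = 4L, BiLSTM = 4L)
  list(Wx = c(input_size, mult * hidden),
       Wh = c(hidden, mult * hidden),
       b = c(1L, mult * hidden))
}

init_cell_params <- function(cell_type, input_size, hidden) {
  if (!cell_type %in% CELL_TYPES) {
    stop_mb(sprintf("unknown cell_type '%s'", cell_type))
  }
  one_dir <- function() {
    sh <- cell_param_shapes(cell_type, input_size, hidden)
    p <- lapply(sh, function(d) {
      fan_in <- d[1]
      matrix(stats::runif(prod(d), -1, 1) / sqrt(fan_in), d[1], d[2])
    })
    # memory-friendly gate bias init (standard forget/update-gate trick):
    # start with strong state retention so early-sequence information
    # survives to the final hidden state
    if (cell_type == "GRU") p$b[1L, hidden + seq_len(hidden)] <- 1
    if (cell_type %in% c("LSTM", "BiLSTM")) {
      p$b[1L, hidden + seq_len(hidden)] <- 1
    }
    p
  }
  if (cell_type == "BiLSTM") list(fwd = one_dir(), bwd = one_dir()) else one_dir()
}

cell_output_size <- function(cell_type, hidden) {
  if (cell_type == "BiLSTM") 2L * hidden else hidden
}

# slice time step t from X[b, t, d] as a (b x d) matrix without dropping dims
.xt <- function(X, t) {
  matrix(X[, t, ], nrow = dim(X)[1], ncol = dim(X)[3])
}

## ---- plain RNN (tanh) -------------------------------------------------

.rnn_forward <- function(params, X, want_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- ncol(params$Wh)
  h <- matrix(0, B, H)
  hs <- if (want_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- tanh(.xt(X, t) %*% params$Wx +
              h %*% params$Wh + matrix(params$b, B, H, byrow = TRUE))
    if (want_cache) hs[[t]] <- h
  }
  list(h = h, cache = if (want_cache) list(X = X, hs = hs))
}

.rnn_backward <- function(params, cache, dh) {
  X <- cache$X; hs <- cache$hs
  B <- dim(X)[1]; Tn <- dim(X)[2]; D <- dim(X)[3]; H <- ncol(params$Wh)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dX <- array(0, dim(X))
  for (t in rev(seq_len(Tn))) {
    ht <- hs[[t]]
    da <- dh * (1 - ht^2)
    hprev <- if (t > 1L) hs[[t - 1L]] else matrix(0, B, H)
    dWx <- dWx + crossprod(.xt(X, t), da)
    dWh <- dWh + crossprod(hprev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(params$Wx)
    dh <- da %*% t(params$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

## ---- GRU --------------------------------------------------------------

.gru_forward <- function(params, X, want_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- ncol(params$Wh) %/% 3L
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  h <- matrix(0, B, H)
  bmat <- matrix(params$b, B, 3L * H, byrow = TRUE)
  steps <- if (want_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- .xt(X, t) %*% params$Wx + bmat
    hh <- h %*% params$Wh
    r <- sigm(a[, ir, drop = FALSE] + hh[, ir, drop = FALSE])
    z <- sigm(a[, iz, drop = FALSE] + hh[, iz, drop = FALSE])
    hn <- hh[, inn, drop = FALSE]
    n <- tanh(a[, inn, drop = FALSE] + r * hn)
    hnew <- (1 - z) * n + z * h
    if (want_cache) steps[[t]] <- list(r = r, z = z, n = n, hn = hn, hprev = h)
    h <- hnew
  }
  list(h = h, cache = if (want_cache) list(X = X, steps = steps))
}

.gru_backward <- function(params, cache, dh) {
  X <- cache$X; steps <- cache$steps
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- ncol(params$Wh) %/% 3L
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dX <- array(0, dim(X))
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    dn <- dh * (1 - st$z)
    dz <- dh * (st$hprev - st$n)
    dh_prev <- dh * st$z
    dan <- dn * (1 - st$n^2)            # grad wrt (an + r * hn)
    dr <- dan * st$hn
    dhn <- dan * st$r
    daz <- dz * st$z * (1 - st$z)       # grad wrt (az + hz)
    dar <- dr * st$r * (1 - st$r)       # grad wrt (ar + hr)
    dA <- cbind(dar, daz, dan)          # wrt x-path pre-activations + biases
    dHH <- cbind(dar, daz, dhn)         # wrt h-path pre-activations
    dWx <- dWx + crossprod(.xt(X, t), dA)
    db <- db + colSums(dA)
    dWh <- dWh + crossprod(st$hprev, dHH)
    dX[, t, ] <- dA %*% t(params$Wx)
    dh <- dh_prev + dHH %*% t(params$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

## ---- LSTM -------------------------------------------------------------

.lstm_forward <- function(params, X, want_cache = FALSE, reverse = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- ncol(params$Wh) %/% 4L
  ii <- seq_len(H); if_ <- H + ii; ig <- 2L * H + ii; io <- 3L * H + ii
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  bmat <- matrix(params$b, B, 4L * H, byrow = TRUE)
  order <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  steps <- if (want_cache) vector("list", Tn)
  for (t in order) {
    a <- .xt(X, t) %*% params$Wx + h %*% params$Wh + bmat
    i <- sigm(a[, ii, drop = FALSE]); f <- sigm(a[, if_, drop = FALSE])
    g <- tanh(a[, ig, drop = FALSE]); o <- sigm(a[, io, drop = FALSE])
    cnew <- f * cst + i * g
    hnew <- o * tanh(cnew)
    if (want_cache) {
      steps[[t]] <- list(i = i, f = f, g = g, o = o,
                         cprev = cst, cnew = cnew, hprev = h)
    }
    cst <- cnew; h <- hnew
  }
  list(h = h, cache = if (want_cache) list(X = X, steps = steps, reverse = reverse))
}

.lstm_backward <- function(params, cache, dh) {
  X <- cache$X; steps <- cache$steps
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- ncol(params$Wh) %/% 4L
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dX <- array(0, dim(X))
  dc <- matrix(0, B, H)
  order <- if (isTRUE(cache$reverse)) seq_len(Tn) else rev(seq_len(Tn))
  for (t in order) {
    st <- steps[[t]]
    tc <- tanh(st$cnew)
    do_ <- dh * tc
    dc <- dc + dh * st$o * (1 - tc^2)
    df <- dc * st$cprev
    di <- dc * st$g
    dg <- dc * st$i
    dc <- dc * st$f
    dA <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(.xt(X, t), dA)
    dWh <- dWh + crossprod(st$hprev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dX[, t, ] + dA %*% t(params$Wx)
    dh <- dA %*% t(params$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

## ---- dispatch ---------------------------------------------------------

cell_forward <- function(cell_type, params, X, want_cache = FALSE) {
  switch(cell_type,
    plainRNN = .rnn_forward(params, X, want_cache),
    GRU = .gru_forward(params, X, want_cache),
    LSTM = .lstm_forward(params, X, want_cache),
    BiLSTM = {
      fw <- .lstm_forward(params$fwd, X, want_cache, reverse = FALSE)
      bw <- .lstm_forward(params$bwd, X, want_cache, reverse = TRUE)
      list(h = cbind(fw$h, bw$h),
           cache = if (want_cache) list(fwd = fw$cache, bwd = bw$cache))
    },
    stop_mb(sprintf("unknown cell_type '%s'", cell_type)))
}

cell_backward <- function(cell_type, params, cache, dh) {
  switch(cell_type,
    plainRNN = .rnn_backward(params, cache, dh),
    GRU = .gru_backward(params, cache, dh),
    LSTM = .lstm_backward(params, cache, dh),
    BiLSTM = {
      H <- ncol(params$fwd$Wh) %/% 4L
      fw <- .lstm_backward(params$fwd, cache$fwd, dh[, seq_len(H), drop = FALSE])
      bw <- .lstm_backward(params$bwd, cache$bwd, dh[, H + seq_len(H), drop = FALSE])
      list(grads = list(fwd = fw$grads, bwd = bw$grads), dX = fw$dX + bw$dX)
    },
    stop_mb(sprintf("unknown cell_type '%s'", cell_type)))
}
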