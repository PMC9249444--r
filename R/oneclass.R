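# Per-class one-class mini-classifier bank.
#
# Each class gets a three-layer scorer f(F) = W3' s(W2' s(W1' F)) + biases
# (s = hidden activation, default tanh; the sigmoid appears only inside the
# negative log-likelihood). The one-class loss for classifier i is
#
#   loss_i = E[-log sigmoid(f_i(F))]                (positive-class NLL)
#          + eta * E[ ||d f_i / d F||_2 ^ c ]       (H-reg gradient penalty)
#          + pi  * ||theta_i - mu*_{1:i-1}||_2^2    (parameter anchor)
#
# over class-i examples only. After training, the KL barycenter of the
# per-classifier parameter distributions (isotropic-Gaussian model, so the
# barycenter mean is sum(phi_i * theta_i)) is scaled by tau and subtracted
# from every theta -- the shared-knowledge removal step.

#' Initialise a three-layer mini-classifier
#'
#' Layer maps `m -> h1 -> h2 -> 1` with biases; weights uniform in
#' `±1/sqrt(fan_in)` from the current RNG stream.
#'
#' @param m input (feature) length.
#' @param h1,h2 hidden layer sizes.
#' @param activation hidden activation, `"tanh"` or `"identity"`.
#' @param class_symbol the class this scorer is responsible for.
#' @return An object of class `mini_classifier`.
#' @export
init_classifier <- function(m, h1 = 32L, h2 = 16L, activation = "tanh",
                            class_symbol = NA_character_) {
  m <- check_count(m, "m", lower = 1L)
  h1 <- check_count(h1, "h1", lower = 1L)
  h2 <- check_count(h2, "h2", lower = 1L)
  if (!activation %in% c("tanh", "identity")) {
    stop_mb("activation must be 'tanh' or 'identity'")
  }
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  structure(list(W1 = u(m, h1), b1 = numeric(h1),
                 W2 = u(h1, h2), b2 = numeric(h2),
                 W3 = u(h2, 1L), b3 = 0,
                 activation = activation, class_symbol = class_symbol),
            class = "mini_classifier")
}

clf_act <- function(z, activation) if (activation == "tanh") tanh(z) else z
clf_act_d <- function(a, activation) if (activation == "tanh") 1 - a^2 else a * 0 + 1
# second derivative expressed through the activation value a = s(z)
clf_act_dd <- function(a, activation) {
  if (activation == "tanh") -2 * a * (1 - a^2) else a * 0
}

#' Flatten mini-classifier parameters to theta
#'
#' Deterministic flattening order: `W1` (column-major), `b1`, `W2`, `b2`,
#' `W3`, `b3`. This order is the contract for every theta-space operation
#' (anchoring, barycenter, removal).
#'
#' @param clf a `mini_classifier`.
#' @return Numeric parameter vector.
#' @export
flatten_theta <- function(clf) {
  c(as.vector(clf$W1), clf$b1, as.vector(clf$W2), clf$b2,
    as.vector(clf$W3), clf$b3)
}

#' Write a theta vector back into a mini-classifier
#'
#' @param clf a `mini_classifier` providing the shapes.
#' @param theta vector in [flatten_theta()] order.
#' @return The updated `mini_classifier`.
#' @export
unflatten_theta <- function(clf, theta) {
  sizes <- c(length(clf$W1), length(clf$b1), length(clf$W2), length(clf$b2),
             length(clf$W3), 1L)
  if (length(theta) != sum(sizes)) {
    stop_mb(sprintf("theta length %d does not match classifier (%d parameters)",
                    length(theta), sum(sizes)))
  }
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  clf$W1[] <- theta[starts[1]:ends[1]]
  clf$b1 <- theta[starts[2]:ends[2]]
  clf$W2[] <- theta[starts[3]:ends[3]]
  clf$b2 <- theta[starts[4]:ends[4]]
  clf$W3[] <- theta[starts[5]:ends[5]]
  clf$b3 <- theta[ends[6]]
  clf
}

# forward pass over a feature batch (n x m); returns raw scores and cache
clf_forward <- function(clf, Fm) {
  Fm <- as.matrix(Fm)
  if (ncol(Fm) != nrow(clf$W1)) {
    stop_mb(sprintf("feature length %d does not match classifier input %d",
                    ncol(Fm), nrow(clf$W1)))
  }
  n <- nrow(Fm)
  z1 <- Fm %*% clf$W1 + matrix(clf$b1, n, length(clf$b1), byrow = TRUE)
  a1 <- clf_act(z1, clf$activation)
  z2 <- a1 %*% clf$W2 + matrix(clf$b2, n, length(clf$b2), byrow = TRUE)
  a2 <- clf_act(z2, clf$activation)
  f <- drop(a2 %*% clf$W3) + clf$b3
  list(f = f, Fm = Fm, a1 = a1, a2 = a2)
}

#' Raw score of a mini-classifier
#'
#' Evaluates the three-layer scorer on one feature vector or a batch;
#' returns the raw (pre-sigmoid) scalar score(s).
#'
#' @param clf a `mini_classifier`.
#' @param F feature vector of length `m` or an `n x m` matrix.
#' @return Numeric score(s).
#' @export
score <- function(clf, F) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  drop(clf_forward(clf, F)$f)
}

#' Negative log-likelihood term of the one-class loss
#'
#' Mean over a batch of class-i features of `-log(sigmoid(f_i(F)))`. Pushes
#' the in-class score up during training.
#'
#' @param clf a `mini_classifier`.
#' @param F feature batch (`n x m` matrix or single vector), all class-i.
#' @return Positive scalar.
#' @export
nll_term <- function(clf, F) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  if (nrow(F) == 0L) stop_mb("empty batch")
  f <- clf_forward(clf, F)$f
  mean(.nll_of_score(f))
}

# -log sigmoid(f) stable in both tails
.nll_of_score <- function(f) ifelse(f > 0, log1p(exp(-f)), -f + log1p(exp(f)))

#' Gradient-penalty (H-reg) term
#'
#' Mean over the batch of `||d f / d F||_2^c`, the c-th power of the input
#' gradient norm of the scorer. The gradient is computed in closed form for
#' the three-layer perceptron.
#'
#' @param clf a `mini_classifier`.
#' @param F feature batch (matrix or single vector).
#' @param c exponent hyperparameter (> 0).
#' @return Non-negative scalar.
#' @export
hreg_term <- function(clf, F, c = 2) {
  check_number(c, "c", lower = 0, strict_lower = TRUE)
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  if (nrow(F) == 0L) stop_mb("empty batch")
  fw <- clf_forward(clf, F)
  g <- clf_input_gradient(clf, fw)
  s2 <- rowSums(g^2)
  mean(s2^(c / 2))
}

# rows of d f / d F for a cached forward pass
clf_input_gradient <- function(clf, fw) {
  act <- clf$activation
  u2 <- clf_act_d(fw$a2, act) * matrix(clf$W3, nrow(fw$a2), length(clf$W3),
                                       byrow = TRUE)
  u1 <- clf_act_d(fw$a1, act) * (u2 %*% t(clf$W2))
  u1 %*% t(clf$W1)
}

#' Parameter anchor term
#'
#' Squared Euclidean distance between the classifier's theta and the mean
#' parameter vector of the previously initialised classifiers; defined as 0
#' for the first classifier (`mu_prev = NULL`).
#'
#' @param clf a `mini_classifier`.
#' @param mu_prev anchor vector in theta space, or `NULL`.
#' @return Non-negative scalar.
#' @export
anchor_term <- function(clf, mu_prev = NULL) {
  if (is.null(mu_prev)) return(0)
  theta <- flatten_theta(clf)
  if (length(mu_prev) != length(theta)) {
    stop_mb("`mu_prev` length does not match theta")
  }
  sum((theta - mu_prev)^2)
}

#' One-class loss
#'
#' `nll + eta * hreg + pi * anchor`, the per-class training objective.
#'
#' @param clf a `mini_classifier`.
#' @param F class-i feature batch.
#' @param hyper list with `eta`, `c`, `pi` (see [ensemble_hyper()]).
#' @param mu_prev anchor vector or `NULL`.
#' @return Scalar loss.
#' @export
one_class_loss <- function(clf, F, hyper = ensemble_hyper(), mu_prev = NULL) {
  nll_term(clf, F) +
    hyper$eta * hreg_term(clf, F, c = hyper$c) +
    hyper$pi * anchor_term(clf, mu_prev)
}

#' Ensemble hyperparameters
#'
#' @param eta weight of the H-reg gradient penalty (>= 0).
#' @param c exponent of the gradient-norm penalty (> 0).
#' @param pi weight of the parameter anchor (>= 0).
#' @param tau shared-knowledge removal step (>= 0).
#' @param phi mixing ratios over classes (simplex); `NULL` means uniform.
#' @return List of validated hyperparameters.
#' @export
ensemble_hyper <- function(eta = 1, c = 2, pi = 0.1, tau = 0.1, phi = NULL) {
  check_number(eta, "eta", lower = 0)
  check_number(c, "c", lower = 0, strict_lower = TRUE)
  check_number(pi, "pi", lower = 0)
  check_number(tau, "tau", lower = 0)
  if (!is.null(phi)) {
    if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) {
      stop_mb("`phi` must be non-negative and sum to 1")
    }
  }
  list(eta = eta, c = c, pi = pi, tau = tau, phi = phi)
}

#' Initialise classifier i from its predecessors
#'
#' The first classifier keeps its seeded random initialisation. Classifier
#' `i > 1` starts at the arithmetic mean of theta_1..theta_{i-1} plus a
#' small seeded Gaussian perturbation (sd 0.01) to break symmetry; the same
#' mean is the anchor `mu_prev` for its loss.
#'
#' @param classifiers list of `mini_classifier` (1..i-1 populated).
#' @param i index of the classifier to initialise.
#' @param perturb_sd perturbation standard deviation.
#' @return List with `clf` (initialised classifier `i`) and `mu_prev`
#'   (anchor vector, `NULL` for `i = 1`).
#' @export
init_from_previous <- function(classifiers, i, perturb_sd = 0.01) {
  i <- check_count(i, "i", lower = 1L)
  clf <- classifiers[[i]]
  if (i == 1L) return(list(clf = clf, mu_prev = NULL))
  thetas <- vapply(classifiers[seq_len(i - 1L)], flatten_theta,
                   numeric(length(flatten_theta(clf))))
  mu <- if (i == 2L) drop(thetas) else rowMeans(thetas)
  theta_i <- mu + stats::rnorm(length(mu), 0, perturb_sd)
  list(clf = unflatten_theta(clf, theta_i), mu_prev = mu)
}

#' Shared knowledge of an ensemble (KL barycenter)
#'
#' Models each classifier's posterior parameter distribution as an
#' isotropic Gaussian centred at theta_i with common variance; the
#' mixing-weighted KL barycenter over Gaussians is then the moment-matched
#' mean, so the shared-knowledge vector is `rho* = sum(phi_i * theta_i)`.
#'
#' @param ensemble a `micro_ensemble` (or plain list with `classifiers` and
#'   `hyper$phi`).
#' @return Numeric vector in theta space.
#' @export
shared_knowledge <- function(ensemble) {
  clfs <- ensemble$classifiers
  T <- length(clfs)
  phi <- ensemble$hyper$phi %||% rep(1 / T, T)
  if (length(phi) != T) stop_mb("`phi` length must equal the number of classifiers")
  if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) {
    stop_mb("`phi` must be non-negative and sum to 1")
  }
  thetas <- lapply(clfs, flatten_theta)
  len <- unique(vapply(thetas, length, integer(1)))
  if (length(len) != 1L) stop_mb("classifier parameter vectors are not aligned")
  rho <- numeric(len)
  for (i in seq_len(T)) rho <- rho + phi[i] * thetas[[i]]
  rho
}

#' Remove shared knowledge from every classifier
#'
#' Applies `theta_i* = theta_i - tau * rho*` with the same barycenter
#' `rho*` for all classifiers. Intended as a one-shot post-training update
#' before evaluation; repeated application keeps shifting parameters.
#'
#' @param ensemble a `micro_ensemble`.
#' @param tau removal step; defaults to the ensemble's `hyper$tau`.
#' @return The updated ensemble (with `shared_removed = TRUE`).
#' @export
remove_shared <- function(ensemble, tau = NULL) {
  tau <- tau %||% ensemble$hyper$tau
  check_number(tau, "tau", lower = 0)
  rho <- shared_knowledge(ensemble)
  ensemble$classifiers <- lapply(ensemble$classifiers, function(clf) {
    unflatten_theta(clf, flatten_theta(clf) - tau * rho)
  })
  ensemble$shared_removed <- TRUE
  ensemble
}

#' Construct an ensemble model
#'
#' @param extractor list with `config` ([extractor_config()]) and `params`.
#' @param classifiers list of `mini_classifier`, one per class symbol.
#' @param hyper hyperparameters from [ensemble_hyper()].
#' @param class_symbols ordered class labels.
#' @param feature_norm optional feature standardisation layer, a list with
#'   `center` and `scale` vectors of length `m`. Raw-score argmax fusion
#'   needs the per-class scorers to be comparable; removing the
#'   class-common feature component (centering) and equalising feature
#'   scales is what makes the comparison meaningful.
#' @return An object of class `micro_ensemble`.
#' @export
micro_ensemble <- function(extractor, classifiers, hyper = ensemble_hyper(),
                           class_symbols, feature_norm = NULL) {
  if (length(classifiers) != length(class_symbols)) {
    stop_mb("one classifier per class symbol is required")
  }
  structure(list(extractor = extractor, classifiers = classifiers,
                 hyper = hyper, class_symbols = as.character(class_symbols),
                 feature_norm = feature_norm,
                 shared_removed = FALSE),
            class = "micro_ensemble")
}

#' Apply an ensemble's feature standardisation
#'
#' Two layer kinds are supported: diagonal (`center` + `scale`, per-feature
#' z-scoring) and whitening (`center` + `transform`, a full decorrelating
#' map), and both reduce to an affine transform of the feature vector.
#'
#' @param ensemble a `micro_ensemble`.
#' @param F feature vector or matrix.
#' @return Standardised features (unchanged if the model has no
#'   standardisation layer).
#' @export
standardize_features <- function(ensemble, F) {
  fn <- ensemble$feature_norm
  if (is.null(fn)) return(F)
  vec <- !is.matrix(F)
  if (vec) F <- matrix(F, nrow = 1)
  Fc <- sweep(F, 2L, fn$center)
  out <- if (!is.null(fn$transform)) Fc %*% fn$transform else
    sweep(Fc, 2L, fn$scale, "/")
  if (vec) drop(out) else out
}

# shrinkage whitening map based on the pooled within-class covariance:
# (S_w + lambda_frac * mean-diag(S_w) * I)^(-1/2). Whitening by the
# within-class scatter equalises the noise scale of every feature
# direction without shrinking between-class separations, so weakly
# expressed but reliable class differences (the confusable-class regime)
# are not drowned by dominant variance axes. Falls back to the total
# covariance when labels are absent.
whitening_map <- function(F, labels = NULL, lambda_frac = 0.1) {
  ctr <- colMeans(F)
  S <- if (is.null(labels)) {
    stats::cov(F)
  } else {
    cls <- unique(labels)
    pooled <- 0
    dof <- 0
    for (cl in cls) {
      Fc <- F[labels == cl, , drop = FALSE]
      if (nrow(Fc) >= 2L) {
        pooled <- pooled + stats::cov(Fc) * (nrow(Fc) - 1L)
        dof <- dof + nrow(Fc) - 1L
      }
    }
    if (dof < 1) stats::cov(F) else pooled / dof
  }
  lam <- lambda_frac * mean(diag(S))
  if (!is.finite(lam) || lam <= 0) lam <- 1e-8
  eig <- eigen(S + lam * diag(ncol(F)), symmetric = TRUE)
  W <- eig$vectors %*% diag(1 / sqrt(pmax(eig$values, 1e-12))) %*% t(eig$vectors)
  list(center = ctr, transform = W)
}

#' @export
print.micro_ensemble <- function(x, ...) {
  np <- count_parameters(x$extractor$params) +
    sum(vapply(x$classifiers, function(c) length(flatten_theta(c)), numeric(1)))
  cat(sprintf("<micro_ensemble: %d classes (%s), %s cell, %d parameters%s>\n",
              length(x$class_symbols), paste(x$class_symbols, collapse = ","),
              x$extractor$config$cell_type, np,
              if (isTRUE(x$shared_removed)) ", shared knowledge removed" else ""))
  invisible(x)
}

#' Ensemble scores for features
#'
#' @param ensemble a `micro_ensemble`.
#' @param F feature vector or `n x m` matrix.
#' @return `n x T` matrix of raw scores (columns in class order).
#' @export
ensemble_scores <- function(ensemble, F) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  vapply(ensemble$classifiers, function(clf) {
    fw <- clf_forward(clf, F)
    as.numeric(fw$f)
  }, numeric(nrow(F)))
}

#' Predict class symbols
#'
#' Scores the feature(s) with every mini-classifier and returns the symbol
#' of the highest raw score; ties break toward the lowest class index.
#' Accepts raw slices (vector, matrix or `beat_dataset`), which are passed
#' through the ensemble's feature extractor first, or precomputed features
#' via `features = TRUE`.
#'
#' @param object a `micro_ensemble`.
#' @param newdata slices or features.
#' @param features set `TRUE` if `newdata` already holds feature vectors.
#' @param ... unused.
#' @return Character vector of class symbols.
#' @export
predict.micro_ensemble <- function(object, newdata, features = FALSE, ...) {
  F <- if (isTRUE(features)) {
    if (!is.matrix(newdata)) matrix(newdata, nrow = 1) else newdata
  } else {
    if (inherits(newdata, "beat_dataset")) newdata <- newdata$x
    if (inherits(newdata, "beat_slice")) newdata <- newdata$values
    if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
    standardize_features(
      object,
      extract_features(newdata, object$extractor$config,
                       object$extractor$params))
  }
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  sc <- ensemble_scores(object, F)
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = 1)
  object$class_symbols[apply(sc, 1L, which.max)]
}
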