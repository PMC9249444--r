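test_that("the three-layer scorer matches a hand-rolled evaluation", {
  clf <- seeded_classifier(m = 6, h1 = 4, h2 = 3, seed = 21)
  x <- rnorm(6)
  hand <- {
    a1 <- tanh(as.vector(x %*% clf$W1) + clf$b1)
    a2 <- tanh(as.vector(a1 %*% clf$W2) + clf$b2)
    sum(a2 * clf$W3) + clf$b3
  }
  expect_equal(score(clf, x), hand, tolerance = 1e-10)

  zero <- clf
  zero$W1[] <- 0; zero$W2[] <- 0; zero$W3[] <- 0
  zero$b1[] <- 0; zero$b2[] <- 0; zero$b3 <- 0
  expect_equal(score(zero, x), 0)

  # 1-d toy: odd activation maps 0 to 0
  toy <- init_classifier(1, 1, 1)
  toy$W1[] <- 1; toy$W2[] <- 1; toy$W3[] <- 1
  toy$b1[] <- 0; toy$b2[] <- 0; toy$b3 <- 0
  expect_equal(score(toy, 0), 0)
})

test_that("the NLL term has its closed-form values and limits", {
  clf <- seeded_classifier(m = 4, h1 = 3, h2 = 2, seed = 5)
  zero <- clf
  zero$W1[] <- 0; zero$W2[] <- 0; zero$W3[] <- 0
  zero$b1[] <- 0; zero$b2[] <- 0; zero$b3 <- 0
  F1 <- matrix(rnorm(4), 1)
  expect_equal(nll_term(zero, F1), log(2), tolerance = 1e-6)   # -log 0.5
  # batch mean: two identical rows equal one
  F2 <- rbind(F1, F1)
  expect_equal(nll_term(zero, F2), nll_term(zero, F1))
  # high-score limit
  hi <- zero
  hi$b3 <- 30
  expect_lt(nll_term(hi, F1), 1e-12)
  expect_error(nll_term(clf, matrix(0, 0, 4)), "empty")
})

test_that("H-reg is exact for a linear scorer and matches finite differences", {
  lin <- init_classifier(2, 1, 1, activation = "identity")
  lin$W1[] <- c(3, 4); lin$W2[] <- 1; lin$W3[] <- 1
  lin$b1[] <- 0; lin$b2[] <- 0; lin$b3 <- 0
  # f(X) = 3x + 4y, gradient (3,4), squared norm 25, for any input
  for (x in list(c(0, 0), c(1, -2), c(5, 5))) {
    expect_equal(hreg_term(lin, matrix(x, 1), c = 2), 25)
  }
  # homogeneity: doubling W3 multiplies the c = 2 term by 4
  lin2 <- lin
  lin2$W3[] <- 2
  expect_equal(hreg_term(lin2, matrix(c(1, 1), 1), c = 2), 100)

  zero <- lin
  zero$W1[] <- 0; zero$W2[] <- 0; zero$W3[] <- 0
  expect_equal(hreg_term(zero, matrix(c(1, 2), 1), c = 2), 0)

  expect_error(hreg_term(lin, matrix(c(1, 1), 1), c = 0), "> 0")

  # finite-difference oracle on random nonlinear scorers
  set.seed(77)
  for (k in 1:5) {
    clf <- init_classifier(5, 4, 3)
    x <- rnorm(5)
    g_an <- microbeat:::clf_input_gradient(clf, microbeat:::clf_forward(clf, matrix(x, 1)))
    g_fd <- fdiff(function(v) score(clf, v), x)
    expect_lt(max(abs(as.vector(g_an) - g_fd)) / max(abs(g_fd)), 1e-4)
    expect_equal(hreg_term(clf, matrix(x, 1), c = 2), sum(g_fd^2),
                 tolerance = 1e-6)
  }
})

test_that("the anchor term is the squared distance in theta space", {
  clf <- seeded_classifier(m = 3, h1 = 2, h2 = 2, seed = 9)
  theta <- flatten_theta(clf)
  expect_equal(anchor_term(clf, theta), 0)
  mu <- theta
  mu[1:3] <- mu[1:3] - c(1, 2, 2)
  expect_equal(anchor_term(clf, mu), 9)
  set.seed(1)
  mu2 <- rnorm(length(theta))
  expect_equal(anchor_term(clf, mu2), sum((theta - mu2)^2), tolerance = 1e-12)
  expect_error(anchor_term(clf, mu2[-1]), "length")
  expect_equal(anchor_term(clf, NULL), 0)
})

test_that("the one-class loss decomposes exactly into its three terms", {
  set.seed(42)
  clf <- init_classifier(6, 4, 3)
  F <- matrix(rnorm(8 * 6), 8, 6)
  mu <- rnorm(length(flatten_theta(clf)))
  hyper <- ensemble_hyper(eta = 0.7, c = 2, pi = 0.3)
  total <- one_class_loss(clf, F, hyper, mu)
  expect_equal(total,
               nll_term(clf, F) + 0.7 * hreg_term(clf, F, 2) +
                 0.3 * anchor_term(clf, mu),
               tolerance = 1e-10)
  # eta = pi = 0 reduces to the NLL
  expect_equal(one_class_loss(clf, F, ensemble_hyper(eta = 0, pi = 0)),
               nll_term(clf, F), tolerance = 1e-12)
})

test_that("sequential initialisation centers each classifier on its predecessors", {
  set.seed(6)
  clfs <- lapply(1:4, function(i) init_classifier(4, 3, 2))
  # i = 2: centered exactly on theta_1
  ini2 <- init_from_previous(clfs, 2)
  expect_equal(ini2$mu_prev, flatten_theta(clfs[[1]]))
  # i = 3 with theta_1 = -theta_2: centered at zero
  clfs2 <- clfs
  clfs2[[2]] <- unflatten_theta(clfs2[[2]], -flatten_theta(clfs2[[1]]))
  ini3 <- init_from_previous(clfs2, 3)
  expect_equal(ini3$mu_prev, rep(0, length(ini3$mu_prev)))
  # i = 4: centered at the arithmetic mean (direct averaging oracle)
  thetas <- sapply(clfs[1:3], flatten_theta)
  ini4 <- init_from_previous(clfs, 4)
  expect_equal(ini4$mu_prev, rowMeans(thetas))
  expect_lt(max(abs(flatten_theta(ini4$clf) - rowMeans(thetas))), 0.06)
})

test_that("shared knowledge is the phi-weighted KL barycenter mean", {
  set.seed(12)
  mk_ens <- function(thetas, phi) {
    clfs <- lapply(seq_along(thetas), function(i) {
      unflatten_theta(init_classifier(3, 2, 2), thetas[[i]])
    })
    micro_ensemble(extractor = list(), classifiers = clfs,
                   hyper = ensemble_hyper(phi = phi),
                   class_symbols = paste0("C", seq_along(thetas)))
  }
  len <- length(flatten_theta(init_classifier(3, 2, 2)))

  th <- rnorm(len)
  expect_equal(shared_knowledge(mk_ens(list(th), 1)), th)
  expect_equal(shared_knowledge(mk_ens(list(th, -th), c(0.5, 0.5))),
               rep(0, len))

  # numerical-optimizer oracle for the Gaussian objective
  thetas <- lapply(1:3, function(i) rnorm(len))
  phi <- c(0.2, 0.3, 0.5)
  rho <- shared_knowledge(mk_ens(thetas, phi))
  obj <- function(mu) sum(sapply(1:3, function(i) {
    phi[i] * 0.5 * sum((thetas[[i]] - mu)^2)   # KL(N(theta_i,I) || N(mu,I))
  }))
  opt <- optim(rnorm(len), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(rho - opt$par)), 1e-4)
  expect_equal(rho, phi[1] * thetas[[1]] + phi[2] * thetas[[2]] +
                 phi[3] * thetas[[3]], tolerance = 1e-12)
})

test_that("shared-knowledge removal shifts every theta by tau * rho", {
  set.seed(13)
  clfs <- lapply(1:2, function(i) init_classifier(3, 2, 2))
  ens <- micro_ensemble(extractor = list(), classifiers = clfs,
                        hyper = ensemble_hyper(tau = 0.1, phi = c(0.5, 0.5)),
                        class_symbols = c("A", "B"))
  th1 <- flatten_theta(clfs[[1]]); th2 <- flatten_theta(clfs[[2]])

  same <- remove_shared(ens, tau = 0)
  expect_equal(flatten_theta(same$classifiers[[1]]), th1)

  upd <- remove_shared(ens, tau = 0.1)
  rho <- 0.5 * th1 + 0.5 * th2
  expect_equal(flatten_theta(upd$classifiers[[1]]), th1 - 0.1 * rho)
  expect_equal(flatten_theta(upd$classifiers[[2]]), th2 - 0.1 * rho)

  solo <- micro_ensemble(extractor = list(), classifiers = clfs[1],
                         hyper = ensemble_hyper(phi = 1), class_symbols = "A")
  gone <- remove_shared(solo, tau = 1)
  expect_equal(flatten_theta(gone$classifiers[[1]]),
               rep(0, length(th1)))
})

test_that("prediction is an argmax with lowest-index tie-breaking", {
  set.seed(14)
  clfs <- lapply(1:3, function(i) init_classifier(4, 3, 2))
  ens <- micro_ensemble(extractor = list(), classifiers = clfs,
                        hyper = ensemble_hyper(), class_symbols = c("N", "S", "V"))
  F <- matrix(rnorm(1000 * 4), 1000, 4)
  sc <- ensemble_scores(ens, F)
  pred <- predict(ens, F, features = TRUE)
  brute <- apply(sc, 1, function(row) {
    best <- 1L
    for (j in 2:3) if (row[j] > row[best]) best <- j   # strict: ties keep lowest
    c("N", "S", "V")[best]
  })
  expect_identical(pred, brute)

  # exact tie between classifiers 1 and 2 resolves to the lower index
  tie <- clfs
  tie[[2]] <- tie[[1]]
  ens_tie <- micro_ensemble(extractor = list(), classifiers = tie,
                            hyper = ensemble_hyper(),
                            class_symbols = c("N", "S", "V"))
  sc_tie <- ensemble_scores(ens_tie, F[1:20, ])
  is_tie_max <- sc_tie[, 1] >= sc_tie[, 3]
  expect_true(all(predict(ens_tie, F[1:20, ][is_tie_max, , drop = FALSE],
                          features = TRUE) == "N"))
})

test_that("loss gradients match finite differences (double backprop included)", {
  set.seed(15)
  clf <- init_classifier(5, 4, 3)
  F <- matrix(rnorm(6 * 5), 6, 5)
  mu <- rnorm(length(flatten_theta(clf)))
  hyper <- ensemble_hyper(eta = 0.5, c = 2, pi = 0.2)
  lg <- microbeat:::clf_loss_grads(clf, F, hyper, mu, train_bias = "all")
  tree <- microbeat:::clf_param_tree(clf)
  f_par <- function(v) {
    cc <- microbeat:::clf_from_tree(clf, utils::relist(v, tree))
    one_class_loss(cc, F, hyper, mu)
  }
  g_fd <- fdiff(f_par, unlist(tree))
  expect_lt(max(abs(g_fd - unlist(lg$grads))), 1e-6)
  f_in <- function(v) one_class_loss(clf, matrix(v, 6, 5), hyper, mu)
  g_fd_in <- fdiff(f_in, as.vector(F))
  expect_lt(max(abs(g_fd_in - as.vector(lg$dF))), 1e-6)
})
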