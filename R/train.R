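# Training of the per-class one-class mini-classifier bank over the
# two-level recurrent representation.
#
# The default protocol has three stages:
#   1. (optional) joint warm-up: extractor and classifiers trained together,
#      every minibatch contributing its class-i rows to classifier i's
#      one-class loss (no negative sampling). Off by default -- the
#      one-class gradients carry no class-contrastive signal, and training
#      the representation with them measurably collapses the directions
#      that separate confusable classes (see the methods vignette).
#   2. representation freeze + whitening: the training set is pushed through
#      the extractor once and a pooled within-class whitening map is fitted;
#      it becomes the model's feature-standardisation layer. Whitening is
#      what makes the raw-score argmax comparison across one-class scorers
#      behave like a proper discriminant.
#   3. classifier-bank training on the frozen whitened features: the scorers
#      start from a common parameter point (the sequential rule -- each
#      classifier is initialised from its predecessors' mean), so every
#      pairwise score difference equals the difference of the accumulated
#      own-class updates. Per-epoch class losses and validation accuracy of
#      the deployed model (with shared-knowledge removal applied) are
#      logged and the best-validation parameters are retained.
#
# The H-reg contribution needs the derivative of an input-gradient norm
# with respect to the parameters, which is written out analytically below
# (double backprop through the three-layer scorer).

# ---- gradients of the one-class loss for one classifier -----------------

zero_clf_grads <- function(clf) {
  list(W1 = clf$W1 * 0, b1 = clf$b1 * 0, W2 = clf$W2 * 0, b2 = clf$b2 * 0,
       W3 = clf$W3 * 0, b3 = 0)
}

# value + parameter gradients + feature gradients of
# nll + eta * hreg + pi * ||theta - mu||^2 on a class batch.
# train_bias: "all" trains every bias, "hidden" freezes the output bias b3
# (the scorer W3.s(W2.s(W1.X)) is bias-free at the output; a free output
# offset lets the one-class NLL inflate scores without learning any input
# dependence), "none" freezes all biases.
clf_loss_grads <- function(clf, Fm, hyper, mu_prev = NULL,
                           train_bias = "hidden") {
  n <- nrow(Fm)
  act <- clf$activation
  fw <- clf_forward(clf, Fm)
  d1 <- clf_act_d(fw$a1, act); d2 <- clf_act_d(fw$a2, act)
  dd1 <- clf_act_dd(fw$a1, act); dd2 <- clf_act_dd(fw$a2, act)
  W3row <- matrix(clf$W3, n, length(clf$W3), byrow = TRUE)
  g <- zero_clf_grads(clf)

  # --- NLL: mean(-log sigmoid(f)) ---
  nll <- mean(.nll_of_score(fw$f))
  df <- -(1 - sigm(fw$f)) / n
  da2 <- outer(df, as.vector(clf$W3))
  g$W3 <- g$W3 + crossprod(fw$a2, matrix(df))
  g$b3 <- g$b3 + sum(df)
  dz2 <- da2 * d2
  g$W2 <- g$W2 + crossprod(fw$a1, dz2)
  g$b2 <- g$b2 + colSums(dz2)
  dz1 <- (dz2 %*% t(clf$W2)) * d1
  g$W1 <- g$W1 + crossprod(fw$Fm, dz1)
  g$b1 <- g$b1 + colSums(dz1)
  dF <- dz1 %*% t(clf$W1)

  # --- H-reg: mean(||df/dF||^c), double backprop ---
  hreg <- 0
  if (hyper$eta > 0) {
    u2 <- d2 * W3row
    v1 <- u2 %*% t(clf$W2)
    u1 <- d1 * v1
    gin <- u1 %*% t(clf$W1)          # rows: d f / d F
    s2 <- rowSums(gin^2)
    cc <- hyper$c
    hreg <- mean(s2^(cc / 2))
    coef <- (cc / n) * s2^((cc - 2) / 2)
    coef[s2 == 0] <- 0               # subgradient 0 at the origin
    D <- gin * coef                  # dh/dgin, averaged
    e <- hyper$eta
    # gin = u1 W1'
    g$W1 <- g$W1 + e * crossprod(D, u1)
    du1 <- D %*% clf$W1
    # u1 = d1 * v1
    dz1h <- du1 * v1 * dd1
    dv1 <- du1 * d1
    # v1 = u2 W2'
    g$W2 <- g$W2 + e * crossprod(dv1, u2)
    du2 <- dv1 %*% clf$W2
    # u2 = d2 * W3
    dz2h <- du2 * W3row * dd2
    g$W3 <- g$W3 + e * matrix(colSums(du2 * d2))
    # primal chain: z2 = a1 W2 + b2, a1 = act(z1), z1 = F W1 + b1
    g$W2 <- g$W2 + e * crossprod(fw$a1, dz2h)
    g$b2 <- g$b2 + e * colSums(dz2h)
    dz1h <- dz1h + (dz2h %*% t(clf$W2)) * d1
    g$W1 <- g$W1 + e * crossprod(fw$Fm, dz1h)
    g$b1 <- g$b1 + e * colSums(dz1h)
    dF <- dF + e * (dz1h %*% t(clf$W1))
  }

  # --- anchor: pi * ||theta - mu||^2 ---
  anchor <- 0
  if (!is.null(mu_prev) && hyper$pi > 0) {
    theta <- flatten_theta(clf)
    diff <- theta - mu_prev
    anchor <- sum(diff^2)
    ga <- unflatten_theta(clf, 2 * hyper$pi * diff)
    for (nm in names(g)) g[[nm]] <- g[[nm]] + ga[[nm]]
  }

  if (train_bias != "all") g$b3 <- 0
  if (train_bias == "none") {
    g$b1 <- g$b1 * 0
    g$b2 <- g$b2 * 0
  }

  list(loss = nll + hyper$eta * hreg + hyper$pi * anchor,
       nll = nll, hreg = hreg, anchor = anchor, grads = g, dF = dF)
}

# ---- optimisers on a flattened parameter vector -------------------------

adam_init <- function(vec) list(m = vec * 0, v = vec * 0, t = 0L)

adam_step <- function(vec, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(vec = vec - lr * mhat / (sqrt(vhat) + eps), st = st)
}

sgd_step <- function(vec, grad, st, lr = 1e-3, momentum = 0.9) {
  st$m <- momentum * st$m + grad
  list(vec = vec - lr * st$m, st = st)
}

opt_step <- function(optimizer, vec, grad, st, lr) {
  if (optimizer == "adam") adam_step(vec, grad, st, lr = lr)
  else sgd_step(vec, grad, st, lr = lr)
}

clf_param_tree <- function(clf) {
  list(W1 = clf$W1, b1 = clf$b1, W2 = clf$W2, b2 = clf$b2,
       W3 = clf$W3, b3 = clf$b3)
}

clf_from_tree <- function(clf, tree) {
  clf[names(tree)] <- tree
  clf
}

# symmetric anchor target: mean of the other classifiers' current thetas
anchor_target <- function(thetas, i) {
  Tn <- length(thetas)
  if (Tn == 1L) return(NULL)
  (Reduce(`+`, thetas) - thetas[[i]]) / (Tn - 1L)
}

# ---- the training driver ------------------------------------------------

#' Train a micro ensemble
#'
#' Fits one one-class mini-classifier per class over the windowed two-level
#' recurrent representation. By default the representation is the seeded
#' recurrent projection left untrained, a pooled within-class whitening map
#' fitted on the training features becomes the model's standardisation
#' layer, and only the classifier bank is optimised (see the methods
#' vignette for why one-class gradients must not shape the shared
#' representation). `joint_epochs > 0` additionally runs a joint warm-up of
#' extractor and classifiers beforehand.
#'
#' Classifiers start from a common point per the sequential initialisation
#' rule; per-epoch class losses and deployed-model validation accuracy are
#' logged; the best-validation parameters are retained; the
#' shared-knowledge removal step ([remove_shared()]) is applied exactly
#' once at the end. Fully deterministic for a fixed seed.
#'
#' @param train a `beat_dataset` with at least one example per class.
#' @param val optional validation `beat_dataset` for model selection.
#' @param config an [extractor_config()].
#' @param hyper hyperparameters from [ensemble_hyper()].
#' @param class_symbols ordered class labels; defaults to the sorted unique
#'   training labels. Training errors if a requested class is absent.
#' @param clf_h1,clf_h2 mini-classifier hidden sizes.
#' @param epochs classifier-bank training epochs.
#' @param joint_epochs joint extractor+classifier warm-up epochs (0 = off).
#' @param batch_size,lr optimisation settings.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param train_bias which scorer biases are trained (`"hidden"` freezes
#'   the output bias; a free output offset lets the one-class objective
#'   inflate scores without learning input dependence).
#' @param seed integer seed covering initialisation and shuffling.
#' @param normalize L2-normalise slices first (skipped if already done).
#' @param verbose print one line per epoch.
#' @return A trained `micro_ensemble`; the training log is in `$log`
#'   (`class_loss` matrix, `val_acc`, `best_epoch`, settings).
#' @export
train_ensemble <- function(train, val = NULL, config = extractor_config(),
                           hyper = ensemble_hyper(), class_symbols = NULL,
                           clf_h1 = 32L, clf_h2 = 16L, epochs = 60L,
                           joint_epochs = 0L, batch_size = 32L, lr = 1e-3,
                           optimizer = c("sgd", "adam"),
                           train_bias = c("hidden", "all", "none"),
                           seed = 0L, normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(train, "beat_dataset"))
  optimizer <- match.arg(optimizer)
  train_bias <- match.arg(train_bias)
  epochs <- check_count(epochs, "epochs", lower = 1L)
  joint_epochs <- check_count(joint_epochs, "joint_epochs", lower = 0L)
  batch_size <- check_count(batch_size, "batch_size", lower = 1L)
  if (normalize && !train$normalized) train <- normalize_dataset(train)
  if (!is.null(val) && normalize && !val$normalized) val <- normalize_dataset(val)

  symbols <- class_symbols %||% sort(unique(train$label))
  missing <- setdiff(symbols, unique(train$label))
  if (length(missing) > 0) {
    stop_mb(sprintf("training set is missing class(es): %s",
                    paste(missing, collapse = ", ")))
  }
  Tn <- length(symbols)
  if (is.null(hyper$phi)) hyper$phi <- rep(1 / Tn, Tn)
  n <- nrow(train$x)

  with_seed(seed, {
    ext_params <- init_extractor(config)
    clfs <- lapply(symbols, function(sym) {
      init_classifier(config$m, clf_h1, clf_h2, class_symbol = sym)
    })
    for (i in seq_len(Tn)) {
      clfs[[i]] <- init_from_previous(clfs, i)$clf
    }

    joint_loss <- NULL
    if (joint_epochs > 0L) {
      warm <- .joint_warmup(train, symbols, config, ext_params, clfs, hyper,
                            joint_epochs, batch_size, lr, optimizer,
                            train_bias, verbose)
      ext_params <- warm$ext_params
      clfs <- warm$clfs
      joint_loss <- warm$class_loss
      # restart the bank from the classifiers' common mean (sequential rule)
      theta_bar <- Reduce(`+`, lapply(clfs, flatten_theta)) / Tn
      for (i in seq_len(Tn)) {
        clfs[[i]] <- unflatten_theta(
          clfs[[i]], theta_bar + stats::rnorm(length(theta_bar), 0, 0.01))
      }
    }

    # representation freeze + whitening layer
    Fraw <- extractor_forward(train$x, config, ext_params)$F
    fn <- whitening_map(Fraw, labels = train$label)
    Ftr <- sweep(Fraw, 2L, fn$center) %*% fn$transform
    Fva <- if (!is.null(val)) {
      Fv <- extractor_forward(val$x, config, ext_params)$F
      sweep(Fv, 2L, fn$center) %*% fn$transform
    }

    # classifier-bank training on the frozen whitened features
    clf_tree <- lapply(clfs, clf_param_tree)
    cvec <- unlist(clf_tree, use.names = FALSE)
    st <- adam_init(cvec)
    log_loss <- matrix(NA_real_, epochs, Tn, dimnames = list(NULL, symbols))
    val_acc <- rep(NA_real_, epochs)
    best <- list(acc = -Inf, tree = NULL, epoch = 0L)
    ctree <- utils::relist(cvec, clf_tree)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / batch_size)
      ep_loss <- numeric(Tn)
      ep_cnt <- numeric(Tn)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        lb <- train$label[rows]
        thetas_now <- lapply(seq_len(Tn), function(i) {
          flatten_theta(clf_from_tree(clfs[[i]], ctree[[i]]))
        })
        gtree <- vector("list", Tn)
        for (i in seq_len(Tn)) {
          clf_i <- clf_from_tree(clfs[[i]], ctree[[i]])
          members <- which(lb == symbols[i])
          if (length(members) == 0L) {
            gtree[[i]] <- zero_clf_grads(clf_i)
            next
          }
          lg <- clf_loss_grads(clf_i, Ftr[rows[members], , drop = FALSE],
                               hyper, anchor_target(thetas_now, i),
                               train_bias = train_bias)
          gtree[[i]] <- lg$grads
          ep_loss[i] <- ep_loss[i] + lg$loss * length(members)
          ep_cnt[i] <- ep_cnt[i] + length(members)
        }
        upd <- opt_step(optimizer, cvec, unlist(gtree, use.names = FALSE),
                        st, lr)
        cvec <- upd$vec
        st <- upd$st
        ctree <- utils::relist(cvec, clf_tree)
      }
      log_loss[ep, ] <- ifelse(ep_cnt > 0, ep_loss / ep_cnt, NA_real_)
      if (!is.null(val)) {
        # validate the deployed model: shared-knowledge removal applied to
        # a copy of the current parameters
        ens_ep <- remove_shared(
          .assemble_ensemble(ext_params, ctree, clfs, config, hyper,
                             symbols, fn))
        pred <- ens_ep$class_symbols[
          apply(ensemble_scores(ens_ep, Fva), 1L, which.max)]
        val_acc[ep] <- mean(pred == val$label)
        if (val_acc[ep] > best$acc) {
          best <- list(acc = val_acc[ep], tree = ctree, epoch = ep)
        }
      }
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f%s\n", ep, sum(log_loss[ep, ]),
                    if (!is.null(val)) sprintf("  val acc %.3f", val_acc[ep])
                    else ""))
      }
    }

    final_tree <- if (!is.null(val) && best$epoch > 0L) best$tree else ctree
    ens <- .assemble_ensemble(ext_params, final_tree, clfs, config, hyper,
                              symbols, fn)
    ens <- remove_shared(ens)
    ens$log <- list(class_loss = log_loss, val_acc = val_acc,
                    joint_class_loss = joint_loss,
                    best_epoch = if (!is.null(val)) best$epoch else epochs,
                    epochs = epochs, joint_epochs = joint_epochs,
                    batch_size = batch_size, lr = lr, optimizer = optimizer,
                    seed = seed)
    ens
  })
}

# joint warm-up of extractor + classifier bank (one-class losses summed);
# feature standardisation during the warm-up uses detached batch statistics
.joint_warmup <- function(train, symbols, config, ext_params, clfs, hyper,
                          joint_epochs, batch_size, lr, optimizer,
                          train_bias, verbose) {
  Tn <- length(symbols)
  n <- nrow(train$x)
  par_tree <- list(ext = ext_params, clfs = lapply(clfs, clf_param_tree))
  vec <- unlist(par_tree, use.names = FALSE)
  st <- adam_init(vec)
  cur <- utils::relist(vec, par_tree)
  class_loss <- matrix(NA_real_, joint_epochs, Tn,
                       dimnames = list(NULL, symbols))
  for (ep in seq_len(joint_epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / batch_size)
    ep_loss <- numeric(Tn); ep_cnt <- numeric(Tn)
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      xb <- train$x[rows, , drop = FALSE]
      lb <- train$label[rows]
      fw <- extractor_forward(xb, config, cur$ext, want_cache = TRUE)
      bmu <- colMeans(fw$F)
      bsd <- apply(fw$F, 2L, stats::sd) + 1e-4
      Fs <- sweep(sweep(fw$F, 2L, bmu), 2L, bsd, "/")
      dF <- Fs * 0
      grad_tree <- list(ext = NULL, clfs = vector("list", Tn))
      thetas_now <- lapply(seq_len(Tn), function(i) {
        flatten_theta(clf_from_tree(clfs[[i]], cur$clfs[[i]]))
      })
      for (i in seq_len(Tn)) {
        clf_i <- clf_from_tree(clfs[[i]], cur$clfs[[i]])
        members <- which(lb == symbols[i])
        if (length(members) == 0L) {
          grad_tree$clfs[[i]] <- zero_clf_grads(clf_i)
          next
        }
        lg <- clf_loss_grads(clf_i, Fs[members, , drop = FALSE], hyper,
                             anchor_target(thetas_now, i),
                             train_bias = train_bias)
        dF[members, ] <- dF[members, ] + lg$dF
        grad_tree$clfs[[i]] <- lg$grads
        ep_loss[i] <- ep_loss[i] + lg$loss * length(members)
        ep_cnt[i] <- ep_cnt[i] + length(members)
      }
      bw <- extractor_backward(config, cur$ext, fw$cache,
                               sweep(dF, 2L, bsd, "/"))
      grad_tree$ext <- bw$grads
      upd <- opt_step(optimizer, vec, unlist(grad_tree, use.names = FALSE),
                      st, lr)
      vec <- upd$vec
      st <- upd$st
      cur <- utils::relist(vec, par_tree)
    }
    class_loss[ep, ] <- ifelse(ep_cnt > 0, ep_loss / ep_cnt, NA_real_)
    if (verbose) {
      cat(sprintf("warm-up %3d  loss %.4f\n", ep, sum(class_loss[ep, ])))
    }
  }
  list(ext_params = cur$ext,
       clfs = lapply(seq_len(Tn), function(i) {
         clf_from_tree(clfs[[i]], cur$clfs[[i]])
       }),
       class_loss = class_loss)
}

.assemble_ensemble <- function(ext_params, ctree, clfs, config, hyper,
                               symbols, feature_norm) {
  clf_objs <- lapply(seq_along(clfs), function(i) {
    clf_from_tree(clfs[[i]], ctree[[i]])
  })
  micro_ensemble(extractor = list(config = config, params = ext_params),
                 classifiers = clf_objs, hyper = hyper,
                 class_symbols = symbols, feature_norm = feature_norm)
}
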