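# Full network assembly and training. Pipeline per window (T x N x F_de):
# temporal attention -> re-weighting -> spatial attention -> adaptive (or
# KNN) adjacency -> scaled Laplacian -> attention-masked Chebyshev spatial
# convolution -> temporal convolution -> time collapse -> extractor f(.) ->
# {classifier head; gradient reversal -> domain discriminator}.
#
# Gradients are computed by explicit reverse-mode passes per stage. The
# adjacency weight vector w is updated from the gradient of the graph loss
# L_gcn alone (the adjacency/Chebyshev basis is stop-gradient in the
# classification path), matching the definition of the adaptive graph
# update; everything else receives classification and (reversed)
# discriminator gradients.

#' Model configuration
#'
#' Defaults follow the reference operating point: context coefficient
#' `d = 3` (window length `T = 7`), Chebyshev order bound `K = 2`, spatial
#' convolution output width `F_out = 5`, graph regularization weight
#' `tau = 1e-2`, RMSprop with learning rate `1e-3`, batch size 96,
#' extractor widths `in -> 64 -> 64 -> 64` and discriminator
#' `64 -> 64 -> 64 -> 2`.
#'
#' @param d temporal context coefficient (window has `T = 2d + 1` samples).
#' @param K Chebyshev polynomial order bound (`>= 1`).
#' @param F_out spatial convolution output width per node.
#' @param tau graph-smoothness regularization weight.
#' @param lr RMSprop learning rate.
#' @param batch_size source windows per training batch.
#' @param max_epochs training epochs.
#' @param seed RNG seed controlling init, shuffling and batching.
#' @param lambda_variant adversarial weight schedule, see [lambda_schedule()].
#' @param lambda_gamma growth rate for the `dann_increasing` variant.
#' @param ablation character subset of `no_discriminator`, `knn_graph`,
#'   `no_temporal_attention`, `no_spatial_attention`.
#' @param knn_k neighbour count for the fixed-KNN ablation graph.
#' @param kernel_len temporal convolution kernel length (odd).
#' @param hidden extractor hidden widths.
#' @param disc_hidden discriminator hidden widths.
#' @param early_stop_train_acc optional source-accuracy threshold at which
#'   training stops early (e.g. 0.99); `NULL` disables.
#' @param verbose print per-epoch progress.
#' @return List of class `model_config`.
#' @export
model_config <- function(d = 3, K = 2, F_out = 5, tau = 1e-2, lr = 1e-3,
                         batch_size = 96, max_epochs = 200, seed = 1,
                         lambda_variant = "decreasing",
                         lambda_gamma = 10,
                         ablation = character(0), knn_k = 3,
                         kernel_len = 3, hidden = c(64, 64, 64),
                         disc_hidden = c(64, 64),
                         early_stop_train_acc = NULL, verbose = FALSE) {
  stopifnot(d >= 0, K >= 1, F_out >= 1, tau >= 0, kernel_len %% 2 == 1)
  bad <- setdiff(ablation, c("no_discriminator", "knn_graph",
                             "no_temporal_attention", "no_spatial_attention"))
  if (length(bad)) {
    stop(sprintf("unknown ablation flag(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(d = as.integer(d), K = as.integer(K),
                 F_out = as.integer(F_out), tau = tau, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 lambda_variant = lambda_variant, lambda_gamma = lambda_gamma,
                 ablation = unique(ablation), knn_k = as.integer(knn_k),
                 kernel_len = as.integer(kernel_len), hidden = hidden,
                 disc_hidden = disc_hidden,
                 early_stop_train_acc = early_stop_train_acc,
                 verbose = isTRUE(verbose)),
            class = "model_config")
}

has_ablation <- function(config, flag) flag %in% config$ablation

#' Initialize model parameters
#'
#' @param config a [model_config()].
#' @param n_channels,n_bands,n_classes data dimensions.
#' @return List of class `stgnn_model` holding all parameter groups.
#' @export
init_model <- function(config, n_channels, n_bands, n_classes) {
  T_len <- 2L * config$d + 1L
  set.seed(config$seed)
  in_width <- n_channels * config$F_out
  params <- list(
    att_t = init_temporal_attention_params(T_len, n_channels, n_bands),
    att_s = init_spatial_attention_params(T_len, n_channels, n_bands),
    w_adj = abs(stats::rnorm(n_bands, 0, 0.1)),
    theta = lapply(seq_len(config$K), function(k) {
      matrix((stats::runif(n_bands * config$F_out) - 0.5) * 2 / sqrt(n_bands),
             n_bands, config$F_out)
    }),
    tconv = init_temporal_conv_params(config$F_out, config$kernel_len),
    extractor = init_mlp(c(in_width, config$hidden)),
    clf = init_mlp(c(config$hidden[length(config$hidden)], n_classes)),
    disc = init_mlp(c(config$hidden[length(config$hidden)],
                      config$disc_hidden, 2L)))
  structure(list(params = params, config = config,
                 n_channels = as.integer(n_channels),
                 n_bands = as.integer(n_bands),
                 n_classes = as.integer(n_classes), T_len = T_len),
            class = "stgnn_model")
}

# ---- front end (per window) -------------------------------------------------

frontend_forward <- function(model, X, mode = "eval") {
  cfg <- model$config
  d <- dim(X)
  if (d[1] != model$T_len || d[2] != model$n_channels ||
      d[3] != model$n_bands) {
    stop(sprintf(
      "front end: window shape %dx%dx%d does not match model (T=%d, N=%d, F_de=%d)",
      d[1], d[2], d[3], model$T_len, model$n_channels, model$n_bands),
      call. = FALSE)
  }
  p <- model$params
  train <- identical(mode, "train")

  if (has_ablation(cfg, "no_temporal_attention")) {
    ta <- NULL
    Q_norm <- diag(d[1])
    X_hat <- X
  } else {
    ta <- temporal_attention_fwd(X, p$att_t)
    Q_norm <- ta$Q_norm
    X_hat <- apply_temporal_attention(X, Q_norm)
  }

  if (has_ablation(cfg, "no_spatial_attention")) {
    sa <- NULL
    P_mask <- matrix(1, d[2], d[2])
  } else {
    sa <- spatial_attention_fwd(X_hat, p$att_s)
    P_mask <- sa$P_norm
  }

  xbar <- t(colMeans(matrix(X_hat, d[1], d[2] * d[3]))) # 1 x (N*F) row
  xbar <- matrix(xbar, d[2], d[3])
  if (has_ablation(cfg, "knn_graph")) {
    A <- knn_adjacency(xbar, cfg$knn_k)
    L_gcn <- 0
    gw <- NULL
  } else if (train) {
    gl <- graph_loss_grad_w(xbar, p$w_adj, cfg$tau)
    A <- gl$A
    L_gcn <- gl$loss
    gw <- gl$grad
  } else {
    A <- compute_adjacency(xbar, p$w_adj)
    L_gcn <- graph_regularization_loss(xbar, A, cfg$tau)
    gw <- NULL
  }
  lap <- scaled_laplacian(symmetrize_adjacency(A))
  basis <- cheb_basis(lap$L_tilde, cfg$K)

  sc <- spatial_graph_conv_fwd(X_hat, P_mask, basis, p$theta)
  tc <- temporal_conv_fwd(sc$out, p$tconv)
  feat <- collapse_time(tc$out)

  cache <- if (train) list(X = X, ta = ta, sa = sa, Q_norm = Q_norm,
                           X_hat = X_hat, sc = sc$cache, tc = tc$cache,
                           dims = dim(tc$out)) else NULL
  list(feat = feat, A = A, L_gcn = L_gcn, gw = gw, cache = cache,
       Q_norm = Q_norm, P_norm = if (is.null(sa)) P_mask else sa$P_norm)
}

# dfeat: gradient at the collapsed feature vector. Accumulates front-end
# parameter gradients into `acc` (a mutable environment).
frontend_backward <- function(model, cache, dfeat, acc) {
  p <- model$params
  cfg <- model$config
  dtgc <- collapse_time_bwd(dfeat, cache$dims)
  tb <- temporal_conv_bwd(dtgc, cache$tc)
  acc$tconv$phi <- acc$tconv$phi + tb$dphi
  sb <- spatial_graph_conv_bwd(tb$dX_sgc, cache$sc)
  for (k in seq_along(sb$dtheta)) {
    acc$theta[[k]] <- acc$theta[[k]] + sb$dtheta[[k]]
  }
  dX_hat <- sb$dX_hat
  if (!is.null(cache$sa)) {
    ab <- spatial_attention_bwd(sb$dP_norm, p$att_s, cache$sa$cache)
    for (nm in names(ab$grads)) {
      acc$att_s[[nm]] <- acc$att_s[[nm]] + ab$grads[[nm]]
    }
    dX_hat <- dX_hat + ab$dX_hat
  }
  if (!is.null(cache$ta)) {
    apb <- apply_temporal_attention_bwd(dX_hat, cache$X, cache$Q_norm)
    tb2 <- temporal_attention_bwd(apb$dQ_norm, p$att_t, cache$ta$cache)
    for (nm in names(tb2$grads)) {
      acc$att_t[[nm]] <- acc$att_t[[nm]] + tb2$grads[[nm]]
    }
  }
  invisible(NULL)
}

# ---- batch forward ----------------------------------------------------------

#' Forward pass over a batch of windows
#'
#' @param model an `stgnn_model`.
#' @param windows list of `window_sample` objects (or bare `T x N x F_de`
#'   arrays).
#' @param mode `"eval"` (no caches) or `"train"`.
#' @return List with `class_logits` (`B x C`), `domain_probs` (`B x 2`,
#'   column 1 = source probability), `features` (`B x 64`), `A_mean`
#'   (batch-mean adjacency), `L_gcn` (batch mean), and internal caches in
#'   train mode.
#' @export
model_forward <- function(model, windows, mode = "eval") {
  B <- length(windows)
  stopifnot(B >= 1)
  tensors <- lapply(windows, function(wd) if (is.list(wd)) wd$tensor else wd)
  fronts <- lapply(tensors, function(X) frontend_forward(model, X, mode))
  feats <- do.call(rbind, lapply(fronts, `[[`, "feat"))
  a_ext <- mlp_forward(model$params$extractor, feats, final_relu = TRUE)
  h <- a_ext[[length(a_ext)]]
  a_clf <- mlp_forward(model$params$clf, h)
  logits <- a_clf[[length(a_clf)]]
  h_rev <- gradient_reversal(h)
  a_disc <- mlp_forward(model$params$disc, h_rev)
  domain_probs <- softmax_rows(a_disc[[length(a_disc)]])
  A_mean <- Reduce(`+`, lapply(fronts, `[[`, "A")) / B
  L_gcn <- mean(vapply(fronts, `[[`, 0, "L_gcn"))
  list(class_logits = logits, domain_probs = domain_probs, features = h,
       A_mean = A_mean, L_gcn = L_gcn,
       fronts = if (identical(mode, "train")) fronts else NULL,
       a_ext = a_ext, a_clf = a_clf, a_disc = a_disc, feats = feats)
}

# ---- optimizer --------------------------------------------------------------

params_zero <- function(p) {
  if (is.list(p)) lapply(p, params_zero) else if (is.null(p)) NULL else p * 0
}

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- r$p
        v[[nm]] <- r$v
      }
      list(p = p, v = v)
    } else if (is.null(p)) {
      list(p = NULL, v = NULL)
    } else {
      v <- rho * v + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(v) + eps), v = v)
    }
  }
  walk(params, grads, state)
}

# ---- training ---------------------------------------------------------------

window_labels <- function(windows) vapply(windows, `[[`, 0L, "label")

#' Train the network with the joint adversarial objective
#'
#' Per epoch: shuffle, pair source batches with (recycled) target batches,
#' update the discriminator on `L_disc` and the extractor/classifier side on
#' `L_classifier + L_gcn - lambda * L_disc` (gradient reversal). Target
#' windows contribute only to the discriminator loss; their labels are
#' never used. Deterministic given `config$seed`.
#'
#' @param source list of labeled source-domain windows.
#' @param target list of unlabeled target-domain windows (may be empty when
#'   the `no_discriminator` ablation is set).
#' @param config a [model_config()].
#' @param n_classes number of emotion classes; inferred from source labels
#'   when `NULL`.
#' @return List of class `stgnn_fit`: `model`, `log` (per-epoch data frame),
#'   `final_train_accuracy`.
#' @export
train_model <- function(source, target = list(), config = model_config(),
                        n_classes = NULL) {
  stopifnot(length(source) >= 1)
  use_disc <- !has_ablation(config, "no_discriminator")
  if (use_disc && length(target) == 0L) {
    stop("target windows required unless the no_discriminator ablation is set",
         call. = FALSE)
  }
  dims <- dim(source[[1]]$tensor)
  if (is.null(n_classes)) n_classes <- max(window_labels(source)) + 1L
  model <- init_model(config, dims[2], dims[3], n_classes)
  state <- params_zero(model$params)
  labels <- window_labels(source)
  n_src <- length(source)
  n_tgt <- length(target)
  bs <- min(config$batch_size, n_src)
  log_rows <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    p_frac <- epoch / config$max_epochs
    lambda <- if (use_disc) {
      lambda_schedule(p_frac, config$lambda_variant, config$lambda_gamma)
    } else 0
    ord <- sample.int(n_src)
    tgt_ord <- if (use_disc) {
      sample(rep_len(sample.int(n_tgt), max(n_src, n_tgt)))
    } else integer(0)
    n_batches <- ceiling(n_src / bs)
    ep <- c(cls = 0, gcn = 0, disc = 0, correct = 0)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n_src)]
      src_batch <- source[idx]
      tgt_batch <- if (use_disc) {
        target[tgt_ord[((b - 1L) * bs + 1L):min(b * bs, length(tgt_ord))]]
      } else list()
      res <- train_step(model, state, src_batch, labels[idx], tgt_batch,
                        lambda, config)
      model <- res$model
      state <- res$state
      if (!all(is.finite(c(res$loss_cls, res$loss_gcn, res$loss_disc)))) {
        stop(sprintf(
          "training diverged at epoch %d batch %d (non-finite loss: cls=%g gcn=%g disc=%g)",
          epoch, b, res$loss_cls, res$loss_gcn, res$loss_disc), call. = FALSE)
      }
      w <- length(src_batch) / n_src
      ep["cls"] <- ep["cls"] + w * res$loss_cls
      ep["gcn"] <- ep["gcn"] + w * res$loss_gcn
      ep["disc"] <- ep["disc"] + w * res$loss_disc
      ep["correct"] <- ep["correct"] + res$n_correct
    }
    acc <- ep[["correct"]] / n_src
    row <- data.frame(epoch = epoch, loss_classifier = ep[["cls"]],
                      loss_gcn = ep[["gcn"]], train_accuracy = acc)
    if (use_disc) {
      row$loss_disc <- ep[["disc"]]
      row$lambda <- lambda
      row$loss_total <- ep[["cls"]] + ep[["gcn"]] - lambda * ep[["disc"]]
    } else {
      row$loss_total <- ep[["cls"]] + ep[["gcn"]]
    }
    log_rows[[epoch]] <- row
    if (config$verbose) {
      message(sprintf("epoch %3d  cls %.4f  gcn %.4f  disc %s  acc %.3f",
                      epoch, ep[["cls"]], ep[["gcn"]],
                      if (use_disc) sprintf("%.4f", ep[["disc"]]) else "-",
                      acc))
    }
    if (!is.null(config$early_stop_train_acc) &&
        acc >= config$early_stop_train_acc) break
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  structure(list(model = model, log = log,
                 final_train_accuracy = log$train_accuracy[nrow(log)]),
            class = "stgnn_fit")
}

train_step <- function(model, state, src_batch, src_labels, tgt_batch,
                       lambda, config) {
  n_s <- length(src_batch)
  n_t <- length(tgt_batch)
  all_windows <- c(src_batch, tgt_batch)
  fwd <- model_forward(model, all_windows, mode = "train")
  B <- n_s + n_t

  # classifier loss on source rows
  ce <- softmax_xent(fwd$class_logits[seq_len(n_s), , drop = FALSE], src_labels)
  preds <- max.col(fwd$class_logits[seq_len(n_s), , drop = FALSE],
                   ties.method = "first") - 1L
  n_correct <- sum(preds == src_labels)

  grads <- params_zero(model$params)
  acc <- as.environment(grads)

  # classifier head backward
  dlog_full <- matrix(0, B, model$n_classes)
  dlog_full[seq_len(n_s), ] <- ce$dlogits
  cb <- mlp_backward(model$params$clf, fwd$a_clf, dlog_full)
  acc$clf <- cb$grads
  dh <- cb$dX

  loss_disc <- 0
  if (n_t > 0L) {
    # discriminator: class 0 = source. mean-reduced BCE over the batch.
    dom_labels <- c(rep(0L, n_s), rep(1L, n_t))
    P <- fwd$domain_probs
    loss_disc <- discriminator_loss(P[seq_len(n_s), 1], P[n_s + seq_len(n_t), 1],
                                    reduce = "mean")
    Y <- cbind(1 - dom_labels, dom_labels)
    ddisc_logits <- (P - Y) / B
    db <- mlp_backward(model$params$disc, fwd$a_disc, ddisc_logits)
    acc$disc <- db$grads                    # discriminator minimizes L_disc
    dh <- dh + grl_backward(db$dX, lambda)  # extractor side: -lambda * grad
  }

  eb <- mlp_backward(model$params$extractor, fwd$a_ext, dh, final_relu = TRUE)
  acc$extractor <- eb$grads
  dfeats <- eb$dX

  use_adaptive <- !has_ablation(config, "knn_graph")
  for (i in seq_len(B)) {
    frontend_backward(model, fwd$fronts[[i]]$cache, dfeats[i, ], acc)
    if (use_adaptive) acc$w_adj <- acc$w_adj + fwd$fronts[[i]]$gw / B
  }
  grads <- as.list(acc)[names(model$params)]

  st <- rmsprop_step(model$params, grads, state, config$lr)
  model$params <- st$p
  list(model = model, state = st$v, loss_cls = ce$loss, loss_gcn = fwd$L_gcn,
       loss_disc = loss_disc, n_correct = n_correct)
}

#' @export
print.stgnn_fit <- function(x, ...) {
  cat(sprintf("<stgnn_fit> %d epochs, final train accuracy %.3f\n",
              nrow(x$log), x$final_train_accuracy))
  invisible(x)
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a fitted model on labeled windows
#'
#' Window-level accuracy is the fraction of windows whose argmax logit
#' matches the label (ties broken by lowest class index). When windows
#' carry a `trial_uid`, trial-level majority-vote accuracy is also
#' reported.
#'
#' @param fit an `stgnn_fit` (or bare `stgnn_model`).
#' @param windows non-empty list of labeled windows.
#' @return List: `accuracy` (window-level, in percent), `trial_accuracy`
#'   (majority vote, percent, or `NA`), `confusion` (`C x C` counts,
#'   rows = truth), `n_windows`.
#' @export
evaluate_model <- function(fit, windows) {
  model <- if (inherits(fit, "stgnn_fit")) fit$model else fit
  if (length(windows) == 0L) stop("no windows to evaluate", call. = FALSE)
  fwd <- model_forward(model, windows, mode = "eval")
  preds <- max.col(fwd$class_logits, ties.method = "first") - 1L
  labels <- window_labels(windows)
  C <- model$n_classes
  confusion <- table(factor(labels, levels = 0:(C - 1)),
                     factor(preds, levels = 0:(C - 1)))
  uids <- vapply(windows, function(w) w$trial_uid %||% NA_character_, "")
  trial_acc <- NA_real_
  if (!anyNA(uids)) {
    per_trial <- tapply(seq_along(windows), uids, function(ii) {
      votes <- tabulate(preds[ii] + 1L, nbins = C)
      maj <- which.max(votes) - 1L
      c(maj = maj, truth = labels[ii[1]])
    })
    per_trial <- do.call(rbind, per_trial)
    trial_acc <- 100 * mean(per_trial[, "maj"] == per_trial[, "truth"])
  }
  list(accuracy = 100 * mean(preds == labels), trial_accuracy = trial_acc,
       confusion = unclass(confusion), n_windows = length(windows))
}
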