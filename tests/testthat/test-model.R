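test_that("forward pass produces the stated shapes at the 62-channel defaults", {
  cfg <- model_config(d = 3, seed = 1)
  m <- init_model(cfg, n_channels = 62, n_bands = 5, n_classes = 3)
  expect_equal(nrow(m$params$extractor[[1]]$W), 310)  # 62 channels x F_out 5
  set.seed(1)
  wins <- lapply(1:4, function(i) rand_window(7, 62, 5))
  fw <- model_forward(m, wins)
  expect_equal(dim(fw$class_logits), c(4L, 3L))
  expect_equal(dim(fw$features), c(4L, 64L))
  expect_equal(dim(fw$domain_probs), c(4L, 2L))
  expect_equal(rowSums(fw$domain_probs), rep(1, 4), tolerance = 1e-8)
  expect_equal(rowSums(fw$A_mean), rep(1, 62), tolerance = 1e-6)
})

test_that("identical windows give identical outputs; shape mismatches name the stage", {
  cfg <- quick_config(seed = 2)
  m <- init_model(cfg, 6, 3, 2)
  set.seed(3)
  w <- rand_window(3, 6, 3)
  fw <- model_forward(m, list(w, w, rand_window(3, 6, 3)))
  expect_equal(fw$class_logits[1, ], fw$class_logits[2, ])
  expect_equal(fw$features[1, ], fw$features[2, ])
  expect_false(isTRUE(all.equal(fw$class_logits[1, ], fw$class_logits[3, ])))
  expect_error(model_forward(m, list(rand_window(5, 6, 3))), "front end")
})

test_that("attention ablations reduce to identity mixing and an all-ones mask", {
  cfg <- quick_config(seed = 4,
                      ablation = c("no_temporal_attention", "no_spatial_attention"))
  m <- init_model(cfg, 6, 3, 2)
  set.seed(5)
  X <- rand_window(3, 6, 3)
  fw <- model_forward(m, list(X))
  # reconstruct by hand: raw X through graph + conv + collapse + extractor
  xbar <- apply(X, c(2, 3), mean)
  A <- compute_adjacency(xbar, m$params$w_adj)
  basis <- cheb_basis(scaled_laplacian(symmetrize_adjacency(A))$L_tilde, cfg$K)
  sgc <- spatial_graph_conv(X, matrix(1, 6, 6), basis, m$params$theta)
  feat <- collapse_time(temporal_conv(sgc, m$params$tconv))
  a <- adstgnn:::mlp_forward(m$params$extractor, matrix(feat, 1),
                             final_relu = TRUE)
  h <- a[[length(a)]]
  logits <- h %*% m$params$clf[[1]]$W + m$params$clf[[1]]$b
  expect_equal(as.numeric(fw$class_logits), as.numeric(logits),
               tolerance = 1e-10)
})

test_that("the KNN ablation swaps in the fixed graph and drops the graph loss", {
  cfg <- quick_config(seed = 6, ablation = "knn_graph", knn_k = 2)
  m <- init_model(cfg, 6, 3, 2)
  set.seed(7)
  fw <- model_forward(m, list(rand_window(3, 6, 3)))
  expect_equal(fw$L_gcn, 0)
  expect_equal(rowSums(fw$A_mean), rep(1, 6), tolerance = 1e-12)
})

test_that("training is deterministic given the seed and logs a consistent decomposition", {
  sim <- quick_sim(seed = 8)
  src <- dataset_windows(sim$dataset, 1, "source")
  tgt <- dataset_windows(sim$dataset, 1, "target")
  cfg <- quick_config(seed = 9, max_epochs = 4)
  fit1 <- train_model(src, tgt, cfg)
  fit2 <- train_model(src, tgt, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model$params, fit2$model$params)
  # extractor-side decomposition: total = cls + gcn - lambda * disc
  expect_equal(fit1$log$loss_total,
               fit1$log$loss_classifier + fit1$log$loss_gcn -
                 fit1$log$lambda * fit1$log$loss_disc, tolerance = 1e-6)
})

test_that("the no-discriminator ablation removes the adversarial term from the log", {
  sim <- quick_sim(seed = 10)
  src <- dataset_windows(sim$dataset, 1, "source")
  fit <- train_model(src, list(), quick_config(seed = 11, max_epochs = 2,
                                               ablation = "no_discriminator"))
  expect_false(any(c("lambda", "loss_disc") %in% names(fit$log)))
  expect_equal(fit$log$loss_total,
               fit$log$loss_classifier + fit$log$loss_gcn, tolerance = 1e-10)
  # target windows are mandatory otherwise
  expect_error(train_model(src, list(), quick_config(seed = 11)),
               "target windows required")
})

test_that("training fits clearly separable data well above chance", {
  sim <- quick_sim(seed = 12, n_subjects = 1, n_trials = 8, L = 10)
  src <- dataset_windows(sim$dataset, 1, "source")
  cfg <- quick_config(seed = 13, max_epochs = 60,
                      ablation = "no_discriminator",
                      early_stop_train_acc = 0.95)
  fit <- train_model(src, list(), cfg)
  expect_gte(fit$final_train_accuracy, 0.9)
})

test_that("evaluation reports window accuracy, tie-breaks and confusion counts", {
  sim <- quick_sim(seed = 14)
  wins <- dataset_windows(sim$dataset, 1, "target")
  cfg <- quick_config(seed = 15)
  m <- init_model(cfg, sim$dataset$n_channels, sim$dataset$n_bands, 2)
  # force constant logits: all ties resolve to the lowest class index
  m$params$clf[[1]]$W[] <- 0
  m$params$clf[[1]]$b[] <- 0
  ev <- evaluate_model(m, wins)
  labels <- vapply(wins, `[[`, 0L, "label")
  expect_equal(ev$accuracy, 100 * mean(labels == 0L))
  expect_equal(sum(ev$confusion), length(wins))
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(labels, levels = 0:1))))
  expect_false(is.na(ev$trial_accuracy))
  expect_error(evaluate_model(m, list()), "no windows")
})
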