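test_that("weighted displacement loss reproduces the worked example", {
  x0 <- rbind(c(0, 0, 0), c(1, 0, 0))
  y <- rbind(c(0, 0, -2), c(1, 0, 0))
  yhat <- rbind(c(0, 0, -1.5), c(1, 0, 0.5))
  expect_equal(weighted_displacement_loss(yhat, y, x0), 0.125,
               tolerance = 1e-7)
  expect_equal(weighted_displacement_loss(y, y, x0), 0)
  # zero-deformation degeneracy: weights vanish and the loss is 0
  expect_warning(
    ld <- weighted_displacement_loss(yhat, x0, x0),
    "zero deformation")
  expect_equal(ld, 0, tolerance = 1e-7)
})

test_that("weighted loss matches the loop oracle and is permutation invariant", {
  set.seed(2)
  for (rep in 1:30) {
    n <- sample(2:20, 1)
    x0 <- matrix(runif(n * 3, 0, 100), n, 3)
    y <- x0 + matrix(rnorm(n * 3), n, 3)
    yhat <- y + matrix(rnorm(n * 3, sd = 0.3), n, 3)
    expect_equal(weighted_displacement_loss(yhat, y, x0),
                 oracle_wd_loss(yhat, y, x0), tolerance = 1e-9)
    pi <- sample(n)
    expect_equal(weighted_displacement_loss(yhat[pi, ], y[pi, ], x0[pi, ]),
                 weighted_displacement_loss(yhat, y, x0),
                 tolerance = 1e-12)
  }
})

test_that("total loss is the stated weighted sum and linear in each term", {
  expect_equal(total_loss(0.125, 1, alpha = 1000, beta = 100), 225)
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(0.3, 0.7, alpha = 0.5, beta = 2),
               0.5 * 0.3 + 2 * 0.7)
  set.seed(1)
  for (rep in 1:10) {
    a <- runif(1, 1, 2000); b <- runif(1, 1, 200)
    ld <- runif(1); lf <- runif(1); s <- runif(1, 0, 3)
    expect_equal(total_loss(s * ld, lf, a, b) - total_loss(0, lf, a, b),
                 s * a * ld, tolerance = 1e-9)
    expect_equal(total_loss(ld, s * lf, a, b) - total_loss(ld, 0, a, b),
                 s * b * lf, tolerance = 1e-9)
  }
})

test_that("splits are location-stratified for every scheme", {
  mk <- function(n_loc, states = 3) {
    tibble::tibble(
      location_id = rep(sprintf("loc%03d", seq_len(n_loc)), each = states),
      state = rep(seq_len(states), n_loc))
  }
  s10 <- make_splits(mk(10), "holdout_7_2_1", seed = 1)
  expect_equal(sum(s10$partition == "train"), 7)
  expect_equal(sum(s10$partition == "val"), 2)
  expect_equal(sum(s10$partition == "test"), 1)
  expect_equal(sort(unique(s10$location_id)),
               sprintf("loc%03d", 1:10))

  s39 <- make_splits(mk(39), "loocv", seed = 2)
  expect_equal(nrow(s39), 39)
  expect_equal(sort(s39$fold), 1:39)

  k <- make_splits(mk(23), "kfold_5", seed = 3)
  expect_equal(sort(unique(k$fold)), 1:5)
  expect_true(all(table(k$fold) %in% c(4, 5)))
  # every location in the test fold exactly once across folds
  expect_equal(sort(k$location_id), sprintf("loc%03d", 1:23))
  expect_false(any(duplicated(k$location_id)))

  # states of one location never straddle partitions
  full <- mk(10)
  joined <- merge(full, s10, by = "location_id")
  per_loc <- tapply(joined$partition, joined$location_id,
                    function(p) length(unique(p)))
  expect_true(all(per_loc == 1))

  expect_error(make_splits(mk(2), "holdout_7_2_1"), "at least 3")
  expect_error(make_splits(mk(1), "loocv"), "at least 2")
})

test_that("analytic gradients match finite differences on a tiny instance", {
  vol <- box_volume()
  cfg <- tiny_config()
  par <- deformgnn:::init_params(cfg, seed = 3, init = "random")
  set.seed(10)
  n <- 6
  x0 <- cbind(runif(n, 40, 60), runif(n, 40, 60), 32)
  h0 <- node_features_matrix(vol, x0, 4)
  ht <- force_features_matrix(h0, x0)
  Ch <- extract_line_profile(vol, c(50, 50, 32), c(52, 49, 22), 4)$Ch
  batch <- deformgnn:::single_batch(x0, h0, c(50, 50, 32), c(52, 49, 22),
                                    Ch, ht)
  y <- x0 + matrix(rnorm(n * 3), n, 3)
  lg <- deformgnn:::loss_and_grad(batch, y, 2.5, par, cfg, train = FALSE)
  w <- deformgnn:::extract_weights(par)

  perturb <- function(tree, path, i, h) {
    if (length(path) == 0) { tree$W[i] <- tree$W[i] + h; return(tree) }
    tree[[path[[1]]]] <- perturb(tree[[path[[1]]]], path[-1], i, h)
    tree
  }
  getW <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree$W }
  paths <- list(list("layers", 1, "phi_e", 1), list("layers", 1, "phi_x", 2),
                list("layers", 2, "phi_h", 1), list("layers", 1, "phi_cs", 2),
                list("layers", 2, "phi_ce", 1), list("readout", 1),
                list("readout", 4), list("phi_feat", 1),
                list("phi_force", 2))
  set.seed(4)
  h <- 1e-5
  for (path in paths) {
    Wg <- getW(lg$grads, path)
    for (i in sample(length(Wg), min(4, length(Wg)))) {
      an <- Wg[i]
      p1 <- deformgnn:::set_weights(par, perturb(w, path, i, h))
      p2 <- deformgnn:::set_weights(par, perturb(w, path, i, -h))
      l1 <- deformgnn:::loss_and_grad(batch, y, 2.5, p1, cfg,
                                      train = FALSE)$loss
      l2 <- deformgnn:::loss_and_grad(batch, y, 2.5, p2, cfg,
                                      train = FALSE)$loss
      fd <- (l1 - l2) / (2 * h)
      expect_lt(abs(an - fd), 1e-4 * max(abs(fd), 1))
    }
  }
})

test_that("training is deterministic and finetune with zero epochs is identity", {
  spec <- generator_spec(surface_mode = "scattered", surface_n = 10,
                         n_locations = 4, depth_steps = 5, n_samples = 4,
                         seed = 8)
  ds <- assemble_dataset(spec)
  cfg <- tiny_config()
  tc <- train_config(epochs = 3, batch_size = 4, lr = 1e-3, seed = 5,
                     steps = 6)
  m1 <- train_model(ds, NULL, cfg, tc)
  m2 <- train_model(ds, NULL, cfg, tc)
  expect_identical(deformgnn:::extract_weights(m1$params),
                   deformgnn:::extract_weights(m2$params))
  expect_identical(m1$history$loss, m2$history$loss)
  expect_s3_class(m1$history, "tbl_df")
  expect_true(all(c("epoch", "loss", "loss_d", "loss_f") %in%
                    names(m1$history)))

  splits <- make_splits(ds, "loocv", seed = 1)
  ft <- finetune(m1, ds, splits,
                 config = train_config(epochs = 0, lr = 1e-4,
                                       batch_size = 4),
                 folds = 1:2)
  for (f in c("1", "2")) {
    expect_identical(deformgnn:::extract_weights(ft$models[[f]]$params),
                     deformgnn:::extract_weights(m1$params))
  }
  expect_equal(ft$metrics$mean_euclid_before,
               ft$metrics$mean_euclid_after, tolerance = 1e-12)
})

test_that("tidy and glance summarise fitted models", {
  spec <- generator_spec(surface_mode = "scattered", surface_n = 8,
                         n_locations = 3, depth_steps = 4, n_samples = 4,
                         seed = 12)
  ds <- assemble_dataset(spec)
  cfg <- tiny_config()
  m <- train_model(ds, NULL, cfg,
                   train_config(epochs = 2, batch_size = 4, seed = 0,
                                steps = 4))
  td <- generics::tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(names(td)[1:2], c("epoch", "loss"))
  gl <- generics::glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mode, "literal")
  expect_true(is.finite(gl$final_loss))
})
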