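#' Training configuration
#'
#' @param epochs training epochs (default 200).
#' @param batch_size samples per optimisation step (64 for FEM-style
#'   grid datasets; 16 for sparse experimental-like sets).
#' @param lr Adam learning rate (1e-3 pretraining, 1e-4 fine-tuning).
#' @param alpha,beta loss weights: total loss is
#'   `alpha * L_d + beta * L_f` with defaults 1000 and 100, chosen to
#'   balance the magnitude of the displacement and force terms.
#' @param eps division guard in the displacement weighting (1e-8).
#' @param seed RNG seed controlling shuffling, dropout and init.
#' @param steps optional cap on total optimisation steps (overrides
#'   `epochs` when smaller; useful for smoke runs).
#' @param point_subsample optional count or length-2 range: when set,
#'   each training step draws this many points per cloud (a range draws
#'   a different count each step - density augmentation). The model has
#'   no fixed point count, so training on subsampled clouds is valid and
#'   much cheaper; evaluation always uses full clouds.
#' @param subsample_bias fraction of the point subsample drawn with
#'   probability proportional to the point's ground-truth deformation
#'   magnitude (importance sampling toward the contact region; 0 =
#'   uniform). Training-time only.
#' @param val_every validate every this many epochs (default 5).
#' @param weight_decay decoupled (AdamW-style) weight shrinkage; 0
#'   disables it. Useful when the weighted loss leaves low-deformation
#'   regions unsupervised: shrinkage pulls their prediction toward the
#'   rest configuration, which is the physically correct far-field limit.
#' @param clip_norm global gradient-norm clip (default 5e5, a few times
#'   the healthy per-step maximum at the default loss weights, so it
#'   only reins in the occasional exploding step - orders of magnitude
#'   larger - that would otherwise poison Adam's second moments).
#' @param val_points,val_max_samples optional caps making validation
#'   cheap on dense clouds: evaluate on this many points per cloud /
#'   this many validation samples (estimates of the full metric).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 64L, lr = 1e-3,
                         alpha = 1000, beta = 100, eps = 1e-8,
                         seed = 0L, steps = NULL, point_subsample = NULL,
                         subsample_bias = 0, val_every = 5L,
                         clip_norm = 5e5,
                         weight_decay = 0,
                         val_points = NULL, val_max_samples = NULL) {
  stopifnot(alpha > 0, beta > 0, eps > 0, epochs >= 0, batch_size >= 1,
            clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 alpha = alpha, beta = beta, eps = eps,
                 seed = as.integer(seed),
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 point_subsample = point_subsample,
                 subsample_bias = subsample_bias,
                 val_every = as.integer(val_every),
                 clip_norm = clip_norm, weight_decay = weight_decay,
                 val_points = val_points,
                 val_max_samples = val_max_samples),
            class = "train_config")
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(tree_flatten(g), function(x) sum(x^2), numeric(1))))
}

clip_grads <- function(g, clip_norm) {
  n <- grad_global_norm(g)
  if (is.finite(n) && n > clip_norm) {
    g <- tree_map(function(x) x * (clip_norm / n), g)
  }
  g
}

#' Weighted displacement loss
#'
#' Each point's squared prediction error is weighted by its relative
#' ground-truth deformation magnitude,
#' `w_i = ||y_i - x_i|| / (max_i ||y_i - x_i|| + eps)`, so the loss
#' concentrates on the contact region:
#' `L_d = (1/N) * sum_i w_i * ||yhat_i - y_i||^2`.
#' When the sample carries no deformation at all every weight is ~0 and
#' the loss collapses to 0 regardless of the prediction; this degeneracy
#' is flagged with a warning.
#'
#' @param yhat,y,x0 N x 3 matrices: prediction, ground truth, rest cloud.
#' @param eps division guard (default 1e-8).
#' @return scalar loss (mm^2).
#' @export
weighted_displacement_loss <- function(yhat, y, x0, eps = 1e-8) {
  yhat <- as_points_matrix(yhat); y <- as_points_matrix(y)
  x0 <- as_points_matrix(x0)
  stopifnot(nrow(yhat) == nrow(y), nrow(y) == nrow(x0), nrow(y) >= 1)
  nrm <- sqrt(rowSums((y - x0)^2))
  mx <- max(nrm)
  if (mx == 0) {
    warning("weighted_displacement_loss: sample has zero deformation; ",
            "all weights vanish")
  }
  w <- nrm / (mx + eps)
  mean(w * rowSums((yhat - y)^2))
}

#' Total training loss
#'
#' `L = alpha * L_d + beta * L_f`, linear in both terms; `L_f` is the
#' batch-mean squared force error.
#'
#' @param loss_d,loss_f non-negative component losses.
#' @param alpha,beta weights (defaults 1000 and 100).
#' @return scalar total loss.
#' @export
total_loss <- function(loss_d, loss_f, alpha = 1000, beta = 100) {
  stopifnot(loss_d >= 0, loss_f >= 0)
  alpha * loss_d + beta * loss_f
}

#' Location-stratified split plans
#'
#' The unit of assignment is always the probe location: every static
#' state of a location lands in the same partition, so test locations
#' are genuinely unseen. Schemes: `holdout_7_2_1` (train/val/test by a
#' 7:2:1 location ratio, counts rounded to nearest with the remainder
#' going to train), `kfold_5` (five near-equal location folds) and
#' `loocv` (one fold per location).
#'
#' @param dataset a `dg_dataset` or its samples tibble (needs a
#'   `location_id` column).
#' @param scheme `"holdout_7_2_1"`, `"kfold_5"` or `"loocv"`.
#' @param seed shuffling seed.
#' @return a tibble (`location_id`, `partition`) for holdout, or
#'   (`location_id`, `fold`) for the cross-validation schemes.
#' @export
make_splits <- function(dataset,
                        scheme = c("holdout_7_2_1", "kfold_5", "loocv"),
                        seed = 0L) {
  scheme <- match.arg(scheme)
  samples <- if (inherits(dataset, "dg_dataset")) dataset$samples else dataset
  locs <- unique(samples$location_id)
  n <- length(locs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  locs <- sample(locs)
  if (scheme == "holdout_7_2_1") {
    if (n < 3) stop("holdout needs at least 3 locations")
    n_test <- max(1L, round(0.1 * n))
    n_val <- max(1L, round(0.2 * n))
    n_train <- n - n_test - n_val
    if (n_train < 1) stop("holdout needs at least 3 locations")
    part <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    return(tibble::tibble(location_id = locs, partition = part))
  }
  if (scheme == "loocv") {
    if (n < 2) stop("loocv needs at least 2 locations")
    return(tibble::tibble(location_id = locs, fold = seq_len(n)))
  }
  if (n < 5) stop("kfold_5 needs at least 5 locations")
  fold <- rep(seq_len(5), length.out = n)
  tibble::tibble(location_id = locs, fold = sort(fold))
}

split_partition <- function(samples, splits, part) {
  if ("partition" %in% names(splits)) {
    ids <- splits$location_id[splits$partition == part]
  } else {
    stop("splits have folds, not partitions; select a fold instead")
  }
  samples[samples$location_id %in% ids, , drop = FALSE]
}

# stack a list of sample rows into one disconnected-graph batch,
# optionally subsampling points (always keeping full clouds intact in
# the dataset itself). `bias` draws that fraction of the subsample with
# probability proportional to the ground-truth deformation magnitude
# (importance sampling: with a compactly-supported contact field a
# uniform draw wastes almost every point on the static far field).
stack_batch <- function(rows, point_subsample = NULL, bias = 0) {
  B <- nrow(rows)
  xs <- list(); hs <- list(); hts <- list(); ys <- list()
  si <- integer(0)
  Cs <- matrix(0, B, 3); Ce <- matrix(0, B, 3)
  Ch <- matrix(0, B, length(rows$Ch[[1]]))
  Fv <- numeric(B)
  for (b in seq_len(B)) {
    x0 <- rows$x0[[b]]; h0 <- rows$h0[[b]]; ht <- rows$htilde0[[b]]
    y <- rows$y[[b]]
    if (!is.null(point_subsample) && point_subsample < nrow(x0)) {
      if (bias > 0) {
        n_b <- round(bias * point_subsample)
        mag <- sqrt(rowSums((y - x0)^2))
        idx_b <- sample.int(nrow(x0), n_b, prob = mag + 1e-6)
        rest <- setdiff(seq_len(nrow(x0)), idx_b)
        idx <- c(idx_b, sample(rest, point_subsample - n_b))
      } else {
        idx <- sample.int(nrow(x0), point_subsample)
      }
      x0 <- x0[idx, , drop = FALSE]; h0 <- h0[idx, , drop = FALSE]
      ht <- ht[idx, , drop = FALSE]; y <- y[idx, , drop = FALSE]
    }
    xs[[b]] <- x0; hs[[b]] <- h0; hts[[b]] <- ht; ys[[b]] <- y
    si <- c(si, rep(b, nrow(x0)))
    Cs[b, ] <- rows$Cs[[b]]; Ce[b, ] <- rows$Ce[[b]]
    Ch[b, ] <- rows$Ch[[b]]
    Fv[b] <- rows$force[b]
  }
  list(batch = list(x0 = do.call(rbind, xs), h0 = do.call(rbind, hs),
                    htilde0 = do.call(rbind, hts), sample_idx = si,
                    Cs = Cs, Ce = Ce, Ch = Ch),
       y = do.call(rbind, ys), F = Fv)
}

eval_mean_euclid <- function(samples, params, config, points = NULL,
                             max_samples = NULL) {
  if (nrow(samples) == 0) return(NA_real_)
  rows <- seq_len(nrow(samples))
  if (!is.null(max_samples) && max_samples < length(rows)) {
    rows <- sample(rows, max_samples)
  }
  errs <- vapply(rows, function(i) {
    s <- as_sample(samples[i, ])
    if (!is.null(points) && points < nrow(s$x0)) {
      idx <- sample.int(nrow(s$x0), points)
      s$x0 <- s$x0[idx, , drop = FALSE]
      s$h0 <- s$h0[idx, , drop = FALSE]
      s$htilde0 <- s$htilde0[idx, , drop = FALSE]
      s$y <- s$y[idx, , drop = FALSE]
    }
    out <- model_forward(s, params, config)
    mean(sqrt(rowSums((out$yhat - s$y)^2)))
  }, numeric(1))
  mean(errs)
}

#' Train the model
#'
#' Seeded Adam loop minimising the weighted total loss
#' `alpha * L_d + beta * L_f` over the training partition, with
#' per-epoch logging and best-epoch selection by validation mean
#' Euclidean distance (falling back to final parameters when no
#' validation partition exists). Aborts with diagnostics on non-finite
#' loss.
#'
#' @param dataset a `dg_dataset`.
#' @param splits a holdout split plan from [make_splits()], or `NULL` to
#'   train on everything.
#' @param model_config a [model_config()].
#' @param config a [train_config()].
#' @param params optional warm-start parameters (used by [finetune()]).
#' @return a `deformgnn_model`: list with `params`, `config`
#'   (model config), `train_config`, `history` tibble and `best_epoch`.
#' @export
train_model <- function(dataset, splits, model_config,
                        config = train_config(), params = NULL) {
  samples <- dataset$samples
  if (!is.null(splits)) {
    train_s <- split_partition(samples, splits, "train")
    val_s <- split_partition(samples, splits, "val")
  } else {
    train_s <- samples
    val_s <- samples[0, ]
  }
  if (nrow(train_s) == 0) stop("train_model: empty training partition")
  if (is.null(params)) {
    params <- init_params(model_config, seed = config$seed)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  weights <- extract_weights(params)
  opt <- adam_init(weights)
  n_train <- nrow(train_s)
  steps_per_epoch <- max(1L, ceiling(n_train / config$batch_size))
  total_cap <- config$steps %||% Inf
  step <- 0L
  history <- list()
  best_val <- Inf
  best_weights <- weights

  n_epochs <- if (is.finite(total_cap)) {
    min(config$epochs, ceiling(total_cap / steps_per_epoch))
  } else config$epochs

  for (epoch in seq_len(max(n_epochs, 0))) {
    perm <- sample.int(n_train)
    ep_l <- ep_ld <- ep_lf <- 0; nb <- 0
    for (bs in seq_len(steps_per_epoch)) {
      if (step >= total_cap) break
      idx <- perm[((bs - 1) * config$batch_size + 1):
                    min(bs * config$batch_size, n_train)]
      ps <- config$point_subsample
      if (length(ps) == 2) ps <- sample(ps[1]:ps[2], 1)
      sb <- stack_batch(train_s[idx, ], ps,
                        bias = config$subsample_bias)
      params <- set_weights(params, weights)
      lg <- loss_and_grad(sb$batch, sb$y, sb$F, params, model_config,
                          alpha = config$alpha, beta = config$beta,
                          eps = config$eps, train = TRUE)
      if (!is.finite(lg$loss)) {
        stop("train_model: non-finite loss at epoch ", epoch, " step ",
             step, " (loss_d=", lg$loss_d, ", loss_f=", lg$loss_f, ")")
      }
      st <- adam_step(weights, clip_grads(lg$grads, config$clip_norm),
                      opt, lr = config$lr,
                      weight_decay = config$weight_decay)
      weights <- st$weights; opt <- st$state
      ep_l <- ep_l + lg$loss; ep_ld <- ep_ld + lg$loss_d
      ep_lf <- ep_lf + lg$loss_f; nb <- nb + 1
      step <- step + 1L
    }
    params <- set_weights(params, weights)
    val_err <- NA_real_
    if (nrow(val_s) > 0 &&
        (epoch %% config$val_every == 0 || epoch == n_epochs)) {
      val_err <- eval_mean_euclid(val_s, params, model_config,
                                  points = config$val_points,
                                  max_samples = config$val_max_samples)
      if (is.finite(val_err) && val_err < best_val) {
        best_val <- val_err
        best_weights <- weights
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_l / max(nb, 1),
      loss_d = ep_ld / max(nb, 1), loss_f = ep_lf / max(nb, 1),
      val_mean_euclid = val_err)
    if (step >= total_cap) break
  }

  history <- if (length(history)) dplyr::bind_rows(history) else
    tibble::tibble(epoch = integer(0), loss = numeric(0),
                   loss_d = numeric(0), loss_f = numeric(0),
                   val_mean_euclid = numeric(0))
  if (nrow(val_s) > 0 && is.finite(best_val)) {
    params <- set_weights(params, best_weights)
    best_epoch <- history$epoch[which.min(history$val_mean_euclid)] %||% NA
  } else {
    best_epoch <- if (nrow(history)) max(history$epoch) else NA_integer_
  }

  structure(list(params = params, config = model_config,
                 train_config = config, history = history,
                 best_epoch = best_epoch),
            class = "deformgnn_model")
}

#' @export
print.deformgnn_model <- function(x, ...) {
  cat("<deformgnn_model>", x$config$mode, "mode, L =", x$config$L,
      ", k =", x$config$k, "\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epoch(s), final loss %.4g (L_d %.4g, L_f %.4g)\n",
                last$epoch, last$loss, last$loss_d, last$loss_f))
  }
  invisible(x)
}

#' Fine-tune a pretrained model per leave-one-out fold
#'
#' Continues training from pretrained parameters on each LOOCV training
#' split of a sparse (experimental-like) dataset at the reduced
#' fine-tuning learning rate, and reports per-fold held-out metrics
#' before and after fine-tuning. Zero epochs leaves the parameters
#' untouched.
#'
#' @param model a pretrained `deformgnn_model`.
#' @param dataset the sparse dataset to adapt to.
#' @param splits a LOOCV plan from [make_splits()] (`fold` column).
#' @param config a [train_config()] (defaults: lr 1e-4, batch 16).
#' @param folds optional subset of fold indices to run.
#' @return list with `models` (per fold) and `metrics` tibble
#'   (fold, mean Euclidean distance before/after).
#' @export
finetune <- function(model, dataset, splits,
                     config = train_config(lr = 1e-4, batch_size = 16L),
                     folds = NULL) {
  stopifnot("fold" %in% names(splits))
  folds <- folds %||% sort(unique(splits$fold))
  samples <- dataset$samples
  models <- list()
  metrics <- list()
  for (f in folds) {
    test_ids <- splits$location_id[splits$fold == f]
    train_s <- samples[!samples$location_id %in% test_ids, ]
    test_s <- samples[samples$location_id %in% test_ids, ]
    sub <- dataset; sub$samples <- train_s
    err_before <- eval_mean_euclid(test_s, model$params, model$config)
    m <- train_model(sub, splits = NULL, model_config = model$config,
                     config = config, params = model$params)
    err_after <- eval_mean_euclid(test_s, m$params, m$config)
    models[[as.character(f)]] <- m
    metrics[[as.character(f)]] <- tibble::tibble(
      fold = f, mean_euclid_before = err_before,
      mean_euclid_after = err_after)
  }
  list(models = models, metrics = dplyr::bind_rows(metrics))
}

#' @exportS3Method generics::tidy
tidy.deformgnn_model <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.deformgnn_model <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(loss = NA_real_, loss_d = NA_real_, loss_f = NA_real_)
  tibble::tibble(
    mode = x$config$mode, L = x$config$L, k = x$config$k,
    epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    final_loss = last$loss, final_loss_d = last$loss_d,
    final_loss_f = last$loss_f)
}

#' @exportS3Method ggplot2::autoplot
autoplot.deformgnn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "loss", "loss_d",
                                              "loss_f")],
                           -"epoch", names_to = "term",
                           values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL,
                  title = "Training loss components")
}
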