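# Shared fixtures and independent oracles. The oracles are deliberately
# naive loop implementations, kept free of the package's vectorised
# internals so they can serve as a cross-check.

slab_volume <- function(top = 16) {
  tissue_volume(primitives = list(
    list(type = "box", min = c(0, 0, 0), max = c(100, 100, top))))
}

box_volume <- function() {
  tissue_volume(primitives = list(
    list(type = "box", min = c(20, 20, 0), max = c(60, 60, 16))))
}

random_phantom <- function(seed) {
  generate_phantom(generator_spec(seed = 1), seed = seed)
}

# plain-loop MLP evaluation on a single vector (independent of
# mlp_forward); params are the package's weight lists
oracle_mlp <- function(mlp, v) {
  for (l in seq_along(mlp$layers)) {
    z <- as.numeric(v %*% mlp$layers[[l]]$W) + mlp$layers[[l]]$b
    v <- switch(mlp$acts[l],
                silu = z / (1 + exp(-z)),
                relu = ifelse(z > 0, z, 0),
                none = z)
  }
  v
}

# dense loop oracle of one conditional equivariant graph convolution:
# messages, coordinate update with condition terms, residual feature
# update - all per-node, per-neighbour
oracle_cegcl <- function(x, h, Cs, Ce, lp, config) {
  n <- nrow(x)
  k_eff <- min(config$k, n)
  x_new <- x
  h_new <- h
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    ord <- order(d, seq_len(n))
    neigh <- setdiff(ord, i)[seq_len(k_eff - 1)]
    agg <- c(0, 0, 0)
    msum <- numeric(config$hidden)
    for (j in neigh) {
      dij2 <- sum((x[i, ] - x[j, ])^2)
      m_ij <- oracle_mlp(lp$phi_e, c(h[i, ], h[j, ], dij2))
      s_ij <- oracle_mlp(lp$phi_x, m_ij)
      agg <- agg + (x[i, ] - x[j, ]) * s_ij
      msum <- msum + m_ij
    }
    agg <- agg / (k_eff - 1)
    if (config$mode == "strict") {
      pcs <- (x[i, ] - Cs) * oracle_mlp(lp$phi_cs, sum((x[i, ] - Cs)^2))
      pce <- (x[i, ] - Ce) * oracle_mlp(lp$phi_ce, sum((x[i, ] - Ce)^2))
    } else {
      pcs <- oracle_mlp(lp$phi_cs, x[i, ] - Cs)
      pce <- oracle_mlp(lp$phi_ce, x[i, ] - Ce)
    }
    x_new[i, ] <- x[i, ] + pcs + pce + agg
    h_new[i, ] <- h[i, ] + oracle_mlp(lp$phi_h, c(h[i, ], msum))
  }
  list(x = x_new, h = h_new)
}

# loop oracle for the force branch (literal mode)
oracle_force <- function(yhat, htilde0, Ce, Ch, params) {
  n <- nrow(yhat)
  z <- NULL
  for (i in seq_len(n)) {
    zi <- oracle_mlp(params$phi_feat,
                     c(yhat[i, ] - Ce, htilde0[i, ] - Ch))
    z <- rbind(z, zi)
  }
  zmax <- apply(z, 2, max)
  zmean <- colMeans(z)
  oracle_mlp(params$phi_force, c(zmax, zmean))
}

# loop oracle for the weighted displacement loss
oracle_wd_loss <- function(yhat, y, x0, eps = 1e-8) {
  n <- nrow(y)
  nrm <- numeric(n)
  for (i in seq_len(n)) nrm[i] <- sqrt(sum((y[i, ] - x0[i, ])^2))
  acc <- 0
  for (i in seq_len(n)) {
    w <- nrm[i] / (max(nrm) + eps)
    acc <- acc + w * sum((yhat[i, ] - y[i, ])^2)
  }
  acc / n
}

# loop oracle for the evaluation metrics
oracle_metrics <- function(yhat, Fhat, y, Ftrue, x0, Cs, Ce) {
  n <- nrow(y)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((yhat[i, ] - y[i, ])^2))
  dc <- numeric(n)
  for (i in seq_len(n)) dc[i] <- sum((x0[i, ] - Cs)^2)
  tip <- which.min(dc)
  travel <- sqrt(sum((Ce - Cs)^2))
  list(force_abs = abs(Fhat - Ftrue), mean_euclid = sum(d) / n,
       max_euclid = max(d), rel_tip = d[tip] / travel)
}

# a small self-consistent sample over a given volume
tiny_sample <- function(volume, n_points = 8, n_samples = 4, seed = 1,
                        Cs = c(50, 50, 32), Ce = c(52, 48, 22)) {
  set.seed(seed)
  x0 <- cbind(runif(n_points, 5, 95), runif(n_points, 5, 95), 32)
  h0 <- node_features_matrix(volume, x0, n_samples)
  list(x0 = x0, h0 = h0,
       htilde0 = force_features_matrix(h0, x0),
       Cs = Cs, Ce = Ce,
       Ch = extract_line_profile(volume, Cs, Ce, n_samples)$Ch,
       y = x0, force = 0)
}

tiny_config <- function(...) {
  model_config(L = 2, k = 3, dh = 8, hidden = 8, n_line = 4, ...)
}

# one-row tibble sample in the dataset layout
sample_row <- function(s, location_id = "loc001", state = 1L,
                       depth = 5, force = s$force %||% 0) {
  tibble::tibble(location_id = location_id, state = state, depth = depth,
                 force = force, x0 = list(s$x0), h0 = list(s$h0),
                 htilde0 = list(s$htilde0), Cs = list(s$Cs),
                 Ce = list(s$Ce), Ch = list(s$Ch), y = list(s$y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
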