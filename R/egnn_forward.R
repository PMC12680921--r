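#' k-nearest-neighbour graph of a point cloud
#'
#' For each node, the `k - 1` nearest *other* nodes by Euclidean
#' distance (the graph the message-passing layers aggregate over; the
#' point itself is excluded). `k` is clamped to the cloud size and ties
#' are broken by lower node index, so the graph is deterministic.
#'
#' @param x N x 3 coordinate matrix, N >= 2.
#' @param k neighbour count before self-exclusion.
#' @return list of integer vectors; element `i` holds node i's
#'   neighbours ordered by increasing distance.
#' @export
knn_edges <- function(x, k) {
  x <- as_points_matrix(x)
  n <- nrow(x)
  if (n < 2) stop("knn_edges: need at least 2 points")
  k_eff <- min(k, n)
  D <- as.matrix(stats::dist(x))
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k_eff - 1)]
  })
}

# flat edge arrays (ei = target, ej = neighbour) for a stacked batch;
# inv = 1/(k_eff - 1) per node
edge_arrays <- function(neigh) {
  deg <- lengths(neigh)
  list(ei = rep(seq_along(neigh), deg),
       ej = unlist(neigh, use.names = FALSE),
       inv = 1 / deg)
}

batch_knn <- function(x, sample_idx, k) {
  ei <- integer(0); ej <- integer(0); inv <- numeric(length(sample_idx))
  for (s in unique(sample_idx)) {
    rows <- which(sample_idx == s)
    ea <- edge_arrays(knn_edges(x[rows, , drop = FALSE], k))
    ei <- c(ei, rows[ea$ei]); ej <- c(ej, rows[ea$ej])
    inv[rows] <- ea$inv
  }
  list(ei = ei, ej = ej, inv = inv)
}

# scatter-add rows of `vals` into an M-row accumulator by index `idx`
index_add <- function(acc, idx, vals) {
  rs <- rowsum(vals, group = idx)
  rows <- as.integer(rownames(rs))
  acc[rows, ] <- acc[rows, , drop = FALSE] + rs
  acc
}

safe_sqrt <- function(x) sqrt(x + 1e-12)

# One conditional equivariant graph convolution layer (batched).
# x: M x 3, h: M x dh, CsN/CeN: M x 3 per-node condition rows,
# edges: list(ei, ej, inv). Returns new x, h and a cache for backward.
layer_forward <- function(x, h, CsN, CeN, edges, lp, config,
                          want_cache = TRUE) {
  ei <- edges$ei; ej <- edges$ej
  diff <- x[ei, , drop = FALSE] - x[ej, , drop = FALSE]
  d2 <- rowSums(diff^2)
  ein <- cbind(h[ei, , drop = FALSE], h[ej, , drop = FALSE], d2)
  fe <- mlp_forward(lp$phi_e, ein)
  m <- fe$out
  fx <- mlp_forward(lp$phi_x, m)
  s <- fx$out[, 1]
  wdiff <- diff * s
  agg <- index_add(matrix(0, nrow(x), 3), ei, wdiff) * edges$inv

  if (config$mode == "strict") {
    rcs <- x - CsN; rce <- x - CeN
    d2cs <- matrix(rowSums(rcs^2), ncol = 1)
    d2ce <- matrix(rowSums(rce^2), ncol = 1)
    fcs <- mlp_forward(lp$phi_cs, d2cs)
    fce <- mlp_forward(lp$phi_ce, d2ce)
    pcs <- rcs * fcs$out[, 1]
    pce <- rce * fce$out[, 1]
  } else {
    rcs <- x - CsN; rce <- x - CeN
    fcs <- mlp_forward(lp$phi_cs, rcs)
    fce <- mlp_forward(lp$phi_ce, rce)
    pcs <- fcs$out
    pce <- fce$out
  }
  x_new <- x + pcs + pce + agg

  msum <- index_add(matrix(0, nrow(x), ncol(m)), ei, m)
  hin <- cbind(h, msum)
  fh <- mlp_forward(lp$phi_h, hin)
  h_new <- h + fh$out

  cache <- NULL
  if (want_cache) {
    cache <- list(x = x, h = h, edges = edges, diff = diff, s = s,
                  m = m, fe = fe$cache, fx = fx$cache, fh = fh$cache,
                  fcs = fcs$cache, fce = fce$cache, rcs = rcs, rce = rce,
                  ein_dim = ncol(ein))
    if (config$mode == "strict") {
      cache$gcs <- fcs$out[, 1]; cache$gce <- fce$out[, 1]
    }
  }
  list(x = x_new, h = h_new, cache = cache)
}

# Full two-branch forward over a stacked batch.
# batch: list(x0 M x 3, h0 M x dh, htilde0 M x (2 dh), sample_idx,
#             Cs B x 3, Ce B x 3, Ch B x ch_len)
# Returns yhat (M x 3), F (length B) and caches when want_cache.
network_forward <- function(batch, params, config, train = FALSE,
                            want_cache = FALSE) {
  si <- batch$sample_idx
  M <- nrow(batch$x0)
  CsN <- batch$Cs[si, , drop = FALSE]
  CeN <- batch$Ce[si, , drop = FALSE]
  ChN <- batch$Ch[si, , drop = FALSE]
  h <- if (config$tissue_features) batch$h0 else batch$h0 * 0
  x <- batch$x0

  edges <- batch_knn(x, si, config$k)
  layer_caches <- vector("list", config$L)
  xs <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    if (config$edge_recompute == "per_layer" && l > 1) {
      edges <- batch_knn(x, si, config$k)
    }
    lf <- layer_forward(x, h, CsN, CeN, edges, params$layers[[l]],
                        config, want_cache = want_cache)
    x <- lf$x; h <- lf$h
    xs[[l]] <- x
    layer_caches[[l]] <- lf$cache
  }

  if (config$mode == "strict") {
    u <- x - batch$x0
    yhat <- x
    ro_cache <- NULL
  } else {
    rin <- cbind(do.call(cbind, xs), CsN, CeN, ChN)
    ro <- mlp_forward(params$readout, rin, train = train)
    u <- ro$out
    yhat <- batch$x0 + u
    ro_cache <- ro$cache
  }

  # force branch
  dye <- yhat - CeN
  if (config$mode == "strict") {
    nl <- config$n_line
    dxy <- safe_sqrt(dye[, 1]^2 + dye[, 2]^2)
    hx <- batch$htilde0[, seq_len(nl), drop = FALSE] -
      ChN[, seq_len(nl), drop = FALSE]
    hy <- batch$htilde0[, nl + seq_len(nl), drop = FALSE] -
      ChN[, nl + seq_len(nl), drop = FALSE]
    hr <- safe_sqrt(hx^2 + hy^2)
    rest <- batch$htilde0[, 2 * nl + seq_len(2 * nl), drop = FALSE] -
      ChN[, 2 * nl + seq_len(2 * nl), drop = FALSE]
    fin <- cbind(dxy, dye[, 3], hr, rest)
    inv_cache <- list(dye = dye, dxy = dxy, hx = hx, hy = hy, hr = hr)
  } else {
    fin <- cbind(dye, batch$htilde0 - ChN)
    inv_cache <- NULL
  }
  ff <- mlp_forward(params$phi_feat, fin)
  z <- ff$out

  B <- nrow(batch$Cs)
  sample_rows <- split(seq_len(M), si)
  zmax <- matrix(0, B, ncol(z)); zmean <- matrix(0, B, ncol(z))
  argmax <- matrix(0L, B, ncol(z))
  for (b in seq_len(B)) {
    rows <- sample_rows[[as.character(b)]]
    zb <- z[rows, , drop = FALSE]
    am <- max.col(t(zb), ties.method = "first")
    argmax[b, ] <- rows[am]
    zmax[b, ] <- zb[cbind(am, seq_len(ncol(z)))]
    zmean[b, ] <- colMeans(zb)
  }
  pin <- cbind(zmax, zmean)
  fo <- mlp_forward(params$phi_force, pin, train = train)
  Fhat <- fo$out[, 1]

  out <- list(yhat = yhat, F = Fhat, u = u)
  if (want_cache) {
    out$cache <- list(layers = layer_caches, xs = xs, ro = ro_cache,
                      ff = ff$cache, fo = fo$cache, fin = fin, z = z,
                      argmax = argmax, sample_rows = sample_rows,
                      CsN = CsN, CeN = CeN, ChN = ChN, edges_last = NULL,
                      inv_cache = inv_cache, batch = batch)
  }
  out
}

# --- spec-level single-sample operations -------------------------------

#' One conditional equivariant graph convolution step
#'
#' Applies a single cEGCL layer to a layer state: messages
#' `m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2)`, coordinate update
#' `x_i <- x_i + phi_cs(x_i - Cs) + phi_ce(x_i - Ce) +
#'  (1/(k-1)) * sum_j (x_i - x_j) * phi_x(m_ij)` and residual feature
#' update `h_i <- h_i + phi_h(h_i, sum_j m_ij)`.
#'
#' @param state list with `x` (N x 3), `h` (N x dh) and optionally
#'   `edges` (neighbour lists from [knn_edges()]; rebuilt from `x` when
#'   missing).
#' @param Cs,Ce probe condition points (3-vectors, mm).
#' @param layer_params one element of `params$layers` from
#'   [init_params()].
#' @param config a [model_config()].
#' @return updated state (`x`, `h`, `edges`).
#' @export
cegcl_forward <- function(state, Cs, Ce, layer_params, config) {
  x <- as_points_matrix(state$x)
  h <- as.matrix(state$h)
  if (ncol(h) != config$dh) stop("feature width does not match config$dh")
  neigh <- state$edges %||% knn_edges(x, config$k)
  edges <- edge_arrays(neigh)
  n <- nrow(x)
  CsN <- matrix(as.numeric(Cs), n, 3, byrow = TRUE)
  CeN <- matrix(as.numeric(Ce), n, 3, byrow = TRUE)
  lf <- layer_forward(x, h, CsN, CeN, edges, layer_params, config,
                      want_cache = FALSE)
  list(x = lf$x, h = lf$h, edges = neigh)
}

# normalise a sample: one-row tibbles with list-columns unwrap to a
# plain list of matrices/vectors
as_sample <- function(sample) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1)
    sample <- lapply(sample, function(col) {
      if (is.list(col)) col[[1]] else col
    })
  }
  sample
}

single_batch <- function(x0, h0, Cs, Ce, Ch, htilde0 = NULL) {
  x0 <- as_points_matrix(x0)
  if (is.null(htilde0)) htilde0 <- force_features_matrix(h0, x0)
  list(x0 = x0, h0 = as.matrix(h0), htilde0 = as.matrix(htilde0),
       sample_idx = rep(1L, nrow(x0)),
       Cs = matrix(as.numeric(Cs), 1, 3),
       Ce = matrix(as.numeric(Ce), 1, 3),
       Ch = matrix(as.numeric(Ch), 1))
}

#' Displacement branch forward pass
#'
#' Runs L stacked cEGCL layers on the rest cloud, then (literal mode)
#' feeds the per-point concatenation of all layer coordinates with the
#' probe conditions `Cs`, `Ce`, `Ch` through the four-layer readout MLP
#' to produce the per-point displacement `u`; strict mode takes
#' `u = x^L - x0` directly. The deformed cloud is `yhat = x0 + u`.
#'
#' @param x0 N x 3 rest cloud (mm).
#' @param h0 N x dh node features ([node_features_matrix()]).
#' @param Cs,Ce probe condition points.
#' @param Ch probe-line condition features ([extract_line_profile()]).
#' @param params a `dg_params`; `config` a [model_config()].
#' @param train enable dropout (training mode).
#' @return list with `u` (N x 3) and `yhat` (N x 3).
#' @export
displacement_forward <- function(x0, h0, Cs, Ce, Ch, params, config,
                                 train = FALSE) {
  if (length(Ch) != config$ch_len) {
    stop("Ch length ", length(Ch), " does not match config (",
         config$ch_len, ")")
  }
  batch <- single_batch(x0, h0, Cs, Ce, Ch)
  out <- network_forward(batch, params, config, train = train)
  list(u = out$u, yhat = out$yhat)
}

#' Force branch forward pass
#'
#' Per-point latent features `z_i = phi_feat(yhat_i - Ce, htilde0_i - Ch)`
#' are pooled with global max and mean and regressed to the scalar
#' contact force by `phi_force`.
#'
#' @param yhat N x 3 (predicted) deformed cloud.
#' @param htilde0 N x (4 n_line) per-point force features
#'   ([force_features_matrix()]).
#' @param Ce probe end point; `Ch` the probe-line features.
#' @param params,config model parameters and configuration.
#' @param train enable dropout.
#' @return scalar force in newtons.
#' @export
force_forward <- function(yhat, htilde0, Ce, Ch, params, config,
                          train = FALSE) {
  yhat <- as_points_matrix(yhat)
  if (nrow(yhat) == 0) stop("force_forward: empty cloud")
  htilde0 <- as.matrix(htilde0)
  if (ncol(htilde0) != length(Ch)) {
    stop("htilde0 and Ch widths differ")
  }
  n <- nrow(yhat)
  si <- rep(1L, n)
  CeN <- matrix(as.numeric(Ce), n, 3, byrow = TRUE)
  ChN <- matrix(as.numeric(Ch), n, length(Ch), byrow = TRUE)
  dye <- yhat - CeN
  if (config$mode == "strict") {
    nl <- config$n_line
    dxy <- safe_sqrt(dye[, 1]^2 + dye[, 2]^2)
    hx <- htilde0[, seq_len(nl), drop = FALSE] - ChN[, seq_len(nl), drop = FALSE]
    hy <- htilde0[, nl + seq_len(nl), drop = FALSE] -
      ChN[, nl + seq_len(nl), drop = FALSE]
    fin <- cbind(dxy, dye[, 3], safe_sqrt(hx^2 + hy^2),
                 htilde0[, 2 * nl + seq_len(2 * nl), drop = FALSE] -
                   ChN[, 2 * nl + seq_len(2 * nl), drop = FALSE])
  } else {
    fin <- cbind(dye, htilde0 - ChN)
  }
  z <- mlp_forward(params$phi_feat, fin)$out
  pin <- cbind(apply(z, 2, max), colMeans(z))
  mlp_forward(params$phi_force, matrix(pin, nrow = 1), train = train)$out[1, 1]
}

#' Full model forward pass on one sample
#'
#' Composition of the displacement branch and the force branch: predicts
#' the deformed cloud and the scalar probe force. With
#' `config$tissue_features = FALSE` the tissue profile input is zeroed
#' (ablation).
#'
#' @param sample a dataset row (list with `x0`, `h0`, `htilde0`, `Cs`,
#'   `Ce`, `Ch`), e.g. one row of [assemble_dataset()]'s samples.
#' @param params,config model parameters and configuration.
#' @param train enable dropout.
#' @return list with `yhat` (N x 3), `F` (scalar N) and `u`.
#' @export
model_forward <- function(sample, params, config, train = FALSE) {
  sample <- as_sample(sample)
  batch <- single_batch(sample$x0, sample$h0, sample$Cs, sample$Ce,
                        sample$Ch, sample$htilde0)
  out <- network_forward(batch, params, config, train = train)
  list(yhat = out$yhat, F = out$F, u = out$u)
}
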