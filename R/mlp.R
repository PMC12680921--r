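# Minimal dense-network substrate: weight init, forward with cache,
# reverse-mode backward. All math is double-precision base matrix algebra.

silu <- function(x) x / (1 + exp(-x))
d_silu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}
relu <- function(x) pmax(x, 0)

apply_act <- function(z, act) {
  switch(act, silu = silu(z), relu = relu(z), none = z,
         stop("unknown activation: ", act))
}
apply_dact <- function(z, act) {
  switch(act, silu = d_silu(z), relu = (z > 0) * 1, none = 1,
         stop("unknown activation: ", act))
}

# sizes: c(in, h1, ..., out); acts/drops: one entry per weight layer.
# ReLU layers get He-normal init, others Xavier-uniform; draws come from
# the current RNG state so callers control determinism.
make_mlp <- function(sizes, acts, drops = rep(0, length(acts)),
                     zero_last = FALSE) {
  n_layer <- length(sizes) - 1
  stopifnot(length(acts) == n_layer, length(drops) == n_layer)
  layers <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1]
    W <- if (acts[l] == "relu") {
      matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
    } else {
      s <- sqrt(6 / (n_in + n_out))
      matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
    }
    if (zero_last && l == n_layer) W[] <- 0
    layers[[l]] <- list(W = W, b = numeric(n_out))
  }
  structure(list(layers = layers, acts = acts, drops = drops),
            class = "dg_mlp")
}

# Rescales first-layer input columns; used at init time to equalise the
# scale of mm-valued inputs against binary features. Pure initialisation
# - the functional form is untouched.
scale_input_cols <- function(mlp, cols, factor) {
  mlp$layers[[1]]$W[cols, ] <- mlp$layers[[1]]$W[cols, , drop = FALSE] * factor
  mlp
}

# X: n x in. Dropout (inverted) is applied after the activation when
# train = TRUE and the layer's rate > 0; masks are drawn from the
# current RNG.
mlp_forward <- function(mlp, X, train = FALSE) {
  n_layer <- length(mlp$layers)
  cache <- vector("list", n_layer)
  A <- X
  for (l in seq_len(n_layer)) {
    lay <- mlp$layers[[l]]
    Z <- A %*% lay$W
    Z <- sweep(Z, 2, lay$b, "+")
    out <- apply_act(Z, mlp$acts[l])
    mask <- NULL
    p <- mlp$drops[l]
    if (train && p > 0) {
      mask <- matrix(stats::rbinom(length(out), 1, 1 - p) / (1 - p),
                     nrow(out), ncol(out))
      out <- out * mask
    }
    cache[[l]] <- list(A = A, Z = Z, mask = mask)
    A <- out
  }
  list(out = A, cache = cache)
}

# dOut: gradient wrt the MLP output. Returns gradient wrt the input and
# per-layer (dW, db).
mlp_backward <- function(mlp, cache, dOut) {
  n_layer <- length(mlp$layers)
  grads <- vector("list", n_layer)
  dA <- dOut
  for (l in rev(seq_len(n_layer))) {
    cc <- cache[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- dA * apply_dact(cc$Z, mlp$acts[l])
    grads[[l]] <- list(W = crossprod(cc$A, dZ), b = colSums(dZ))
    dA <- dZ %*% t(mlp$layers[[l]]$W)
  }
  list(dX = dA, grads = grads)
}

mlp_zero_grads <- function(mlp) {
  lapply(mlp$layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

# --- nested parameter-tree helpers (params, grads and Adam moments all
# --- share one shape: nested lists with numeric leaves) ---

tree_map2 <- function(f, a, b) {
  if (is.atomic(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
  out
}

tree_map <- function(f, a) {
  if (is.atomic(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- tree_map(f, a[[nm]])
  out
}

tree_flatten <- function(a) {
  if (is.atomic(a)) return(list(a))
  unlist(lapply(a, tree_flatten), recursive = FALSE)
}

adam_init <- function(grad_tree) {
  list(m = tree_map(function(x) x * 0, grad_tree),
       v = tree_map(function(x) x * 0, grad_tree),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  new_w <- tree_map2(`-`, weights, upd)
  if (weight_decay > 0) {
    # decoupled shrinkage (AdamW); biases are left alone
    new_w <- tree_map(function(x) {
      if (is.matrix(x)) x * (1 - lr * weight_decay) else x
    }, new_w)
  }
  list(weights = new_w, state = state)
}
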