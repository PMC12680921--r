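#' Model configuration
#'
#' Architectural switches for the conditional equivariant graph network.
#'
#' @param L number of stacked conditional equivariant graph convolution
#'   layers (default 4).
#' @param k neighbour count for dynamic kNN graph construction (default
#'   5; each node aggregates over its k - 1 nearest other nodes, k is
#'   clamped to the cloud size).
#' @param dh node-feature width; 256 = 128 binary tissue labels + their
#'   128 z positions.
#' @param hidden hidden width of the edge/coordinate/feature MLPs
#'   (default 64; the message dimension equals this).
#' @param n_line samples along the probe line for the condition features
#'   `Ch` (default 128, so `Ch` has length 512).
#' @param dropout_readout,dropout_force dropout rates of the displacement
#'   readout (0.3) and the force regressor (0.2); active in training only.
#' @param mode `"literal"` reads the coordinate update verbatim
#'   (`phi_cs`/`phi_ce` are vector-valued 3->hidden->3 MLPs and the
#'   displacement readout sees absolute coordinates); `"strict"` swaps in
#'   scalar-gated condition terms, takes the last layer's coordinates as
#'   the prediction and feeds the force branch rotation-invariant
#'   reductions, making the model provably equivariant to z-rotations and
#'   in-plane translations.
#' @param tissue_features `FALSE` zeroes the tissue profile input (the
#'   no-tissue-features ablation).
#' @param edge_recompute `"per_layer"` rebuilds the kNN graph from each
#'   layer's updated coordinates (dynamic graphs); `"fixed"` keeps the
#'   rest-cloud graph.
#'
#' @return a `dg_config` list.
#' @export
model_config <- function(L = 4L, k = 5L, dh = 256L, hidden = 64L,
                         n_line = 128L,
                         dropout_readout = 0.3, dropout_force = 0.2,
                         mode = c("literal", "strict"),
                         tissue_features = TRUE,
                         edge_recompute = c("per_layer", "fixed")) {
  mode <- match.arg(mode)
  edge_recompute <- match.arg(edge_recompute)
  stopifnot(L >= 1, k >= 2, dh >= 2, dh %% 2 == 0, hidden >= 1,
            n_line >= 1)
  structure(
    list(L = as.integer(L), k = as.integer(k), dh = as.integer(dh),
         hidden = as.integer(hidden), n_line = as.integer(n_line),
         ch_len = 4L * as.integer(n_line),
         dropout_readout = dropout_readout, dropout_force = dropout_force,
         mode = mode, tissue_features = tissue_features,
         edge_recompute = edge_recompute),
    class = "dg_config"
  )
}

readout_in_width <- function(config) {
  3L * config$L + 6L + config$ch_len
}

force_in_width <- function(config) {
  if (config$mode == "strict") 2L + 3L * config$n_line else 3L + config$ch_len
}

#' Initialise model parameters
#'
#' Draws all MLP weights for the displacement and force branches. With
#' `init = "train"` (default) the output layers of the coordinate-update
#' MLPs, the displacement readout and the force regressor start at zero,
#' so the untrained model predicts the identity deformation and zero
#' force - a stable starting point. `init = "random"` makes every layer
#' generic (used by the property tests). First-layer weights on
#' millimetre-valued input columns are shrunk at init time to balance
#' them against binary features.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @param init `"train"` or `"random"`.
#' @return a `dg_params` nested list of per-layer weights.
#' @export
init_params <- function(config, seed = 0L, init = c("train", "random")) {
  init <- match.arg(init)
  zl <- init == "train"
  w <- config$hidden; dh <- config$dh
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  layers <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    phi_e <- make_mlp(c(2 * dh + 1, w, w), c("silu", "silu"))
    phi_e <- scale_input_cols(phi_e, 2 * dh + 1, 1 / 100) # squared mm dists
    phi_x <- make_mlp(c(w, w, 1), c("silu", "none"), zero_last = zl)
    phi_h <- make_mlp(c(dh + w, w, dh), c("silu", "none"))
    if (config$mode == "strict") {
      phi_cs <- make_mlp(c(1, w, 1), c("silu", "none"), zero_last = zl)
      phi_cs <- scale_input_cols(phi_cs, 1, 1 / 1000)
      phi_ce <- make_mlp(c(1, w, 1), c("silu", "none"), zero_last = zl)
      phi_ce <- scale_input_cols(phi_ce, 1, 1 / 1000)
    } else {
      phi_cs <- make_mlp(c(3, w, 3), c("silu", "none"), zero_last = zl)
      phi_cs <- scale_input_cols(phi_cs, 1:3, 1 / 30)
      phi_ce <- make_mlp(c(3, w, 3), c("silu", "none"), zero_last = zl)
      phi_ce <- scale_input_cols(phi_ce, 1:3, 1 / 30)
    }
    layers[[l]] <- list(phi_e = phi_e, phi_x = phi_x, phi_h = phi_h,
                        phi_cs = phi_cs, phi_ce = phi_ce)
  }

  dr <- config$dropout_readout
  readout <- make_mlp(c(readout_in_width(config), 512, 256, 128, 3),
                      c("relu", "relu", "relu", "none"),
                      drops = c(dr, dr, dr, 0), zero_last = zl)
  # coordinate-valued readout inputs: L stacked clouds + Cs + Ce + the
  # x,y,z blocks of Ch (first 3 * n_line entries of the Ch block)
  co_cols <- c(seq_len(3 * config$L + 6),
               3 * config$L + 6 + seq_len(3 * config$n_line))
  readout <- scale_input_cols(readout, co_cols, 1 / 50)

  df <- config$dropout_force
  fin <- force_in_width(config)
  phi_feat <- make_mlp(c(fin, 128, 128), c("relu", "relu"))
  phi_feat <- scale_input_cols(phi_feat, seq_len(fin), 1 / 30)
  phi_force <- make_mlp(c(256, 512, 256, 128, 1),
                        c("relu", "relu", "relu", "none"),
                        drops = c(0, df, df, 0), zero_last = zl)

  structure(list(layers = layers, readout = readout,
                 phi_feat = phi_feat, phi_force = phi_force),
            class = "dg_params")
}

# save/restore global RNG so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

params_shapes <- function(params) {
  tree_map(function(x) paste(dim(x) %||% length(x), collapse = "x"), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a model checkpoint
#'
#' A checkpoint stores the named weight arrays together with the model
#' configuration (serialised as JSON text inside the archive); loading
#' verifies that every weight has the shape the configuration implies.
#' Round-trips are bit-exact.
#'
#' @param model a fitted `deformgnn_model` (or a list with `params` and
#'   `config`).
#' @param path file path for the checkpoint archive.
#' @return `read_checkpoint()` returns a list with `params` and `config`;
#'   `write_checkpoint()` returns `path` invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(!is.null(model$params), !is.null(model$config))
  obj <- list(
    params = unclass(model$params),
    config_json = jsonlite::toJSON(unclass(model$config),
                                   auto_unbox = TRUE, digits = NA),
    package_version = as.character(utils::packageVersion("deformgnn"))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg_l <- jsonlite::fromJSON(obj$config_json)
  config <- do.call(model_config, cfg_l[c("L", "k", "dh", "hidden",
                                          "n_line", "dropout_readout",
                                          "dropout_force", "mode",
                                          "tissue_features",
                                          "edge_recompute")])
  params <- structure(obj$params, class = "dg_params")
  ref <- init_params(config, seed = 0L)
  ok <- tree_map2(function(a, b) identical(dim(a) %||% length(a),
                                           dim(b) %||% length(b)),
                  params, unclass(ref))
  if (!all(unlist(tree_flatten(tree_map(as.numeric, ok))) == 1)) {
    stop("checkpoint weight shapes are incompatible with its configuration")
  }
  list(params = params, config = config)
}
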