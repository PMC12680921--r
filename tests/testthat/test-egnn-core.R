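test_that("knn graphs pick the nearest others with deterministic ties", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  nb <- knn_edges(x, 3)
  expect_equal(nb[[1]], c(2, 3))
  expect_equal(nb[[2]], c(1, 3))
  expect_equal(nb[[3]], c(2, 1))  # ordered by distance

  set.seed(1)
  x40 <- cbind(runif(40, 0, 100), runif(40, 0, 100), 32)
  nb40 <- knn_edges(x40, 5)
  expect_true(all(lengths(nb40) == 4))
  # clamping at N = 2
  nb2 <- knn_edges(rbind(c(0, 0, 0), c(5, 5, 5)), 7)
  expect_equal(nb2, list(2L, 1L))
  # tie broken by lower index
  xt <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(9, 9, 9))
  expect_equal(knn_edges(xt, 2)[[1]], 2L)
  expect_error(knn_edges(rbind(c(0, 0, 0)), 3), "at least 2")
})

test_that("cegcl_forward matches the dense loop oracle in both modes", {
  vol <- box_volume()
  for (mode in c("literal", "strict")) {
    cfg <- tiny_config(mode = mode)
    set.seed(7)
    for (rep in 1:15) {
      par <- deformgnn:::init_params(cfg, seed = rep, init = "random")
      n <- sample(4:9, 1)
      x <- cbind(runif(n, 0, 100), runif(n, 0, 100), runif(n, 28, 32))
      h <- matrix(rnorm(n * cfg$dh), n, cfg$dh)
      Cs <- c(runif(1, 20, 80), runif(1, 20, 80), 32)
      Ce <- Cs + c(runif(1, -3, 3), runif(1, -3, 3), -runif(1, 5, 15))
      st <- cegcl_forward(list(x = x, h = h), Cs, Ce,
                          par$layers[[1]], cfg)
      orc <- oracle_cegcl(x, h, Cs, Ce, par$layers[[1]], cfg)
      expect_lt(max(abs(st$x - orc$x)), 1e-6)
      expect_lt(max(abs(st$h - orc$h)), 1e-6)
    }
  }
})

test_that("zeroed coordinate MLPs leave coordinates fixed", {
  cfg <- tiny_config()
  par <- deformgnn:::init_params(cfg, seed = 0, init = "random")
  for (nm in c("phi_x", "phi_cs", "phi_ce")) {
    nl <- length(par$layers[[1]][[nm]]$layers)
    par$layers[[1]][[nm]]$layers[[nl]]$W[] <- 0
    par$layers[[1]][[nm]]$layers[[nl]]$b[] <- 0
  }
  set.seed(3)
  x <- cbind(runif(6, 0, 100), runif(6, 0, 100), 32)
  h <- matrix(rnorm(6 * cfg$dh), 6, cfg$dh)
  st <- cegcl_forward(list(x = x, h = h), c(50, 50, 32), c(50, 50, 20),
                      par$layers[[1]], cfg)
  expect_equal(st$x, x, tolerance = 1e-12)
})

test_that("displacement branch has the documented readout width and identity limit", {
  cfg <- model_config()
  expect_equal(deformgnn:::readout_in_width(cfg), 4 * 3 + 3 + 3 + 512)
  vol <- box_volume()
  s <- tiny_sample(vol, n_points = 10, n_samples = 128, seed = 2)
  # zeroed final readout layer => u = 0, yhat = x0
  par <- deformgnn:::init_params(cfg, seed = 1, init = "random")
  par$readout$layers[[4]]$W[] <- 0
  par$readout$layers[[4]]$b[] <- 0
  out <- displacement_forward(s$x0, s$h0, s$Cs, s$Ce, s$Ch, par, cfg)
  expect_equal(out$u, matrix(0, 10, 3), tolerance = 1e-12)
  expect_equal(out$yhat, s$x0)
  # deterministic at inference (dropout off)
  par2 <- deformgnn:::init_params(cfg, seed = 1, init = "random")
  o1 <- displacement_forward(s$x0, s$h0, s$Cs, s$Ce, s$Ch, par2, cfg)
  o2 <- displacement_forward(s$x0, s$h0, s$Cs, s$Ce, s$Ch, par2, cfg)
  expect_identical(o1$yhat, o2$yhat)
})

test_that("force branch matches the loop oracle and pools symmetrically", {
  vol <- box_volume()
  cfg <- model_config()
  set.seed(5)
  for (rep in 1:10) {
    par <- deformgnn:::init_params(cfg, seed = rep, init = "random")
    s <- tiny_sample(vol, n_points = 7, n_samples = 128, seed = rep)
    yhat <- s$x0 + matrix(rnorm(21), 7, 3)
    f1 <- force_forward(yhat, s$htilde0, s$Ce, s$Ch, par, cfg)
    f2 <- oracle_force(yhat, s$htilde0, s$Ce, s$Ch, par)
    expect_lt(abs(f1 - f2), 1e-6)
    # permutation invariance
    pi <- sample(7)
    f3 <- force_forward(yhat[pi, ], s$htilde0[pi, ], s$Ce, s$Ch, par, cfg)
    expect_lt(abs(f1 - f3), 1e-6)
  }
  # N = 1: max pooling equals mean pooling
  par <- deformgnn:::init_params(cfg, seed = 0, init = "random")
  s <- tiny_sample(vol, n_points = 1, n_samples = 128, seed = 1)
  expect_silent(force_forward(s$x0, s$htilde0, s$Ce, s$Ch, par, cfg))
  # per-point input width is 3 + 512
  expect_equal(deformgnn:::force_in_width(model_config()), 515)
})

test_that("model_forward honours shape contracts across resolutions", {
  vol <- box_volume()
  cfg <- model_config(dh = 8, n_line = 4, L = 2, hidden = 8)
  par <- deformgnn:::init_params(cfg, seed = 2, init = "random")
  s40 <- tiny_sample(vol, n_points = 40, n_samples = 4, seed = 1)
  out40 <- model_forward(s40, par, cfg)
  expect_equal(dim(out40$yhat), c(40, 3))
  expect_length(out40$F, 1)
  # same weights on a much denser cloud: no fixed-N assumption
  s200 <- tiny_sample(vol, n_points = 200, n_samples = 4, seed = 2)
  out200 <- model_forward(s200, par, cfg)
  expect_equal(dim(out200$yhat), c(200, 3))
  expect_true(all(is.finite(out200$yhat)))
  expect_true(is.finite(out200$F))
})

test_that("tissue-feature ablation changes predictions for generic weights", {
  vol <- box_volume()
  cfg_on <- tiny_config()
  cfg_off <- tiny_config(tissue_features = FALSE)
  par <- deformgnn:::init_params(cfg_on, seed = 4, init = "random")
  s <- tiny_sample(vol, n_points = 9, n_samples = 4, seed = 3)
  o_on <- model_forward(s, par, cfg_on)
  o_off <- model_forward(s, par, cfg_off)
  expect_gt(max(abs(o_on$yhat - o_off$yhat)), 1e-8)
  # and zeroed h0 equals the ablation explicitly
  s0 <- s; s0$h0 <- s$h0 * 0
  o_zero <- model_forward(s0, par, cfg_on)
  expect_equal(o_zero$yhat, o_off$yhat)
})

test_that("permutation equivariance holds for every configuration", {
  vol <- box_volume()
  configs <- list(
    tiny_config(),
    tiny_config(mode = "strict"),
    tiny_config(tissue_features = FALSE),
    tiny_config(edge_recompute = "fixed"))
  set.seed(9)
  for (cfg in configs) {
    par <- deformgnn:::init_params(cfg, seed = 11, init = "random")
    s <- tiny_sample(vol, n_points = 12, n_samples = 4, seed = 8)
    out <- model_forward(s, par, cfg)
    pi <- sample(12)
    sp <- s
    sp$x0 <- s$x0[pi, ]; sp$h0 <- s$h0[pi, ]; sp$htilde0 <- s$htilde0[pi, ]
    outp <- model_forward(sp, par, cfg)
    expect_lt(max(abs(outp$yhat - out$yhat[pi, ])), 1e-6)
    expect_lt(abs(outp$F - out$F), 1e-6)
  }
})

test_that("batched evaluation equals per-sample evaluation", {
  vol <- box_volume()
  cfg <- tiny_config()
  par <- deformgnn:::init_params(cfg, seed = 6, init = "random")
  s1 <- tiny_sample(vol, n_points = 6, n_samples = 4, seed = 1)
  s2 <- tiny_sample(vol, n_points = 9, n_samples = 4, seed = 2,
                    Cs = c(40, 60, 32), Ce = c(42, 58, 20))
  rows <- dplyr::bind_rows(sample_row(s1, "a"), sample_row(s2, "b"))
  sb <- deformgnn:::stack_batch(rows)
  out <- deformgnn:::network_forward(sb$batch, par, cfg)
  o1 <- model_forward(s1, par, cfg)
  o2 <- model_forward(s2, par, cfg)
  expect_equal(out$yhat[1:6, ], o1$yhat, tolerance = 1e-12)
  expect_equal(out$yhat[7:15, ], o2$yhat, tolerance = 1e-12)
  expect_equal(out$F, c(o1$F, o2$F), tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-exactly and verify shapes", {
  cfg <- tiny_config()
  par <- deformgnn:::init_params(cfg, seed = 1, init = "random")
  model <- list(params = par, config = cfg)
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(model, tmp)
  back <- read_checkpoint(tmp)
  expect_identical(back$params$layers, par$layers)
  expect_equal(unclass(back$config), unclass(cfg))
  # corrupt a weight shape -> load refuses
  obj <- readRDS(tmp)
  obj$params$readout$layers[[1]]$W <- obj$params$readout$layers[[1]]$W[, 1:3]
  obj$params <- structure(obj$params, class = "dg_params")
  saveRDS(obj, tmp)
  expect_error(read_checkpoint(tmp), "incompatible")
})
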