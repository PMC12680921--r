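test_that("metrics reproduce the worked example and the degenerate cases", {
  x0 <- rbind(c(0, 0, 32), c(10, 0, 32))
  y <- rbind(c(0, 0, 27), c(10, 0, 31))
  yhat <- y + rbind(c(0, 0, 0.5), c(0.3, 0, 0))
  # engineered distances d = (0.5, 0.3); tip is point 1 (nearest to Cs)
  s <- list(x0 = x0, y = y, force = 1.0, Cs = c(0, 0, 32),
            Ce = c(0, 0, 22))
  m <- evaluate_metrics(yhat, 1.2, s)
  expect_equal(m$force_abs_error, 0.2)
  expect_equal(m$mean_euclid, 0.4)
  expect_equal(m$max_euclid, 0.5)
  expect_equal(m$rel_tip_error, 0.05)  # 0.5 mm over 10 mm travel = 5%
  expect_true(m$tip_defined)

  perfect <- evaluate_metrics(y, 1.0, s)
  expect_equal(perfect$force_abs_error, 0)
  expect_equal(perfect$mean_euclid, 0)
  expect_equal(perfect$max_euclid, 0)
  expect_equal(perfect$rel_tip_error, 0)

  single <- evaluate_metrics(yhat[1, , drop = FALSE], 1.1,
                             list(x0 = x0[1, , drop = FALSE],
                                  y = y[1, , drop = FALSE], force = 1,
                                  Cs = c(0, 0, 32), Ce = c(0, 0, 22)))
  expect_equal(single$mean_euclid, single$max_euclid)

  undef <- evaluate_metrics(yhat, 1.2,
                            list(x0 = x0, y = y, force = 1,
                                 Cs = c(0, 0, 32), Ce = c(0, 0, 32)))
  expect_true(is.na(undef$rel_tip_error))
  expect_false(undef$tip_defined)
})

test_that("metrics equal the loop oracle on random instances", {
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(2:30, 1)
    x0 <- cbind(runif(n, 0, 100), runif(n, 0, 100), 32)
    y <- x0 + matrix(rnorm(n * 3), n, 3)
    yhat <- y + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    Cs <- c(runif(1, 0, 100), runif(1, 0, 100), 32)
    Ce <- Cs + c(runif(1, -5, 5), runif(1, -5, 5), -runif(1, 2, 20))
    Fh <- runif(1, 0, 5); Ft <- runif(1, 0, 5)
    m <- evaluate_metrics(yhat, Fh, list(x0 = x0, y = y, force = Ft,
                                         Cs = Cs, Ce = Ce))
    o <- oracle_metrics(yhat, Fh, y, Ft, x0, Cs, Ce)
    expect_lt(abs(m$force_abs_error - o$force_abs), 1e-9)
    expect_lt(abs(m$mean_euclid - o$mean_euclid), 1e-9)
    expect_lt(abs(m$max_euclid - o$max_euclid), 1e-9)
    expect_lt(abs(m$rel_tip_error - o$rel_tip), 1e-9)
  }
})

test_that("rotation is an isometry with period four and fixed binary rows", {
  vol <- box_volume()
  s <- tiny_sample(vol, n_points = 15, n_samples = 8, seed = 3)
  s$y <- s$x0 + matrix(rnorm(45, sd = 0.5), 15, 3)
  row <- sample_row(s)

  r90 <- rotate_sample(row, 90)
  expect_equal(r90$x0[[1]][, 3], row$x0[[1]][, 3])
  # (60, 50, 30) -> (50, 60, 30) about the domain centre
  pt <- rotate_sample(sample_row(list(
    x0 = rbind(c(60, 50, 30)), h0 = s$h0[1, , drop = FALSE],
    htilde0 = s$htilde0[1, , drop = FALSE], Cs = s$Cs, Ce = s$Ce,
    Ch = s$Ch, y = rbind(c(60, 50, 30)), force = 0)), 90)
  expect_equal(as.numeric(pt$x0[[1]]), c(50, 60, 30), tolerance = 1e-9)

  # identity at 0 and 360 degrees
  for (ang in c(0, 360)) {
    r <- rotate_sample(row, ang)
    expect_equal(r$x0[[1]], row$x0[[1]], tolerance = 1e-9)
    expect_equal(r$Ch[[1]], row$Ch[[1]], tolerance = 1e-9)
  }

  # pairwise distances preserved
  d0 <- dist(row$x0[[1]])
  expect_equal(as.numeric(dist(r90$x0[[1]])), as.numeric(d0),
               tolerance = 1e-9)
  # four 90-degree rotations = identity
  r <- row
  for (i in 1:4) r <- rotate_sample(r, 90)
  expect_equal(r$x0[[1]], row$x0[[1]], tolerance = 1e-9)
  expect_equal(r$y[[1]], row$y[[1]], tolerance = 1e-9)
  expect_equal(r$htilde0[[1]], row$htilde0[[1]], tolerance = 1e-9)

  # binary rows unchanged under any angle; z rows unchanged too
  r37 <- rotate_sample(row, 37, allow_any_angle = TRUE)
  nl <- 8
  expect_identical(r37$Ch[[1]][3 * nl + 1:nl], row$Ch[[1]][3 * nl + 1:nl])
  expect_identical(r37$Ch[[1]][2 * nl + 1:nl], row$Ch[[1]][2 * nl + 1:nl])
  expect_error(rotate_sample(row, 37), "90")
})

test_that("strict models are exactly equivariant, literal deviation is reported", {
  vol <- box_volume()
  cfg_s <- tiny_config(mode = "strict")
  par_s <- deformgnn:::init_params(cfg_s, seed = 0, init = "random")
  s <- tiny_sample(vol, n_points = 20, n_samples = 4, seed = 5)
  row <- sample_row(s)
  model_s <- list(params = par_s, config = cfg_s)

  dev0 <- equivariance_check(model_s, row, 0)
  expect_equal(unname(dev0), c(0, 0))

  dev37 <- equivariance_check(model_s, row, 37, translation = c(4, -3))
  expect_lt(dev37["deviation_pos"], 1e-5)
  expect_lt(dev37["deviation_force"], 1e-6)

  cfg_l <- tiny_config()
  model_l <- list(params = deformgnn:::init_params(cfg_l, seed = 0,
                                                   init = "random"),
                  config = cfg_l)
  devl <- equivariance_check(model_l, row, 90)
  expect_true(is.finite(devl["deviation_pos"]))
  expect_true(is.finite(devl["deviation_force"]))
})

test_that("the generalisation suite emits the Table-style metric schema", {
  spec <- generator_spec(surface_mode = "scattered", surface_n = 10,
                         n_locations = 3, depth_steps = 4, n_samples = 4,
                         seed = 17)
  ds <- assemble_dataset(spec)
  cfg <- tiny_config()
  model <- list(params = deformgnn:::init_params(cfg, seed = 1),
                config = cfg)
  tbl <- run_generalization_suite(model, list(`10` = ds$samples),
                                  angles = c(0, 90, 180, 270))
  expect_equal(nrow(tbl), 4)
  expect_true(all(c("condition", "angle",
                    "force_abs_mean", "force_abs_sd",
                    "mean_euclid_mean", "mean_euclid_sd",
                    "max_euclid_mean", "max_euclid_sd",
                    "rel_tip_mean", "rel_tip_sd") %in% names(tbl)))
  expect_equal(tbl$angle, c(0, 90, 180, 270))

  # strict model: rotated metrics match unrotated ones
  cfg_s <- tiny_config(mode = "strict")
  model_s <- list(params = deformgnn:::init_params(cfg_s, seed = 2,
                                                   init = "random"),
                  config = cfg_s)
  tbl_s <- run_generalization_suite(model_s, list(`10` = ds$samples),
                                    angles = c(0, 90))
  expect_equal(tbl_s$mean_euclid_mean[2], tbl_s$mean_euclid_mean[1],
               tolerance = 1e-7)
  expect_equal(tbl_s$force_abs_mean[2], tbl_s$force_abs_mean[1],
               tolerance = 1e-7)

  # ablation variant doubles the rows
  tbl_a <- run_generalization_suite(model, list(`10` = ds$samples),
                                    angles = 0, ablation = TRUE)
  expect_equal(sort(unique(tbl_a$model)), c("full", "no_tissue"))
})
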