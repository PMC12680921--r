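#' Per-sample evaluation metrics
#'
#' Standard (unweighted) metrics used for reporting: absolute force
#' error, mean and max per-point Euclidean distance, and the relative
#' tip error - the displacement error at the tip point (the rest point
#' nearest to the probe contact `Cs`, ties broken by lower index)
#' divided by the ground-truth tip distance, taken as the probe travel
#' `||Ce - Cs||`. A zero-travel probe makes the relative tip error
#' undefined; it is returned as `NA` with `tip_defined = FALSE`.
#'
#' @param yhat N x 3 predicted cloud; `Fhat` predicted force (scalar).
#' @param sample a dataset row (list with `x0`, `y`, `force`, `Cs`,
#'   `Ce`).
#' @return one-row tibble: `force_abs_error` (N), `mean_euclid` (mm),
#'   `max_euclid` (mm), `rel_tip_error` (fraction), `tip_index`,
#'   `tip_defined`.
#' @export
evaluate_metrics <- function(yhat, Fhat, sample) {
  sample <- as_sample(sample)
  yhat <- as_points_matrix(yhat)
  y <- as_points_matrix(sample$y)
  x0 <- as_points_matrix(sample$x0)
  stopifnot(nrow(yhat) == nrow(y))
  d <- sqrt(rowSums((yhat - y)^2))
  Cs <- as.numeric(sample$Cs); Ce <- as.numeric(sample$Ce)
  tip <- which.min(rowSums(sweep(x0, 2, Cs)^2))  # ties -> lower index
  travel <- sqrt(sum((Ce - Cs)^2))
  tibble::tibble(
    force_abs_error = abs(Fhat - sample$force),
    mean_euclid = mean(d),
    max_euclid = max(d),
    rel_tip_error = if (travel > 0) d[tip] / travel else NA_real_,
    tip_index = tip,
    tip_defined = travel > 0)
}

#' Evaluate a model on a set of samples
#'
#' Runs the forward pass on every sample (dropout off) and collects
#' [evaluate_metrics()] rows.
#'
#' @param model a `deformgnn_model` (or list with `params`, `config`).
#' @param samples a samples tibble or `dg_dataset`.
#' @return tibble with one metrics row per sample plus `location_id`.
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(samples, "dg_dataset")) samples <- samples$samples
  if (nrow(samples) == 0) stop("evaluate_model: empty test set")
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    row <- samples[i, ]
    out <- model_forward(row, model$params, model$config)
    dplyr::bind_cols(tibble::tibble(location_id = row$location_id),
                     evaluate_metrics(out$yhat, out$F, row))
  })
}

rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rotate_points <- function(pts, R, center) {
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
}

#' Rotate a sample about the vertical axis through the domain centre
#'
#' Applies a z-rotation (and optional in-plane translation) jointly to
#' the rest cloud, the ground-truth cloud, the probe points and the x, y
#' rows of the probe-line features `Ch` and the per-point force features
#' `htilde0`; z rows and binary tissue rows are untouched. For test-set
#' evaluation on the square domain only multiples of 90 degrees keep the
#' cloud inside the footprint, so other angles are rejected unless
#' `allow_any_angle = TRUE` (equivariance audits).
#'
#' @param sample a dataset row (one-row tibble or list).
#' @param angle_deg rotation angle, degrees, counter-clockwise.
#' @param domain box edge lengths (centre of rotation is the domain
#'   centre).
#' @param translation optional in-plane translation c(tx, ty) applied
#'   after the rotation.
#' @param allow_any_angle permit non-right angles.
#' @return the transformed sample (same shape as the input).
#' @export
rotate_sample <- function(sample, angle_deg, domain = c(100, 100, 32),
                          translation = c(0, 0),
                          allow_any_angle = FALSE) {
  if (!allow_any_angle && abs(angle_deg %% 90) > 1e-9) {
    stop("rotate_sample: dataset evaluation uses 90-degree increments; ",
         "set allow_any_angle = TRUE for audits")
  }
  R <- rot_z(angle_deg)
  center <- c(domain[1] / 2, domain[2] / 2, 0)
  tr <- c(translation, 0)
  tf <- function(p) sweep(rotate_points(p, R, center), 2, tr, "+")
  out <- sample
  n_entries <- if (is.data.frame(sample)) 1L else NA
  get <- function(nm) if (is.data.frame(sample)) sample[[nm]][[1]] else
    sample[[nm]]
  set <- function(nm, v) {
    if (is.data.frame(sample)) out[[nm]][[1]] <<- v else out[[nm]] <<- v
  }

  for (nm in c("x0", "y")) if (!is.null(get(nm))) set(nm, tf(get(nm)))
  for (nm in c("Cs", "Ce")) {
    set(nm, as.numeric(tf(matrix(get(nm), 1, 3))))
  }
  rot_feature_xy <- function(feat, nblock) {
    # feat: vector (4*nblock) or matrix (N x 4*nblock), blocks x,y,z,bin
    vec <- is.null(dim(feat))
    if (vec) feat <- matrix(feat, 1)
    xb <- feat[, seq_len(nblock), drop = FALSE]
    yb <- feat[, nblock + seq_len(nblock), drop = FALSE]
    xc <- xb - center[1]; yc <- yb - center[2]
    a <- angle_deg * pi / 180
    feat[, seq_len(nblock)] <- cos(a) * xc - sin(a) * yc + center[1] + tr[1]
    feat[, nblock + seq_len(nblock)] <- sin(a) * xc + cos(a) * yc +
      center[2] + tr[2]
    if (vec) feat[1, ] else feat
  }
  if (!is.null(get("Ch"))) {
    set("Ch", rot_feature_xy(get("Ch"), length(get("Ch")) / 4))
  }
  if (!is.null(get("htilde0"))) {
    set("htilde0", rot_feature_xy(get("htilde0"), ncol(get("htilde0")) / 4))
  }
  out
}

#' Rotated / cross-resolution generalisation suite
#'
#' Evaluates a trained model on one or more test sets under z-rotations
#' in 90-degree increments, reporting the four standard metric columns
#' (mean +/- sd) per condition. Optionally repeats the evaluation with
#' tissue features zeroed (the ablation comparison).
#'
#' @param model a `deformgnn_model`.
#' @param testsets named list of samples tibbles (names become the
#'   condition labels, e.g. resolutions `"40"`, `"1024"`).
#' @param angles rotation angles in degrees (default 0, 90, 180, 270).
#' @param domain domain box for the rotation centre.
#' @param ablation also evaluate with `tissue_features = FALSE`.
#' @return tibble with one row per condition x angle (x model variant).
#' @export
run_generalization_suite <- function(model, testsets,
                                     angles = c(0, 90, 180, 270),
                                     domain = c(100, 100, 32),
                                     ablation = FALSE) {
  stopifnot(length(testsets) > 0)
  if (is.null(names(testsets))) {
    names(testsets) <- paste0("set", seq_along(testsets))
  }
  variants <- list(full = model)
  if (ablation) {
    abl <- model
    abl$config$tissue_features <- FALSE
    variants$no_tissue <- abl
  }
  purrr::map_dfr(names(variants), function(vn) {
    purrr::map_dfr(names(testsets), function(cond) {
      ts <- testsets[[cond]]
      if (inherits(ts, "dg_dataset")) ts <- ts$samples
      if (nrow(ts) == 0) stop("run_generalization_suite: empty test set")
      purrr::map_dfr(angles, function(ang) {
        rs <- ts
        if (ang %% 360 != 0) {
          for (i in seq_len(nrow(rs))) {
            rs[i, ] <- rotate_sample(rs[i, ], ang, domain = domain)
          }
        }
        m <- evaluate_model(variants[[vn]], rs)
        tibble::tibble(
          condition = cond, model = vn, angle = ang,
          n = nrow(m),
          force_abs_mean = mean(m$force_abs_error),
          force_abs_sd = stats::sd(m$force_abs_error),
          mean_euclid_mean = mean(m$mean_euclid),
          mean_euclid_sd = stats::sd(m$mean_euclid),
          max_euclid_mean = mean(m$max_euclid),
          max_euclid_sd = stats::sd(m$max_euclid),
          rel_tip_mean = mean(m$rel_tip_error, na.rm = TRUE),
          rel_tip_sd = stats::sd(m$rel_tip_error, na.rm = TRUE))
      })
    })
  })
}

#' Equivariance audit
#'
#' Measures how far the model is from exact equivariance under a
#' z-rotation plus in-plane translation: transforms the sample, runs the
#' model on both versions and compares the transformed prediction with
#' the prediction of the transformed input. Strict-mode models should be
#' equivariant to numerical precision; literal mode reports a finite
#' measured deviation.
#'
#' @param model a `deformgnn_model`.
#' @param sample one dataset row.
#' @param angle_deg z-rotation angle (any angle allowed here).
#' @param translation in-plane translation c(tx, ty) (mm).
#' @param domain domain box (rotation centre).
#' @return named numeric: `deviation_pos` (max per-point mm) and
#'   `deviation_force` (N).
#' @export
equivariance_check <- function(model, sample, angle_deg,
                               translation = c(0, 0),
                               domain = c(100, 100, 32)) {
  out0 <- model_forward(sample, model$params, model$config)
  rs <- rotate_sample(sample, angle_deg, domain = domain,
                      translation = translation, allow_any_angle = TRUE)
  out1 <- model_forward(rs, model$params, model$config)
  R <- rot_z(angle_deg)
  center <- c(domain[1] / 2, domain[2] / 2, 0)
  yhat0_t <- sweep(rotate_points(out0$yhat, R, center), 2,
                   c(translation, 0), "+")
  c(deviation_pos = max(sqrt(rowSums((yhat0_t - out1$yhat)^2))),
    deviation_force = abs(out1$F - out0$F))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dg_metrics <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$angle),
                               y = .data$mean_euclid_mean,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "rotation angle (deg)",
                  y = "mean Euclidean distance (mm)",
                  title = "Generalisation suite")
}

#' Metric table as a classed tibble (for autoplot)
#'
#' @param x a metrics tibble from [run_generalization_suite()].
#' @return same tibble with class `dg_metrics` prepended.
#' @export
as_dg_metrics <- function(x) {
  class(x) <- c("dg_metrics", class(x))
  x
}
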