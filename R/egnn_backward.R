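# Reverse-mode gradients for the two-branch network. The gradient tree
# mirrors extract_weights(params); finite-difference checks in the test
# suite guard every path.

extract_weights <- function(params) {
  list(layers = lapply(params$layers, function(ly) {
    lapply(ly, function(mlp) mlp$layers)
  }),
  readout = params$readout$layers,
  phi_feat = params$phi_feat$layers,
  phi_force = params$phi_force$layers)
}

set_weights <- function(params, w) {
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      params$layers[[l]][[nm]]$layers <- w$layers[[l]][[nm]]
    }
  }
  params$readout$layers <- w$readout
  params$phi_feat$layers <- w$phi_feat
  params$phi_force$layers <- w$phi_force
  params
}

zero_grad_tree <- function(params, config) {
  g <- list(layers = lapply(params$layers, function(ly) {
    lapply(ly, mlp_zero_grads)
  }),
  readout = mlp_zero_grads(params$readout),
  phi_feat = mlp_zero_grads(params$phi_feat),
  phi_force = mlp_zero_grads(params$phi_force))
  g
}

layer_backward <- function(cc, lp, gx, gh, config) {
  ei <- cc$edges$ei; ej <- cc$edges$ej; inv <- cc$edges$inv
  dh <- ncol(cc$h)

  bh <- mlp_backward(lp$phi_h, cc$fh, gh)
  dhin <- bh$dX
  gh_prev <- gh + dhin[, seq_len(dh), drop = FALSE]
  dmsum <- dhin[, dh + seq_len(ncol(dhin) - dh), drop = FALSE]
  dm <- dmsum[ei, , drop = FALSE]

  gx_prev <- gx
  if (config$mode == "strict") {
    dgcs <- rowSums(gx * cc$rcs)
    bcs <- mlp_backward(lp$phi_cs, cc$fcs, matrix(dgcs, ncol = 1))
    gx_prev <- gx_prev + gx * cc$gcs + 2 * cc$rcs * bcs$dX[, 1]
    dgce <- rowSums(gx * cc$rce)
    bce <- mlp_backward(lp$phi_ce, cc$fce, matrix(dgce, ncol = 1))
    gx_prev <- gx_prev + gx * cc$gce + 2 * cc$rce * bce$dX[, 1]
  } else {
    bcs <- mlp_backward(lp$phi_cs, cc$fcs, gx)
    gx_prev <- gx_prev + bcs$dX
    bce <- mlp_backward(lp$phi_ce, cc$fce, gx)
    gx_prev <- gx_prev + bce$dX
  }

  # aggregation term: agg_i = inv_i * sum_{e: ei=i} diff_e * s_e
  ginv <- gx * inv
  dwdiff <- ginv[ei, , drop = FALSE]
  ds <- rowSums(dwdiff * cc$diff)
  ddiff <- dwdiff * cc$s
  gx_prev <- index_add(gx_prev, ei, ddiff)
  gx_prev <- index_add(gx_prev, ej, -ddiff)
  bx <- mlp_backward(lp$phi_x, cc$fx, matrix(ds, ncol = 1))
  dm <- dm + bx$dX

  be <- mlp_backward(lp$phi_e, cc$fe, dm)
  dein <- be$dX
  gh_prev <- index_add(gh_prev, ei, dein[, seq_len(dh), drop = FALSE])
  gh_prev <- index_add(gh_prev, ej, dein[, dh + seq_len(dh), drop = FALSE])
  dd2 <- dein[, 2 * dh + 1]
  ddiff2 <- 2 * cc$diff * dd2
  gx_prev <- index_add(gx_prev, ei, ddiff2)
  gx_prev <- index_add(gx_prev, ej, -ddiff2)

  list(gx = gx_prev, gh = gh_prev,
       grads = list(phi_e = be$grads, phi_x = bx$grads, phi_h = bh$grads,
                    phi_cs = bcs$grads, phi_ce = bce$grads))
}

# dyhat: M x 3 gradient wrt the predicted cloud, dF: length-B gradient
# wrt the predicted forces. Returns the parameter-gradient tree.
network_backward <- function(out, params, config, dyhat, dF) {
  cc <- out$cache
  batch <- cc$batch
  M <- nrow(batch$x0)
  B <- nrow(batch$Cs)

  bo <- mlp_backward(params$phi_force, cc$fo, matrix(dF, ncol = 1))
  dpin <- bo$dX
  nz <- ncol(cc$z)
  dzmax <- dpin[, seq_len(nz), drop = FALSE]
  dzmean <- dpin[, nz + seq_len(nz), drop = FALSE]
  dz <- matrix(0, M, nz)
  for (b in seq_len(B)) {
    rows <- cc$sample_rows[[as.character(b)]]
    dz[rows, ] <- dz[rows, , drop = FALSE] +
      matrix(dzmean[b, ] / length(rows), length(rows), nz, byrow = TRUE)
    dz[cbind(cc$argmax[b, ], seq_len(nz))] <-
      dz[cbind(cc$argmax[b, ], seq_len(nz))] + dzmax[b, ]
  }

  bf <- mlp_backward(params$phi_feat, cc$ff, dz)
  dfin <- bf$dX
  if (config$mode == "strict") {
    ic <- cc$inv_cache
    dyhat_f <- matrix(0, M, 3)
    dyhat_f[, 1] <- dfin[, 1] * ic$dye[, 1] / ic$dxy
    dyhat_f[, 2] <- dfin[, 1] * ic$dye[, 2] / ic$dxy
    dyhat_f[, 3] <- dfin[, 2]
  } else {
    dyhat_f <- dfin[, 1:3, drop = FALSE]
  }
  dyhat_tot <- dyhat + dyhat_f

  grads <- list(layers = vector("list", config$L))
  dxs <- vector("list", config$L)
  if (config$mode == "strict") {
    for (l in seq_len(config$L)) dxs[[l]] <- matrix(0, M, 3)
    dxs[[config$L]] <- dyhat_tot
    grads$readout <- mlp_zero_grads(params$readout)
  } else {
    bro <- mlp_backward(params$readout, cc$ro, dyhat_tot)
    grads$readout <- bro$grads
    drin <- bro$dX
    for (l in seq_len(config$L)) {
      dxs[[l]] <- drin[, 3 * (l - 1) + 1:3, drop = FALSE]
    }
  }

  gx <- dxs[[config$L]]
  gh <- matrix(0, M, config$dh)
  for (l in rev(seq_len(config$L))) {
    lb <- layer_backward(cc$layers[[l]], params$layers[[l]], gx, gh, config)
    grads$layers[[l]] <- lb$grads
    gx <- lb$gx
    gh <- lb$gh
    if (l > 1) gx <- gx + dxs[[l - 1]]
  }

  grads$phi_feat <- bf$grads
  grads$phi_force <- bo$grads
  grads
}

# Weighted displacement + force loss over a stacked batch, with
# parameter gradients. Targets: y (M x 3), F (length B).
loss_and_grad <- function(batch, y, F, params, config, alpha = 1000,
                          beta = 100, eps = 1e-8, train = TRUE) {
  out <- network_forward(batch, params, config, train = train,
                         want_cache = TRUE)
  si <- batch$sample_idx
  B <- nrow(batch$Cs)
  dyhat <- matrix(0, nrow(y), 3)
  ld <- numeric(B)
  for (b in seq_len(B)) {
    rows <- which(si == b)
    dvec <- y[rows, , drop = FALSE] - batch$x0[rows, , drop = FALSE]
    nrm <- sqrt(rowSums(dvec^2))
    w <- nrm / (max(nrm) + eps)
    err <- out$yhat[rows, , drop = FALSE] - y[rows, , drop = FALSE]
    ld[b] <- mean(w * rowSums(err^2))
    dyhat[rows, ] <- (alpha / B) * (2 / length(rows)) * w * err
  }
  loss_d <- mean(ld)
  ferr <- out$F - F
  loss_f <- mean(ferr^2)
  dF <- (beta / B) * 2 * ferr
  grads <- network_backward(out, params, config, dyhat, dF)
  list(loss = alpha * loss_d + beta * loss_f, loss_d = loss_d,
       loss_f = loss_f, grads = grads, yhat = out$yhat, F = out$F)
}
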