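#' Generator specification for synthetic indentation datasets
#'
#' Bundles every knob of the analytic indentation surrogate that stands
#' in for quasi-static finite-element runs: phantom geometry, surface
#' sampling, probe schedule, the contact force model and marker noise.
#' Defaults emulate the silicone-over-bone phantom protocol: a
#' 100 x 100 x 32 mm block, indentation depths up to 30 mm, probe
#' inclinations up to 41 degrees from the inward normal, static states
#' retained at 0.1 N force increments and forces in the 0-5 N range.
#'
#' @param domain box edge lengths in mm.
#' @param n_primitives integer range, rigid primitives per phantom.
#' @param surface_mode `"grid"` (n x n regular lattice, the FEM-style
#'   cloud) or `"scattered"` (n quasi-uniform marker-like points).
#' @param surface_n grid edge count or scattered point count.
#' @param n_locations probe locations per dataset.
#' @param depth_steps loading steps per location before retention.
#' @param max_depth maximum indentation depth (mm).
#' @param max_inclination maximum probe inclination from the inward
#'   surface normal (degrees).
#' @param depth_fraction range of the per-location fraction of the
#'   feasible depth actually reached (loading never drives the probe
#'   into the rigid structure).
#' @param k_s linear surface stiffness (N/mm); `k_c`, `p`, `t_min` the
#'   contact-stiffening constants of the force law
#'   `F = k_s * delta + k_c * (delta / max(t_p - delta, t_min))^p`
#'   where `t_p` is the soft-layer thickness under the contact point.
#' @param sigma_c Gaussian contact-kernel radius (mm).
#' @param bulge lateral bulge amplitude (dimensionless).
#' @param margin soft-tissue margin kept above bone (mm); `clamp` the
#'   fraction of the available soft column a point may traverse.
#' @param delta_f retention threshold (N): a static state is stored only
#'   when force has grown by at least this much since the last stored
#'   state.
#' @param noise_sigma isotropic marker noise s.d. (mm); 0.2 mm mimics
#'   motion-capture tracking accuracy, 0 disables noise.
#' @param n_samples depth/line samples for tissue features (128).
#' @param seed mandatory integer seed; the whole dataset is a pure
#'   function of (spec, seed).
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(domain = c(100, 100, 32),
                           n_primitives = c(1L, 4L),
                           surface_mode = c("grid", "scattered"),
                           surface_n = 32L,
                           n_locations = 10L,
                           depth_steps = 24L,
                           max_depth = 30,
                           max_inclination = 41,
                           depth_fraction = c(0.4, 1),
                           k_s = 0.08, k_c = 0.5, p = 2, t_min = 1,
                           sigma_c = 8, bulge = 0.1, margin = 0.5,
                           clamp = 0.9,
                           delta_f = 0.1,
                           noise_sigma = 0,
                           n_samples = 128L,
                           seed = NULL) {
  surface_mode <- match.arg(surface_mode)
  if (is.null(seed)) stop("generator_spec: `seed` is mandatory")
  stopifnot(k_s > 0, k_c > 0, p > 0, t_min > 0, sigma_c > 0, margin > 0,
            clamp > 0, clamp <= 1, delta_f >= 0, noise_sigma >= 0,
            max_depth > 0, max_inclination > 0, n_locations >= 0,
            depth_steps >= 1, surface_n >= 2)
  structure(
    list(domain = domain, n_primitives = as.integer(n_primitives),
         surface_mode = surface_mode, surface_n = as.integer(surface_n),
         n_locations = as.integer(n_locations),
         depth_steps = as.integer(depth_steps), max_depth = max_depth,
         max_inclination = max_inclination,
         depth_fraction = depth_fraction,
         k_s = k_s, k_c = k_c, p = p, t_min = t_min, sigma_c = sigma_c,
         bulge = bulge, margin = margin, clamp = clamp,
         delta_f = delta_f, noise_sigma = noise_sigma,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Generate a random phantom volume
#'
#' Draws 1-4 rigid primitives (boxes, spheres, vertical cylinders) fully
#' inside the domain with their top surfaces at least 4 mm below the
#' soft top surface, so a compliant layer always covers the rigid
#' structure. Deterministic given the seed.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a primitive-backed [tissue_volume()].
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  d <- spec$domain
  zcap <- d[3] - 4  # rigid tops stay >= 4 mm below the surface
  n_prim <- if (spec$n_primitives[1] == spec$n_primitives[2]) {
    spec$n_primitives[1]
  } else {
    sample(spec$n_primitives[1]:spec$n_primitives[2], 1)
  }
  prims <- vector("list", n_prim)
  for (i in seq_len(n_prim)) {
    ok <- FALSE
    for (try in 1:100) {
      type <- sample(c("box", "sphere", "cylinder"), 1)
      p <- switch(type,
        box = {
          sx <- stats::runif(1, 15, 50); sy <- stats::runif(1, 15, 50)
          h <- stats::runif(1, 6, zcap)
          x0 <- stats::runif(1, 0, d[1] - sx)
          y0 <- stats::runif(1, 0, d[2] - sy)
          list(type = "box", min = c(x0, y0, 0), max = c(x0 + sx, y0 + sy, h))
        },
        sphere = {
          r <- stats::runif(1, 6, min(14, zcap / 2))
          list(type = "sphere",
               center = c(stats::runif(1, r, d[1] - r),
                          stats::runif(1, r, d[2] - r),
                          stats::runif(1, r, zcap - r)),
               radius = r)
        },
        cylinder = {
          r <- stats::runif(1, 6, 20)
          h <- stats::runif(1, 6, zcap)
          list(type = "cylinder",
               center_xy = c(stats::runif(1, r, d[1] - r),
                             stats::runif(1, r, d[2] - r)),
               radius = r, zmin = 0, zmax = h)
        })
      bb <- primitive_bbox(p)
      if (all(bb$min >= 0) && all(bb$max <= d) && bb$max[3] <= zcap) {
        prims[[i]] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("generate_phantom: could not fit primitive ", i,
                  " after bounded retries")
  }
  tissue_volume(domain = d, primitives = prims)
}

#' Sample a rest surface point cloud
#'
#' Grid mode places an n x n regular lattice on the top face,
#' cell-centred (each point inset half a cell from the boundary).
#' Scattered mode draws n quasi-uniform points by seeded dart throwing
#' with a minimum-separation radius, emulating glued marker positions.
#'
#' @param mode `"grid"` or `"scattered"`.
#' @param n lattice edge count (grid) or point count (scattered), >= 2.
#' @param seed integer seed.
#' @param domain box edge lengths (mm).
#' @return N x 3 matrix of points on the top face (N = n^2 for grid).
#' @export
sample_surface_points <- function(mode = c("grid", "scattered"), n,
                                  seed = 0L, domain = c(100, 100, 32)) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  H <- domain[3]
  if (mode == "grid") {
    gx <- (seq_len(n) - 0.5) * domain[1] / n
    gy <- (seq_len(n) - 0.5) * domain[2] / n
    g <- expand.grid(x = gx, y = gy)
    return(cbind(g$x, g$y, rep(H, nrow(g))))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  r <- 0.75 * sqrt(domain[1] * domain[2] / n)
  repeat {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < n && tries < 4000 * n) {
      cand <- c(stats::runif(1, 0, domain[1]), stats::runif(1, 0, domain[2]))
      tries <- tries + 1
      if (nrow(pts) == 0 ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r^2) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) == n) break
    r <- r * 0.8
  }
  out <- cbind(pts, rep(H, n))
  dimnames(out) <- NULL
  out
}

#' Construct a probe state
#'
#' @param Cs surface contact point (3-vector, on the top face).
#' @param direction unit 3-vector pointing into the tissue (within the
#'   maximum inclination of the inward normal -z).
#' @param depth indentation depth along `direction` (mm, >= 0).
#' @param max_inclination,max_depth limits enforced on construction.
#' @return a `probe_state` with `Ce = Cs + depth * direction`.
#' @export
probe_state <- function(Cs, direction, depth, max_inclination = 41,
                        max_depth = 30) {
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  ang <- acos(pmin(pmax(-direction[3], -1), 1)) * 180 / pi
  if (ang > max_inclination + 1e-9) {
    stop("probe_state: inclination ", round(ang, 2),
         " deg exceeds the ", max_inclination, " deg limit")
  }
  if (depth < 0 || depth > max_depth + 1e-9) {
    stop("probe_state: depth outside [0, ", max_depth, "] mm")
  }
  Cs <- as.numeric(Cs)
  structure(list(Cs = Cs, direction = direction, depth = depth,
                 Ce = Cs + depth * direction),
            class = "probe_state")
}

# vectorised highest-rigid-z per (x, y) column; exact for
# primitive-backed volumes, scanned for voxel grids
bone_top_cols <- function(volume, xy, n_scan = 256) {
  xy <- matrix(xy, ncol = 2)
  if (is.null(volume$voxels)) {
    top <- rep(-Inf, nrow(xy))
    for (p in volume$primitives) {
      pt <- switch(p$type,
        box = ifelse(xy[, 1] >= p$min[1] & xy[, 1] <= p$max[1] &
                     xy[, 2] >= p$min[2] & xy[, 2] <= p$max[2],
                     p$max[3], -Inf),
        sphere = {
          d2 <- (xy[, 1] - p$center[1])^2 + (xy[, 2] - p$center[2])^2
          ifelse(d2 <= p$radius^2,
                 p$center[3] + sqrt(pmax(p$radius^2 - d2, 0)), -Inf)
        },
        cylinder = ifelse((xy[, 1] - p$center_xy[1])^2 +
                          (xy[, 2] - p$center_xy[2])^2 <= p$radius^2,
                          p$zmax, -Inf))
      top <- pmax(top, pt)
    }
    return(top)
  }
  H <- volume$domain[3]
  z <- (seq_len(n_scan) - 0.5) * H / n_scan
  pts <- cbind(rep(xy[, 1], each = n_scan), rep(xy[, 2], each = n_scan),
               rep(z, nrow(xy)))
  occ <- matrix(occupancy_query(volume, pts), nrow = n_scan)
  apply(occ, 2, function(col) {
    r <- which(col == 1L)
    if (length(r) == 0) -Inf else z[max(r)]
  })
}

#' Analytic indentation surrogate
#'
#' Closed-form stand-in for a quasi-static contact simulation. Each rest
#' point at perpendicular distance r from the probe axis is displaced by
#' a Gaussian bump `u = depth * exp(-r^2 / (2 sigma_c^2))` along the
#' probe direction, clamped to `clamp * allowed` where `allowed` is the
#' soft column between the point and the rigid structure (minus
#' `margin`), plus an outward radial bulge
#' `bulge * depth * (r/sigma_c) * exp(-r^2/(2 sigma_c^2))`. The contact
#' force follows the thin-layer stiffening law documented in
#' [generator_spec()], so indenting over a shallow bone is stiffer than
#' over a thick soft column.
#'
#' @param volume a [tissue_volume()].
#' @param x0 N x 3 rest cloud on the top surface.
#' @param probe a [probe_state()].
#' @param spec a [generator_spec()] (force-model constants).
#' @param bone_tops optional precomputed per-point rigid-top heights.
#' @return list with `y` (N x 3 deformed cloud) and `F` (scalar N).
#' @export
simulate_indentation <- function(volume, x0, probe, spec,
                                 bone_tops = NULL) {
  x0 <- as_points_matrix(x0)
  H <- volume$domain[3]
  if (abs(probe$Cs[3] - H) > 1e-6 ||
      probe$Cs[1] < 0 || probe$Cs[1] > volume$domain[1] ||
      probe$Cs[2] < 0 || probe$Cs[2] > volume$domain[2]) {
    stop("simulate_indentation: probe axis misses the top surface")
  }
  if (probe$depth > spec$max_depth + 1e-9) {
    stop("simulate_indentation: depth exceeds max_depth")
  }
  delta <- probe$depth
  dir <- probe$direction
  rel <- sweep(x0, 2, probe$Cs)
  proj <- as.numeric(rel %*% dir)
  perp <- rel - outer(proj, dir)
  r <- sqrt(rowSums(perp^2))
  eradial <- perp / ifelse(r > 1e-12, r, 1)
  eradial[r <= 1e-12, ] <- 0

  if (is.null(bone_tops)) bone_tops <- bone_top_cols(volume, x0[, 1:2])
  allowed <- pmax(0, x0[, 3] - pmax(bone_tops, 0) - spec$margin)
  allowed[is.infinite(bone_tops)] <-
    pmax(0, x0[is.infinite(bone_tops), 3] - spec$margin)

  kern <- exp(-r^2 / (2 * spec$sigma_c^2))
  u <- pmin(delta * kern, spec$clamp * allowed)
  bul <- spec$bulge * delta * (r / spec$sigma_c) * kern
  y <- x0 + outer(u, dir) + bul * eradial

  t_p <- H - max(bone_top_cols(volume, matrix(probe$Cs[1:2], 1, 2)), 0)
  F <- spec$k_s * delta +
    spec$k_c * (delta / max(t_p - delta, spec$t_min))^spec$p
  list(y = y, F = F)
}

#' Retention filter for quasi-static states
#'
#' Keeps the first state and thereafter only states whose force exceeds
#' the last kept state's force by at least `delta_f` - the rule used to
#' discard redundant intermediate loading steps.
#'
#' @param forces non-decreasing force sequence (N); decreasing input
#'   (beyond 1e-9 tolerance) is an error.
#' @param delta_f retention threshold (N, default 0.1).
#' @return integer vector of kept indices (1-based).
#' @export
retention_filter <- function(forces, delta_f = 0.1) {
  if (length(forces) == 0) return(integer(0))
  if (any(diff(forces) < -1e-9)) {
    stop("retention_filter: force sequence is not non-decreasing")
  }
  kept <- 1L
  last <- forces[1]
  for (i in seq_along(forces)[-1]) {
    if (forces[i] - last >= delta_f) {
      kept <- c(kept, i)
      last <- forces[i]
    }
  }
  kept
}

#' Add isotropic marker noise
#'
#' Zero-mean Gaussian noise on every coordinate, emulating motion
#' capture tracking error; deterministic per seed.
#'
#' @param cloud N x 3 matrix.
#' @param sigma noise s.d. in mm (>= 0).
#' @param seed integer seed.
#' @return noisy N x 3 matrix.
#' @export
add_marker_noise <- function(cloud, sigma, seed = 0L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(cloud)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cloud + matrix(stats::rnorm(length(cloud), sd = sigma), nrow(cloud), 3)
}

# feasible indentation depth at a probe: never through the rigid
# structure, vertically or along the probe line, and never past the
# domain side walls
probe_depth_cap <- function(volume, Cs, dir, spec) {
  H <- volume$domain[3]
  t_p <- H - max(bone_top_cols(volume, matrix(Cs[1:2], 1, 2)), 0)
  # first rigid hit along the probe line (or domain exit)
  tmax <- spec$max_depth
  for (a in 1:3) {
    if (dir[a] > 1e-12) tmax <- min(tmax, (volume$domain[a] - Cs[a]) / dir[a])
    if (dir[a] < -1e-12) tmax <- min(tmax, (0 - Cs[a]) / dir[a])
  }
  ts <- seq(0, tmax, length.out = 200)
  pts <- cbind(Cs[1] + ts * dir[1], Cs[2] + ts * dir[2], Cs[3] + ts * dir[3])
  occ <- occupancy_query(volume, pts)
  d_bone <- if (any(occ == 1L)) ts[which(occ == 1L)[1]] else tmax
  min(spec$max_depth, 0.8 * (t_p - spec$margin),
      0.9 * (d_bone - spec$margin))
}

#' Assemble a synthetic indentation dataset
#'
#' Runs the full stand-in pipeline: draw a phantom, sample the rest
#' surface cloud and its tissue features, then for each probe location
#' simulate a quasi-static loading sequence, apply the retention filter
#' and (optionally) marker noise. Every retained state becomes one
#' sample carrying `x0`, `h0`, `htilde0`, the probe condition
#' (`Cs`, `Ce`, `Ch`), the deformed cloud `y`, the force and its
#' `location_id`. The manifest records the spec, seed, counts and
#' dataset summary statistics (max force per location, mean
#' nearest-neighbour point distance, mean probe travel).
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a `dg_dataset`: list with `samples` (tibble), `volume`,
#'   `x0`, `h0`, `htilde0`, `spec`, `seed`, `manifest`.
#' @export
assemble_dataset <- function(spec, seed = spec$seed) {
  if (spec$n_locations < 1) stop("assemble_dataset: no probe locations")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  volume <- generate_phantom(spec, seed = sample.int(2^30, 1))
  x0 <- sample_surface_points(spec$surface_mode, spec$surface_n,
                              seed = sample.int(2^30, 1),
                              domain = spec$domain)
  h0 <- node_features_matrix(volume, x0, spec$n_samples)
  htilde0 <- force_features_matrix(h0, x0)
  bone_tops <- bone_top_cols(volume, x0[, 1:2])
  H <- spec$domain[3]
  max_ang <- spec$max_inclination * pi / 180

  rows <- list()
  loc <- 0L
  attempts <- 0L
  skipped <- 0L
  while (loc < spec$n_locations && attempts < 20 * spec$n_locations) {
    attempts <- attempts + 1L
    Cs <- c(stats::runif(1, 12, spec$domain[1] - 12),
            stats::runif(1, 12, spec$domain[2] - 12), H)
    cosb <- stats::runif(1, cos(max_ang), 1)
    phi <- stats::runif(1, 0, 2 * pi)
    sinb <- sqrt(1 - cosb^2)
    dir <- c(sinb * cos(phi), sinb * sin(phi), -cosb)
    cap <- probe_depth_cap(volume, Cs, dir, spec)
    f <- stats::runif(1, spec$depth_fraction[1], spec$depth_fraction[2])
    d_loc <- f * cap
    if (!is.finite(d_loc) || d_loc < 0.5) { skipped <- skipped + 1L; next }
    loc <- loc + 1L
    loc_id <- sprintf("loc%03d", loc)
    depths <- seq(d_loc / spec$depth_steps, d_loc,
                  length.out = spec$depth_steps)
    forces <- numeric(spec$depth_steps)
    sims <- vector("list", spec$depth_steps)
    for (s in seq_along(depths)) {
      pr <- probe_state(Cs, dir, depths[s],
                        max_inclination = spec$max_inclination,
                        max_depth = spec$max_depth)
      sims[[s]] <- simulate_indentation(volume, x0, pr, spec,
                                        bone_tops = bone_tops)
      forces[s] <- sims[[s]]$F
    }
    kept <- retention_filter(forces, spec$delta_f)
    for (s in kept) {
      pr <- probe_state(Cs, dir, depths[s],
                        max_inclination = spec$max_inclination,
                        max_depth = spec$max_depth)
      Ch <- extract_line_profile(volume, pr$Cs, pr$Ce, spec$n_samples)$Ch
      y <- sims[[s]]$y
      if (spec$noise_sigma > 0) {
        y <- add_marker_noise(y, spec$noise_sigma,
                              seed = sample.int(2^30, 1))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        location_id = loc_id, state = match(s, kept), depth = depths[s],
        force = forces[s],
        x0 = list(x0), h0 = list(h0), htilde0 = list(htilde0),
        Cs = list(pr$Cs), Ce = list(pr$Ce), Ch = list(Ch), y = list(y))
    }
  }
  if (loc < spec$n_locations) {
    stop("assemble_dataset: could not place ", spec$n_locations,
         " probe locations (", skipped, " skipped)")
  }
  samples <- dplyr::bind_rows(rows)

  nnd <- apply(as.matrix(stats::dist(x0)), 1, function(r) min(r[r > 0]))
  fmax <- samples |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(fmax = max(.data$force), .groups = "drop")
  travel <- vapply(seq_len(nrow(samples)), function(i) {
    sqrt(sum((samples$Ce[[i]] - samples$Cs[[i]])^2))
  }, numeric(1))
  manifest <- list(
    spec = unclass(spec), seed = as.integer(seed),
    n_locations = spec$n_locations, n_samples = nrow(samples),
    points_per_cloud = nrow(x0),
    fmax_mean = mean(fmax$fmax), fmax_sd = stats::sd(fmax$fmax),
    dmean = mean(nnd),
    tip_mean = mean(travel), tip_sd = stats::sd(travel))

  structure(list(samples = samples, volume = volume, x0 = x0, h0 = h0,
                 htilde0 = htilde0, spec = spec,
                 seed = as.integer(seed), manifest = manifest),
            class = "dg_dataset")
}

#' @export
print.dg_dataset <- function(x, ...) {
  m <- x$manifest
  cat("<dg_dataset>", m$n_samples, "static states at", m$n_locations,
      "probe locations,", m$points_per_cloud, "surface points\n")
  cat(sprintf("  Fmax %.3f +/- %.3f N | dmean %.3f mm | tip %.3f +/- %.3f mm\n",
              m$fmax_mean, m$fmax_sd %||% NA_real_, m$dmean, m$tip_mean,
              m$tip_sd %||% NA_real_))
  invisible(x)
}

#' Write / read a dataset as CSV + JSON on disk
#'
#' Plain-text container: `manifest.json` (spec, seed, statistics),
#' `volume.json` (phantom primitives), `points.csv` (rest cloud) and
#' `samples.csv` / `deformed.csv` (per-state conditions, forces and
#' deformed clouds in long format). Tissue features are recomputed from
#' the volume on read, so the files stay small and the round trip is
#' exact up to full double precision.
#'
#' @param dataset a `dg_dataset`.
#' @param dir directory to create/fill.
#' @return `read_dataset()` returns the `dg_dataset`; `write_dataset()`
#'   the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_volume_json(dataset$volume, file.path(dir, "volume.json"))
  x0 <- dataset$x0
  utils::write.csv(
    data.frame(point = seq_len(nrow(x0)), x = x0[, 1], y = x0[, 2],
               z = x0[, 3]),
    file.path(dir, "points.csv"), row.names = FALSE)
  s <- dataset$samples
  cond <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    c(s$Cs[[i]], s$Ce[[i]])
  }))
  utils::write.csv(
    data.frame(location_id = s$location_id, state = s$state,
               depth = s$depth, force = s$force,
               cs_x = cond[, 1], cs_y = cond[, 2], cs_z = cond[, 3],
               ce_x = cond[, 4], ce_y = cond[, 5], ce_z = cond[, 6]),
    file.path(dir, "samples.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    y <- s$y[[i]]
    data.frame(location_id = s$location_id[i], state = s$state[i],
               point = seq_len(nrow(y)), x = y[, 1], y = y[, 2],
               z = y[, 3])
  }))
  utils::write.csv(long, file.path(dir, "deformed.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- manifest$spec
  spec <- generator_spec(
    domain = sp$domain, n_primitives = sp$n_primitives,
    surface_mode = sp$surface_mode, surface_n = sp$surface_n,
    n_locations = sp$n_locations, depth_steps = sp$depth_steps,
    max_depth = sp$max_depth, max_inclination = sp$max_inclination,
    depth_fraction = sp$depth_fraction, k_s = sp$k_s, k_c = sp$k_c,
    p = sp$p, t_min = sp$t_min, sigma_c = sp$sigma_c, bulge = sp$bulge,
    margin = sp$margin, clamp = sp$clamp, delta_f = sp$delta_f,
    noise_sigma = sp$noise_sigma, n_samples = sp$n_samples,
    seed = sp$seed)
  volume <- read_volume_json(file.path(dir, "volume.json"))
  pts <- utils::read.csv(file.path(dir, "points.csv"))
  x0 <- as.matrix(pts[order(pts$point), c("x", "y", "z")])
  dimnames(x0) <- NULL
  h0 <- node_features_matrix(volume, x0, spec$n_samples)
  htilde0 <- force_features_matrix(h0, x0)
  st <- utils::read.csv(file.path(dir, "samples.csv"))
  long <- utils::read.csv(file.path(dir, "deformed.csv"))
  rows <- lapply(seq_len(nrow(st)), function(i) {
    Cs <- c(st$cs_x[i], st$cs_y[i], st$cs_z[i])
    Ce <- c(st$ce_x[i], st$ce_y[i], st$ce_z[i])
    yl <- long[long$location_id == st$location_id[i] &
                 long$state == st$state[i], ]
    y <- as.matrix(yl[order(yl$point), c("x", "y", "z")])
    dimnames(y) <- NULL
    Ch <- extract_line_profile(volume, Cs, Ce, spec$n_samples)$Ch
    tibble::tibble(
      location_id = st$location_id[i], state = st$state[i],
      depth = st$depth[i], force = st$force[i],
      x0 = list(x0), h0 = list(h0), htilde0 = list(htilde0),
      Cs = list(Cs), Ce = list(Ce), Ch = list(Ch),
      y = list(y))
  })
  structure(list(samples = dplyr::bind_rows(rows), volume = volume,
                 x0 = x0, h0 = h0, htilde0 = htilde0, spec = spec,
                 seed = manifest$seed, manifest = manifest),
            class = "dg_dataset")
}
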