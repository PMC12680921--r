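#' Heterogeneous tissue volume
#'
#' Represents a block of soft tissue (label 0) with embedded rigid,
#' bone-like structures (label 1) inside an axis-aligned box domain.
#' Coordinates are millimetres, z-up, origin at the bottom corner of the
#' box. The volume can be backed either by a list of rigid primitives
#' (boxes, spheres, vertical cylinders) or by a binary voxel grid.
#'
#' @param domain numeric length-3, box edge lengths in mm
#'   (default `c(100, 100, 32)`, the phantom footprint and height).
#' @param primitives list of primitive descriptions. Each is a list with a
#'   `type` field: `"box"` (`min`, `max` corners), `"sphere"` (`center`,
#'   `radius`) or `"cylinder"` (`center_xy`, `radius`, `zmin`, `zmax`).
#' @param voxels optional 3D binary array backing the volume; when given,
#'   `spacing` (mm per voxel, length 3 or scalar) is required and
#'   `primitives` must be empty. Occupancy queries use nearest-voxel
#'   lookup (no interpolation — occupancy is binary).
#' @param spacing voxel spacing in mm, used only with `voxels`.
#'
#' @return an object of class `tissue_volume`.
#' @export
tissue_volume <- function(domain = c(100, 100, 32), primitives = list(),
                          voxels = NULL, spacing = NULL) {
  stopifnot(is.numeric(domain), length(domain) == 3, all(domain > 0))
  domain <- as.numeric(domain)
  if (!is.null(voxels)) {
    if (length(primitives) > 0) {
      stop("a tissue_volume is either primitive-backed or voxel-backed, not both")
    }
    stopifnot(length(dim(voxels)) == 3)
    if (is.null(spacing)) stop("voxel-backed volumes need `spacing`")
    spacing <- rep(as.numeric(spacing), length.out = 3)
    if (any(abs(dim(voxels) * spacing - domain) > 1e-6)) {
      stop("voxel grid extent (dim * spacing) must match `domain`")
    }
    if (!all(voxels %in% c(0, 1))) stop("voxel values must be binary (0/1)")
  } else {
    for (p in primitives) check_primitive(p, domain)
  }
  structure(
    list(domain = domain, primitives = primitives,
         voxels = voxels, spacing = spacing),
    class = "tissue_volume"
  )
}

check_primitive <- function(p, domain) {
  if (is.null(p$type)) stop("primitive missing `type`")
  bb <- primitive_bbox(p)
  if (any(bb$min < -1e-9) || any(bb$max > domain + 1e-9)) {
    stop("primitive `", p$type, "` is not contained in the domain box")
  }
  invisible(TRUE)
}

primitive_bbox <- function(p) {
  switch(p$type,
    box = list(min = as.numeric(p$min), max = as.numeric(p$max)),
    sphere = list(min = as.numeric(p$center) - p$radius,
                  max = as.numeric(p$center) + p$radius),
    cylinder = list(
      min = c(as.numeric(p$center_xy) - p$radius, p$zmin),
      max = c(as.numeric(p$center_xy) + p$radius, p$zmax)),
    stop("unknown primitive type: ", p$type)
  )
}

#' @export
print.tissue_volume <- function(x, ...) {
  backing <- if (!is.null(x$voxels)) {
    sprintf("voxel grid %s @ %.3g mm", paste(dim(x$voxels), collapse = "x"),
            x$spacing[1])
  } else {
    sprintf("%d rigid primitive(s)", length(x$primitives))
  }
  cat(sprintf("<tissue_volume> domain %s mm, %s\n",
              paste(x$domain, collapse = " x "), backing))
  invisible(x)
}

in_domain <- function(volume, pts, tol = 1e-9) {
  d <- volume$domain
  pts[, 1] >= -tol & pts[, 1] <= d[1] + tol &
    pts[, 2] >= -tol & pts[, 2] <= d[2] + tol &
    pts[, 3] >= -tol & pts[, 3] <= d[3] + tol
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Binary occupancy query
#'
#' Returns the tissue label at one or more points: 1 when the point lies
#' inside a rigid primitive (or in a rigid voxel, nearest-voxel lookup),
#' 0 for soft tissue. Points outside the domain box are an error.
#'
#' @param volume a [tissue_volume()].
#' @param points a 3-vector or an N x 3 matrix of query points (mm).
#' @return integer vector of 0/1 labels, one per query point.
#' @export
occupancy_query <- function(volume, points) {
  pts <- as_points_matrix(points)
  if (!all(in_domain(volume, pts))) {
    stop("occupancy_query: point outside the domain box")
  }
  if (!is.null(volume$voxels)) {
    dims <- dim(volume$voxels)
    idx <- vapply(1:3, function(a) {
      pmin(pmax(floor(pts[, a] / volume$spacing[a]) + 1L, 1L), dims[a])
    }, numeric(nrow(pts)))
    idx <- matrix(as.integer(idx), ncol = 3)
    return(as.integer(volume$voxels[idx]))
  }
  occ <- rep(0L, nrow(pts))
  for (p in volume$primitives) {
    inside <- switch(p$type,
      box = pts[, 1] >= p$min[1] & pts[, 1] <= p$max[1] &
            pts[, 2] >= p$min[2] & pts[, 2] <= p$max[2] &
            pts[, 3] >= p$min[3] & pts[, 3] <= p$max[3],
      sphere = colSums((t(pts) - as.numeric(p$center))^2) <= p$radius^2,
      cylinder = (pts[, 1] - p$center_xy[1])^2 +
                 (pts[, 2] - p$center_xy[2])^2 <= p$radius^2 &
                 pts[, 3] >= p$zmin & pts[, 3] <= p$zmax
    )
    occ[inside] <- 1L
  }
  occ
}

#' Depth profile of tissue labels beneath a surface point
#'
#' Samples the occupancy along the vertical (z) axis beneath a surface
#' point at `n_samples` regularly spaced, cell-centred depths
#' z_j = (j + 1/2) * H / n_samples, j = 0..n_samples-1, ordered bottom-up
#' (H = domain height). The resulting binary vector encodes the vertical
#' material distribution under the point and is the model's per-point
#' tissue feature source.
#'
#' @param volume a [tissue_volume()].
#' @param surface_point 3-vector (mm); only its (x, y) is used as the
#'   column anchor and must lie inside the domain footprint.
#' @param n_samples number of depth samples (default 128).
#' @return a `tissue_profile`: list with `values` (0/1 vector),
#'   `z_positions` (mm, strictly increasing) and `anchor` (x, y).
#' @export
extract_profile <- function(volume, surface_point, n_samples = 128) {
  stopifnot(n_samples >= 1)
  sp <- as.numeric(surface_point)
  d <- volume$domain
  if (sp[1] < 0 || sp[1] > d[1] || sp[2] < 0 || sp[2] > d[2]) {
    stop("extract_profile: anchor outside the domain footprint")
  }
  z <- (seq_len(n_samples) - 0.5) * d[3] / n_samples
  pts <- cbind(sp[1], sp[2], z)
  structure(
    list(values = occupancy_query(volume, pts), z_positions = z,
         anchor = sp[1:2]),
    class = "tissue_profile"
  )
}

#' Per-point node features from a depth profile
#'
#' Flattens a tissue profile into the node feature vector
#' `h0 = c(values, z_positions)` of length `2 * n_samples`
#' (256 at the default 128 depth samples). The first half is binary
#' labels, the second half the matching z positions; this layout is fixed
#' package-wide.
#'
#' @param profile a `tissue_profile` from [extract_profile()].
#' @return numeric vector of length `2 * n_samples`.
#' @export
build_node_features <- function(profile) {
  stopifnot(inherits(profile, "tissue_profile"))
  c(as.numeric(profile$values), profile$z_positions)
}

#' Condition features along the probe line
#'
#' Samples `n_samples` points evenly spaced on the segment from the probe
#' surface contact `Cs` to the probe end `Ce` (both endpoints included)
#' and flattens rows (x, y, z, occupancy) into the condition feature
#' vector `Ch` of length `4 * n_samples` (512 at the default). Block
#' order x, y, z, binary matches [build_force_features()] so differences
#' h0_tilde - Ch are elementwise meaningful.
#'
#' @param volume a [tissue_volume()].
#' @param Cs,Ce 3-vectors (mm); `Cs != Ce`, segment inside the domain.
#' @param n_samples samples along the line (default 128).
#' @return a `condition_features`: list with `Cs`, `Ce`, `Ch`.
#' @export
extract_line_profile <- function(volume, Cs, Ce, n_samples = 128) {
  Cs <- as.numeric(Cs); Ce <- as.numeric(Ce)
  stopifnot(n_samples >= 1)
  if (sqrt(sum((Ce - Cs)^2)) <= 0) {
    stop("extract_line_profile: degenerate probe (Cs == Ce)")
  }
  t <- if (n_samples == 1) 0.5 else seq(0, 1, length.out = n_samples)
  pts <- cbind(Cs[1] + t * (Ce[1] - Cs[1]),
               Cs[2] + t * (Ce[2] - Cs[2]),
               Cs[3] + t * (Ce[3] - Cs[3]))
  if (!all(in_domain(volume, pts))) {
    stop("extract_line_profile: segment exits the domain box")
  }
  occ <- occupancy_query(volume, pts)
  structure(
    list(Cs = Cs, Ce = Ce,
         Ch = c(pts[, 1], pts[, 2], pts[, 3], as.numeric(occ))),
    class = "condition_features"
  )
}

#' Per-point force-branch features
#'
#' Builds the flattened 4 x n_samples feature vector
#' `h0_tilde = c(x * 1, y * 1, z_positions, values)` for a surface point,
#' i.e. the node features `h0` augmented with the point's constant x and
#' y coordinates so its length and block order match the probe-line
#' features `Ch`.
#'
#' @param h0 node feature vector from [build_node_features()].
#' @param point_xy length-2 (x, y) of the surface point (mm).
#' @return numeric vector of length `4 * n_samples`.
#' @export
build_force_features <- function(h0, point_xy) {
  n <- length(h0) / 2
  stopifnot(n == floor(n))
  values <- h0[seq_len(n)]
  z <- h0[n + seq_len(n)]
  c(rep(point_xy[1], n), rep(point_xy[2], n), z, values)
}

#' Node-feature matrix for a surface cloud
#'
#' Applies [extract_profile()] + [build_node_features()] to every row of
#' a rest point cloud.
#'
#' @param volume a [tissue_volume()].
#' @param x0 N x 3 rest cloud (mm).
#' @param n_samples depth samples per point (default 128).
#' @return N x (2 * n_samples) matrix.
#' @export
node_features_matrix <- function(volume, x0, n_samples = 128) {
  x0 <- as_points_matrix(x0)
  t(apply(x0, 1, function(p) {
    build_node_features(extract_profile(volume, p, n_samples))
  }))
}

#' Force-feature matrix for a surface cloud
#'
#' Row-wise [build_force_features()]: each point's `h0` plus its x, y.
#'
#' @param h0 N x (2 * n_samples) node feature matrix.
#' @param x0 N x 3 rest cloud.
#' @return N x (4 * n_samples) matrix with the `Ch` block layout.
#' @export
force_features_matrix <- function(h0, x0) {
  x0 <- as_points_matrix(x0)
  stopifnot(nrow(h0) == nrow(x0))
  t(vapply(seq_len(nrow(h0)),
           function(i) build_force_features(h0[i, ], x0[i, 1:2]),
           numeric(2 * ncol(h0))))
}

# highest rigid z in the column under (x, y); -Inf when the column is
# all-soft. Scanned at n_scan cell-centred depths (0.125 mm at default).
bone_top <- function(volume, xy, n_scan = 256) {
  prof <- extract_profile(volume, c(xy[1], xy[2], 0), n_samples = n_scan)
  rigid <- which(prof$values == 1L)
  if (length(rigid) == 0) return(-Inf)
  prof$z_positions[max(rigid)]
}

#' Convert a primitive-backed volume to a voxel grid
#'
#' @param volume a primitive-backed [tissue_volume()].
#' @param spacing voxel edge length in mm (default 1).
#' @return a voxel-backed [tissue_volume()].
#' @export
voxelize <- function(volume, spacing = 1) {
  d <- volume$domain
  dims <- as.integer(round(d / spacing))
  stopifnot(all(abs(dims * spacing - d) < 1e-6))
  cx <- (seq_len(dims[1]) - 0.5) * spacing
  cy <- (seq_len(dims[2]) - 0.5) * spacing
  cz <- (seq_len(dims[3]) - 0.5) * spacing
  grid <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  occ <- occupancy_query(volume, grid)
  tissue_volume(domain = d, voxels = array(occ, dim = dims),
                spacing = spacing)
}

#' Read / write a tissue volume as a JSON primitive spec
#'
#' The on-disk format is
#' `{"domain": [100,100,32], "primitives": [{"type":"box", ...}, ...]}`.
#'
#' @param volume a primitive-backed [tissue_volume()].
#' @param path file path.
#' @return `read_volume_json()` returns a [tissue_volume()];
#'   `write_volume_json()` returns `path` invisibly.
#' @export
write_volume_json <- function(volume, path) {
  if (!is.null(volume$voxels)) {
    stop("JSON volume spec covers primitive-backed volumes only")
  }
  jsonlite::write_json(
    list(domain = volume$domain, primitives = volume$primitives),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_json
#' @export
read_volume_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  prims <- lapply(spec$primitives, function(p) {
    p[setdiff(names(p), "type")] <- lapply(p[setdiff(names(p), "type")],
                                           as.numeric)
    p$type <- as.character(p$type)
    p
  })
  tissue_volume(domain = as.numeric(spec$domain), primitives = prims)
}

#' Dump a depth profile to CSV for debugging
#'
#' One row per depth sample: x, y, z, label.
#'
#' @param profile a `tissue_profile`.
#' @param path CSV path.
#' @return the written tibble, invisibly.
#' @export
dump_profile_csv <- function(profile, path) {
  df <- tibble::tibble(
    x = profile$anchor[1], y = profile$anchor[2],
    z = profile$z_positions, label = as.integer(profile$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
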