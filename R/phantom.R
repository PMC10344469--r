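TISSUE_LABELS <- c(brain = 1L, bone = 2L, blubber_skin = 3L, muscle = 4L)

#' Labeled voxel volume
#'
#' Integer-labeled 3D grid with physical voxel size: 0 air, 1 brain, 2 bone,
#' 3 blubber+skin, 4 muscle.
#'
#' @param labels 3D integer array
#' @param voxel_size (dx, dy, dz), mm (scalar recycled)
#' @param origin mm coordinates of the corner of voxel (1,1,1)
#' @param landmark_blowhole optional voxel coordinate (i, j, k) of the
#'   blowhole landmark
#' @param meta optional metadata list
#' @return object of class \code{labeled_volume}
#' @export
labeled_volume <- function(labels, voxel_size, origin = c(0, 0, 0),
                           landmark_blowhole = NULL, meta = list()) {
  stopifnot(length(dim(labels)) == 3)
  voxel_size <- rep_len(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (!all(labels %in% 0:4)) stop("labels must be integers in 0..4")
  structure(list(labels = labels, voxel_size = voxel_size, origin = origin,
                 landmark_blowhole = landmark_blowhole, meta = meta),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %g x %g x %g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  print(table(x$labels))
  invisible(x)
}

#' Geometry configuration for the layered head phantom
#'
#' Defaults describe an adult-dolphin-scale head: a superellipsoid body about
#' 260 mm dorsoventrally, a ~20 mm blubber+skin shell, a muscle layer, and an
#' ellipsoidal brain enclosed by bone. Axes: x lateral (midsagittal plane at
#' x = 0), y dorsoventral (dorsal +y), z longitudinal (caudal +z).
#'
#' @param semi_axes body semi-axes (ax, ay, az), mm
#' @param exponent superellipsoid exponent (2 = ellipsoid)
#' @param blubber,muscle,skull layer thicknesses, mm (measured inward from
#'   the surface; the skull thickness is enforced as a minimum bone margin
#'   around the brain)
#' @param brain_semi_axes brain ellipsoid semi-axes, mm
#' @param brain_center brain center, mm (dorsal-caudal by default)
#' @param blowhole_z longitudinal position of the blowhole landmark, mm
#' @param surface_noise relative amplitude of a smooth seeded surface
#'   perturbation (0 disables; the phantom is then seed-independent)
#' @return a list of class \code{phantom_config}
#' @export
phantom_config <- function(semi_axes = c(110, 130, 220), exponent = 2.5,
                           blubber = 20, muscle = 25, skull = 15,
                           brain_semi_axes = c(40, 35, 45),
                           brain_center = c(0, 25, 40),
                           blowhole_z = -20, surface_noise = 0) {
  cfg <- list(semi_axes = semi_axes, exponent = exponent, blubber = blubber,
              muscle = muscle, skull = skull,
              brain_semi_axes = brain_semi_axes, brain_center = brain_center,
              blowhole_z = blowhole_z, surface_noise = surface_noise)
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate a layered head phantom volume
#'
#' Builds the labeled volume of nested smooth shells: blubber+skin outermost,
#' muscle beneath it, an ellipsoidal brain deep inside, and bone filling the
#' space between muscle and brain (so the brain is fully enclosed by bone).
#' Shell membership uses the distance from the voxel center to the body
#' surface along the radial ray. Deterministic given the seed; the seed only
#' perturbs the surface when \code{surface_noise > 0}.
#'
#' @param config a \code{phantom_config}
#' @param voxel_size voxel pitch, mm (scalar or length 3)
#' @param seed RNG seed for the optional surface perturbation
#' @return a \code{labeled_volume}; \code{meta$skin_to_brain_mm} reports the
#'   dorsal-midline skin-to-brain distance
#' @export
generate_phantom <- function(config = phantom_config(), voxel_size = 10,
                             seed = 1) {
  ax <- config$semi_axes; p <- config$exponent
  tb <- config$blubber; tm <- config$muscle; ts <- config$skull
  if (min(tb + tm + ts, na.rm = TRUE) <= 0 || any(c(tb, tm, ts) < 0))
    stop("thicknesses must be >= 0")
  if (tb + tm + ts >= min(ax)) stop("thicknesses exceed body radius")
  voxel_size <- rep_len(voxel_size, 3)
  pad <- 2 * voxel_size
  lo <- -ax - pad; hi <- ax + pad
  n <- ceiling((hi - lo) / voxel_size)
  cx <- lo[1] + (seq_len(n[1]) - 0.5) * voxel_size[1]
  cy <- lo[2] + (seq_len(n[2]) - 0.5) * voxel_size[2]
  cz <- lo[3] + (seq_len(n[3]) - 0.5) * voxel_size[3]
  X <- array(rep(cx, times = n[2] * n[3]), n)
  Y <- array(rep(rep(cy, each = n[1]), times = n[3]), n)
  Z <- array(rep(cz, each = n[1] * n[2]), n)

  rho <- (abs(X / ax[1])^p + abs(Y / ax[2])^p + abs(Z / ax[3])^p)^(1 / p)
  if (config$surface_noise > 0) {
    set.seed(seed)
    ph <- stats::runif(4, 0, 2 * pi)
    th <- atan2(Y, X)
    rho <- rho * (1 + config$surface_noise *
                    sin(3 * th + ph[1]) * cos(2 * pi * Z / ax[3] + ph[2]))
  }
  r <- sqrt(X^2 + Y^2 + Z^2)
  depth <- ifelse(rho > 0, r * (1 / rho - 1), Inf)
  inside <- rho <= 1

  bc <- config$brain_center; ba <- config$brain_semi_axes
  brain <- ((X - bc[1]) / ba[1])^2 + ((Y - bc[2]) / ba[2])^2 +
    ((Z - bc[3]) / ba[3])^2 <= 1
  skull_guard <- ((X - bc[1]) / (ba[1] + ts))^2 +
    ((Y - bc[2]) / (ba[2] + ts))^2 + ((Z - bc[3]) / (ba[3] + ts))^2 <= 1
  if (any(skull_guard & inside & depth < tb + tm))
    stop("brain plus skull margin reaches into the muscle/blubber shells; ",
         "enlarge the body or shrink the brain")
  if (any(skull_guard & !inside))
    stop("brain plus skull margin leaves the body")

  labels <- array(0L, n)
  labels[inside] <- TISSUE_LABELS["bone"]
  labels[inside & depth < tb + tm] <- TISSUE_LABELS["muscle"]
  labels[inside & depth < tb] <- TISSUE_LABELS["blubber_skin"]
  labels[brain] <- TISSUE_LABELS["brain"]

  # blowhole: dorsal midline surface at z = blowhole_z
  zbh <- config$blowhole_z
  ybh <- ax[2] * (1 - abs(zbh / ax[3])^p)^(1 / p)
  bh_vox <- pmax(1, pmin(n, ceiling((c(0, ybh, zbh) - lo) / voxel_size)))

  # dorsal-midline skin-to-brain distance from the voxel labels
  icol <- which.min(abs(cx - bc[1])); kcol <- which.min(abs(cz - bc[3]))
  col <- labels[icol, , kcol]
  y_skin <- max(cy[col != 0]); y_brain <- max(cy[col == TISSUE_LABELS["brain"]])
  labeled_volume(labels, voxel_size, origin = lo,
                 landmark_blowhole = bh_vox,
                 meta = list(config = config,
                             skin_to_brain_mm = y_skin - y_brain,
                             landmark_blowhole_mm = c(0, ybh, zbh)))
}

#' Labeled box volume (test and slab geometries)
#'
#' Builds a rectangular labeled volume. \code{label_fun}, if given, receives
#' voxel-center coordinates (x, y, z in mm) and returns labels (0 allowed);
#' otherwise all voxels get \code{label}.
#'
#' @param dims_mm box edge lengths, mm
#' @param voxel_size voxel pitch, mm
#' @param label uniform label (default brain = 1)
#' @param label_fun optional vectorized function(x, y, z) -> labels
#' @return a \code{labeled_volume} with origin at (0,0,0)
#' @export
labeled_box <- function(dims_mm, voxel_size, label = 1L, label_fun = NULL) {
  voxel_size <- rep_len(voxel_size, 3)
  dims_mm <- rep_len(dims_mm, 3)
  n <- pmax(1, round(dims_mm / voxel_size))
  if (is.null(label_fun)) {
    labels <- array(as.integer(label), n)
  } else {
    cx <- (seq_len(n[1]) - 0.5) * voxel_size[1]
    cy <- (seq_len(n[2]) - 0.5) * voxel_size[2]
    cz <- (seq_len(n[3]) - 0.5) * voxel_size[3]
    g <- expand.grid(x = cx, y = cy, z = cz)
    labels <- array(as.integer(label_fun(g$x, g$y, g$z)), n)
  }
  labeled_volume(labels, voxel_size)
}

# Kuhn (orthoscheme) subdivision: 6 right tetrahedra per box around the main
# diagonal; conforming across neighbors, and nonobtuse, so the P1 stiffness
# matrix is an M-matrix and the discrete maximum principle holds (positive
# fluence) when the mass term is lumped.
# corner order: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0)
#               5=(0,0,1) 6=(1,0,1) 7=(0,1,1) 8=(1,1,1)
.kuhn_corners <- matrix(c(
  1, 2, 4, 8,
  1, 2, 6, 8,
  1, 3, 4, 8,
  1, 3, 7, 8,
  1, 5, 6, 8,
  1, 5, 7, 8), ncol = 4, byrow = TRUE)
.corner_offsets <- cbind(c(0,1,0,1,0,1,0,1), c(0,0,1,1,0,0,1,1),
                         c(0,0,0,0,1,1,1,1))

#' Mesh a labeled volume into tetrahedra
#'
#' Conforming tetrahedral mesh of all non-air voxels: each voxel is split
#' into six equal-volume right tetrahedra (Kuhn subdivision around a fixed
#' diagonal), a nonobtuse decomposition under which the diffusion operator
#' satisfies the discrete maximum principle. When
#' \code{target_element_volume} is given, the volume is first resampled
#' (nearest-neighbor) to the voxel pitch whose split elements have
#' approximately that volume. Nodes take the majority label of their incident
#' voxels.
#'
#' @param vol a \code{labeled_volume}
#' @param target_element_volume desired mean tetrahedron volume, mm^3
#'   (NULL = mesh at the native voxel pitch)
#' @return object of class \code{tetra_mesh} with fields \code{nodes} (mm),
#'   \code{elems}, \code{node_label}, \code{elem_label},
#'   \code{element_volumes} (mm^3) and a precomputed boundary \code{surface}
#' @export
mesh_labeled_volume <- function(vol, target_element_volume = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  labels <- vol$labels; vs <- vol$voxel_size; origin <- vol$origin
  if (!is.null(target_element_volume)) {
    h <- (6 * target_element_volume)^(1 / 3)
    f <- pmax(1L, round(h / vs))
    if (any(f > 1)) {
      d <- dim(labels)
      idx <- lapply(1:3, function(k) {
        ctr <- seq(f[k] / 2 + 0.5, d[k], by = f[k])
        pmin(d[k], pmax(1, round(ctr)))
      })
      labels <- labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      vs <- vs * f
    }
  }
  d <- dim(labels)
  vox <- which(labels > 0L)
  if (!length(vox)) stop("volume contains no tissue voxels")
  vi <- arrayInd(vox, d)

  # global corner-node grid of size (d+1)^3, keep only used nodes
  nd <- d + 1L
  corner_id <- function(i, j, k) (i) + (j - 1L) * nd[1] +
    (k - 1L) * nd[1] * nd[2]
  corners <- matrix(0L, length(vox), 8)
  for (c in 1:8) {
    off <- .corner_offsets[c, ]
    corners[, c] <- corner_id(vi[, 1] + off[1], vi[, 2] + off[2],
                              vi[, 3] + off[3])
  }
  used <- sort(unique(as.vector(corners)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  corners[] <- remap[corners]

  # node coordinates
  kk <- (used - 1L) %/% (nd[1] * nd[2])
  jj <- (used - 1L - kk * nd[1] * nd[2]) %/% nd[1]
  ii <- used - 1L - kk * nd[1] * nd[2] - jj * nd[1]
  nodes <- cbind(origin[1] + ii * vs[1],
                 origin[2] + jj * vs[2],
                 origin[3] + kk * vs[3])

  # majority node label (ties -> lowest label id)
  counts <- matrix(0L, length(used), 4)
  lv <- as.integer(labels[vox])
  for (lab in 1:4) {
    sel <- lv == lab
    if (any(sel))
      counts[, lab] <- tabulate(corners[sel, , drop = FALSE],
                                nbins = length(used))
  }
  node_label <- max.col(counts, ties.method = "first")

  # 6 tets per voxel
  m <- length(vox)
  elems <- matrix(0L, 6 * m, 4)
  for (t in 1:6)
    elems[seq(t, by = 6, length.out = m), ] <- corners[, .kuhn_corners[t, ]]
  elem_label <- rep(lv, each = 6)

  # enforce positive orientation
  sv <- .signed_volumes(nodes, elems)
  neg <- sv < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]
  vol_e <- abs(sv)
  mesh <- structure(list(nodes = nodes, elems = elems,
                         node_label = as.integer(node_label),
                         elem_label = elem_label,
                         element_volumes = vol_e,
                         voxel_pitch = vs,
                         grid = list(dims = d, origin = origin, pitch = vs,
                                     vox = vox, vox_label = lv),
                         landmark_blowhole_mm = vol$meta$landmark_blowhole_mm,
                         meta = vol$meta),
                    class = "tetra_mesh")
  mesh$surface <- .extract_surface(mesh)
  mesh
}

.signed_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

.extract_surface <- function(mesh) {
  el <- mesh$elems
  faces <- rbind(el[, c(2, 3, 4)], el[, c(1, 4, 3)],
                 el[, c(1, 2, 4)], el[, c(1, 3, 2)])
  owner <- rep(seq_len(nrow(el)), 4)
  kmin <- pmin(faces[, 1], faces[, 2], faces[, 3])
  kmax <- pmax(faces[, 1], faces[, 2], faces[, 3])
  key <- cbind(kmin, faces[, 1] + faces[, 2] + faces[, 3] - kmin - kmax, kmax)
  nn <- nrow(mesh$nodes) + 1
  if (as.numeric(nn)^3 < 2^53) {
    k <- (key[, 1] * nn + key[, 2]) * nn + key[, 3]
    dup <- k %in% k[duplicated(k)]
  } else {
    o <- do.call(order, as.data.frame(key))
    same_next <- c(rowSums(key[o[-length(o)], , drop = FALSE] ==
                           key[o[-1], , drop = FALSE]) == 3, FALSE)
    same_prev <- c(FALSE, same_next[-length(same_next)])
    dup <- logical(nrow(key)); dup[o] <- same_next | same_prev
  }
  bf <- faces[!dup, , drop = FALSE]
  bown <- owner[!dup]
  p1 <- mesh$nodes[bf[, 1], , drop = FALSE]
  e1 <- mesh$nodes[bf[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[bf[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(nrm^2))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # orient outward: away from owner tet centroid
  cen_t <- (mesh$nodes[el[bown, 1], ] + mesh$nodes[el[bown, 2], ] +
            mesh$nodes[el[bown, 3], ] + mesh$nodes[el[bown, 4], ]) / 4
  cen_f <- (p1 + mesh$nodes[bf[, 2], ] + mesh$nodes[bf[, 3], ]) / 3
  flip <- rowSums(nrm * (cen_f - cen_t)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  surf_nodes <- sort(unique(as.vector(bf)))
  # area-weighted node normals
  nnorm <- matrix(0, nrow(mesh$nodes), 3)
  w <- nrm * area
  for (c in 1:3) {
    agg <- rowsum(w, group = bf[, c])
    ids <- as.integer(rownames(agg))
    nnorm[ids, ] <- nnorm[ids, ] + agg
  }
  len <- sqrt(rowSums(nnorm^2)); len[len == 0] <- 1
  nnorm <- nnorm / len
  list(faces = bf, face_normal = nrm, face_area = area,
       nodes = surf_nodes, node_normal = nnorm)
}

#' @export
print.tetra_mesh <- function(x, ...) {
  cat(sprintf("<tetra_mesh> %d nodes, %d tetrahedra, mean volume %.3g mm^3\n",
              nrow(x$nodes), nrow(x$elems), mean(x$element_volumes)))
  invisible(x)
}

#' Scale a mesh uniformly
#'
#' Multiplies all coordinates (and the blowhole landmark) by \code{factor};
#' connectivity and labels are unchanged, element volumes scale by
#' \code{factor^3}, surface areas by \code{factor^2}. \code{factor = 0.75}
#' produces the juvenile model (all dimensions shrunk by 25%).
#'
#' @param mesh a \code{tetra_mesh}
#' @param factor scale factor (> 0)
#' @return scaled \code{tetra_mesh}
#' @export
scale_mesh <- function(mesh, factor = 0.75) {
  stopifnot(inherits(mesh, "tetra_mesh"), factor > 0)
  mesh$nodes <- mesh$nodes * factor
  mesh$element_volumes <- mesh$element_volumes * factor^3
  mesh$voxel_pitch <- mesh$voxel_pitch * factor
  if (!is.null(mesh$landmark_blowhole_mm))
    mesh$landmark_blowhole_mm <- mesh$landmark_blowhole_mm * factor
  if (!is.null(mesh$surface)) {
    mesh$surface$face_area <- mesh$surface$face_area * factor^2
    if (factor < 0) mesh$surface$face_normal <- -mesh$surface$face_normal
  }
  if (!is.null(mesh$meta$skin_to_brain_mm))
    mesh$meta$skin_to_brain_mm <- mesh$meta$skin_to_brain_mm * factor
  mesh
}

#' Assign per-node optical properties at a wavelength
#'
#' Sets mu_a, mus', kappa and ri for every node from its tissue label via
#' \code{\link{tissue_property_table}}. Reassigning at a new wavelength
#' changes only \code{node_props} (geometry untouched).
#'
#' @param mesh a \code{tetra_mesh}
#' @param lambda wavelength, nm
#' @param basis spectral basis
#' @param compositions tissue composition table
#' @return the mesh with \code{node_props} (data.frame) and \code{lambda} set
#' @export
assign_properties <- function(mesh, lambda, basis = spectral_basis(),
                              compositions = tissue_compositions()) {
  stopifnot(inherits(mesh, "tetra_mesh"), length(lambda) == 1)
  labs <- sort(unique(mesh$node_label))
  bad <- setdiff(labs, TISSUE_LABELS)
  if (length(bad)) stop("unknown node labels: ", paste(bad, collapse = ", "))
  props <- data.frame(mu_a = rep(NA_real_, nrow(mesh$nodes)),
                      mu_s_prime = NA_real_, kappa = NA_real_, ri = NA_real_)
  for (lab in labs) {
    tis <- names(TISSUE_LABELS)[TISSUE_LABELS == lab]
    tp <- tissue_property_table(tis, lambda, basis, compositions)
    sel <- mesh$node_label == lab
    props$mu_a[sel] <- tp$mu_a
    props$mu_s_prime[sel] <- tp$mu_s_prime
    props$kappa[sel] <- tp$kappa
    props$ri[sel] <- tp$ri
  }
  mesh$node_props <- props
  mesh$lambda <- lambda
  mesh
}

#' Assign uniform optical properties to every node
#'
#' Convenience for homogeneous benchmark media (analytic-oracle geometries).
#'
#' @param mesh a \code{tetra_mesh}
#' @param mu_a,mu_s_prime properties, mm^-1
#' @param ri refractive index
#' @param lambda nominal wavelength tag, nm
#' @return mesh with \code{node_props} set
#' @export
assign_uniform_properties <- function(mesh, mu_a, mu_s_prime, ri = 1.37,
                                      lambda = NA_real_) {
  op <- optical_properties(mu_a, mu_s_prime, ri)
  n <- nrow(mesh$nodes)
  mesh$node_props <- data.frame(mu_a = rep(op$mu_a, n),
                                mu_s_prime = rep(op$mu_s_prime, n),
                                kappa = rep(op$kappa, n),
                                ri = rep(op$ri, n))
  mesh$lambda <- lambda
  mesh
}

#' Distance from each node to the outer surface
#'
#' Euclidean distance to the nearest boundary node, used as the depth
#' coordinate of reconstruction summaries.
#'
#' @param mesh a \code{tetra_mesh}
#' @return numeric vector, mm (0 on the surface)
#' @export
node_depths <- function(mesh) {
  s <- mesh$surface
  sn <- mesh$nodes[s$nodes, , drop = FALSE]
  n <- nrow(mesh$nodes)
  out <- numeric(n)
  s2 <- rowSums(sn^2)
  chunk <- max(1, floor(2e7 / nrow(sn)))
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1)
    x <- mesh$nodes[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(x^2), s2, "+") - 2 * tcrossprod(x, sn)
    out[i0:i1] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)),
                                        max.col(-d2, ties.method = "first"))]))
  }
  out
}

#' Voxelize mesh labels back onto a grid
#'
#' Looks up, for each tissue voxel center of \code{vol}, the label of the
#' mesh element containing it (via the mesh's own voxel grid); used for
#' round-trip checks of the meshing step, in particular after resampling to
#' a coarser target element volume.
#'
#' @param mesh a \code{tetra_mesh} from \code{\link{mesh_labeled_volume}}
#' @param vol the originating \code{labeled_volume}
#' @return integer array of predicted labels (0 where the mesh has no
#'   element)
#' @export
voxelize_labels <- function(mesh, vol) {
  if (is.null(mesh$grid)) stop("mesh carries no voxel grid")
  g <- mesh$grid
  d <- dim(vol$labels)
  out <- array(0L, d)
  vox <- which(vol$labels > 0L)
  vi <- arrayInd(vox, d)
  ctr <- sweep(sweep(vi - 0.5, 2, vol$voxel_size, "*"), 2, vol$origin, "+")
  gi <- sweep(ctr, 2, g$origin, "-")
  gi <- sweep(gi, 2, g$pitch, "/")
  gi <- pmin(pmax(ceiling(gi), 1L),
             matrix(g$dims, nrow(gi), 3, byrow = TRUE))
  lin <- gi[, 1] + (gi[, 2] - 1L) * g$dims[1] +
    (gi[, 3] - 1L) * g$dims[1] * g$dims[2]
  hit <- match(lin, g$vox)
  lab <- ifelse(is.na(hit), 0L, g$vox_label[hit])
  out[vox] <- lab
  out
}

.nearest_node <- function(nodes, pts) {
  n2 <- rowSums(nodes^2)
  res <- integer(nrow(pts))
  chunk <- max(1, floor(2e7 / nrow(nodes)))
  for (i0 in seq(1, nrow(pts), by = chunk)) {
    i1 <- min(nrow(pts), i0 + chunk - 1)
    x <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(x^2), n2, "+") - 2 * tcrossprod(x, nodes)
    res[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  res
}
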