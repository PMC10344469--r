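#' Internal-reflection boundary factor A(ri)
#'
#' Standard polynomial/critical-angle approximation to the refractive-index
#' mismatch factor entering the Robin boundary condition
#' phi + 2 A kappa dphi/dn = 0 at a tissue-air interface.
#'
#' @param ri tissue refractive index relative to air
#' @return boundary factor A (>= 1)
#' @export
boundary_factor <- function(ri) {
  n <- ri
  r0 <- ((n - 1) / (n + 1))^2
  ct <- abs(cos(asin(1 / n)))^3
  (2 / (1 - r0) - 1 + ct) / (1 - ct)
}

#' Assemble the CW diffusion finite-element system
#'
#' Symmetric positive-definite sparse operator from linear (P1) tetrahedral
#' elements: stiffness weighted by the element-mean diffusion coefficient
#' kappa, an absorption mass term integrated by nodal (lumped) quadrature
#' with the nodal mu_a, and a Robin boundary term with coefficient
#' 1/(2 A(ri)) on surface faces (also lumped). On the nonobtuse Kuhn meshes
#' produced by \code{\link{mesh_labeled_volume}} this discretization is an
#' M-matrix, so the computed fluence respects the maximum principle and stays
#' positive; the lumped mass also makes the adjoint Jacobian product
#' -phi_src(n) phi_det(n) V(n) the exact derivative of the discrete system.
#'
#' @param mesh a \code{tetra_mesh} with \code{node_props} assigned
#' @return object of class \code{diffusion_system}: the sparse operator
#'   \code{K}, the mesh, lumped nodal volumes \code{vlump}, and a
#'   node-to-element incidence index
#' @export
assemble_system <- function(mesh) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  if (is.null(mesh$node_props)) stop("assign_properties() first")
  pr <- mesh$node_props
  if (any(pr$mu_a <= 0) || any(pr$mu_s_prime <= 0) || any(pr$kappa <= 0))
    stop("non-positive optical properties")
  el <- mesh$elems
  nn <- nrow(mesh$nodes)
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  e1 <- mesh$nodes[el[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[el[, 3], , drop = FALSE] - p1
  e3 <- mesh$nodes[el[, 4], , drop = FALSE] - p1
  # inverse of T = [e1 e2 e3] (columns) per element, via cofactors
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e2[, 1] * (e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]) +
         e3[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])
  vol <- det / 6
  if (any(vol <= 0)) stop("non-positive element volume")
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  # gradients of barycentric coords lambda_2..4 are rows of T^{-1}
  g2 <- cross(e2, e3) / det
  g3 <- cross(e3, e1) / det
  g4 <- cross(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  kap_e <- (pr$kappa[el[, 1]] + pr$kappa[el[, 2]] + pr$kappa[el[, 3]] +
            pr$kappa[el[, 4]]) / 4
  m <- nrow(el)
  ii <- jj <- integer(16 * m); xx <- numeric(16 * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * m + seq_len(m)
    ii[idx] <- el[, a]; jj[idx] <- el[, b]
    xx[idx] <- kap_e * vol * rowSums(G[[a]] * G[[b]])
    k <- k + 1L
  }
  # lumped nodal volumes and absorption mass
  vlump <- numeric(nn)
  for (a in 1:4) {
    agg <- rowsum(vol / 4, el[, a])
    ids <- as.integer(rownames(agg))
    vlump[ids] <- vlump[ids] + agg
  }
  # Robin boundary term, lumped (Area/3 per face node)
  s <- mesh$surface
  bf <- s$faces
  ri_f <- (pr$ri[bf[, 1]] + pr$ri[bf[, 2]] + pr$ri[bf[, 3]]) / 3
  gam <- 1 / (2 * boundary_factor(ri_f))
  bdiag <- numeric(nn)
  for (a in 1:3) {
    agg <- rowsum(gam * s$face_area / 3, bf[, a])
    ids <- as.integer(rownames(agg))
    bdiag[ids] <- bdiag[ids] + agg
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn)) +
    Matrix::Diagonal(nn, pr$mu_a * vlump + bdiag)
  node_elems <- split(rep(seq_len(m), 4), as.vector(el))
  structure(list(K = K, mesh = mesh, vlump = vlump, node_elems = node_elems,
                 factor = NULL),
            class = "diffusion_system")
}

.system_factor <- function(system) {
  if (is.null(system$factor))
    system$factor <- Matrix::Cholesky(system$K, LDL = FALSE, super = TRUE)
  system
}

#' Barycentric interpolation weights for a point
#'
#' Locates the tetrahedron containing \code{pos} (searching elements incident
#' to the nearest nodes) and returns its node indices and barycentric
#' weights; falls back to the nearest node if the point lies outside the
#' mesh.
#'
.knearest <- function(nodes, pts, k = 8) {
  n2 <- rowSums(nodes^2)
  k <- min(k, nrow(nodes))
  res <- matrix(0L, nrow(pts), k)
  chunk <- max(1, floor(2e7 / nrow(nodes)))
  for (i0 in seq(1, nrow(pts), by = chunk)) {
    i1 <- min(nrow(pts), i0 + chunk - 1)
    x <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(x^2), n2, "+") - 2 * tcrossprod(x, nodes)
    if (k == 1) {
      res[i0:i1, 1] <- max.col(-d2, ties.method = "first")
    } else {
      for (r in seq_len(nrow(d2))) {
        row <- d2[r, ]
        for (j in seq_len(k)) {
          m <- which.min(row)
          res[i0 + r - 1, j] <- m
          row[m] <- Inf
        }
      }
    }
  }
  res
}

#' @keywords internal
point_weights <- function(system, pos, near = NULL) {
  mesh <- system$mesh
  if (is.null(near))
    near <- .knearest(mesh$nodes, matrix(pos, ncol = 3), 8)[1, ]
  cands <- unique(unlist(system$node_elems[as.character(near)],
                         use.names = FALSE))
  el <- mesh$elems
  best <- NULL; best_min <- -Inf
  for (e in cands) {
    vid <- el[e, ]
    p1 <- mesh$nodes[vid[1], ]
    T <- cbind(mesh$nodes[vid[2], ] - p1, mesh$nodes[vid[3], ] - p1,
               mesh$nodes[vid[4], ] - p1)
    lam <- tryCatch(solve(T, pos - p1), error = function(e) NULL)
    if (is.null(lam)) next
    w <- c(1 - sum(lam), lam)
    if (min(w) > best_min) { best <- list(nodes = vid, w = w)
                             best_min <- min(w) }
    if (best_min >= -1e-9) break
  }
  if (is.null(best) || best_min < -0.05) {
    return(list(nodes = near[1], w = 1, inside = FALSE))
  }
  best$w <- pmax(best$w, 0); best$w <- best$w / sum(best$w)
  best$inside <- best_min >= -1e-9
  best
}

#' Interpolate nodal fields at arbitrary points
#'
#' @param system a \code{diffusion_system}
#' @param phi nodal field vector or nodes-x-k matrix
#' @param points n-x-3 matrix of positions, mm
#' @return n-x-k matrix of interpolated values; attribute
#'   \code{n_offsurface} counts points that fell outside the mesh (nearest
#'   node used)
#' @export
interpolate_field <- function(system, phi, points) {
  phi <- as.matrix(phi)
  points <- matrix(points, ncol = 3)
  out <- matrix(NA_real_, nrow(points), ncol(phi))
  nearest <- .knearest(system$mesh$nodes, points, 8)
  n_off <- 0L
  for (i in seq_len(nrow(points))) {
    pw <- point_weights(system, points[i, ], near = nearest[i, ])
    if (!pw$inside) n_off <- n_off + 1L
    out[i, ] <- crossprod(phi[pw$nodes, , drop = FALSE], pw$w)
  }
  attr(out, "n_offsurface") <- n_off
  out
}

.point_load <- function(system, pos) {
  pw <- point_weights(system, pos)
  b <- numeric(nrow(system$mesh$nodes))
  b[pw$nodes] <- pw$w
  b
}

#' Source positions beneath the surface
#'
#' Point sources are placed one transport mean free path (1/mus' at the
#' optode's node) beneath the surface along the inward normal.
#' @keywords internal
source_positions <- function(mesh, optodes) {
  mus <- mesh$node_props$mu_s_prime[optodes$node]
  as.matrix(optodes[, c("x", "y", "z")]) +
    as.matrix(optodes[, c("nx", "ny", "nz")]) / mus
}

#' Solve the CW forward model
#'
#' One linear solve per source optode (point load at depth 1/mus' beneath the
#' surface); channel amplitudes are the fluence rate interpolated at the
#' detector surface positions, relative to a unit input source.
#'
#' @param system a \code{diffusion_system}
#' @param optodes an \code{optode_set}
#' @param channels a \code{channel_set} (may be NULL: fields only)
#' @return list of class \code{forward_result}: \code{phi} (nodes x sources,
#'   columns named by optode id), \code{amplitudes} (channel vector),
#'   \code{channels}, and the factored system
#' @export
solve_forward <- function(system, optodes, channels = NULL) {
  system <- .system_factor(system)
  src <- optodes[optodes$role == "source", ]
  spos <- source_positions(system$mesh, src)
  B <- matrix(0, nrow(system$mesh$nodes), nrow(src))
  for (i in seq_len(nrow(src))) B[, i] <- .point_load(system, spos[i, ])
  phi <- as.matrix(Matrix::solve(system$factor, B))
  colnames(phi) <- as.character(src$id)
  if (!all(is.finite(phi))) stop("forward solve produced non-finite fluence")
  amplitudes <- NULL
  if (!is.null(channels) && nrow(channels)) {
    det <- optodes[optodes$role == "detector", ]
    dpos <- as.matrix(det[, c("x", "y", "z")])
    vals <- interpolate_field(system, phi, dpos)  # ndet x nsrc
    rownames(vals) <- as.character(det$id)
    amplitudes <- vals[cbind(match(as.character(channels$det), rownames(vals)),
                             match(as.character(channels$src), colnames(phi)))]
    if (any(amplitudes <= 0))
      warning(sum(amplitudes <= 0), " non-positive channel amplitudes")
  }
  structure(list(phi = phi, amplitudes = amplitudes, channels = channels,
                 optodes = optodes, system = system),
            class = "forward_result")
}

#' Adjoint sensitivity (Jacobian) matrix J = dPhi/dmu_a
#'
#' Adjoint formulation: J[ch, n] = -phi_src(n) phi_det(n) V(n), where phi_det
#' is the adjoint field solved with a point load at the detector position and
#' V(n) is the lumped nodal volume (one quarter of each incident
#' tetrahedron). Under the lumped absorption quadrature used by
#' \code{\link{assemble_system}} this is the exact derivative of each
#' discrete channel amplitude with respect to nodal absorption. Entries are
#' <= 0: increasing absorption anywhere reduces the detected fluence.
#' Scattering perturbations are neglected (CW assumption).
#'
#' @param forward a \code{forward_result} (fields for all sources)
#' @param channel_idx optional subset of channel rows to compute
#' @return matrix (channels x nodes), mm; rownames are channel indices
#' @export
compute_jacobian <- function(forward, channel_idx = NULL) {
  stopifnot(inherits(forward, "forward_result"))
  system <- .system_factor(forward$system)
  mesh <- system$mesh
  channels <- forward$channels
  if (is.null(channels) || !nrow(channels))
    stop("forward result has no channels")
  if (is.null(channel_idx)) channel_idx <- seq_len(nrow(channels))
  ch <- channels[channel_idx, , drop = FALSE]
  optodes <- forward$optodes
  dets <- sort(unique(ch$det))
  drow <- match(dets, optodes$id)
  dpos <- as.matrix(optodes[drow, c("x", "y", "z")])
  B <- matrix(0, nrow(mesh$nodes), length(dets))
  for (i in seq_along(dets)) B[, i] <- .point_load(system, dpos[i, ])
  psi <- as.matrix(Matrix::solve(system$factor, B))
  colnames(psi) <- as.character(dets)

  nn <- nrow(mesh$nodes)
  J <- matrix(0, nrow(ch), nn)
  vlump <- system$vlump
  for (r in seq_len(nrow(ch))) {
    phi_s <- forward$phi[, as.character(ch$src[r])]
    psi_d <- psi[, as.character(ch$det[r])]
    J[r, ] <- -phi_s * psi_d * vlump
  }
  if (!all(is.finite(J))) stop("non-finite Jacobian entries")
  rownames(J) <- as.character(channel_idx)
  J
}
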