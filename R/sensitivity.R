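#' Simulate activation of a target tissue
#'
#' Multiplies the blood volume fraction B of the target tissue (default
#' brain, multiplier 1.1: a 10% hemoglobin increase) and re-composes mu_a at
#' the mesh's wavelength; mus' is blood-independent under the power law, so
#' only mu_a and kappa change, and only at nodes of the target tissue.
#'
#' @param mesh a \code{tetra_mesh} with properties assigned
#' @param target tissue name (\code{brain}, \code{muscle}, ...)
#' @param multiplier blood-fraction multiplier (> 0)
#' @param basis spectral basis
#' @param compositions composition table
#' @return mesh with updated \code{node_props}
#' @export
activate_region <- function(mesh, target = "brain", multiplier = 1.1,
                            basis = spectral_basis(),
                            compositions = tissue_compositions()) {
  stopifnot(inherits(mesh, "tetra_mesh"), multiplier > 0)
  if (is.null(mesh$node_props)) stop("assign_properties() first")
  lab <- TISSUE_LABELS[target]
  if (is.na(lab)) stop("unknown tissue: ", target)
  if (!any(mesh$node_label == lab)) stop("target tissue absent from mesh")
  row <- compositions[compositions$tissue == target, ]
  row$B <- row$B * multiplier
  if (row$B > 1) stop("activated blood fraction exceeds 1")
  comp <- tissue_composition(row$B, row$S, row$W, row$M, row$F, row$a, row$b)
  mu_a <- compose_mu_a(comp, basis, mesh$lambda)
  mus <- power_law_mus(row$a, row$b, mesh$lambda) / 10
  sel <- mesh$node_label == lab
  mesh$node_props$mu_a[sel] <- mu_a
  mesh$node_props$mu_s_prime[sel] <- mus
  mesh$node_props$kappa[sel] <- 1 / (3 * (mu_a + mus))
  mesh
}

#' Tissue-sensitivity index
#'
#' TS = log10(Phi_0) - log10(Phi_active) per channel: the log-ratio of
#' baseline to activated detector amplitude. Positive for absorption-
#' increasing activations.
#'
#' @param phi0,phi_active matched positive channel amplitude vectors
#' @return TS per channel (log10 units)
#' @export
ts_index <- function(phi0, phi_active) {
  if (length(phi0) != length(phi_active)) stop("channel sets must match")
  if (any(phi0 <= 0) || any(phi_active <= 0))
    stop("amplitudes must be positive")
  log10(phi0 / phi_active)
}

#' Jacobian depth-sensitivity metric
#'
#' Per channel: max |J| over target-tissue nodes divided by max |J| over all
#' nodes. Lies in [0, 1]; invariant to global scaling of J.
#'
#' @param J channels-x-nodes Jacobian matrix
#' @param mesh the mesh (for node labels)
#' @param target target tissue name
#' @return fraction per channel
#' @export
jacobian_depth_metric <- function(J, mesh, target = "brain") {
  lab <- TISSUE_LABELS[target]
  if (is.na(lab)) stop("unknown tissue: ", target)
  sel <- mesh$node_label == lab
  if (!any(sel)) stop("target tissue absent from mesh")
  aJ <- abs(J)
  apply(aJ[, sel, drop = FALSE], 1, max) / apply(aJ, 1, max)
}

#' Regularized flatfield back-projection
#'
#' Probes where a uniform relative absorption increase (default 1%) is seen
#' by a channel group: forward-projects dPhi = J dmu_a with
#' dmu_a = flat_frac * mu_a, then inverts with the two-part diagonal
#' regularization L = diag(J'J) + alpha (alpha = 1e-2 max diag(J'J)),
#' M = diag(JhJh') + beta (beta = 1e-2 max diag(JhJh'), Jh = J L^-1) and a
#' Tikhonov identity weight: dmu_rec = L^-1 Jt' (Jt Jt' + lambda I)^-1 dPhi~.
#' The depth (distance from the outer surface) of the maximum reconstructed
#' value summarizes the group's depth sensitivity.
#'
#' @param J channels-x-nodes Jacobian of one channel group
#' @param mu_a nodal absorption, mm^-1
#' @param mesh optional mesh; enables the depth summary
#' @param flat_frac flatfield fraction (default 0.01)
#' @param lambda_reg Tikhonov weight on the identity (default 1)
#' @param sqrt_diag use diag^(1/2) scaling instead of the literal diagonal
#'   inverses (compatibility convention)
#' @return list: \code{dmu_rec} per node, \code{percent_map} (of the group
#'   maximum), \code{node_of_max}, \code{depth_of_max} (mm, NA without mesh),
#'   \code{dropped} zero-row channels
#' @export
flatfield_reconstruct <- function(J, mu_a, mesh = NULL, flat_frac = 0.01,
                                  lambda_reg = 1, sqrt_diag = FALSE) {
  J <- as.matrix(J)
  if (!nrow(J)) stop("empty channel group")
  zr <- rowSums(abs(J)) == 0
  if (any(zr)) {
    warning(sum(zr), " zero-row channels dropped")
    J <- J[!zr, , drop = FALSE]
  }
  dmu_true <- flat_frac * mu_a
  dphi <- as.vector(J %*% dmu_true)
  dJtJ <- colSums(J^2)
  alpha <- 1e-2 * max(dJtJ)
  L <- dJtJ + alpha
  Ls <- if (sqrt_diag) sqrt(L) else L
  Jh <- sweep(J, 2, Ls, "/")
  dJJt <- rowSums(Jh^2)
  beta <- 1e-2 * max(dJJt)
  M <- dJJt + beta
  Ms <- if (sqrt_diag) sqrt(M) else M
  Jt <- Jh / Ms
  dphit <- dphi / Ms
  G <- tcrossprod(Jt)
  diag(G) <- diag(G) + lambda_reg
  x <- solve(G, dphit)
  dmu <- as.vector(crossprod(Jt, x)) / Ls
  imax <- which.max(dmu)
  depth <- if (is.null(mesh)) NA_real_ else node_depths(mesh)[imax]
  list(dmu_rec = dmu, percent_map = 100 * dmu / dmu[imax],
       node_of_max = imax, depth_of_max = depth, dropped = which(zr))
}

#' Power collected by a large surface detector
#'
#' Approximates a detector of area A by a square grid of sub-detectors laid
#' out in the local tangent plane of the surface at the detector center, each
#' sampling the fluence rate (projected back onto the surface when the
#' tangent plane leaves it): P = (A/N) sum(Phi_n).
#'
#' @param forward a \code{forward_result}
#' @param source_id source optode id whose field is measured
#' @param center detector center position (length-3, mm) on the surface
#' @param grid_n sub-detectors per side (51 x 51 = 2601 by default)
#' @param spacing sub-detector spacing, mm
#' @param area detector area, mm^2 (default ((grid_n-1) spacing)^2, i.e.
#'   100 mm^2 for the defaults)
#' @return power P (per s, relative to unit source), with attributes
#'   \code{n_offsurface} and \code{area}
#' @export
large_detector_power <- function(forward, source_id, center, grid_n = 51,
                                 spacing = 0.2, area = NULL) {
  system <- forward$system
  mesh <- system$mesh
  if (is.null(area))
    area <- if (grid_n > 1) ((grid_n - 1) * spacing)^2 else spacing^2
  s <- mesh$surface
  sn <- mesh$nodes[s$nodes, , drop = FALSE]
  i0 <- which.min(rowSums(sweep(sn, 2, center)^2))
  nrm <- s$node_normal[s$nodes[i0], ]
  e <- c(1, 0, 0); if (abs(nrm[1]) > 0.9) e <- c(0, 1, 0)
  t1 <- c(nrm[2] * e[3] - nrm[3] * e[2], nrm[3] * e[1] - nrm[1] * e[3],
          nrm[1] * e[2] - nrm[2] * e[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2], nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  off <- (seq_len(grid_n) - (grid_n + 1) / 2) * spacing
  g <- expand.grid(u = off, v = off)
  pts <- matrix(rep(center, each = nrow(g)), ncol = 3) +
    outer(g$u, t1) + outer(g$v, t2)
  # project each point onto the surface along the local normal
  jn <- .knearest(sn, pts, 1)[, 1]
  nj <- s$node_normal[s$nodes[jn], , drop = FALSE]
  d <- rowSums((pts - sn[jn, , drop = FALSE]) * nj)
  pts <- pts - (d + 1e-6) * nj  # 1e-6 nudge inward for interpolation
  n_proj <- sum(abs(d) > spacing)
  if (n_proj > 0)
    warning(n_proj, " sub-detectors projected onto the surface from > ",
            "one grid spacing away")
  phi <- forward$phi[, as.character(source_id)]
  vals <- interpolate_field(system, phi, pts)
  P <- area / nrow(pts) * sum(vals)
  attr(P, "n_offsurface") <- attr(vals, "n_offsurface")
  attr(P, "area") <- area
  P
}

#' Detector power metrics
#'
#' From baseline and activated detector powers: Delta P = P0 - Pactive,
#' Pmax = max(P0, Pactive), and the required dynamic range Pmax/DeltaP
#' (its reciprocal DeltaP/Pmax is also reported).
#'
#' @param P0,Pactive positive powers
#' @return list of class \code{detector_power_metrics}: \code{P0},
#'   \code{Pactive}, \code{delta_P}, \code{P_max}, \code{dynamic_range},
#'   \code{delta_over_pmax}, \code{flagged} (TRUE when Delta P = 0)
#' @export
detector_power_metrics <- function(P0, Pactive) {
  if (P0 <= 0 || Pactive <= 0) stop("powers must be positive")
  dP <- P0 - Pactive
  Pm <- max(P0, Pactive)
  flagged <- dP == 0
  list(P0 = as.numeric(P0), Pactive = as.numeric(Pactive),
       delta_P = dP, P_max = Pm,
       dynamic_range = if (flagged) Inf else Pm / dP,
       delta_over_pmax = dP / Pm,
       flagged = flagged)
}
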