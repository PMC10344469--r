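#' Place optodes on the mesh surface
#'
#' Chooses \code{n_slices} equidistant cross-sections along the body (z)
#' axis; on each slice places \code{per_slice} optodes at radially
#' equidistant target angles around the axis, snapped to the nearest surface
#' node. Optodes are then greedily pruned in placement order (ascending
#' slice, then angle) until no pair lies within the exclusion radius, and the
#' retained optodes alternate source/detector in placement order.
#'
#' @param mesh a \code{tetra_mesh}
#' @param n_slices number of slices along the body axis
#' @param per_slice optodes per slice
#' @param exclusion minimum allowed pairwise distance, mm
#' @return object of class \code{optode_set}: data.frame with position,
#'   inward normal, role, slice and angular indices; the blowhole landmark
#'   (if present) is carried in \code{attr(, "landmark_mm")}
#' @export
place_optodes <- function(mesh, n_slices = 11, per_slice = 21,
                          exclusion = 10) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  s <- mesh$surface
  sn <- s$nodes
  if (length(sn) < per_slice) stop("surface too small for optode placement")
  pos <- mesh$nodes[sn, , drop = FALSE]
  nrm <- s$node_normal[sn, , drop = FALSE]
  zr <- range(pos[, 3])
  zs <- seq(zr[1], zr[2], length.out = n_slices + 2)[2:(n_slices + 1)]
  tol <- max(mesh$voxel_pitch) * 0.75
  cand <- list()
  for (si in seq_along(zs)) {
    sel <- which(abs(pos[, 3] - zs[si]) <= tol)
    k <- 1
    while (length(sel) < per_slice && k < 8) {
      k <- k + 1
      sel <- which(abs(pos[, 3] - zs[si]) <= k * tol)
    }
    if (length(sel) < 3) next
    cx <- mean(pos[sel, 1]); cy <- mean(pos[sel, 2])
    ang <- atan2(pos[sel, 1] - cx, pos[sel, 2] - cy)  # 0 at dorsal (+y)
    targets <- seq(-pi, pi, length.out = per_slice + 1)[seq_len(per_slice)]
    for (ai in seq_len(per_slice)) {
      dd <- abs(atan2(sin(ang - targets[ai]), cos(ang - targets[ai])))
      j <- sel[which.min(dd)]
      cand[[length(cand) + 1]] <- c(node = j, slice = si, angular = ai)
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, "node"]), , drop = FALSE]
  # greedy pruning in placement order (cand[, "node"] are rows of pos)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- pos[cand[i, "node"], ]
    if (length(keep)) {
      q <- pos[cand[keep, "node"], , drop = FALSE]
      if (min(sqrt(rowSums(sweep(q, 2, p)^2))) < exclusion) next
    }
    keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  ridx <- cand[, "node"]
  out <- data.frame(id = seq_len(nrow(cand)),
                    x = pos[ridx, 1], y = pos[ridx, 2], z = pos[ridx, 3],
                    nx = -nrm[ridx, 1], ny = -nrm[ridx, 2],
                    nz = -nrm[ridx, 3],
                    role = rep_len(c("source", "detector"), nrow(cand)),
                    slice_index = cand[, "slice"],
                    angular_index = cand[, "angular"],
                    node = sn[ridx])
  class(out) <- c("optode_set", "data.frame")
  attr(out, "landmark_mm") <- mesh$landmark_blowhole_mm
  out
}

#' Place optodes at given approximate surface positions
#'
#' Snaps each requested position to the nearest surface node and fills in the
#' inward normal; used for bench geometries (slabs, cubes) where the regular
#' slice-based placement of \code{\link{place_optodes}} does not apply.
#'
#' @param mesh a \code{tetra_mesh}
#' @param positions n-x-3 matrix of approximate positions, mm
#' @param roles character vector (\code{"source"}/\code{"detector"}),
#'   recycled; default alternates
#' @return an \code{optode_set}
#' @export
surface_optodes <- function(mesh, positions,
                            roles = c("source", "detector")) {
  positions <- matrix(positions, ncol = 3)
  sn <- mesh$surface$nodes
  spos <- mesh$nodes[sn, , drop = FALSE]
  idx <- .knearest(spos, positions, 1)[, 1]
  nodes <- sn[idx]
  out <- data.frame(id = seq_along(nodes),
                    x = mesh$nodes[nodes, 1], y = mesh$nodes[nodes, 2],
                    z = mesh$nodes[nodes, 3],
                    nx = -mesh$surface$node_normal[nodes, 1],
                    ny = -mesh$surface$node_normal[nodes, 2],
                    nz = -mesh$surface$node_normal[nodes, 3],
                    role = rep_len(roles, length(nodes)),
                    slice_index = 1L, angular_index = seq_along(nodes),
                    node = nodes)
  class(out) <- c("optode_set", "data.frame")
  attr(out, "landmark_mm") <- mesh$landmark_blowhole_mm
  out
}

#' Build source-detector channels
#'
#' All and only source-detector pairs whose straight-line separation lies in
#' [dmin, dmax], with channel midpoints and polar coordinates: the angle is
#' measured around the body (z) axis with 180 deg at the dorsal midsagittal
#' plane, and the longitudinal offset is measured caudally (+z) from the
#' blowhole landmark when one is available.
#'
#' @param optodes an \code{optode_set}
#' @param dmin,dmax separation limits, mm
#' @return object of class \code{channel_set} (data.frame); empty (0 rows,
#'   with attribute \code{empty}) when no pair qualifies
#' @export
build_channels <- function(optodes, dmin = 50, dmax = 120) {
  src <- optodes[optodes$role == "source", ]
  det <- optodes[optodes$role == "detector", ]
  g <- expand.grid(si = seq_len(nrow(src)), di = seq_len(nrow(det)))
  ps <- as.matrix(src[g$si, c("x", "y", "z")])
  pd <- as.matrix(det[g$di, c("x", "y", "z")])
  sep <- sqrt(rowSums((ps - pd)^2))
  ok <- sep >= dmin & sep <= dmax
  mid <- (ps[ok, , drop = FALSE] + pd[ok, , drop = FALSE]) / 2
  lm <- attr(optodes, "landmark_mm")
  zbh <- if (is.null(lm)) 0 else lm[3]
  out <- data.frame(src = src$id[g$si[ok]], det = det$id[g$di[ok]],
                    separation_mm = sep[ok],
                    mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
                    angle_deg = (atan2(mid[, 1], mid[, 2]) * 180 / pi + 180) %% 360,
                    caudal_offset_mm = mid[, 3] - zbh)
  rownames(out) <- NULL
  class(out) <- c("channel_set", "data.frame")
  if (!nrow(out)) attr(out, "empty") <- TRUE
  out
}

#' Bin channels by source-detector separation
#'
#' Half-open 10-mm bins over [50, 120] mm by default ([50,60), ...,
#' [110,120]); the last bin is closed.
#'
#' @param channels a \code{channel_set}
#' @param bin_width bin width, mm
#' @param range separation range, mm
#' @return the channels with a \code{bin} column, plus attributes
#'   \code{breaks} and \code{groups} (list of per-bin row indices)
#' @export
bin_channels <- function(channels, bin_width = 10, range = c(50, 120)) {
  nb <- (range[2] - range[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("range must be a multiple of bin_width")
  nb <- as.integer(round(nb))
  bin <- pmin(nb, floor((channels$separation_mm - range[1]) / bin_width) + 1)
  if (any(bin < 1 | channels$separation_mm > range[2]))
    stop("channels outside binning range")
  channels$bin <- as.integer(bin)
  attr(channels, "breaks") <- seq(range[1], range[2], by = bin_width)
  attr(channels, "groups") <- split(seq_len(nrow(channels)), channels$bin)
  channels
}
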