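#' Write a labeled volume as NIfTI (+ JSON sidecar)
#'
#' Labels are stored as int16 with the voxel size in the header; landmarks
#' and metadata go to a JSON sidecar next to the image. Requires the RNifti
#' package.
#'
#' @param vol a \code{labeled_volume}
#' @param path output path (.nii or .nii.gz)
#' @return invisibly, the sidecar path
#' @export
write_labeled_volume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI volumes")
  arr <- array(as.integer(vol$labels), dim(vol$labels))
  attr(arr, "pixdim") <- vol$voxel_size
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(origin_mm = vol$origin,
                            landmark_blowhole_voxel = vol$landmark_blowhole,
                            meta = vol$meta["skin_to_brain_mm"]),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a labeled volume from NIfTI (+ JSON sidecar)
#'
#' @param path NIfTI file written by \code{\link{write_labeled_volume}}
#' @return a \code{labeled_volume}
#' @export
read_labeled_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI volumes")
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list()
  labeled_volume(array(as.integer(img), dim(img)),
                 voxel_size = RNifti::pixdim(img)[1:3],
                 origin = meta$origin_mm %||% c(0, 0, 0),
                 landmark_blowhole = meta$landmark_blowhole_voxel,
                 meta = as.list(meta$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Unstructured grid with the tissue label and any extra nodal scalar fields
#' as point data.
#'
#' @param mesh a \code{tetra_mesh}
#' @param path output .vtk path
#' @param fields optional named list of per-node numeric vectors
#' @export
write_vtk_mesh <- function(mesh, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "tetra mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, scientific = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$node_label), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(fields[[nm]], scientific = TRUE, digits = 9), con)
  }
  invisible(path)
}

#' Write a tetrahedral mesh in Gmsh MSH 2.2 ASCII format
#'
#' Tissue labels are written as the elements' physical tags.
#'
#' @param mesh a \code{tetra_mesh}
#' @param path output .msh path
#' @export
write_msh_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  utils::write.table(cbind(seq_len(n),
                           format(mesh$nodes, scientific = TRUE, digits = 9)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  utils::write.table(cbind(seq_len(m), 4L, 2L, mesh$elem_label,
                           mesh$elem_label, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write optodes and channels as CSV
#'
#' @param optodes an \code{optode_set}
#' @param channels a \code{channel_set}
#' @param dir output directory
#' @return invisibly, the two file paths
#' @export
write_layout_csv <- function(optodes, channels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  po <- file.path(dir, "optodes.csv"); pc <- file.path(dir, "channels.csv")
  utils::write.csv(as.data.frame(optodes)[, c("id", "x", "y", "z", "role",
                                              "slice_index",
                                              "angular_index")],
                   po, row.names = FALSE)
  utils::write.csv(as.data.frame(channels), pc, row.names = FALSE)
  invisible(c(po, pc))
}

#' Read a multi-distance FD-NIRS record from CSV
#'
#' Long format with columns time_s, distance_mm, AC, DC, phase_rad (or
#' phase_deg with \code{phase_unit = "deg"}); modulation frequency and medium
#' refractive index are passed as arguments or read from
#' \code{# key: value} header comment lines.
#'
#' @param path CSV path
#' @param mod_freq modulation frequency, Hz (overrides header)
#' @param medium_ri medium refractive index (overrides header)
#' @param phase_unit \code{"rad"} or \code{"deg"}
#' @return an \code{fd_record}
#' @export
read_fd_csv <- function(path, mod_freq = NULL, medium_ri = NULL,
                        phase_unit = c("rad", "deg")) {
  phase_unit <- match.arg(phase_unit)
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  get_hdr <- function(key) {
    ln <- grep(paste0(key, ":"), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*:", "", ln[1])) else NULL
  }
  mod_freq <- mod_freq %||% get_hdr("mod_freq_hz") %||% 130e6
  medium_ri <- medium_ri %||% get_hdr("medium_ri") %||% 1.4
  tab <- utils::read.csv(path, comment.char = "#")
  pcol <- if (phase_unit == "deg") "phase_deg" else "phase_rad"
  need <- c("time_s", "distance_mm", "AC", "DC", pcol)
  if (!all(need %in% names(tab)))
    stop("FD CSV must have columns ", paste(need, collapse = ", "))
  dists <- sort(unique(tab$distance_mm))
  times <- sort(unique(tab$time_s))
  shape <- function(col) {
    m <- matrix(NA_real_, length(times), length(dists))
    m[cbind(match(tab$time_s, times), match(tab$distance_mm, dists))] <-
      tab[[col]]
    m
  }
  fd_record(dists, shape("AC"), shape("DC"), shape(pcol),
            mod_freq = mod_freq, medium_ri = medium_ri,
            phase_unit = phase_unit)
}
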