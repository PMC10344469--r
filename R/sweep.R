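#' Select the top fraction of channels by tissue sensitivity
#'
#' The ceiling(fraction * N) channels with the largest TS; ties broken by
#' smaller channel index (deterministic).
#'
#' @param ts TS per channel
#' @param fraction fraction in (0, 1]
#' @return integer channel indices, best first
#' @export
top_percent_select <- function(ts, fraction = 0.01) {
  if (!length(ts)) stop("no channels")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * length(ts))
  order(-ts, seq_along(ts))[seq_len(k)]
}

#' Placement map of target-tissue sensitivity
#'
#' Per channel: the midpoint polar coordinates (angle from the midsagittal
#' plane around the body axis; longitudinal offset caudal of the blowhole)
#' and the maximum |J| inside the target tissue — the map used to choose
#' optode locations.
#'
#' @param J channels-x-nodes Jacobian (rows matching \code{channels})
#' @param channels a \code{channel_set}
#' @param mesh the mesh (node labels)
#' @param target target tissue name
#' @return data.frame: src, det, separation_mm, angle_deg, caudal_offset_mm,
#'   max_J_target
#' @export
placement_map <- function(J, channels, mesh, target = "brain") {
  if (!nrow(channels)) return(data.frame())
  lab <- TISSUE_LABELS[target]
  sel <- mesh$node_label == lab
  if (!any(sel)) stop("target tissue absent from mesh")
  mj <- apply(abs(J[, sel, drop = FALSE]), 1, max)
  data.frame(src = channels$src, det = channels$det,
             separation_mm = channels$separation_mm,
             angle_deg = channels$angle_deg,
             caudal_offset_mm = channels$caudal_offset_mm,
             max_J_target = mj)
}

#' Sweep configuration
#'
#' Study conditions of the wavelength/separation/size sweep. Defaults follow
#' the feasibility-study design: wavelengths 600--1700 nm in 50 nm steps,
#' separations 50--120 mm in 10 mm bins, adult (1.0) and juvenile (0.75)
#' scales, brain activation with a 10% hemoglobin increase, top-1% channel
#' averaging. \code{voxel_size} and optode counts set the desk-scale problem
#' size.
#'
#' @param wavelengths nm grid
#' @param separations c(dmin, dmax), mm
#' @param bin_width mm
#' @param scales named scale factors
#' @param activation_target \code{brain} or \code{muscle}
#' @param multiplier blood-fraction multiplier
#' @param top_fraction fraction of channels averaged
#' @param phantom a \code{phantom_config}
#' @param voxel_size phantom voxel pitch, mm
#' @param n_slices,per_slice,exclusion optode placement parameters
#' @param detector_grid_n,detector_spacing large-detector sub-grid
#' @param flatfield_lambda wavelength for flatfield/placement maps, nm
#' @param seed RNG seed (the pipeline is deterministic given the seed)
#' @return list of class \code{sweep_config}
#' @export
sweep_config <- function(wavelengths = seq(600, 1700, by = 50),
                         separations = c(50, 120), bin_width = 10,
                         scales = c(adult = 1, juvenile = 0.75),
                         activation_target = "brain", multiplier = 1.1,
                         top_fraction = 0.01,
                         phantom = phantom_config(), voxel_size = 10,
                         n_slices = 11, per_slice = 21, exclusion = 10,
                         detector_grid_n = 51, detector_spacing = 0.2,
                         flatfield_lambda = 850, seed = 1) {
  if (!length(wavelengths)) stop("wavelength grid must be nonempty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sweep_config"
  cfg
}

.fnv_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full sensitivity sweep
#'
#' For each scale factor and wavelength: build the phantom mesh, place
#' optodes and channels, solve baseline and activated forward models,
#' compute TS, select the top channels, compute Jacobian depth metrics and
#' large-detector power metrics for them, and (at
#' \code{flatfield_lambda}) flatfield depth summaries per separation bin and
#' the placement map. Deterministic given the seed.
#'
#' @param config a \code{sweep_config}
#' @param out_dir optional directory; CSV tables and a JSON manifest are
#'   written there
#' @param verbose print stage messages
#' @return list: \code{summary} (per scale x wavelength means/SDs over the
#'   top channels), \code{flatfield} (per scale x bin peak depths),
#'   \code{placement} (per scale map tables), \code{manifest}
#' @export
run_pipeline <- function(config = sweep_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  set.seed(config$seed)
  basis <- spectral_basis()
  comps <- tissue_compositions()
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  vol <- generate_phantom(config$phantom, config$voxel_size,
                          seed = config$seed)
  mesh0 <- mesh_labeled_volume(vol)
  summary_rows <- list(); ff_rows <- list(); maps <- list()
  for (sc_name in names(config$scales)) {
    sc <- config$scales[[sc_name]]
    say("scale ", sc_name, " (", sc, ")")
    mesh <- if (sc == 1) mesh0 else scale_mesh(mesh0, sc)
    optodes <- place_optodes(mesh, config$n_slices, config$per_slice,
                             config$exclusion)
    channels <- build_channels(optodes, config$separations[1],
                               config$separations[2])
    if (!nrow(channels)) stop("pipeline: empty channel set at scale ", sc)
    channels <- bin_channels(channels, config$bin_width, config$separations)
    for (lam in config$wavelengths) {
      say("  lambda ", lam, " nm")
      mesh_l <- assign_properties(mesh, lam, basis, comps)
      sys0 <- assemble_system(mesh_l)
      fwd0 <- solve_forward(sys0, optodes, channels)
      mesh_a <- activate_region(mesh_l, config$activation_target,
                                config$multiplier, basis, comps)
      fwd_a <- solve_forward(assemble_system(mesh_a), optodes, channels)
      ts <- ts_index(fwd0$amplitudes, fwd_a$amplitudes)
      top <- top_percent_select(ts, config$top_fraction)
      J_top <- compute_jacobian(fwd0, top)
      depth_m <- jacobian_depth_metric(J_top, mesh_l,
                                       config$activation_target)
      mjt <- {
        lab <- TISSUE_LABELS[config$activation_target]
        apply(abs(J_top[, mesh_l$node_label == lab, drop = FALSE]), 1, max)
      }
      P0 <- Pa <- dP <- dr <- numeric(length(top))
      for (i in seq_along(top)) {
        chd <- channels$det[top[i]]; chs <- channels$src[top[i]]
        ctr <- unlist(optodes[optodes$id == chd, c("x", "y", "z")])
        P0[i] <- large_detector_power(fwd0, chs, ctr,
                                      config$detector_grid_n,
                                      config$detector_spacing)
        Pa[i] <- large_detector_power(fwd_a, chs, ctr,
                                      config$detector_grid_n,
                                      config$detector_spacing)
        m <- detector_power_metrics(P0[i], Pa[i])
        dP[i] <- m$delta_P; dr[i] <- m$dynamic_range
      }
      sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        scale = sc_name, lambda_nm = lam, n_top = length(top),
        ts_mean = mean(ts[top]), ts_sd = sd_pop(ts[top]),
        max_j_target_mean = mean(mjt), max_j_target_sd = sd_pop(mjt),
        depth_metric_mean = mean(depth_m), depth_metric_sd = sd_pop(depth_m),
        P_mean = mean(P0), P_sd = sd_pop(P0),
        delta_P_mean = mean(dP), delta_P_sd = sd_pop(dP),
        dynamic_range_mean = mean(dr), dynamic_range_sd = sd_pop(dr),
        separation_mean = mean(channels$separation_mm[top]),
        separation_sd = sd_pop(channels$separation_mm[top]))
      if (isTRUE(lam == config$flatfield_lambda)) {
        J_all <- compute_jacobian(fwd0)
        depths <- node_depths(mesh_l)
        for (b in seq_along(attr(channels, "groups"))) {
          idx <- attr(channels, "groups")[[b]]
          if (!length(idx)) next
          ff <- flatfield_reconstruct(J_all[idx, , drop = FALSE],
                                      mesh_l$node_props$mu_a)
          ff_rows[[length(ff_rows) + 1]] <- data.frame(
            scale = sc_name, bin = as.integer(names(attr(channels,
                                                         "groups"))[b]),
            n_channels = length(idx),
            peak_depth_mm = depths[ff$node_of_max])
        }
        maps[[sc_name]] <- placement_map(J_all, channels, mesh_l,
                                         config$activation_target)
      }
    }
  }
  out <- list(summary = do.call(rbind, summary_rows),
              flatfield = if (length(ff_rows)) do.call(rbind, ff_rows),
              placement = maps,
              manifest = list(config_hash = .fnv_hash(unclass(config)),
                              n_nodes = nrow(mesh0$nodes),
                              n_elements = nrow(mesh0$elems),
                              package_version =
                                as.character(utils::packageVersion("cetanirs")),
                              elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(out$flatfield))
      utils::write.csv(out$flatfield,
                       file.path(out_dir, "flatfield_depths.csv"),
                       row.names = FALSE)
    for (nm in names(maps))
      utils::write.csv(maps[[nm]],
                       file.path(out_dir, paste0("placement_map_", nm,
                                                 ".csv")),
                       row.names = FALSE)
    man <- out$manifest; man$elapsed_s <- NULL  # keep outputs reproducible
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
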