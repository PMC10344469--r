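SPEED_OF_LIGHT_MM_S <- 2.99792458e11  # mm/s

#' Multi-distance frequency-domain NIRS record
#'
#' Container for a multi-distance FD measurement: AC amplitude, DC amplitude
#' and phase per time frame and source-detector distance, with the modulation
#' frequency and medium refractive index (which fixes the light speed
#' v = c/ri used in property estimation).
#'
#' @param distances source-detector distances, mm, strictly increasing (>= 2)
#' @param AC,DC,phase numeric matrices, frames x distances (vectors are
#'   treated as a single frame); AC and DC must be positive, phase in radians
#'   unless \code{phase_unit = "deg"}
#' @param mod_freq modulation frequency, Hz
#' @param medium_ri refractive index of the medium
#' @param phase_unit \code{"rad"} (default) or \code{"deg"}
#' @return object of class \code{fd_record}
#' @export
fd_record <- function(distances, AC, DC, phase, mod_freq = 130e6,
                      medium_ri = 1.4, phase_unit = c("rad", "deg")) {
  phase_unit <- match.arg(phase_unit)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  AC <- as_mat(AC); DC <- as_mat(DC); phase <- as_mat(phase)
  if (phase_unit == "deg") phase <- phase * pi / 180
  nd <- length(distances)
  if (nd < 2 || any(diff(distances) <= 0))
    stop("need >= 2 strictly increasing distances")
  if (ncol(AC) != nd || ncol(DC) != nd || ncol(phase) != nd)
    stop("AC/DC/phase must have one column per distance")
  structure(list(distances = distances, AC = AC, DC = DC, phase = phase,
                 mod_freq = mod_freq, medium_ri = medium_ri),
            class = "fd_record")
}

#' Simulate a semi-infinite frequency-domain record
#'
#' Generates AC, DC and phase over distance from the asymptotic semi-infinite
#' diffusion solution: with complex wavenumber k, k^2 = (mu_a + i w/v)/kappa,
#' the modulated fluence decays as exp(-Re(k) r)/r^2 with phase Im(k) r; the
#' DC component uses w = 0. This is the generating model inverted by
#' \code{\link{multi_distance_fit}}.
#'
#' @param mu_a,mu_s_prime true optical properties, mm^-1
#' @param distances source-detector distances, mm
#' @param mod_freq modulation frequency, Hz
#' @param medium_ri refractive index (sets v = c/ri)
#' @param n_frames number of time frames
#' @param amplitude source amplitude scale
#' @param phase_offset instrumental phase offset, radians
#' @param mod_depth source modulation depth (AC/DC at the source)
#' @param noise_sd relative (multiplicative) amplitude noise and absolute
#'   phase noise sd, radians; 0 gives a noiseless record
#' @param seed optional RNG seed
#' @return an \code{fd_record}
#' @export
simulate_fd_record <- function(mu_a, mu_s_prime, distances = c(9, 18, 27, 36),
                               mod_freq = 130e6, medium_ri = 1.4,
                               n_frames = 1, amplitude = 1e6,
                               phase_offset = 0.3, mod_depth = 0.9,
                               noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- SPEED_OF_LIGHT_MM_S / medium_ri
  kappa <- 1 / (3 * (mu_a + mu_s_prime))
  omega <- 2 * pi * mod_freq
  k_ac <- sqrt(complex(real = mu_a, imaginary = omega / v) / kappa)
  k_dc <- sqrt(mu_a / kappa)
  ac0 <- amplitude * mod_depth * exp(-Re(k_ac) * distances) / distances^2
  ph0 <- Im(k_ac) * distances + phase_offset
  dc0 <- amplitude * exp(-k_dc * distances) / distances^2
  one <- function(base, rel) base * matrix(exp(stats::rnorm(n_frames * length(base),
                                                            0, rel)),
                                           n_frames, length(base), byrow = FALSE)
  AC <- matrix(ac0, n_frames, length(distances), byrow = TRUE)
  DC <- matrix(dc0, n_frames, length(distances), byrow = TRUE)
  PH <- matrix(ph0, n_frames, length(distances), byrow = TRUE)
  if (noise_sd > 0) {
    AC <- AC * exp(matrix(stats::rnorm(length(AC), 0, noise_sd), nrow(AC)))
    DC <- DC * exp(matrix(stats::rnorm(length(DC), 0, noise_sd), nrow(DC)))
    PH <- PH + matrix(stats::rnorm(length(PH), 0, noise_sd), nrow(PH))
  }
  fd_record(distances, AC, DC, PH, mod_freq, medium_ri)
}

#' Modulation-percentage quality control
#'
#' A frame is retained iff the modulation percentage AC/DC exceeds the
#' threshold at every distance and all values are finite and unsaturated.
#'
#' @param record an \code{fd_record}
#' @param threshold modulation threshold (default 0.20, i.e. mod% > 20%)
#' @param saturation optional upper bound on DC counts; frames at or above it
#'   are rejected
#' @return logical vector, one entry per frame (TRUE = retained); an
#'   all-FALSE result carries attribute \code{empty = TRUE}
#' @export
qc_modulation <- function(record, threshold = 0.20, saturation = Inf) {
  stopifnot(inherits(record, "fd_record"))
  mod <- record$AC / record$DC
  ok <- is.finite(mod) & mod > threshold &
    is.finite(record$phase) & record$DC < saturation & record$AC > 0 &
    record$DC > 0
  mask <- apply(ok, 1, all)
  if (!any(mask)) attr(mask, "empty") <- TRUE
  mask
}

#' Multi-distance frequency-domain property estimation
#'
#' Standard semi-infinite slope method: straight-line fits over distance of
#' ln(r^2 AC) (slope S_AC) and phase (slope S_ph) give
#' mu_a = (w/2v) (S_ph/S_AC - S_AC/S_ph) and
#' mus' = (S_AC^2 - S_ph^2)/(3 mu_a) - mu_a.
#' Estimates are gain- and phase-offset-invariant. Frames failing QC (or with
#' slopes of the wrong sign: S_AC must be negative, S_ph positive) are
#' flagged.
#'
#' @param record an \code{fd_record}
#' @param qc apply \code{\link{qc_modulation}} first (default TRUE)
#' @param threshold modulation threshold passed to QC
#' @return list with per-frame vectors \code{mu_a}, \code{mu_s_prime},
#'   \code{ok}, and scalars \code{mu_a_mean}, \code{mu_s_prime_mean}
#'   (means over valid frames)
#' @export
multi_distance_fit <- function(record, qc = TRUE, threshold = 0.20) {
  stopifnot(inherits(record, "fd_record"))
  keep <- if (qc) qc_modulation(record, threshold) else rep(TRUE, nrow(record$AC))
  r <- record$distances
  v <- SPEED_OF_LIGHT_MM_S / record$medium_ri
  omega <- 2 * pi * record$mod_freq
  n <- nrow(record$AC)
  mu_a <- mu_s <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  slope <- function(y) {
    rc <- r - mean(r)
    sum(rc * (y - mean(y))) / sum(rc^2)
  }
  for (i in seq_len(n)) {
    if (!keep[i]) next
    s_ac <- slope(log(r^2 * record$AC[i, ]))
    s_ph <- slope(record$phase[i, ])
    if (!is.finite(s_ac) || !is.finite(s_ph) || s_ac >= 0 || s_ph <= 0) next
    ma <- (omega / (2 * v)) * (s_ph / s_ac - s_ac / s_ph)
    ms <- (s_ac^2 - s_ph^2) / (3 * ma) - ma
    if (is.finite(ma) && is.finite(ms) && ma > 0 && ms > 0) {
      mu_a[i] <- ma; mu_s[i] <- ms; ok[i] <- TRUE
    }
  }
  list(mu_a = mu_a, mu_s_prime = mu_s, ok = ok,
       mu_a_mean = if (any(ok)) mean(mu_a[ok]) else NA_real_,
       mu_s_prime_mean = if (any(ok)) mean(mu_s[ok]) else NA_real_)
}

#' Median after interquartile-range outlier exclusion
#'
#' Removes values farther than 1.5 IQR outside [Q1, Q3], then takes the
#' median of the remainder.
#'
#' @param values numeric vector with at least one finite value
#' @return scalar median of the retained values
#' @export
robust_median <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  stats::median(values[keep])
}

#' Broadband absorbance spectrum
#'
#' @param wavelength ascending wavelength grid, nm
#' @param absorbance absorbance values (arbitrary units)
#' @param integration_time integration time, s (metadata)
#' @return object of class \code{absorbance_spectrum}
#' @export
absorbance_spectrum <- function(wavelength, absorbance, integration_time = NA) {
  if (any(diff(wavelength) <= 0)) stop("wavelength grid must be ascending")
  if (length(wavelength) != length(absorbance)) stop("length mismatch")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 integration_time = integration_time),
            class = "absorbance_spectrum")
}

#' Boxcar smoothing with edge truncation
#'
#' Moving average over \code{width} samples; the window shrinks at the
#' spectrum boundaries. Width 15 on a ~0.28 nm grid corresponds to about
#' 4.2 nm.
#'
#' @param spectrum an \code{absorbance_spectrum}
#' @param width odd window width in samples
#' @return smoothed \code{absorbance_spectrum} on the same grid
#' @export
smooth_boxcar <- function(spectrum, width = 15) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  n <- length(spectrum$absorbance)
  if (width < 1 || width %% 2 != 1) stop("width must be odd and >= 1")
  if (width > n) stop("width exceeds spectrum length")
  h <- (width - 1) / 2
  cs <- c(0, cumsum(spectrum$absorbance))
  i <- seq_len(n)
  lo <- pmax(1, i - h); hi <- pmin(n, i + h)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  absorbance_spectrum(spectrum$wavelength, sm, spectrum$integration_time)
}

#' Calibrate absorbance to absolute absorption
#'
#' Least-squares affine map (gain and, by default, offset) from absorbance to
#' FD-NIRS-measured mu_a at anchor wavelengths in 700--900 nm, applied to the
#' whole spectrum.
#'
#' @param spec an \code{absorbance_spectrum}
#' @param anchors data.frame with columns \code{lambda} (nm) and \code{mu_a}
#'   (mm^-1); at least two anchors inside 700--900 nm
#' @param offset include an offset term (default TRUE); FALSE fits gain only
#' @return list: \code{lambda}, calibrated \code{mu_a}, \code{gain},
#'   \code{offset}, anchor \code{residuals}
#' @export
calibrate_absorbance <- function(spec, anchors, offset = TRUE) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  anchors <- anchors[anchors$lambda >= 700 & anchors$lambda <= 900, ]
  if (nrow(anchors) < 2) stop("need >= 2 anchors inside 700-900 nm")
  at_anchor <- stats::approx(spec$wavelength, spec$absorbance,
                             anchors$lambda)$y
  if (any(is.na(at_anchor))) stop("anchors outside spectrum grid")
  fit <- if (offset) stats::lm(anchors$mu_a ~ at_anchor)
         else stats::lm(anchors$mu_a ~ at_anchor - 1)
  cf <- stats::coef(fit)
  g <- if (offset) cf[[2]] else cf[[1]]
  o <- if (offset) cf[[1]] else 0
  list(lambda = spec$wavelength,
       mu_a = g * spec$absorbance + o,
       gain = g, offset = o,
       residuals = stats::residuals(fit))
}

#' Bounded least-squares chromophore composition fit
#'
#' Fits (B, S, W, M, F) of the composition model
#' \code{\link{compose_mu_a}} to an absolute absorption spectrum over
#' 700--900 nm by bounded nonlinear least squares (L-BFGS-B from the fixed
#' midpoint of the bounds; optional deterministic multistart). Lower bounds
#' default to 20% fat and 10% water to keep the fit in a blubber-like regime.
#'
#' @param lambda wavelengths, nm (must cover 700--900 nm)
#' @param mu_a measured absorption, mm^-1
#' @param basis a \code{spectral_basis}
#' @param lower,upper named bounds for B, S, W, M, F
#' @param multistart number of additional fixed starting points (0 = single
#'   midpoint start)
#' @return list with the fitted \code{composition}, \code{residual} (sum of
#'   squares), \code{converged}
#' @export
fit_composition <- function(lambda, mu_a, basis = spectral_basis(),
                            lower = c(B = 0, S = 0, W = 0.1, M = 0, F = 0.2),
                            upper = c(B = 1, S = 1, W = 1, M = 1, F = 1),
                            multistart = 0) {
  if (min(lambda) > 701 || max(lambda) < 899)
    stop("spectrum must cover 700-900 nm")
  sel <- lambda >= 700 & lambda <= 900
  lam <- lambda[sel]; y <- mu_a[sel]
  X <- cbind(HbO = basis$funs$HbO(lam), HbR = basis$funs$HbR(lam),
             water = basis$funs$water(lam), melanin = basis$funs$melanin(lam),
             fat = basis$funs$fat(lam))
  nm <- c("B", "S", "W", "M", "F")
  lo <- lower[nm]; up <- upper[nm]
  # The model is linear in q = (B*S, B*(1-S), W, M, F), so the bounded fit is
  # a convex least-squares problem: solve it exactly by bounded L-BFGS-B with
  # analytic gradient from the deterministic midpoint start (the convexity
  # makes the optional multistart a no-op safeguard).
  qlo <- c(0, 0, lo[c("W", "M", "F")])
  qup <- c(up["B"], up["B"], up[c("W", "M", "F")])
  obj <- function(q) { r <- X %*% q - y; sum(r * r) }
  grad <- function(q) as.vector(2 * crossprod(X, X %*% q - y))
  starts <- list((qlo + qup) / 2)
  if (multistart > 0) {
    fr <- seq(0.15, 0.85, length.out = multistart)
    starts <- c(starts, lapply(fr, function(f) qlo + f * (qup - qlo)))
  }
  best <- NULL
  for (q0 in starts) {
    res <- stats::optim(q0, obj, grad, method = "L-BFGS-B",
                        lower = qlo, upper = qup,
                        control = list(maxit = 5000, factr = 1, pgtol = 0))
    if (is.null(best) || res$value < best$value) best <- res
  }
  q <- as.numeric(best$par)
  # polish with an equality-constrained solve on the active set
  q <- .polish_bounded_ls(X, y, q, qlo, qup)
  B <- q[1] + q[2]
  S <- if (B > 0) q[1] / B else 0.5
  B <- min(max(B, lo["B"]), up["B"])
  S <- min(max(S, lo["S"]), up["S"])
  p <- stats::setNames(c(B, S, q[3], q[4], q[5]), nm)
  list(composition = tissue_composition(p["B"], p["S"], p["W"], p["M"], p["F"]),
       residual = sum((X %*% q - y)^2),
       converged = best$convergence == 0)
}

# Active-set polish for the bounded linear least-squares step: variables at
# (or numerically near) a bound whose KKT multiplier keeps them there are
# clamped, the free ones re-solved by QR; repeats until the active set is
# stable.
.polish_bounded_ls <- function(X, y, q, qlo, qup, tol = 1e-9, maxit = 20) {
  for (it in seq_len(maxit)) {
    at_lo <- q <= qlo + tol; at_up <- q >= qup - tol
    g <- as.vector(2 * crossprod(X, X %*% q - y))
    active <- (at_lo & g >= -tol) | (at_up & g <= tol)
    if (all(active)) break
    free <- which(!active)
    qf <- q; qf[at_lo & !seq_along(q) %in% free] <- qlo[at_lo]
    q2 <- q; q2[at_lo] <- qlo[at_lo]; q2[at_up] <- qup[at_up]
    rhs <- y - X[, active, drop = FALSE] %*% q2[active]
    sol <- qr.solve(X[, free, drop = FALSE], rhs)
    sol <- pmin(pmax(sol, qlo[free]), qup[free])
    q2[free] <- sol
    if (sum((X %*% q2 - y)^2) <= sum((X %*% q - y)^2) + tol^2) q <- q2
    else break
  }
  q
}

#' Fit the scattering power law mus' = a * lambda^-b
#'
#' Log-log linear initialization followed by Gauss-Newton refinement of the
#' untransformed least-squares problem; exact on noiseless power-law data.
#'
#' @param lambda wavelengths, nm (> 0)
#' @param mus reduced scattering values (> 0), any consistent units
#' @return list with \code{a} (units of \code{mus} times nm^b) and \code{b}
#' @export
fit_power_law <- function(lambda, mus) {
  if (length(lambda) < 2) stop("need >= 2 points")
  if (any(mus <= 0)) stop("mus' values must be > 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  cf <- stats::coef(stats::lm(log(mus) ~ log(lambda)))
  a0 <- exp(cf[[1]]); b0 <- -cf[[2]]
  # exact on noiseless power-law data: skip the refinement then
  if (max(abs(a0 * lambda^(-b0) / mus - 1)) < 1e-12)
    return(list(a = a0, b = b0))
  fit <- try(suppressWarnings(
    stats::nls(mus ~ a * lambda^(-b),
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(a = a0, b = b0))
  cf <- stats::coef(fit)
  list(a = cf[["a"]], b = cf[["b"]])
}

#' Assemble a JSON-able property report
#'
#' Bundles per-wavelength properties, the fitted composition and power law,
#' and QC counts in the pipeline's report format.
#'
#' @param tissue tissue label
#' @param lambda_nm wavelengths
#' @param mu_a,mu_s_prime property vectors, mm^-1
#' @param composition a \code{tissue_composition}
#' @param a,b fitted power-law coefficients
#' @param n_total,n_retained QC counts
#' @param path optional path; if given, the report is written as JSON
#' @return the report list, invisibly if written
#' @export
property_report <- function(tissue, lambda_nm, mu_a, mu_s_prime, composition,
                            a, b, n_total, n_retained, path = NULL) {
  rep <- list(tissue = tissue, lambda_nm = lambda_nm, mu_a = mu_a,
              mu_s_prime = mu_s_prime,
              composition = list(B = composition$B, S = composition$S,
                                 W = composition$W, M = composition$M,
                                 F = composition$F, a = a, b = b),
              qc = list(n_total = n_total, n_retained = n_retained))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
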