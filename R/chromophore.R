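#' Load a pure-absorber spectral basis
#'
#' Reads a long-format table of pure-chromophore absorption spectra
#' (columns \code{wavelength_nm}, \code{absorber}, \code{mu_a_per_mm}) and
#' returns an object that linearly interpolates each absorber between its
#' tabulated wavelengths. The packaged default is an approximate compilation
#' of standard literature spectra: whole-blood oxy-/deoxy-hemoglobin at
#' 150 g/L, pure water, purified fat, and the melanosome power law. The five
#' absorbers \code{HbO}, \code{HbR}, \code{water}, \code{melanin}, \code{fat}
#' must all be present and must jointly cover at least 600--1700 nm.
#'
#' @param path CSV file; default the packaged basis.
#' @return An object of class \code{spectral_basis}.
#' @export
spectral_basis <- function(path = system.file("extdata", "chromophore_basis.csv",
                                              package = "cetanirs")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "absorber", "mu_a_per_mm")
  if (!all(need %in% names(tab)))
    stop("basis table must have columns ", paste(need, collapse = ", "))
  absorbers <- c("HbO", "HbR", "water", "melanin", "fat")
  missing <- setdiff(absorbers, unique(tab$absorber))
  if (length(missing))
    stop("basis table missing absorbers: ", paste(missing, collapse = ", "))
  if (any(tab$mu_a_per_mm < 0)) stop("pure-absorber spectra must be >= 0")
  funs <- list(); rng <- c(-Inf, Inf)
  for (ab in absorbers) {
    sub <- tab[tab$absorber == ab, ]
    sub <- sub[order(sub$wavelength_nm), ]
    if (any(duplicated(sub$wavelength_nm)))
      stop("duplicated wavelengths for absorber ", ab)
    funs[[ab]] <- stats::approxfun(sub$wavelength_nm, sub$mu_a_per_mm)
    rng <- c(max(rng[1], min(sub$wavelength_nm)),
             min(rng[2], max(sub$wavelength_nm)))
  }
  if (rng[1] > 600 || rng[2] < 1700)
    stop("basis must cover at least 600-1700 nm; covers ",
         rng[1], "-", rng[2], " nm")
  structure(list(table = tab, funs = funs, range = rng),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat("<spectral_basis> absorbers:", paste(names(x$funs), collapse = ", "),
      sprintf("| coverage %g-%g nm\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Pure-absorber absorption at given wavelengths
#'
#' @param basis a \code{spectral_basis}
#' @param absorber one of \code{HbO}, \code{HbR}, \code{water},
#'   \code{melanin}, \code{fat}
#' @param lambda wavelengths, nm
#' @return absorption coefficient of the pure chromophore, mm^-1
#' @export
basis_mu_a <- function(basis, absorber, lambda) {
  stopifnot(inherits(basis, "spectral_basis"))
  f <- basis$funs[[absorber]]
  if (is.null(f)) stop("unknown absorber: ", absorber)
  .check_lambda(basis, lambda)
  f(lambda)
}

.check_lambda <- function(basis, lambda) {
  if (any(!is.finite(lambda)))
    stop("wavelengths must be finite")
  if (any(lambda < basis$range[1] | lambda > basis$range[2]))
    stop(sprintf("wavelength outside basis coverage [%g, %g] nm",
                 basis$range[1], basis$range[2]))
  invisible(TRUE)
}

#' Tissue composition for the chromophore absorption model
#'
#' Volume/weight fractions entering the absorption composition rule
#' mu_a = B*S*mu_a,HbO + B*(1-S)*mu_a,HbR + W*mu_a,water + M*mu_a,melanin
#'      + F*mu_a,fat,
#' where B is blood volume fraction relative to whole blood at 150 g/L
#' hemoglobin, S hemoglobin oxygen saturation, W water, M melanin and F fat
#' fractions. \code{a} and \code{b} parameterize reduced scattering as the
#' power law mus' = a * lambda^-b (lambda in nm, result in cm^-1 in the
#' conventional reporting units; divide by 10 for mm^-1).
#'
#' @param B,S,W,M,F fractions in [0, 1]
#' @param a,b power-law scattering coefficients (a > 0)
#' @return object of class \code{tissue_composition}
#' @export
tissue_composition <- function(B, S, W, M = 0, F = 0, a = 1, b = 1) {
  for (nm in c("B", "S", "W", "M", "F")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop(nm, " must be a fraction in [0, 1]")
  }
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  structure(list(B = unname(B), S = unname(S), W = unname(W), M = unname(M),
                 F = unname(F), a = unname(a), b = unname(b)),
            class = "tissue_composition")
}

#' Load the per-tissue composition table
#'
#' Returns the packaged (or user-supplied) table of compositions and
#' scattering power-law coefficients for the four model tissues
#' \code{brain}, \code{bone}, \code{blubber_skin}, \code{muscle}, plus
#' refractive indices. Values for brain, bone and muscle follow standard
#' tissue-optics review compilations; blubber_skin carries the fitted
#' dolphin sculp parameters.
#'
#' @param path CSV with columns tissue, B, S, W, M, F, a, b, ri
#' @return data.frame, one row per tissue
#' @export
tissue_compositions <- function(path = system.file("extdata",
                                                   "tissue_compositions.csv",
                                                   package = "cetanirs")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "B", "S", "W", "M", "F", "a", "b", "ri")
  if (!all(need %in% names(tab)))
    stop("composition table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Compose tissue absorption from chromophore fractions
#'
#' Weighted summation of pure-absorber spectra:
#' mu_a = B*S*mu_a,HbO + B*(1-S)*mu_a,HbR + W*mu_a,water
#'      + M*mu_a,melanin + F*mu_a,fat.
#'
#' @param comp a \code{tissue_composition} (or list with B,S,W,M,F)
#' @param basis a \code{spectral_basis}
#' @param lambda wavelengths, nm; must lie inside the basis coverage
#' @return absorption coefficient, mm^-1 (vector over \code{lambda})
#' @export
compose_mu_a <- function(comp, basis, lambda) {
  .check_lambda(basis, lambda)
  with(comp,
       B * S       * basis$funs$HbO(lambda) +
       B * (1 - S) * basis$funs$HbR(lambda) +
       W           * basis$funs$water(lambda) +
       M           * basis$funs$melanin(lambda) +
       F           * basis$funs$fat(lambda))
}

#' Power-law reduced scattering
#'
#' Evaluates mus' = a * lambda^-b. Units follow \code{a}: with lambda in nm
#' and \code{a} in the conventional reporting units the result is cm^-1.
#'
#' @param a scaling factor (> 0)
#' @param b exponent (unitless)
#' @param lambda wavelengths, nm (> 0)
#' @return reduced scattering coefficient in the units implied by \code{a}
#' @export
power_law_mus <- function(a, b, lambda) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (any(!is.finite(lambda) | lambda <= 0)) stop("lambda must be > 0")
  a * lambda^(-b)
}

#' Construct optical properties, deriving the diffusion coefficient
#'
#' kappa = 1/(3 (mu_a + mu_s_prime)) in mm.
#'
#' @param mu_a absorption coefficient, mm^-1 (> 0)
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0)
#' @param ri refractive index (>= 1)
#' @return list with mu_a, mu_s_prime, kappa, ri
#' @export
optical_properties <- function(mu_a, mu_s_prime, ri) {
  if (any(mu_a <= 0)) stop("mu_a must be > 0")
  if (any(mu_s_prime <= 0)) stop("mu_s_prime must be > 0")
  if (any(ri < 1)) stop("ri must be >= 1")
  kappa <- 1 / (3 * (mu_a + mu_s_prime))
  stopifnot(all(abs(kappa * 3 * (mu_a + mu_s_prime) - 1) < 1e-12))
  list(mu_a = mu_a, mu_s_prime = mu_s_prime, kappa = kappa, ri = ri)
}

#' Wavelength table of optical properties for a model tissue
#'
#' mu_a via \code{\link{compose_mu_a}} from the tissue's composition, mus'
#' via \code{\link{power_law_mus}} (converted to mm^-1), kappa derived, and
#' the fixed refractive index per tissue.
#'
#' @param tissue one of \code{brain}, \code{bone}, \code{blubber_skin},
#'   \code{muscle}
#' @param lambdas wavelengths, nm
#' @param basis spectral basis (default packaged)
#' @param compositions composition table (default packaged)
#' @return data.frame with lambda_nm, mu_a, mu_s_prime, kappa, ri
#' @export
tissue_property_table <- function(tissue, lambdas,
                                  basis = spectral_basis(),
                                  compositions = tissue_compositions()) {
  row <- compositions[compositions$tissue == tissue, ]
  if (nrow(row) != 1)
    stop("unknown tissue label: ", tissue)
  comp <- tissue_composition(row$B, row$S, row$W, row$M, row$F, row$a, row$b)
  mu_a <- compose_mu_a(comp, basis, lambdas)
  mus <- power_law_mus(row$a, row$b, lambdas) / 10  # cm^-1 -> mm^-1
  op <- optical_properties(mu_a, mus, row$ri)
  data.frame(lambda_nm = lambdas, mu_a = op$mu_a, mu_s_prime = op$mu_s_prime,
             kappa = op$kappa, ri = op$ri)
}
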