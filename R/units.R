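# Calibration of model units (sigma, model time tau) to physical
# nanometres and seconds.

#' Calibrate the model length unit sigma
#'
#' Two independent estimates are combined:
#' \itemize{
#'   \item genomic: `sigma = (s/G)^(1/3) * D`, where `s` is the genomic
#'     content per bead (bp), `G` the genome length (bp) and `D` the
#'     nucleus diameter (nm) - the bead occupies a volume fraction `s/G`
#'     of the nucleus;
#'   \item imaging: `sigma = Rg_imaging / Rg_model`, matching the
#'     model gyration radius (in sigma) to a microscopy measurement of
#'     the same locus (in nm).
#' }
#' The reference value is the arithmetic mean of the two.
#'
#' @param s genomic content per bead, bp (default 2500 = 2 Mb / 800).
#' @param G genome length, bp (default 6e9).
#' @param D nucleus diameter, nm (default 1e4 = 10 um).
#' @param rg_imaging imaged locus gyration radius, nm (default 464).
#' @param rg_model model gyration radius in sigma (default 6.4).
#' @return list of class `sbs_sigma`: `sigma_genomic`, `sigma_imaging`,
#'   `sigma_ref` (nm).
#' @export
calibrate_sigma <- function(s = 2500, G = 6e9, D = 1e4, rg_imaging = 464,
                            rg_model = 6.4) {
  stopifnot(s > 0, G > 0, D > 0, rg_imaging > 0, rg_model > 0)
  sigma_genomic <- (s / G)^(1 / 3) * D
  sigma_imaging <- rg_imaging / rg_model
  structure(list(sigma_genomic = sigma_genomic,
                 sigma_imaging = sigma_imaging,
                 sigma_ref = (sigma_genomic + sigma_imaging) / 2),
            class = "sbs_sigma")
}

#' @export
print.sbs_sigma <- function(x, ...) {
  cat(sprintf(
    "sigma calibration: genomic %.1f nm, imaging %.1f nm -> reference %.1f nm\n",
    x$sigma_genomic, x$sigma_imaging, x$sigma_ref))
  invisible(x)
}

#' Physical duration of one model time unit
#'
#' `tau = 6 pi eta sigma^3 / (kB T)`: the Brownian time of a sphere of
#' diameter sigma in a medium of viscosity eta.
#'
#' @param eta viscosity, Pa s (default 0.01, a few fractions of poise).
#' @param sigma_nm model length unit, nm.
#' @param t_kelvin absolute temperature, K.
#' @return tau in seconds.
#' @export
tau_physical <- function(eta = 0.01, sigma_nm = 73.6, t_kelvin = 300) {
  stopifnot(eta > 0, sigma_nm > 0, t_kelvin > 0)
  kB <- 1.380649e-23
  6 * pi * eta * (sigma_nm * 1e-9)^3 / (kB * t_kelvin)
}

#' Convert a model quantity to physical units
#'
#' Multiplies by `sigma_nm^k`. Lengths (k = 1) and areas (k = 2) are
#' returned in nm and nm^2; volumes (k = 3) in um^3.
#'
#' @param value quantity in sigma^k.
#' @param sigma_nm model length unit, nm.
#' @param k power of length (1, 2 or 3).
#' @return physical value (nm, nm^2, or um^3).
#' @export
to_physical <- function(value, sigma_nm = 73.6, k = 1) {
  stopifnot(k %in% 1:3, sigma_nm > 0)
  out <- value * sigma_nm^k
  if (k == 3) out <- out * 1e-9  # nm^3 -> um^3
  out
}

#' Full unit-mapping report
#'
#' Bundles the sigma calibration and the time mapping with the inputs
#' used.
#'
#' @inheritParams calibrate_sigma
#' @inheritParams tau_physical
#' @return list of class `sbs_units` with all inputs and derived values.
#' @export
unit_mapping <- function(s = 2500, G = 6e9, D = 1e4, rg_imaging = 464,
                         rg_model = 6.4, eta = 0.01, t_kelvin = 300) {
  sig <- calibrate_sigma(s, G, D, rg_imaging, rg_model)
  structure(list(
    s = s, G = G, D = D, rg_imaging = rg_imaging, rg_model = rg_model,
    eta = eta, t_kelvin = t_kelvin,
    sigma_genomic = sig$sigma_genomic,
    sigma_imaging = sig$sigma_imaging, sigma_ref = sig$sigma_ref,
    tau_seconds = tau_physical(eta, sig$sigma_ref, t_kelvin)),
    class = "sbs_units")
}

#' @export
print.sbs_units <- function(x, ...) {
  cat("SBS unit mapping\n")
  cat(sprintf("  sigma: genomic %.1f nm | imaging %.1f nm | ref %.1f nm\n",
              x$sigma_genomic, x$sigma_imaging, x$sigma_ref))
  cat(sprintf("  tau: %.3g s (eta %.3g Pa s, T %g K)\n", x$tau_seconds,
              x$eta, x$t_kelvin))
  invisible(x)
}
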