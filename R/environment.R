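#' @keywords internal
".kB_pNnm_per_K" <- 0.0138065

#' @keywords internal
".pNnm_to_kJmol" <- 0.60221

#' Thermal environment of a tweezers experiment
#'
#' Bundles the absolute temperature with the derived thermal energy
#' \eqn{k_B T} used throughout the polymer mechanics. All measurements the
#' package models were taken at 25 degrees C, so the default is 298.15 K.
#'
#' @param temperature_K absolute temperature in kelvin (> 0).
#' @return An object of class \code{tweezer_env} with elements
#'   \code{temperature_K} and \code{thermal_energy_pNnm}
#'   (\eqn{k_B T} in pN nm; 4.1164 pN nm at the default temperature).
#' @examples
#' env <- tweezer_env()
#' env$thermal_energy_pNnm
#' @export
tweezer_env <- function(temperature_K = 298.15) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      temperature_K = temperature_K,
      thermal_energy_pNnm = .kB_pNnm_per_K * temperature_K
    ),
    class = "tweezer_env"
  )
}

#' @export
print.tweezer_env <- function(x, ...) {
  cat(sprintf("Tweezer environment: T = %.2f K, kBT = %.4f pN nm\n",
              x$temperature_K, x$thermal_energy_pNnm))
  invisible(x)
}

#' Worm-like-chain polymer state
#'
#' A mechanical state of the tether described by an inextensible worm-like
#' chain: a contour length \code{L} (nm) and a persistence length \code{A}
#' (nm, 50 nm for dsDNA).
#'
#' @param name label for the state, e.g. \code{"unfolded_chain"} or
#'   \code{"folded_nucleosome"}.
#' @param contour_length_nm contour length L in nm (> 0).
#' @param persistence_length_nm persistence length A in nm (> 0, default 50).
#' @return An object of class \code{polymer_state}.
#' @examples
#' dna <- polymer_state("unfolded_chain", 119)
#' ncp <- polymer_state("folded_nucleosome", 99)
#' @export
polymer_state <- function(name, contour_length_nm, persistence_length_nm = 50) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(contour_length_nm) || length(contour_length_nm) != 1L ||
      !is.finite(contour_length_nm) || contour_length_nm <= 0) {
    stop("`contour_length_nm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(persistence_length_nm) || length(persistence_length_nm) != 1L ||
      !is.finite(persistence_length_nm) || persistence_length_nm <= 0) {
    stop("`persistence_length_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      name = name,
      contour_length_nm = contour_length_nm,
      persistence_length_nm = persistence_length_nm
    ),
    class = "polymer_state"
  )
}

#' @export
print.polymer_state <- function(x, ...) {
  cat(sprintf("Polymer state '%s': L = %g nm, A = %g nm\n",
              x$name, x$contour_length_nm, x$persistence_length_nm))
  invisible(x)
}

#' Convert between energy units
#'
#' Exact linear conversion between the three energy units used in
#' single-molecule work: \code{"pN.nm"}, \code{"kJ/mol"} and \code{"kBT"}.
#' 1 pN nm = 0.60221 kJ/mol (Avogadro's number times 1e-21 J); the
#' \code{"kBT"} unit is defined by the supplied environment.
#'
#' @param value numeric vector of energies.
#' @param from,to units, each one of \code{"pN.nm"}, \code{"kJ/mol"},
#'   \code{"kBT"}.
#' @param env a [tweezer_env()]; required only when \code{"kBT"} is involved.
#' @return numeric vector in the target units.
#' @examples
#' convert_energy(1, "pN.nm", "kJ/mol")
#' convert_energy(1, "kBT", "kJ/mol", tweezer_env())
#' @export
convert_energy <- function(value, from, to, env = tweezer_env()) {
  units <- c("pN.nm", "kJ/mol", "kBT")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  stopifnot(inherits(env, "tweezer_env"))
  # scale of one unit in pN nm
  scale <- function(u) {
    switch(u,
      "pN.nm" = 1,
      "kJ/mol" = 1 / .pNnm_to_kJmol,
      "kBT" = env$thermal_energy_pNnm
    )
  }
  value * scale(from) / scale(to)
}
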