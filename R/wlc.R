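# Worm-like-chain mechanics and two-state free-energy reconstruction.
#
# The force-extension relation used everywhere is the Marko-Siggia
# interpolation for an inextensible WLC,
#   f A / kBT = 1/(4 (1-z)^2) - 1/4 + z,   z = x / L,
# which is strictly increasing in z on [0, 1). Forces stay <= ~30 pN in the
# experiments modelled here, where enthalpic stretching is negligible, so no
# stretch-modulus term is included.

# dimensionless Marko-Siggia right-hand side
.ms_rhs <- function(z) 1 / (4 * (1 - z)^2) - 1 / 4 + z

# Vectorised inversion of the Marko-Siggia relation: relative extension z at
# force f (pN). Bracketed bisection on z in [0, 1 - 1e-12]; unconditionally
# convergent because the relation is monotone. Tolerance |f(z) - f| < 1e-9 pN.
.wlc_invert <- function(force_pN, persistence_length_nm, kBT_pNnm,
                        tol_pN = 1e-9, max_iter = 200L) {
  pref <- kBT_pNnm / persistence_length_nm
  lo <- rep(0, length(force_pN))
  hi <- rep(1 - 1e-12, length(force_pN))
  active <- force_pN > 0
  lo[!active] <- 0
  hi[!active] <- 0
  for (i in seq_len(max_iter)) {
    if (!any(active)) break
    mid <- (lo + hi) / 2
    fm <- pref * .ms_rhs(mid)
    up <- active & (fm < force_pN)
    lo[up] <- mid[up]
    dn <- active & !up
    hi[dn] <- mid[dn]
    active <- active & (abs(fm - force_pN) >= tol_pN)
  }
  if (any(active)) {
    stop(sprintf(
      "WLC inversion failed to converge for %d force value(s); max residual %.3g pN",
      sum(active), max(abs(pref * .ms_rhs((lo + hi) / 2) - force_pN)[active])
    ), call. = FALSE)
  }
  (lo + hi) / 2
}

#' WLC force at a relative extension
#'
#' Evaluates the Marko-Siggia worm-like-chain force law
#' \deqn{f = (k_B T / A)\,[1/(4(1-z)^2) - 1/4 + z]}
#' at relative extension \eqn{z = x/L}.
#'
#' @param rel_extension relative extension(s) in \[0, 1).
#' @param polymer a [polymer_state()] supplying the persistence length.
#' @param env a [tweezer_env()].
#' @return force(s) in pN; 0 at \code{rel_extension = 0}, strictly increasing.
#' @examples
#' dna <- polymer_state("dna", 119)
#' wlc_force(0.5, dna)
#' @export
wlc_force <- function(rel_extension, polymer, env = tweezer_env()) {
  stopifnot(inherits(polymer, "polymer_state"), inherits(env, "tweezer_env"))
  if (!is.numeric(rel_extension) || any(!is.finite(rel_extension)) ||
      any(rel_extension < 0) || any(rel_extension >= 1)) {
    stop("`rel_extension` must lie in [0, 1)", call. = FALSE)
  }
  env$thermal_energy_pNnm / polymer$persistence_length_nm * .ms_rhs(rel_extension)
}

#' WLC extension at a force
#'
#' Numerically inverts the Marko-Siggia relation to give the equilibrium
#' extension of a worm-like chain at tension \code{force}. The inversion is a
#' bracketed bisection converged to |residual| < 1e-9 pN.
#'
#' @param force force(s) in pN (>= 0).
#' @param polymer a [polymer_state()].
#' @param env a [tweezer_env()].
#' @return extension(s) in nm, always < the contour length.
#' @examples
#' wlc_extension(3.5, polymer_state("dna", 119))
#' @export
wlc_extension <- function(force, polymer, env = tweezer_env()) {
  stopifnot(inherits(polymer, "polymer_state"), inherits(env, "tweezer_env"))
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0)) {
    stop("`force` must be finite and >= 0", call. = FALSE)
  }
  polymer$contour_length_nm *
    .wlc_invert(force, polymer$persistence_length_nm, env$thermal_energy_pNnm)
}

# force grid for quadrature at step <= step_pN, always including both ends
.force_grid <- function(f, step_pN = 5e-4) {
  n <- max(2L, ceiling(f / step_pN) + 1L)
  seq(0, f, length.out = n)
}

#' Force-dependent term of the unfolding free energy
#'
#' The stretching-work difference between the unfolded chain and the folded
#' particle,
#' \deqn{\Delta\Phi(f) = -\int_0^f [x_{dna}(f') - x_{ncp}(f')]\, df',}
#' evaluated by composite trapezoid quadrature on a force grid with step at
#' most \code{step_pN}. Negative whenever the unfolded contour exceeds the
#' folded one.
#'
#' @param force upper integration limit in pN (single value, >= 0).
#' @param unfolded,folded [polymer_state()] objects for the unfolded chain and
#'   the folded particle.
#' @param env a [tweezer_env()].
#' @param step_pN quadrature step (default 5e-4 pN, always at or below the 0.001 pN contract).
#' @return energy in pN nm (<= 0 when \code{unfolded} is longer).
#' @examples
#' dna <- polymer_state("dna", 119); ncp <- polymer_state("ncp", 99)
#' delta_phi(3.5, dna, ncp)
#' @export
delta_phi <- function(force, unfolded, folded, env = tweezer_env(),
                      step_pN = 5e-4) {
  stopifnot(inherits(unfolded, "polymer_state"),
            inherits(folded, "polymer_state"),
            inherits(env, "tweezer_env"))
  if (!is.numeric(force) || length(force) != 1L || !is.finite(force) ||
      force < 0) {
    stop("`force` must be a single number >= 0", call. = FALSE)
  }
  if (force == 0) return(0)
  fg <- .force_grid(force, step_pN)
  kBT <- env$thermal_energy_pNnm
  xu <- unfolded$contour_length_nm *
    .wlc_invert(fg, unfolded$persistence_length_nm, kBT)
  xf <- folded$contour_length_nm *
    .wlc_invert(fg, folded$persistence_length_nm, kBT)
  dx <- xu - xf
  h <- fg[2] - fg[1]
  -h * (sum(dx) - (dx[1] + dx[length(dx)]) / 2)
}

#' Unfolding free energy by quadrature at the equilibrium force
#'
#' The force-independent free-energy cost of unfolding,
#' \deqn{\Delta G_0 = -\Delta\Phi(F_{eq}) =
#'   \int_0^{F_{eq}} [x_{dna}(f') - x_{ncp}(f')]\, df',}
#' converted to kJ/mol (0.60221 kJ/mol per pN nm).
#'
#' @param feq equilibrium force in pN (>= 0).
#' @inheritParams delta_phi
#' @return energy in kJ/mol.
#' @examples
#' dna <- polymer_state("dna", 119); ncp <- polymer_state("ncp", 99)
#' delta_g0_quadrature(4.0, dna, ncp)
#' @export
delta_g0_quadrature <- function(feq, unfolded, folded, env = tweezer_env(),
                                step_pN = 5e-4) {
  if (!is.numeric(feq) || length(feq) != 1L || !is.finite(feq) || feq < 0) {
    stop("`feq` must be a single number >= 0", call. = FALSE)
  }
  -delta_phi(feq, unfolded, folded, env, step_pN) * .pNnm_to_kJmol
}

#' Unfolding free energy as rip work at the equilibrium force
#'
#' The rectangle (rip-work) estimator
#' \deqn{\Delta G_0 \approx F_{eq}\,[x_{dna}(F_{eq}) - x_{ncp}(F_{eq})],}
#' converted to kJ/mol. Because the WLC relative extension is increasing in
#' force, this always bounds the quadrature estimator from above; both are
#' reported by [outer_wrap_energy()] so neither is silently preferred.
#'
#' @inheritParams delta_g0_quadrature
#' @return energy in kJ/mol.
#' @examples
#' dna <- polymer_state("dna", 119); ncp <- polymer_state("ncp", 99)
#' delta_g0_ripwork(3.5, dna, ncp)
#' @export
delta_g0_ripwork <- function(feq, unfolded, folded, env = tweezer_env()) {
  stopifnot(inherits(unfolded, "polymer_state"),
            inherits(folded, "polymer_state"),
            inherits(env, "tweezer_env"))
  if (!is.numeric(feq) || length(feq) != 1L || !is.finite(feq) || feq < 0) {
    stop("`feq` must be a single number >= 0", call. = FALSE)
  }
  dx <- wlc_extension(feq, unfolded, env) - wlc_extension(feq, folded, env)
  feq * dx * .pNnm_to_kJmol
}

#' Free energy from two-state folding and unfolding rates
#'
#' \deqn{\Delta G(f) = k_B T \ln[k_{u\to f}(f) / k_{f\to u}(f)],}
#' converted to kJ/mol. Zero when the rates are equal (the definition of the
#' equilibrium force) and antisymmetric under swapping the rates.
#'
#' @param k_fold folding rate \eqn{k_{u\to f}} in 1/s (> 0).
#' @param k_unfold unfolding rate \eqn{k_{f\to u}} in 1/s (> 0).
#' @param env a [tweezer_env()].
#' @return energy in kJ/mol.
#' @examples
#' delta_g_from_rates(10, 1)
#' @export
delta_g_from_rates <- function(k_fold, k_unfold, env = tweezer_env()) {
  stopifnot(inherits(env, "tweezer_env"))
  if (!is.numeric(k_fold) || !is.numeric(k_unfold) ||
      any(!is.finite(k_fold)) || any(!is.finite(k_unfold)) ||
      any(k_fold <= 0) || any(k_unfold <= 0)) {
    stop("rates must be finite and > 0", call. = FALSE)
  }
  env$thermal_energy_pNnm * log(k_fold / k_unfold) * .pNnm_to_kJmol
}

#' Outer-wrap unfolding energetics at an equilibrium force
#'
#' Convenience wrapper computing both \eqn{\Delta G_0} estimators (quadrature
#' and rip work) for a two-state unfolding transition, together with
#' \eqn{\Delta\Phi(F_{eq})}.
#'
#' @inheritParams delta_g0_quadrature
#' @param method_note free-text provenance recorded in the result.
#' @return An object of class \code{energy_result}: a list with
#'   \code{feq_pN}, \code{delta_g0_quadrature_kJmol},
#'   \code{delta_g0_ripwork_kJmol}, \code{delta_phi_pNnm} (at \code{feq}) and
#'   \code{method_note}.
#' @examples
#' dna <- polymer_state("dna", 119); ncp <- polymer_state("ncp", 99)
#' outer_wrap_energy(3.5, dna, ncp)
#' @export
outer_wrap_energy <- function(feq, unfolded, folded, env = tweezer_env(),
                              step_pN = 5e-4, method_note = "") {
  dphi <- delta_phi(feq, unfolded, folded, env, step_pN)
  structure(
    list(
      feq_pN = feq,
      delta_g0_quadrature_kJmol = -dphi * .pNnm_to_kJmol,
      delta_g0_ripwork_kJmol = delta_g0_ripwork(feq, unfolded, folded, env),
      delta_phi_pNnm = dphi,
      unfolded = unfolded,
      folded = folded,
      method_note = method_note
    ),
    class = "energy_result"
  )
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("Outer-wrap unfolding free energy at Feq = %g pN\n", x$feq_pN))
  cat(sprintf("  quadrature:  %.2f kJ/mol\n", x$delta_g0_quadrature_kJmol))
  cat(sprintf("  rip work:    %.2f kJ/mol\n", x$delta_g0_ripwork_kJmol))
  cat(sprintf("  delta Phi:   %.2f pN nm\n", x$delta_phi_pNnm))
  if (nzchar(x$method_note)) cat("  note:", x$method_note, "\n")
  invisible(x)
}
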