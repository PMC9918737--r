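# Trajectory simulators. These generate every input the analysis layer
# consumes: force-ramp stretch cycles with Bell-kinetics transitions between
# discrete wrapping states, constant-force two-state hopping, force-jump
# binding cycles, real-time deposition traces and bead-fluctuation series for
# force calibration. All are seeded and byte-reproducible.

# per-cycle RNG substream: root seed plus a fixed odd multiplier per cycle,
# reduced mod 2^31 - 1 so the value is a valid integer seed
.substream <- function(seed, k) {
  set.seed(as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647))
}

# exact-discretisation stationary OU sample of length n (zero mean)
.ou_noise <- function(n, dt, tau, sd) {
  if (n == 0L || sd <= 0) return(numeric(n))
  if (tau <= 0) return(stats::rnorm(n, 0, sd))
  a <- exp(-dt / tau)
  innov <- c(stats::rnorm(1, 0, sd),
             stats::rnorm(n - 1L, 0, sd * sqrt(1 - a^2)))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Ornstein-Uhlenbeck bead-noise model
#'
#' Stationary Gaussian model of tethered-bead Brownian motion added to the
#' deterministic WLC extension: relaxation time \code{ou_relaxation_s} and
#' stationary standard deviation \code{ou_sd_nm}. Zero sd disables noise.
#'
#' @param ou_relaxation_s bead relaxation time in s (>= 0).
#' @param ou_sd_nm stationary sd of the extension noise in nm (>= 0).
#' @return list of class \code{noise_model}.
#' @export
noise_model <- function(ou_relaxation_s = 0.01, ou_sd_nm = 2) {
  stopifnot(ou_relaxation_s >= 0, ou_sd_nm >= 0)
  structure(list(ou_relaxation_s = ou_relaxation_s, ou_sd_nm = ou_sd_nm),
            class = "noise_model")
}

#' Force-ramp protocol
#'
#' The stretch-cycle schedule: magnets approach the sample at
#' \code{magnet_speed_um_s} (10 um/s in the experiments modelled), the tension
#' following \code{force_law}, from the rest force up to \code{max_force_pN};
#' the trace is sampled at \code{sample_rate_Hz}. Rest periods between cycles
#' are collapsed to an instantaneous state reset (recorded in the metadata)
#' rather than simulated minutes of idle data.
#'
#' @param magnet_speed_um_s magnet approach speed, um/s.
#' @param force_law a [force_law()] giving F(magnet distance).
#' @param max_force_pN force at which the ramp stops (default 32).
#' @param rest_force_pN force at which each cycle starts (default 0.1).
#' @param rest_duration_s nominal rest duration, recorded but not sampled.
#' @param sample_rate_Hz sampling rate of the recorded trace.
#' @param n_cycles number of stretch cycles.
#' @return list of class \code{ramp_protocol}.
#' @export
ramp_protocol <- function(magnet_speed_um_s = 10,
                          force_law = default_force_law(),
                          max_force_pN = 32, rest_force_pN = 0.1,
                          rest_duration_s = 300, sample_rate_Hz = 200,
                          n_cycles = 1L) {
  stopifnot(magnet_speed_um_s > 0, inherits(force_law, "force_law"),
            max_force_pN > rest_force_pN, rest_force_pN > 0,
            sample_rate_Hz > 0, n_cycles >= 1)
  structure(
    list(magnet_speed_um_s = magnet_speed_um_s, force_law = force_law,
         max_force_pN = max_force_pN, rest_force_pN = rest_force_pN,
         rest_duration_s = rest_duration_s, sample_rate_Hz = sample_rate_Hz,
         n_cycles = as.integer(n_cycles)),
    class = "ramp_protocol"
  )
}

#' Default force versus magnet-position calibration
#'
#' The double-exponential magnet law used by the bundled protocol defaults:
#' a short-range component dominating above ~10 pN and a long-range component
#' setting the low-force tail. The parameters are a representative setup
#' calibration, configurable per experiment.
#'
#' @return a [force_law()].
#' @export
default_force_law <- function() force_law(80, 0.3, 6, 1.2)

#' Mechanical-state and kinetics presets for the tether constructs
#'
#' Returns the state ladder, Bell transition parameters and reassembly flag
#' for one experimental condition. Nucleosome constructs carry three states
#' (intact, outer wrap open, fully unfolded; contour gains +20 nm for the
#' outer wrap, matching the printed 119 vs 99 nm pair, and +27 nm for the
#' inner wrap); tetrasome constructs have two states (+24 nm). The zero-force
#' rates are calibration constants committed once so that the detected median
#' rupture forces under the default [ramp_protocol()] sit near the observed
#' medians (outer/inner about 4/23 pN for the unmodified nucleosome, 2/15 pN
#' for ubH2B, 10/20 pN for ubH2B with FACT, 16 pN for the tetrasome, 7 pN for
#' the tetrasome with FACT); they are documented defaults, not claims.
#' \code{reassemble} encodes whether the construct refolds after full
#' unfolding (true only in the presence of the FACT chaperone).
#'
#' @param name one of \code{"h2b"}, \code{"ubh2b"}, \code{"ubh2b_fact"},
#'   \code{"tetrasome"}, \code{"tetrasome_fact"}.
#' @return list of class \code{sim_condition} with elements \code{name},
#'   \code{mode}, \code{states} (data frame name / tether_contour_nm),
#'   \code{transitions} (data frame from / to / k0_per_s / x_dagger_nm),
#'   \code{reassemble}, \code{persistence_length_nm}.
#' @export
nucleosome_condition <- function(name = c("h2b", "ubh2b", "ubh2b_fact",
                                          "tetrasome", "tetrasome_fact")) {
  name <- match.arg(name)
  nuc_states <- data.frame(
    name = c("intact", "outer_open", "fully_unfolded"),
    tether_contour_nm = c(99, 119, 146),
    stringsAsFactors = FALSE
  )
  tet_states <- data.frame(
    name = c("folded", "unfolded"),
    tether_contour_nm = c(115, 139),
    stringsAsFactors = FALSE
  )
  tr <- function(from, to, k0, xd) {
    data.frame(from = from, to = to, k0_per_s = k0, x_dagger_nm = xd,
               stringsAsFactors = FALSE)
  }
  cfg <- switch(name,
    h2b = list(
      mode = "nucleosome", states = nuc_states, reassemble = FALSE,
      transitions = rbind(
        tr("intact", "outer_open", 7.58e-4, 3.0),
        tr("outer_open", "fully_unfolded", 3.14e-5, 1.5))),
    ubh2b = list(
      mode = "nucleosome", states = nuc_states, reassemble = FALSE,
      transitions = rbind(
        tr("intact", "outer_open", 1.28e-3, 3.0),
        tr("outer_open", "fully_unfolded", 2.63e-4, 1.5))),
    ubh2b_fact = list(
      mode = "nucleosome", states = nuc_states, reassemble = TRUE,
      transitions = rbind(
        tr("intact", "outer_open", 6.54e-5, 3.0),
        tr("outer_open", "fully_unfolded", 7.47e-5, 1.5))),
    tetrasome = list(
      mode = "tetrasome", states = tet_states, reassemble = FALSE,
      transitions = tr("folded", "unfolded", 2.10e-4, 1.5)),
    tetrasome_fact = list(
      mode = "tetrasome", states = tet_states, reassemble = TRUE,
      transitions = tr("folded", "unfolded", 2.80e-4, 3.0))
  )
  cfg$name <- name
  cfg$persistence_length_nm <- 50
  structure(cfg, class = "sim_condition")
}

# assemble a trajectory data frame with class + metadata attributes
.trajectory <- function(df, condition, seed, extra = list()) {
  attr(df, "condition") <- condition
  attr(df, "seed") <- seed
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("sm_trajectory", "data.frame")
  df
}

#' Simulate repeated force-ramp stretch cycles
#'
#' Generates the force-extension trajectory of one tethered molecule over
#' \code{protocol$n_cycles} stretch cycles. The tension follows the force law
#' along the magnet schedule; the wrapping state evolves by exact exponential
#' waiting-time sampling of the Bell rates
#' \eqn{k(f) = k_0 \exp(f x^\ddagger / k_B T)} (rates frozen at the
#' interval-start force within each sample interval); the recorded extension
#' is the WLC extension of the current state's contour length plus
#' Ornstein-Uhlenbeck bead noise. Each cycle ends with an instantaneous reset:
#' the molecule refolds to the first state unless it reached full unfolding
#' and \code{condition$reassemble} is \code{FALSE}, in which case it stays
#' unfolded for all later cycles (nucleosomes cannot reassemble after total
#' disruption without a chaperone).
#'
#' @param condition a [nucleosome_condition()] (or a compatible list with the
#'   same elements) defining states, transitions and reassembly.
#' @param protocol a [ramp_protocol()].
#' @param noise a [noise_model()].
#' @param seed integer root seed; cycle k uses substream seed
#'   \code{(seed + 7919 k) mod (2^31 - 1)}.
#' @param env a [tweezer_env()].
#' @return An \code{sm_trajectory}: a data frame with columns \code{time_s},
#'   \code{magnet_pos_um}, \code{force_pN}, \code{extension_nm}, \code{cycle},
#'   \code{truth_state}, with the condition name and seed as attributes.
#' @examples
#' cond <- nucleosome_condition("h2b")
#' prot <- ramp_protocol(sample_rate_Hz = 5, n_cycles = 1)
#' traj <- simulate_stretch_cycles(cond, prot, noise_model(0.01, 0), seed = 1)
#' @export
simulate_stretch_cycles <- function(condition, protocol = ramp_protocol(),
                                    noise = noise_model(), seed = 1L,
                                    env = tweezer_env()) {
  if (is.character(condition)) condition <- nucleosome_condition(condition)
  stopifnot(inherits(protocol, "ramp_protocol"), inherits(noise, "noise_model"),
            inherits(env, "tweezer_env"))
  states <- condition$states
  if (any(diff(states$tether_contour_nm) <= 0)) {
    stop("state contour lengths must strictly increase along the unfolding order",
         call. = FALSE)
  }
  trans <- condition$transitions
  if (any(trans$k0_per_s <= 0)) stop("transition k0 must be > 0", call. = FALSE)
  kBT <- env$thermal_energy_pNnm
  law <- protocol$force_law
  dt <- 1 / protocol$sample_rate_Hz
  z_start <- .force_law_invert(law, protocol$rest_force_pN)
  z_end <- .force_law_invert(law, protocol$max_force_pN)
  if (z_end >= z_start) stop("force law cannot realise the requested ramp",
                             call. = FALSE)
  duration <- (z_start - z_end) * 1e3 / protocol$magnet_speed_um_s
  t_loc <- seq(0, duration, by = dt)
  z_mm <- z_start - protocol$magnet_speed_um_s * t_loc / 1e3
  f_pN <- predict(law, z_mm)
  zeta <- .wlc_invert(f_pN, condition$persistence_length_nm, kBT)
  n <- length(t_loc)
  n_states <- nrow(states)
  state_of <- function(nm) match(nm, states$name)
  out <- vector("list", protocol$n_cycles)
  carry_state <- 1L
  for (cyc in seq_len(protocol$n_cycles)) {
    .substream(seed, cyc)
    s_idx <- integer(n)
    cur <- carry_state
    p <- 1L
    while (p <= n) {
      rows <- trans[trans$from == states$name[cur], , drop = FALSE]
      if (nrow(rows) == 0L) { s_idx[p:n] <- cur; break }
      rate_mat <- vapply(seq_len(nrow(rows)), function(j) {
        rows$k0_per_s[j] * exp(f_pN[p:n] * rows$x_dagger_nm[j] / kBT)
      }, numeric(n - p + 1L))
      rate_mat <- matrix(rate_mat, ncol = nrow(rows))
      total <- rowSums(rate_mat)
      cumhaz <- cumsum(total * dt)
      e <- stats::rexp(1)
      hit <- which(cumhaz >= e)
      if (length(hit) == 0L) { s_idx[p:n] <- cur; break }
      jump_at <- p + hit[1L]           # state changes at the following sample
      s_idx[p:min(jump_at - 1L, n)] <- cur
      if (jump_at > n) break
      pr <- rate_mat[hit[1L], ]
      target <- rows$to[sample.int(length(pr), 1L, prob = pr)]
      cur <- state_of(target)
      p <- jump_at
    }
    if (p > n && s_idx[n] == 0L) s_idx[n] <- cur
    ext <- states$tether_contour_nm[s_idx] * zeta +
      .ou_noise(n, dt, noise$ou_relaxation_s, noise$ou_sd_nm)
    out[[cyc]] <- data.frame(
      time_s = (cyc - 1L) * duration + t_loc,
      magnet_pos_um = z_mm * 1e3,
      force_pN = f_pN,
      extension_nm = ext,
      cycle = cyc,
      truth_state = states$name[s_idx],
      stringsAsFactors = FALSE
    )
    # instantaneous rest-period reset
    carry_state <- if (cur == n_states && !condition$reassemble) n_states else 1L
  }
  .trajectory(do.call(rbind, out), condition$name, seed,
              list(rest_collapsed = TRUE,
                   rest_duration_s = protocol$rest_duration_s))
}

#' Simulate constant-force two-state hopping
#'
#' Alternating exponential dwells between a folded and an unfolded state at a
#' force clamp, mapped to the WLC extensions of the two contour lengths at the
#' clamp force, plus OU bead noise. A zero rate pins the trace in the
#' corresponding state.
#'
#' @param force_pN clamp force (> 0).
#' @param k_fold_per_s,k_unfold_per_s folding / unfolding rates (>= 0, not
#'   both zero).
#' @param duration_s trace length in s (> 0).
#' @param folded_contour_nm,unfolded_contour_nm contour lengths of the two
#'   states (defaults 99 and 119 nm, the outer-wrap pair).
#' @param persistence_length_nm WLC persistence length (nm).
#' @param noise a [noise_model()].
#' @param sample_rate_Hz sampling rate.
#' @param seed integer seed.
#' @param env a [tweezer_env()].
#' @return An \code{sm_trajectory} with \code{truth_state} in
#'   \code{{"folded", "unfolded"}}; the trace starts folded.
#' @export
simulate_constant_force_hopping <- function(force_pN, k_fold_per_s,
                                            k_unfold_per_s, duration_s,
                                            folded_contour_nm = 99,
                                            unfolded_contour_nm = 119,
                                            persistence_length_nm = 50,
                                            noise = noise_model(),
                                            sample_rate_Hz = 200, seed = 1L,
                                            env = tweezer_env()) {
  stopifnot(force_pN > 0, k_fold_per_s >= 0, k_unfold_per_s >= 0,
            inherits(noise, "noise_model"), inherits(env, "tweezer_env"))
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  # alternate folded (exit rate k_unfold) / unfolded (exit rate k_fold)
  switch_t <- numeric(0)
  state0 <- 1L  # folded
  t_acc <- 0; s <- state0
  while (t_acc < duration_s) {
    rate <- if (s == 1L) k_unfold_per_s else k_fold_per_s
    if (rate <= 0) break
    t_acc <- t_acc + stats::rexp(1, rate)
    if (t_acc < duration_s) switch_t <- c(switch_t, t_acc)
    s <- 3L - s
  }
  dt <- 1 / sample_rate_Hz
  tt <- seq(0, duration_s, by = dt)
  n_switch <- findInterval(tt, switch_t)
  s_idx <- 1L + (n_switch + state0 - 1L) %% 2L  # 1 folded, 2 unfolded
  zeta <- .wlc_invert(force_pN, persistence_length_nm, env$thermal_energy_pNnm)
  levels_nm <- c(folded_contour_nm, unfolded_contour_nm) * zeta
  ext <- levels_nm[s_idx] +
    .ou_noise(length(tt), dt, noise$ou_relaxation_s, noise$ou_sd_nm)
  df <- data.frame(
    time_s = tt, magnet_pos_um = NA_real_, force_pN = force_pN,
    extension_nm = ext, cycle = 1L,
    truth_state = c("folded", "unfolded")[s_idx],
    stringsAsFactors = FALSE
  )
  .trajectory(df, "constant_force_hopping", seed,
              list(k_fold_per_s = k_fold_per_s, k_unfold_per_s = k_unfold_per_s,
                   switch_times_s = switch_t))
}

#' Simulate force-jump binding cycles
#'
#' Each cycle the tethered nucleosome is probed once; it is chaperone-bound
#' with equilibrium occupancy \eqn{p = [FACT] / ([FACT] + K_d)}, independently
#' across cycles. What the probe force reveals depends on the construct:
#' for the unmodified nucleosome (probe 11 pN) the inner wrap ruptures only
#' when FACT is bound; for the ubH2B nucleosome (probe 6 pN) the outer wrap
#' ruptures only when FACT is absent. The observable recorded per cycle is
#' whether a disruption occurred at the probe force; [classify_binding_cycle()]
#' turns it into a bound/unbound call.
#'
#' @param kd_nM dissociation constant (>= 0).
#' @param fact_conc_nM chaperone concentration (> 0; 83 nM in the experiments
#'   modelled).
#' @param n_cycles number of force-jump cycles (>= 1).
#' @param condition \code{"unmodified"} (probe 11 pN) or \code{"ubh2b"}
#'   (probe 6 pN).
#' @param seed integer seed.
#' @return data frame of class \code{binding_cycles} with columns
#'   \code{cycle_index}, \code{condition}, \code{probe_force_pN},
#'   \code{truth_bound}, \code{disruption_at_probe}.
#' @examples
#' cyc <- simulate_force_jump_binding(16.3, 83, 100, "unmodified", seed = 4)
#' mean(cyc$truth_bound)
#' @export
simulate_force_jump_binding <- function(kd_nM, fact_conc_nM = 83, n_cycles,
                                        condition = c("unmodified", "ubh2b"),
                                        seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(kd_nM) || kd_nM < 0) stop("`kd_nM` must be >= 0", call. = FALSE)
  stopifnot(fact_conc_nM > 0, n_cycles >= 1)
  set.seed(as.integer(seed %% 2147483647))
  p <- fact_conc_nM / (fact_conc_nM + kd_nM)
  bound <- stats::runif(n_cycles) < p
  probe <- if (condition == "unmodified") 11 else 6
  disruption <- if (condition == "unmodified") bound else !bound
  structure(
    data.frame(
      cycle_index = seq_len(n_cycles),
      condition = condition,
      probe_force_pN = probe,
      truth_bound = bound,
      disruption_at_probe = disruption,
      stringsAsFactors = FALSE
    ),
    class = c("binding_cycles", "data.frame"),
    kd_nM = kd_nM, fact_conc_nM = fact_conc_nM, seed = seed
  )
}

#' Simulate a real-time deposition trace
#'
#' Piecewise-constant extension at a constant holding force (1.5 pN in the
#' deposition assays modelled) with the given extension increments occurring
#' at exponential waiting times, plus OU noise. Each histone-dimer deposition
#' appears as one discrete ~10 nm step; increments are applied with the sign
#' supplied.
#'
#' @param step_sizes_nm extension increments in nm (may be empty for a flat
#'   trace).
#' @param mean_wait_s mean exponential waiting time before each step.
#' @param force_pN holding force (default 1.5).
#' @param base_contour_nm contour length setting the starting extension
#'   (default 115 nm, a tetrasome tether).
#' @param persistence_length_nm WLC persistence length.
#' @param noise a [noise_model()].
#' @param sample_rate_Hz sampling rate.
#' @param duration_s trace length; default covers all steps plus three mean
#'   waits of settled baseline.
#' @param seed integer seed.
#' @param env a [tweezer_env()].
#' @return An \code{sm_trajectory}; \code{truth_state} counts completed steps.
#' @export
simulate_deposition_trace <- function(step_sizes_nm = c(10, 10),
                                      mean_wait_s = 10, force_pN = 1.5,
                                      base_contour_nm = 115,
                                      persistence_length_nm = 50,
                                      noise = noise_model(),
                                      sample_rate_Hz = 100,
                                      duration_s = NULL, seed = 1L,
                                      env = tweezer_env()) {
  stopifnot(mean_wait_s > 0, force_pN > 0, inherits(noise, "noise_model"))
  set.seed(as.integer(seed %% 2147483647))
  n_steps <- length(step_sizes_nm)
  waits <- if (n_steps) stats::rexp(n_steps, 1 / mean_wait_s) else numeric(0)
  step_t <- cumsum(waits)
  if (is.null(duration_s)) {
    duration_s <- (if (n_steps) step_t[n_steps] else 0) + 3 * mean_wait_s
  }
  dt <- 1 / sample_rate_Hz
  tt <- seq(0, duration_s, by = dt)
  n_done <- findInterval(tt, step_t)
  base <- base_contour_nm *
    .wlc_invert(force_pN, persistence_length_nm, env$thermal_energy_pNnm)
  level <- base + c(0, cumsum(step_sizes_nm))[n_done + 1L]
  ext <- level + .ou_noise(length(tt), dt, noise$ou_relaxation_s, noise$ou_sd_nm)
  df <- data.frame(
    time_s = tt, magnet_pos_um = NA_real_, force_pN = force_pN,
    extension_nm = ext, cycle = 1L,
    truth_state = as.character(n_done),
    stringsAsFactors = FALSE
  )
  .trajectory(df, "deposition", seed,
              list(step_times_s = step_t, step_sizes_nm = step_sizes_nm))
}

#' Simulate transverse bead fluctuations for force calibration
#'
#' Exact-discretisation Ornstein-Uhlenbeck process for the transverse
#' coordinate of a bead tethered at extension \eqn{\ell} under tension F:
#' pendulum stiffness \eqn{\kappa = F/\ell}, drag \eqn{\gamma = 6\pi\eta r},
#' stationary variance \eqn{k_B T \ell / F}, corner frequency
#' \eqn{F / (2\pi\gamma\ell)}.
#'
#' @param force_pN tension (> 0).
#' @param extension_nm tether extension (> 0).
#' @param bead_radius_um bead radius (default 1.4 um).
#' @param viscosity_Pa_s medium viscosity (default 8.9e-4 Pa s).
#' @param sample_rate_Hz sampling rate (default 500 Hz, the calibration
#'   recording rate modelled).
#' @param duration_s recording length in s.
#' @param seed integer seed.
#' @param env a [tweezer_env()].
#' @return data frame with columns \code{time_s}, \code{y_nm}; attributes
#'   carry the generating parameters.
#' @examples
#' b <- simulate_bead_fluctuations(10, 3000, duration_s = 2, seed = 5)
#' var(b$y_nm)
#' @export
simulate_bead_fluctuations <- function(force_pN, extension_nm,
                                       bead_radius_um = 1.4,
                                       viscosity_Pa_s = 8.9e-4,
                                       sample_rate_Hz = 500, duration_s,
                                       seed = 1L, env = tweezer_env()) {
  if (force_pN <= 0 || extension_nm <= 0) {
    stop("`force_pN` and `extension_nm` must be > 0", call. = FALSE)
  }
  stopifnot(duration_s > 0, inherits(env, "tweezer_env"))
  set.seed(as.integer(seed %% 2147483647))
  gam <- .bead_drag(bead_radius_um, viscosity_Pa_s)
  kappa <- force_pN / extension_nm
  tau <- gam / kappa
  sd <- sqrt(env$thermal_energy_pNnm / kappa)
  dt <- 1 / sample_rate_Hz
  tt <- seq(0, duration_s, by = dt)
  y <- .ou_noise(length(tt), dt, tau, sd)
  structure(
    data.frame(time_s = tt, y_nm = y),
    class = c("bead_series", "data.frame"),
    force_pN = force_pN, extension_nm = extension_nm,
    relaxation_s = tau, stationary_sd_nm = sd,
    corner_frequency_Hz = 1 / (2 * pi * tau),
    sample_rate_Hz = sample_rate_Hz, seed = seed
  )
}
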