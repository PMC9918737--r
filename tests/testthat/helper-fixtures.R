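# Shared fixtures and independent oracles.

env25 <- tweezer_env()
dna119 <- polymer_state("unfolded_chain", 119)
ncp99 <- polymer_state("folded_nucleosome", 99)

# Independent closed-form oracle for the quadrature term: integration by
# parts of the Marko-Siggia relation gives
#   int_0^F z df = (kBT/A) [ z_eq phi_eq - (1/(4(1-z_eq)) - z_eq/4
#                             + z_eq^2/2 - 1/4) ],  phi_eq = F A / kBT,
# with z_eq obtained here by uniroot (a different root finder than the
# implementation's bisection).
oracle_delta_phi <- function(force, L_unfolded, L_folded, A,
                             kBT = env25$thermal_energy_pNnm) {
  if (force == 0) return(0)
  ms <- function(z) 1 / (4 * (1 - z)^2) - 1 / 4 + z
  int_z_df <- function(A) {
    z <- uniroot(function(z) kBT / A * ms(z) - force, c(0, 1 - 1e-12),
                 tol = 1e-15)$root
    phi <- force * A / kBT
    kBT / A * (z * phi - (1 / (4 * (1 - z)) - z / 4 + z^2 / 2 - 1 / 4))
  }
  -(L_unfolded - L_folded) * int_z_df(A)
}

# Build a noiseless (or noisy) single-cycle ramp trajectory with programmed
# state changes at given threshold forces, bypassing the stochastic kinetics.
programmed_ramp <- function(thresholds_pN, contours_nm, noise_sd = 0,
                            sample_rate_Hz = 25, max_force_pN = 32,
                            seed = 1L) {
  prot <- ramp_protocol(sample_rate_Hz = sample_rate_Hz,
                        max_force_pN = max_force_pN)
  law <- prot$force_law
  z_start <- uniroot(function(z) predict(law, z) - prot$rest_force_pN,
                     c(1e-6, 50), tol = 1e-12)$root
  z_end <- uniroot(function(z) predict(law, z) - prot$max_force_pN,
                   c(1e-6, 50), tol = 1e-12)$root
  dt <- 1 / sample_rate_Hz
  tt <- seq(0, (z_start - z_end) * 1e3 / prot$magnet_speed_um_s, by = dt)
  z <- z_start - prot$magnet_speed_um_s * tt / 1e3
  f <- predict(law, z)
  state <- findInterval(f, thresholds_pN) + 1L
  zeta <- vapply(f, function(fi) {
    if (fi <= 0) 0 else
      uniroot(function(zz) env25$thermal_energy_pNnm / 50 *
                (1 / (4 * (1 - zz)^2) - 1 / 4 + zz) - fi,
              c(0, 1 - 1e-12), tol = 1e-14)$root
  }, numeric(1))
  set.seed(seed)
  data.frame(
    time_s = tt, magnet_pos_um = z * 1e3, force_pN = f,
    extension_nm = contours_nm[state] * zeta + rnorm(length(tt), 0, noise_sd),
    cycle = 1L,
    truth_state = as.character(state),
    stringsAsFactors = FALSE
  )
}

# true transitions of a simulated trajectory, from its truth labels:
# one row per state change with the force at the last pre-change sample
truth_transitions <- function(traj) {
  out <- lapply(split(seq_len(nrow(traj)), traj$cycle), function(idx) {
    s <- traj$truth_state[idx]
    ch <- which(s[-1] != s[-length(s)])
    if (!length(ch)) return(NULL)
    data.frame(
      cycle = traj$cycle[idx[1]],
      time_s = traj$time_s[idx[ch + 1L]],
      force_pN = traj$force_pN[idx[ch]],
      from = s[ch], to = s[ch + 1L],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
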