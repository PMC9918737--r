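# Force calibration: power-spectral-density and variance methods for the
# tethered-bead pendulum, and the double-exponential force vs magnet-position
# law used to convert the magnet schedule into tension.

#' Double-exponential force versus magnet-position law
#'
#' \deqn{F(z) = a_1 e^{-z/d_1} + a_2 e^{-z/d_2}} with the magnet distance
#' \code{z} in mm. Monotone decreasing in z for non-negative amplitudes.
#'
#' @param a1_pN,a2_pN amplitudes in pN (>= 0).
#' @param d1_mm,d2_mm decay lengths in mm (> 0).
#' @return An object of class \code{force_law}.
#' @examples
#' fl <- force_law(80, 0.3, 6, 1.2)
#' predict(fl, z_mm = c(0.5, 2, 4))
#' @export
force_law <- function(a1_pN, d1_mm, a2_pN, d2_mm) {
  stopifnot(
    is.numeric(a1_pN), a1_pN >= 0, is.numeric(a2_pN), a2_pN >= 0,
    is.numeric(d1_mm), d1_mm > 0, is.numeric(d2_mm), d2_mm > 0
  )
  structure(
    list(a1_pN = a1_pN, d1_mm = d1_mm, a2_pN = a2_pN, d2_mm = d2_mm),
    class = "force_law"
  )
}

#' @export
print.force_law <- function(x, ...) {
  cat(sprintf("Force law: F(z) = %.4g exp(-z/%.4g) + %.4g exp(-z/%.4g)  [pN; z in mm]\n",
              x$a1_pN, x$d1_mm, x$a2_pN, x$d2_mm))
  if (!is.null(attr(x, "fit"))) {
    cat(sprintf("  fitted to %d points, residual sd %.3g pN\n",
                attr(x, "n_points"), attr(x, "resid_sd")))
  }
  invisible(x)
}

#' @param object a \code{force_law}.
#' @param z_mm magnet distances in mm.
#' @param ... unused.
#' @rdname force_law
#' @export
predict.force_law <- function(object, z_mm, ...) {
  object$a1_pN * exp(-z_mm / object$d1_mm) +
    object$a2_pN * exp(-z_mm / object$d2_mm)
}

#' @export
coef.force_law <- function(object, ...) {
  c(a1_pN = object$a1_pN, d1_mm = object$d1_mm,
    a2_pN = object$a2_pN, d2_mm = object$d2_mm)
}

# magnet distance at which the law gives `force`; bracketed on [lo, hi] mm
.force_law_invert <- function(law, force, lo = 1e-6, hi = 50) {
  vapply(force, function(f) {
    uniroot(function(z) predict(law, z) - f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Welch-averaged power spectral density
#'
#' One-sided PSD by the mean of modified periodograms over Hann-windowed,
#' 50\%-overlapping segments. Normalised so that the integral of the spectrum
#' over frequency equals the signal variance (Parseval): the periodogram of a
#' segment is \code{2 |FFT|^2 / (fs * sum(w^2))} with the DC and Nyquist bins
#' not doubled.
#'
#' @param series numeric vector, the bead coordinate in nm.
#' @param sample_rate_Hz sampling rate in Hz.
#' @param segment_length samples per segment; default the power of two nearest
#'   4096, capped at half the series length.
#' @param overlap_fraction fractional overlap between segments (default 0.5).
#' @return An object of class \code{psd_estimate}: list with
#'   \code{frequency_Hz}, \code{psd_nm2_per_Hz}, \code{n_segments},
#'   \code{segment_length}, \code{sample_rate_Hz}. The DC bin is excluded.
#' @examples
#' y <- sin(2 * pi * 50 * seq(0, 2, by = 1/500))
#' sp <- estimate_psd(y, 500, segment_length = 256)
#' @export
estimate_psd <- function(series, sample_rate_Hz, segment_length = NULL,
                         overlap_fraction = 0.5) {
  stopifnot(is.numeric(series), sample_rate_Hz > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  n <- length(series)
  if (is.null(segment_length)) {
    segment_length <- 2^round(log2(min(4096, floor(n / 2))))
  }
  segment_length <- as.integer(segment_length)
  step <- max(1L, as.integer(round(segment_length * (1 - overlap_fraction))))
  starts <- seq(1L, n - segment_length + 1L, by = step)
  if (length(starts) < 2L) {
    stop("series too short for PSD estimation: need at least 2 segments",
         call. = FALSE)
  }
  w <- 0.5 * (1 - cos(2 * pi * seq(0, segment_length - 1) / (segment_length - 1)))
  u <- sum(w^2)
  half <- segment_length %/% 2L
  acc <- numeric(half + 1L)
  for (s in starts) {
    seg <- series[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg)[1:(half + 1L)])^2 / (sample_rate_Hz * u)
    p[2:half] <- 2 * p[2:half]            # one-sided; DC & Nyquist not doubled
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freq <- (0:half) * sample_rate_Hz / segment_length
  structure(
    list(
      frequency_Hz = freq[-1L],
      psd_nm2_per_Hz = psd[-1L],
      n_segments = length(starts),
      segment_length = segment_length,
      sample_rate_Hz = sample_rate_Hz
    ),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("PSD estimate: %d segments of %d samples at %g Hz, %d bins (%.3g-%.3g Hz)\n",
              x$n_segments, x$segment_length, x$sample_rate_Hz,
              length(x$frequency_Hz), min(x$frequency_Hz), max(x$frequency_Hz)))
  invisible(x)
}

#' Force from the equipartition (variance) method
#'
#' For a bead tethered at extension \eqn{\ell} under tension F, the transverse
#' pendulum stiffness is \eqn{F/\ell} and equipartition gives
#' \deqn{F = k_B T\,\ell / \langle \delta y^2 \rangle.}
#'
#' @param variance_nm2 stationary variance of the transverse coordinate (nm^2).
#' @param extension_nm tether extension in nm.
#' @param env a [tweezer_env()].
#' @return force in pN.
#' @examples
#' force_from_variance(1234.9, 3000)
#' @export
force_from_variance <- function(variance_nm2, extension_nm, env = tweezer_env()) {
  stopifnot(inherits(env, "tweezer_env"))
  if (!is.numeric(variance_nm2) || any(variance_nm2 <= 0) ||
      !is.numeric(extension_nm) || any(extension_nm <= 0)) {
    stop("`variance_nm2` and `extension_nm` must be > 0", call. = FALSE)
  }
  env$thermal_energy_pNnm * extension_nm / variance_nm2
}

# drag coefficient of a sphere, pN s / nm
.bead_drag <- function(bead_radius_um, viscosity_Pa_s) {
  6 * pi * viscosity_Pa_s * bead_radius_um * 1e-6 * 1e3
}

#' Force from a Lorentzian fit to the bead power spectrum
#'
#' The transverse fluctuation spectrum of a tethered bead is a Lorentzian
#' \deqn{S(f) = S_0 / (1 + (f/f_c)^2),\qquad f_c = F / (2\pi\gamma\ell),}
#' with \eqn{\gamma = 6\pi\eta r} the bead drag. The fit is least squares on
#' log-PSD over log-spaced frequency bins between \code{f_min_Hz} and half the
#' Nyquist frequency, which balances the decades; the force is recovered from
#' the corner frequency as \eqn{F = 2\pi\gamma\ell f_c}. A second force
#' estimate from the plateau (\eqn{F = \ell\sqrt{4 k_B T \gamma / S_0}}) is
#' reported as a cross-check.
#'
#' @param spectrum a [estimate_psd()] result.
#' @param extension_nm tether extension in nm.
#' @param bead_radius_um bead radius in um (default 1.4, an M280 bead).
#' @param viscosity_Pa_s medium viscosity (default 8.9e-4, water at 25 C).
#' @param env a [tweezer_env()].
#' @param f_min_Hz lower edge of the fitted band (default 0.5 Hz).
#' @param n_bins number of log-spaced bins (default 60).
#' @return An object of class \code{lorentzian_fit}: list with
#'   \code{force_pN}, \code{corner_frequency_Hz}, \code{plateau_nm2_per_Hz},
#'   \code{force_from_plateau_pN}, \code{band_Hz}, \code{warnings}.
#' @export
fit_lorentzian_force <- function(spectrum, extension_nm, bead_radius_um = 1.4,
                                 viscosity_Pa_s = 8.9e-4, env = tweezer_env(),
                                 f_min_Hz = 0.5, n_bins = 60) {
  stopifnot(inherits(spectrum, "psd_estimate"), extension_nm > 0)
  f_max <- spectrum$sample_rate_Hz / 4   # Nyquist / 2
  sel <- spectrum$frequency_Hz >= f_min_Hz & spectrum$frequency_Hz <= f_max &
    spectrum$psd_nm2_per_Hz > 0
  if (sum(sel) < 8) stop("spectrum has too few usable bins in the fit band",
                         call. = FALSE)
  f <- spectrum$frequency_Hz[sel]
  s <- spectrum$psd_nm2_per_Hz[sel]
  # log-spaced binning
  edges <- exp(seq(log(f_min_Hz), log(f_max), length.out = n_bins + 1))
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= n_bins
  fb <- tapply(f[keep], idx[keep], function(v) exp(mean(log(v))))
  sb <- tapply(s[keep], idx[keep], function(v) exp(mean(log(v))))
  fb <- as.numeric(fb); sb <- as.numeric(sb)
  warnings <- character(0)
  # flat-spectrum guard: a Lorentzian decays ~100x over two decades
  dyn <- stats::median(sb[fb <= stats::quantile(fb, 0.2)]) /
    stats::median(sb[fb >= stats::quantile(fb, 0.8)])
  if (!is.finite(dyn) || dyn < 2) {
    stop("no corner detectable: spectrum is flat over the fitted band",
         call. = FALSE)
  }
  s0_init <- stats::median(sb[fb <= stats::quantile(fb, 0.15)])
  fc_init <- fb[which.min(abs(sb - s0_init / 2))]
  fit <- minpack.lm::nlsLM(
    log(sb) ~ ls0 - log(1 + (fb / exp(lfc))^2),
    start = list(ls0 = log(s0_init), lfc = log(fc_init)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  s0 <- exp(coef(fit)[["ls0"]])
  fc <- exp(coef(fit)[["lfc"]])
  if (fc < f_min_Hz || fc > f_max) {
    warnings <- c(warnings, sprintf(
      "corner frequency %.3g Hz outside fitted band [%.3g, %.3g] Hz; force poorly constrained",
      fc, f_min_Hz, f_max))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  gam <- .bead_drag(bead_radius_um, viscosity_Pa_s)
  structure(
    list(
      force_pN = 2 * pi * gam * extension_nm * fc,
      corner_frequency_Hz = fc,
      plateau_nm2_per_Hz = s0,
      force_from_plateau_pN =
        extension_nm * sqrt(4 * env$thermal_energy_pNnm * gam / s0),
      band_Hz = c(f_min_Hz, f_max),
      fit = fit,
      warnings = warnings
    ),
    class = "lorentzian_fit"
  )
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian PSD fit: fc = %.3g Hz, F = %.3g pN (plateau cross-check %.3g pN)\n",
              x$corner_frequency_Hz, x$force_pN, x$force_from_plateau_pN))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Fit the double-exponential force versus magnet-position law
#'
#' Nonlinear least squares with multiple starting points (the decay-length
#' pair is seeded over a grid of scale splits) so the fit does not depend on a
#' lucky initialisation. Amplitudes and decay lengths are constrained
#' positive through a log parameterisation.
#'
#' @param magnet_pos_mm magnet distances in mm.
#' @param force_pN measured forces in pN.
#' @param weights optional fitting weights.
#' @return a [force_law()] with attributes \code{fit} (the nls object),
#'   \code{resid_sd} and \code{n_points}.
#' @export
fit_force_magnet_law <- function(magnet_pos_mm, force_pN, weights = NULL) {
  stopifnot(length(magnet_pos_mm) == length(force_pN))
  if (length(magnet_pos_mm) < 5) {
    stop("need at least 5 calibration points", call. = FALSE)
  }
  ord <- order(magnet_pos_mm)
  z <- magnet_pos_mm[ord]; fo <- force_pN[ord]
  w <- if (is.null(weights)) rep(1, length(z)) else weights[ord]
  if (any(diff(fo) > 0.05 * max(fo))) {
    warning("forces are not monotone decreasing in magnet position", call. = FALSE)
  }
  span <- diff(range(z))
  # multi-start over decay-length splits
  starts <- expand.grid(d1 = span * c(0.05, 0.15, 0.4),
                        d2 = span * c(0.5, 1, 2))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(la1 = log(max(fo) * 0.9 + 1e-6), ld1 = log(starts$d1[i]),
               la2 = log(max(fo) * 0.1 + 1e-6), ld2 = log(starts$d2[i]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fo ~ exp(la1) * exp(-z / exp(ld1)) + exp(la2) * exp(-z / exp(ld2)),
        start = st, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) {
    stop("force-law fit failed from all starting points", call. = FALSE)
  }
  cf <- exp(coef(best))
  names(cf) <- c("a1", "d1", "a2", "d2")
  # report the faster-decaying component first
  if (cf[["d1"]] > cf[["d2"]]) {
    cf <- cf[c("a2", "d2", "a1", "d1")]
    names(cf) <- c("a1", "d1", "a2", "d2")
  }
  law <- force_law(cf[["a1"]], cf[["d1"]], cf[["a2"]], cf[["d2"]])
  attr(law, "fit") <- best
  attr(law, "resid_sd") <- sqrt(best_rss / max(1, length(z) - 4))
  attr(law, "n_points") <- length(z)
  law
}
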