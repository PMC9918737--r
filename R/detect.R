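# Event detection: ruptures and contour gains from force-ramp cycles,
# reversibility calls across cycles, dwell records at constant force,
# deposition steps, and bound/unbound calls for force-jump cycles.

.require_columns <- function(trajectory, cols) {
  missing <- setdiff(cols, names(trajectory))
  if (length(missing)) {
    stop("trajectory is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Detect rupture events in force-ramp trajectories
#'
#' A rupture is a sustained forward extension jump of at least
#' \code{jump_threshold_nm} between the means of adjacent
#' \code{window_samples}-sample windows. The rupture force is read at the
#' last pre-jump sample (the "rupture force" of a monotone ramp), the
#' extension jump is the difference of the post- and pre-jump window means,
#' and the contour gain converts the jump to contour length through the WLC
#' relative extension at the rupture force. Cycles are processed
#' independently; events are returned in time order.
#'
#' @param trajectory an \code{sm_trajectory} (or data frame) with columns
#'   \code{time_s}, \code{force_pN}, \code{extension_nm} and optionally
#'   \code{cycle}.
#' @param jump_threshold_nm minimum sustained jump (default 8 nm, about four
#'   times the default bead-noise sd).
#' @param window_samples window length for the pre/post means (default 5).
#' @param guard_samples samples excluded on each side of the located boundary
#'   when measuring the jump size (default 2), so that a boundary mislocated
#'   by a sample or two under noise does not bias the size estimate.
#' @param persistence_length_nm WLC persistence length for the contour
#'   conversion.
#' @param env a [tweezer_env()].
#' @return data frame with one row per event: \code{cycle}, \code{time_s},
#'   \code{force_pN}, \code{extension_jump_nm}, \code{contour_gain_nm},
#'   \code{wrap_class} (all \code{"unclassified"}; see
#'   [classify_ruptures()]).
#' @export
detect_ruptures <- function(trajectory, jump_threshold_nm = 8,
                            window_samples = 5L, guard_samples = 2L,
                            persistence_length_nm = 50,
                            env = tweezer_env()) {
  .require_columns(trajectory, c("time_s", "force_pN", "extension_nm"))
  if (is.null(trajectory$cycle)) trajectory$cycle <- 1L
  w <- as.integer(window_samples)
  stopifnot(w >= 1L, jump_threshold_nm > 0)
  events <- lapply(split(seq_len(nrow(trajectory)), trajectory$cycle),
                   function(idx) {
    x <- trajectory$extension_nm[idx]
    n <- length(x)
    if (n < 2L * w + 1L) return(NULL)
    cm <- c(0, cumsum(x))
    # mean of the w samples ending at i / starting at i+1
    pre <- (cm[(w + 1L):(n + 1L)] - cm[1:(n - w + 1L)]) / w     # i = w..n
    d <- pre[(w + 1L):(n - w + 1L)] - pre[1:(n - 2L * w + 1L)]  # i = w..n-w
    cand <- which(d >= jump_threshold_nm)
    if (!length(cand)) return(NULL)
    grp <- cumsum(c(1L, diff(cand) > 1L))
    rows <- lapply(split(cand, grp), function(g) {
      # cand position j corresponds to boundary after sample i = j + w - 1
      j <- g[which.max(d[g])]
      i <- j + w - 1L
      # size re-measured with a guard band around the located boundary
      gd <- as.integer(guard_samples)
      pre_idx <- max(1L, i - gd - w + 1L):max(1L, i - gd)
      post_idx <- min(n, i + 1L + gd):min(n, i + gd + w)
      jump <- mean(x[post_idx]) - mean(x[pre_idx])
      f <- trajectory$force_pN[idx[i]]
      zeta <- .wlc_invert(f, persistence_length_nm, env$thermal_energy_pNnm)
      data.frame(
        cycle = trajectory$cycle[idx[1L]],
        time_s = trajectory$time_s[idx[i]],
        force_pN = f,
        extension_jump_nm = jump,
        contour_gain_nm = jump / zeta,
        wrap_class = "unclassified",
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, events)
  if (is.null(out)) {
    out <- data.frame(cycle = integer(0), time_s = numeric(0),
                      force_pN = numeric(0), extension_jump_nm = numeric(0),
                      contour_gain_nm = numeric(0), wrap_class = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$time_s), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Classify rupture events as outer- or inner-wrap transitions
#'
#' Nucleosome mode: within a cycle the first event is the outer wrap and the
#' second the inner wrap; a lone event is called inner when its force exceeds
#' \code{boundary_pN} (default 12 pN, between the outer and inner force
#' scales), otherwise outer; any events beyond the second are flagged
#' unclassified. Tetrasome mode: every event is the inner wrap.
#'
#' @param events a rupture-event data frame from [detect_ruptures()].
#' @param mode \code{"nucleosome"} or \code{"tetrasome"}.
#' @param boundary_pN outer/inner boundary for single-event cycles.
#' @return the events with \code{wrap_class} filled in.
#' @export
classify_ruptures <- function(events, mode = c("nucleosome", "tetrasome"),
                              boundary_pN = 12) {
  mode <- match.arg(mode)
  if (nrow(events) == 0L) return(events)
  for (cyc in unique(events$cycle)) {
    sel <- which(events$cycle == cyc)
    sel <- sel[order(events$time_s[sel])]
    if (mode == "tetrasome") {
      events$wrap_class[sel] <- "inner"
    } else if (length(sel) == 1L) {
      events$wrap_class[sel] <-
        if (events$force_pN[sel] > boundary_pN) "inner" else "outer"
    } else {
      events$wrap_class[sel[1L]] <- "outer"
      events$wrap_class[sel[2L]] <- "inner"
      if (length(sel) > 2L) events$wrap_class[sel[-(1:2)]] <- "unclassified"
    }
  }
  events
}

#' Assess reversibility of unfolding across stretch cycles
#'
#' A molecule is called reversible when the complete unfolding pattern (both
#' outer and inner steps in nucleosome mode; the single step in tetrasome
#' mode) recurs in at least \code{min_fraction} of the cycles after the
#' first. With a single cycle the call is indeterminate.
#'
#' @param events rupture events (classified or not) for one molecule.
#' @param n_cycles total number of stretch cycles run (cycles with no events
#'   do not appear in \code{events}).
#' @param mode \code{"nucleosome"} or \code{"tetrasome"}.
#' @param min_fraction fraction of post-first cycles that must show the full
#'   pattern (default 0.8).
#' @return list with \code{reversible} (logical, \code{NA} if indeterminate),
#'   \code{pattern_by_cycle} (logical vector of length \code{n_cycles}) and
#'   \code{fraction_after_first}.
#' @export
assess_reversibility <- function(events, n_cycles,
                                 mode = c("nucleosome", "tetrasome"),
                                 min_fraction = 0.8) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 1)
  need <- if (mode == "nucleosome") 2L else 1L
  counts <- integer(n_cycles)
  if (nrow(events)) {
    tb <- table(factor(events$cycle, levels = seq_len(n_cycles)))
    counts <- as.integer(tb)
  }
  pattern <- counts >= need
  if (n_cycles < 2L) {
    return(list(reversible = NA, pattern_by_cycle = pattern,
                fraction_after_first = NA_real_))
  }
  frac <- mean(pattern[-1L])
  list(reversible = frac >= min_fraction, pattern_by_cycle = pattern,
       fraction_after_first = frac)
}

#' Extract dwell records from a constant-force hopping trace
#'
#' Two-level state assignment by a half-amplitude threshold with a hysteresis
#' band: the state switches up only when the extension exceeds the midpoint
#' plus \code{hysteresis_fraction} of the amplitude and down only below the
#' symmetric lower bound, which suppresses noise-driven double counting. The
#' first and last dwells are censored by the trace edges and excluded.
#'
#' @param trajectory constant-force trace with columns \code{time_s},
#'   \code{extension_nm}.
#' @param hysteresis_fraction half-width of the dead band as a fraction of
#'   the two-level amplitude (default 0.25).
#' @param min_dwell_samples dwells shorter than this many samples are
#'   discarded as threshold glitches (default 2).
#' @return data frame with columns \code{state} (\code{"folded"} low level,
#'   \code{"unfolded"} high level), \code{duration_s}, \code{clamp_force_pN}.
#' @export
extract_dwells <- function(trajectory, hysteresis_fraction = 0.25,
                           min_dwell_samples = 2L) {
  .require_columns(trajectory, c("time_s", "extension_nm"))
  x <- trajectory$extension_nm
  lo_lev <- stats::quantile(x, 0.05, names = FALSE)
  hi_lev <- stats::quantile(x, 0.95, names = FALSE)
  amp <- hi_lev - lo_lev
  if (amp == 0) {
    return(data.frame(state = character(0), duration_s = numeric(0),
                      clamp_force_pN = numeric(0), stringsAsFactors = FALSE))
  }
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (amp < 4 * noise_sd) {
    stop("levels indistinguishable: two-level amplitude is below the noise",
         call. = FALSE)
  }
  mid <- (lo_lev + hi_lev) / 2
  h <- hysteresis_fraction * amp
  s <- rep(NA_integer_, length(x))
  s[x > mid + h] <- 2L
  s[x < mid - h] <- 1L
  # carry the last decided state forward; leading undecided samples take the
  # first decided state
  decided <- which(!is.na(s))
  if (!length(decided)) {
    return(data.frame(state = character(0), duration_s = numeric(0),
                      clamp_force_pN = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- cumsum(!is.na(s))
  idx[idx == 0L] <- 1L
  filled <- s[decided][idx]
  r <- rle(filled)
  if (length(r$lengths) < 3L) {
    return(data.frame(state = character(0), duration_s = numeric(0),
                      clamp_force_pN = numeric(0), stringsAsFactors = FALSE))
  }
  dt <- stats::median(diff(trajectory$time_s))
  keep <- 2:(length(r$lengths) - 1L)
  keep <- keep[r$lengths[keep] >= min_dwell_samples]
  force <- if (!is.null(trajectory$force_pN)) {
    stats::median(trajectory$force_pN)
  } else NA_real_
  data.frame(
    state = c("folded", "unfolded")[r$values[keep]],
    duration_s = r$lengths[keep] * dt,
    clamp_force_pN = force,
    stringsAsFactors = FALSE
  )
}

# Welch t statistic for a mean shift at the best split of x; returns the
# split index (last sample of the left segment) and the statistic
.best_split <- function(x, min_segment) {
  n <- length(x)
  if (n < 2L * min_segment) return(NULL)
  cm <- c(0, cumsum(x)); cm2 <- c(0, cumsum(x^2))
  k <- min_segment:(n - min_segment)
  m1 <- cm[k + 1L] / k
  m2 <- (cm[n + 1L] - cm[k + 1L]) / (n - k)
  v1 <- pmax(0, (cm2[k + 1L] - k * m1^2) / pmax(1, k - 1L))
  v2 <- pmax(0, (cm2[n + 1L] - cm2[k + 1L] - (n - k) * m2^2) / pmax(1, n - k - 1L))
  se <- sqrt(v1 / k + v2 / (n - k))
  tt <- abs(m2 - m1) / pmax(se, .Machine$double.eps)
  j <- which.max(tt)
  list(split = k[j], stat = tt[j])
}

#' Detect steps in a near-constant-force trace
#'
#' Change-point detection by recursive binary segmentation on mean shifts:
#' the best split of each segment is accepted when its Welch-style statistic
#' exceeds \code{stat_threshold}, and the two halves are searched in turn.
#' Step sizes are differences of the means of consecutive final segments.
#'
#' @param trajectory trace with columns \code{time_s}, \code{extension_nm}.
#' @param stat_threshold acceptance threshold for the Welch statistic
#'   (default 10; the best-split statistic of pure noise grows only like
#'   \eqn{\sqrt{2\log n}}).
#' @param min_segment minimum samples per segment (default 5).
#' @return data frame with one row per step: \code{time_s} (of the first
#'   post-step sample), \code{size_nm} (signed). Zero rows for a flat trace.
#' @export
detect_steps <- function(trajectory, stat_threshold = 10, min_segment = 5L) {
  .require_columns(trajectory, c("time_s", "extension_nm"))
  x <- trajectory$extension_nm
  breaks <- integer(0)
  recurse <- function(from, to) {
    seg <- x[from:to]
    bs <- .best_split(seg, min_segment)
    if (is.null(bs) || bs$stat < stat_threshold) return(invisible())
    cut <- from + bs$split - 1L
    breaks <<- c(breaks, cut)
    recurse(from, cut)
    recurse(cut + 1L, to)
  }
  recurse(1L, length(x))
  if (!length(breaks)) {
    return(data.frame(time_s = numeric(0), size_nm = numeric(0)))
  }
  breaks <- sort(breaks)
  # pruning pass: re-test every break against its two adjacent final
  # segments and drop the weakest until all survive, which removes spurious
  # splits introduced next to genuine change points
  repeat {
    bounds <- c(0L, breaks, length(x))
    stat_at <- vapply(seq_along(breaks), function(i) {
      l <- x[(bounds[i] + 1L):bounds[i + 1L]]
      r <- x[(bounds[i + 1L] + 1L):bounds[i + 2L]]
      se <- sqrt(stats::var(l) / length(l) + stats::var(r) / length(r))
      abs(mean(r) - mean(l)) / max(se, .Machine$double.eps)
    }, numeric(1))
    if (all(is.finite(stat_at) & stat_at >= stat_threshold) ||
        length(breaks) == 0L) break
    breaks <- breaks[-which.min(stat_at)]
    if (!length(breaks)) {
      return(data.frame(time_s = numeric(0), size_nm = numeric(0)))
    }
  }
  bounds <- c(0L, breaks, length(x))
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(x[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  data.frame(
    time_s = trajectory$time_s[breaks + 1L],
    size_nm = diff(seg_means)
  )
}

#' Classify force-jump cycles as bound (complex) or free (nucleosome)
#'
#' Maps the per-cycle observable (was a disruption seen at the probe force?)
#' to a bound/unbound call. For the unmodified nucleosome at the 11 pN probe
#' the inner wrap is disrupted only when FACT is bound, so disruption means
#' \code{"complex"}. For the ubH2B nucleosome at the 6 pN probe the outer
#' wrap is disrupted only when FACT is absent, so disruption means
#' \code{"nucleosome"}.
#'
#' @param cycles a \code{binding_cycles} data frame (from
#'   [simulate_force_jump_binding()] or equivalent) with columns
#'   \code{condition} and \code{disruption_at_probe}; alternatively a logical
#'   vector of disruption flags together with \code{condition}.
#' @param condition used only when \code{cycles} is a bare logical vector.
#' @return the data frame with an \code{outcome} column added (factor levels
#'   \code{"complex"}, \code{"nucleosome"}), or a character vector of
#'   outcomes for vector input.
#' @export
classify_binding_cycle <- function(cycles, condition = NULL) {
  map <- function(disrupted, cond) {
    if (!cond %in% c("unmodified", "ubh2b")) {
      stop("unknown condition: ", cond, call. = FALSE)
    }
    bound_call <- if (cond == "unmodified") disrupted else !disrupted
    ifelse(bound_call, "complex", "nucleosome")
  }
  if (is.logical(cycles)) {
    if (is.null(condition)) stop("`condition` required for vector input",
                                 call. = FALSE)
    return(map(cycles, condition))
  }
  .require_columns(cycles, c("condition", "disruption_at_probe"))
  cycles$outcome <- unlist(lapply(seq_len(nrow(cycles)), function(i) {
    map(cycles$disruption_at_probe[i], cycles$condition[i])
  }))
  cycles
}
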