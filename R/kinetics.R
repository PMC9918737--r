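# Statistical layer: exponential rate estimation from dwell times,
# equilibrium-force determination, state-counting Kd estimation with
# bootstrap uncertainty and condition comparison, box-plot style
# distribution summaries and assembly fractions.

#' Exponential rate from dwell durations
#'
#' Maximum-likelihood rate for exponentially distributed dwells,
#' \eqn{\hat k = 1/\bar d}, with the exact chi-square confidence interval for
#' exponential samples: \eqn{k \in \chi^2_{2n}(\alpha/2, 1-\alpha/2) / (2
#' \sum d_i)}.
#'
#' @param dwells vector of complete dwell durations in s (>= 1 value, all
#'   > 0).
#' @param conf confidence level (default 0.95).
#' @return list with \code{rate_per_s}, \code{ci} (length 2), \code{n}.
#' @examples
#' estimate_rate(c(1, 2, 3, 4))
#' @export
estimate_rate <- function(dwells, conf = 0.95) {
  if (length(dwells) < 1L) stop("need at least one complete dwell", call. = FALSE)
  if (any(dwells <= 0)) stop("dwell durations must be > 0", call. = FALSE)
  n <- length(dwells)
  total <- sum(dwells)
  a <- (1 - conf) / 2
  list(
    rate_per_s = n / total,
    ci = stats::qchisq(c(a, 1 - a), df = 2 * n) / (2 * total),
    n = n
  )
}

#' Equilibrium force of a two-state transition
#'
#' Two conventions are supported. \code{method = "rates"}: fit a straight
#' line to \eqn{\ln K(f) = \ln[k_{u\to f}(f)/k_{f\to u}(f)]} against force
#' and return its root, the force at which folding and unfolding rates are
#' equal (\eqn{\Delta G(F_{eq}) = 0}). \code{method = "median_rupture"} (the
#' default convention): the sample median of the outer-wrap rupture forces.
#'
#' @param x for \code{"rates"}, a data frame with columns \code{force_pN},
#'   \code{k_fold_per_s}, \code{k_unfold_per_s} (at least two forces); for
#'   \code{"median_rupture"}, a numeric vector of rupture forces.
#' @param method \code{"median_rupture"} or \code{"rates"}.
#' @return equilibrium force in pN.
#' @examples
#' equilibrium_force(c(3.0, 3.5, 4.0, 4.5, 5.0))
#' @export
equilibrium_force <- function(x, method = c("median_rupture", "rates")) {
  method <- match.arg(method)
  if (method == "median_rupture") {
    if (!is.numeric(x) || length(x) < 1L) {
      stop("need at least one rupture force", call. = FALSE)
    }
    return(stats::median(x))
  }
  stopifnot(is.data.frame(x),
            all(c("force_pN", "k_fold_per_s", "k_unfold_per_s") %in% names(x)))
  if (nrow(x) < 2L) stop("need rates at >= 2 forces", call. = FALSE)
  lnK <- log(x$k_fold_per_s / x$k_unfold_per_s)
  if (all(lnK > 0) || all(lnK < 0)) {
    warning("ln K does not change sign over the measured forces; ",
            "the equilibrium force is an extrapolation", call. = FALSE)
  }
  fit <- stats::lm(lnK ~ x$force_pN)
  -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
}

#' State-counting dissociation constant
#'
#' \deqn{K_d = \frac{N_{nucleosome}}{N_{complex}}\,[FACT],}
#' the ratio of free-nucleosome to complex counts over repeated force-jump
#' cycles times the chaperone concentration.
#'
#' @param n_nucleosome count of FACT-free outcomes (>= 0).
#' @param n_complex count of bound outcomes (>= 1; with no bound cycles the
#'   Kd is unbounded).
#' @param fact_conc_nM chaperone concentration in nM.
#' @return Kd in nM.
#' @examples
#' estimate_kd(300, 700, 83)
#' @export
estimate_kd <- function(n_nucleosome, n_complex, fact_conc_nM) {
  stopifnot(n_nucleosome >= 0, fact_conc_nM > 0)
  if (n_complex < 1) stop("no bound cycles; Kd unbounded", call. = FALSE)
  (n_nucleosome / n_complex) * fact_conc_nM
}

.counts_from_cycles <- function(cycles) {
  if (is.null(cycles$outcome)) cycles <- classify_binding_cycle(cycles)
  c(n_nucleosome = sum(cycles$outcome == "nucleosome"),
    n_complex = sum(cycles$outcome == "complex"))
}

#' Kd with cycle-level bootstrap uncertainty
#'
#' Point estimate by [estimate_kd()] on the outcome counts, uncertainty by
#' nonparametric bootstrap over cycles: the SE is the bootstrap standard
#' deviation and the 95% interval the percentile interval. Resamples with no
#' bound cycle leave the Kd unbounded and are dropped, with the count
#' reported.
#'
#' @param cycles a \code{binding_cycles} data frame (classified or not) with
#'   at least 10 cycles.
#' @param fact_conc_nM chaperone concentration in nM.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the resampling.
#' @return object of class \code{kd_estimate}: list with \code{kd_nM},
#'   \code{se_nM}, \code{ci_95}, \code{n_cycles}, \code{n_nucleosome},
#'   \code{n_complex}, \code{fact_conc_nM}, \code{n_degenerate_dropped}.
#' @export
kd_uncertainty <- function(cycles, fact_conc_nM = 83, n_boot = 2000, seed = 1L) {
  if (nrow(cycles) < 10L) stop("need at least 10 cycles", call. = FALSE)
  if (is.null(cycles$outcome)) cycles <- classify_binding_cycle(cycles)
  free <- cycles$outcome == "nucleosome"
  n <- length(free)
  cnt <- .counts_from_cycles(cycles)
  kd <- estimate_kd(cnt[["n_nucleosome"]], cnt[["n_complex"]], fact_conc_nM)
  set.seed(as.integer(seed %% 2147483647))
  boot <- vapply(seq_len(n_boot), function(b) {
    nf <- sum(free[sample.int(n, n, replace = TRUE)])
    if (nf == n) NA_real_ else (nf / (n - nf)) * fact_conc_nM
  }, numeric(1))
  dropped <- sum(is.na(boot))
  boot <- boot[!is.na(boot)]
  structure(
    list(
      kd_nM = kd,
      se_nM = stats::sd(boot),
      ci_95 = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
      n_cycles = n,
      n_nucleosome = cnt[["n_nucleosome"]],
      n_complex = cnt[["n_complex"]],
      fact_conc_nM = fact_conc_nM,
      n_degenerate_dropped = dropped
    ),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd = %.2f +/- %.2f nM (bootstrap SE; 95%% CI %.2f-%.2f nM)\n",
              x$kd_nM, x$se_nM, x$ci_95[1], x$ci_95[2]))
  cat(sprintf("  %d cycles at [FACT] = %g nM: %d nucleosome, %d complex\n",
              x$n_cycles, x$fact_conc_nM, x$n_nucleosome, x$n_complex))
  if (x$n_degenerate_dropped > 0) {
    cat(sprintf("  %d degenerate resamples (all bound) dropped\n",
                x$n_degenerate_dropped))
  }
  invisible(x)
}

#' Compare Kd between two conditions
#'
#' Primary test: two-sided bootstrap on the Kd difference (cycle-level
#' resampling in each arm; the p-value is the two-sided percentile position
#' of zero in the difference distribution, with add-one smoothing). An exact
#' two-proportion test on the bound fractions is reported as a cross-check.
#'
#' @param cycles_a,cycles_b \code{binding_cycles} data frames (>= 10 cycles
#'   each).
#' @param fact_conc_nM chaperone concentration (shared).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list with \code{kd_a_nM}, \code{kd_b_nM}, \code{difference_nM},
#'   \code{ci_95_difference}, \code{p_value} (bootstrap),
#'   \code{p_value_proportion} (prop.test cross-check).
#' @export
compare_conditions <- function(cycles_a, cycles_b, fact_conc_nM = 83,
                               n_boot = 2000, seed = 1L) {
  for (cyc in list(cycles_a, cycles_b)) {
    if (nrow(cyc) < 10L) stop("need at least 10 cycles per condition",
                              call. = FALSE)
  }
  if (is.null(cycles_a$outcome)) cycles_a <- classify_binding_cycle(cycles_a)
  if (is.null(cycles_b$outcome)) cycles_b <- classify_binding_cycle(cycles_b)
  fa <- cycles_a$outcome == "nucleosome"; na <- length(fa)
  fb <- cycles_b$outcome == "nucleosome"; nb <- length(fb)
  kd_of <- function(nf, n) if (nf >= n) NA_real_ else (nf / (n - nf)) * fact_conc_nM
  kd_a <- kd_of(sum(fa), na)
  kd_b <- kd_of(sum(fb), nb)
  set.seed(as.integer(seed %% 2147483647))
  diffs <- vapply(seq_len(n_boot), function(b) {
    kd_of(sum(fa[sample.int(na, na, replace = TRUE)]), na) -
      kd_of(sum(fb[sample.int(nb, nb, replace = TRUE)]), nb)
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  p_lo <- (1 + sum(diffs <= 0)) / (1 + length(diffs))
  p_hi <- (1 + sum(diffs >= 0)) / (1 + length(diffs))
  pt <- stats::prop.test(c(sum(fa), sum(fb)), c(na, nb))
  list(
    kd_a_nM = kd_a, kd_b_nM = kd_b,
    difference_nM = kd_a - kd_b,
    ci_95_difference = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
    p_value = min(1, 2 * min(p_lo, p_hi)),
    p_value_proportion = pt$p.value
  )
}

#' Box-plot style distribution summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7), outliers defined as points beyond the box edges by more
#' than 1.5 times the interquartile range, and whiskers at the most extreme
#' non-outlier points.
#'
#' @param values numeric vector (n >= 1).
#' @return object of class \code{distribution_summary}: list with \code{n},
#'   \code{median}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}, \code{outliers}.
#' @examples
#' summarize_distribution(c(1, 2, 3, 4, 100))
#' @export
summarize_distribution <- function(values) {
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  out <- values[values < lo_fence | values > hi_fence]
  inlier <- values[values >= lo_fence & values <= hi_fence]
  structure(
    list(
      n = length(values),
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inlier), whisker_high = max(inlier),
      outliers = sort(out)
    ),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d: median %.3g [Q1 %.3g, Q3 %.3g], whiskers %.3g-%.3g, %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Assembly fraction across replicate batches
#'
#' Per-batch fraction of molecules successfully assembled, reported as mean
#' plus/minus the standard deviation across batches, in percent.
#'
#' @param batches list of logical vectors (one per batch; TRUE = assembled).
#'   Empty batches are skipped with a warning.
#' @return list with \code{mean_percent}, \code{sd_percent},
#'   \code{per_batch_percent}, \code{n_batches}.
#' @examples
#' assembly_fraction(list(rep(c(TRUE, FALSE), c(8, 2)),
#'                        rep(c(TRUE, FALSE), c(7, 3)),
#'                        rep(c(TRUE, FALSE), c(9, 1))))
#' @export
assembly_fraction <- function(batches) {
  stopifnot(is.list(batches), length(batches) >= 1L)
  empty <- vapply(batches, function(b) length(b) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " empty batch(es) skipped", call. = FALSE)
    batches <- batches[!empty]
  }
  if (!length(batches)) stop("no non-empty batches", call. = FALSE)
  per <- vapply(batches, function(b) 100 * mean(as.logical(b)), numeric(1))
  list(
    mean_percent = mean(per),
    sd_percent = if (length(per) > 1L) stats::sd(per) else 0,
    per_batch_percent = per,
    n_batches = length(per)
  )
}
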