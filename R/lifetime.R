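#' Construct a TCSPC decay curve
#'
#' @param time_ns Uniformly spaced ascending bin centers, ns.
#' @param counts Non-negative photon counts per bin; total must be > 0.
#' @param repetition_period_ns Optional excitation repetition period, ns
#'   (400 ns for the 2.5 MHz source modeled here).
#' @return A `qdfret_decay` list with fields `time_ns`, `counts`,
#'   `bin_width_ns`, `repetition_period_ns`.
#' @export
decay_curve <- function(time_ns, counts, repetition_period_ns = NULL) {
  time_ns <- as.numeric(time_ns)
  counts <- as.numeric(counts)
  if (length(time_ns) < 4L) stop("decay curve needs at least 4 bins")
  if (length(counts) != length(time_ns))
    stop("time_ns and counts differ in length")
  d <- diff(time_ns)
  if (any(d <= 0)) stop("time bins must be strictly ascending")
  if (max(abs(d - d[1])) > 1e-9 * d[1])
    stop("time bins must be uniformly spaced (within 1e-9 relative)")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("decay curve has no photons")
  if (!is.null(repetition_period_ns) && repetition_period_ns <= 0)
    stop("repetition_period_ns must be > 0")
  structure(list(time_ns = time_ns, counts = counts,
                 bin_width_ns = d[1],
                 repetition_period_ns = repetition_period_ns),
            class = "qdfret_decay")
}

#' @export
print.qdfret_decay <- function(x, ...) {
  cat(sprintf("<TCSPC decay: %d bins x %.3g ns, %.3g counts, peak at %.3g ns>\n",
              length(x$time_ns), x$bin_width_ns, sum(x$counts),
              x$time_ns[which.max(x$counts)]))
  invisible(x)
}

# Multi-exponential model evaluated at times t (relative to window
# start; amplitudes are back-projected to the time origin afterwards):
# C * sum_i f_i exp(-t/tau_i) + bg, parameterized by raw amplitudes
# a_i = C * f_i.
decay_model <- function(t, amplitudes, taus, background) {
  m <- outer(t, taus, function(tt, tau) exp(-tt / tau)) %*% amplitudes
  as.vector(m) + background
}

# Weighted chi-square with Neyman weights 1/max(count, 1).
decay_chisq <- function(y, mu) sum((y - mu)^2 / pmax(y, 1))

#' Fit a multi-exponential model to a TCSPC decay histogram
#'
#' Tail fit (no IRF reconvolution) of
#' I(t) = C * sum_i gamma_i exp(-t/tau_i) + background over a window
#' starting after the histogram peak, by weighted nonlinear least squares
#' with Neyman weights 1/max(count, 1) (Levenberg-Marquardt). Amplitude
#' fractions are back-projected to the histogram time origin (the
#' excitation pulse at t = 0) via a_i(0) = a_i(t_start) exp(t_start /
#' tau_i), renormalized to sum to 1, and components are sorted by
#' lifetime. The optimizer is restarted from `n_starts` log-spaced,
#' seed-jittered lifetime initializations and the best-loss solution
#' kept.
#'
#' @param curve A `qdfret_decay`.
#' @param n_components Number of exponential components, 1 to 4.
#' @param fit_window Optional `c(start, end)` in ns. Default: from the
#'   peak bin plus two bins to the last bin.
#' @param seed Integer seed controlling the multistart jitter.
#' @param n_starts Number of multistart initializations (>= 5 recommended).
#' @param prune_below Components with fitted amplitude fraction below this
#'   value are dropped with a warning (default 0.005).
#' @return A `qdfret_decay_fit` list: `total_amplitude`,
#'   `amplitude_fractions` (sum to 1), `lifetimes_ns` (ascending),
#'   `tau_amplitude_weighted_ns`, `background`, `chisq_reduced`,
#'   `n_components`, `fit_window_ns`.
#' @export
fit_decay <- function(curve, n_components, fit_window = NULL, seed = 1L,
                      n_starts = 5L, prune_below = 0.005) {
  stopifnot(inherits(curve, "qdfret_decay"))
  if (n_components < 1 || n_components > 4)
    stop("n_components must be between 1 and 4, got ", n_components)
  n_components <- as.integer(n_components)

  if (is.null(fit_window)) {
    start <- curve$time_ns[min(which.max(curve$counts) + 2L,
                               length(curve$time_ns) - 3L)]
    fit_window <- c(start, max(curve$time_ns))
  }
  sel <- curve$time_ns >= fit_window[1] & curve$time_ns <= fit_window[2]
  if (sum(sel) < 3 * n_components + 2)
    stop("fit window holds ", sum(sel), " bins; too few for ",
         n_components, " components")
  t <- curve$time_ns[sel] - curve$time_ns[sel][1]
  y <- curve$counts[sel]
  if (sum(y) < 10 * (2 * n_components + 1))
    stop("only ", sum(y), " counts in the fit window; need > 10x the ",
         2 * n_components + 1, " free parameters")
  w <- 1 / pmax(y, 1)

  span <- max(t[length(t)], 2 * curve$bin_width_ns)
  resid_fn <- function(par) {
    a <- par[seq_len(n_components)]
    tau <- par[n_components + seq_len(n_components)]
    bg <- par[2 * n_components + 1]
    (decay_model(t, a, tau, bg) - y) * sqrt(w)
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  peak <- max(y)
  bg0 <- mean(utils::tail(y, max(5L, length(y) %/% 20L)))
  best <- NULL
  for (k in seq_len(max(n_starts, 1L))) {
    tau0 <- exp(seq(log(max(curve$bin_width_ns, span / 500)),
                    log(span / 2), length.out = n_components + 2L)
                )[1L + seq_len(n_components)]
    tau0 <- tau0 * exp(stats::rnorm(n_components, 0, 0.3))
    a0 <- rep(max(peak - bg0, peak * 0.1) / n_components, n_components)
    par0 <- c(a0, tau0, max(bg0, 1e-3))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fn,
        lower = c(rep(0, n_components),
                  rep(curve$bin_width_ns / 10, n_components), 0),
        upper = c(rep(Inf, n_components), rep(span * 10, n_components), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss)
      best <- list(fit = fit, loss = loss)
  }
  if (is.null(best))
    stop("decay fit failed to converge from any of ", n_starts,
         " initializations")

  par <- best$fit$par
  a <- par[seq_len(n_components)]
  tau <- par[n_components + seq_len(n_components)]
  bg <- par[2 * n_components + 1]

  # degenerate-input guard: the decay model must beat a constant fit
  const <- sum(y * w) / sum(w)
  chisq_const <- decay_chisq(y, const)
  chisq_fit <- decay_chisq(y, decay_model(t, a, tau, bg))
  if (sum(a) <= 0 ||
      (chisq_const - chisq_fit) < 0.01 * chisq_const)
    stop("no decaying component resolvable: model does not improve on a ",
         "flat fit (chi-square ", format(chisq_fit, digits = 4), " vs ",
         format(chisq_const, digits = 4),
         "); best residual retained in condition")

  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]
  # refer amplitudes to the excitation pulse at t = 0 on the curve's axis
  t_start <- curve$time_ns[sel][1]
  a <- a * exp(t_start / tau)
  frac <- a / sum(a)
  if (any(frac < prune_below) && n_components > 1L) {
    keep <- frac >= prune_below
    warning(sum(!keep), " component(s) with amplitude fraction < ",
            prune_below, " pruned")
    a <- a[keep]; tau <- tau[keep]
    frac <- a / sum(a)
  }
  npar <- 2 * length(tau) + 1
  structure(list(
    total_amplitude = sum(a),
    amplitude_fractions = frac,
    lifetimes_ns = tau,
    tau_amplitude_weighted_ns = sum(frac * tau),
    background = bg,
    chisq_reduced = chisq_fit / max(length(y) - npar, 1),
    n_components = length(tau),
    fit_window_ns = fit_window), class = "qdfret_decay_fit")
}

#' @export
print.qdfret_decay_fit <- function(x, ...) {
  cat(sprintf("<decay fit: %d component(s), chi2_red %.3f>\n",
              x$n_components, x$chisq_reduced))
  for (i in seq_len(x$n_components))
    cat(sprintf("  gamma %.3f  tau %.3f ns\n",
                x$amplitude_fractions[i], x$lifetimes_ns[i]))
  cat(sprintf("  amplitude-weighted tau = %.3f ns\n",
              x$tau_amplitude_weighted_ns))
  invisible(x)
}

#' Amplitude-weighted mean lifetime of a decay fit
#'
#' tau = sum_i gamma_i tau_i over the fitted components, the average
#' entering the lifetime-based FRET efficiency.
#'
#' @param fit A `qdfret_decay_fit`.
#' @return Amplitude-weighted lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(fit) {
  stopifnot(inherits(fit, "qdfret_decay_fit"))
  sum(fit$amplitude_fractions * fit$lifetimes_ns)
}

#' Choose the number of exponential components for a decay curve
#'
#' Fits 1, 2, ... components in turn and stops when adding a component
#' improves the reduced chi-square by less than `threshold` (relative),
#' returning the simpler model's count. The decision trace is attached as
#' attribute `trace`.
#'
#' @param curve A `qdfret_decay`.
#' @param max_components Cap on the component count (default 4).
#' @param threshold Relative chi-square improvement below which the extra
#'   component is rejected (default 0.05).
#' @param seed,fit_window Passed to [fit_decay()].
#' @return Integer component count with attribute `trace` (data frame of
#'   n and reduced chi-square). Warns if improvements persist at the cap.
#' @export
select_component_count <- function(curve, max_components = 4L,
                                   threshold = 0.05, seed = 1L,
                                   fit_window = NULL) {
  stopifnot(inherits(curve, "qdfret_decay"))
  chis <- rep(NA_real_, max_components)
  for (n in seq_len(max_components)) {
    f <- tryCatch(
      suppressWarnings(fit_decay(curve, n, fit_window = fit_window,
                                 seed = seed)),
      error = function(e) NULL)
    if (is.null(f) || f$n_components < n) {
      # a higher-order fit that fails or prunes back down cannot justify
      # the extra component
      n <- max(n - 1L, 1L)
      break
    }
    chis[n] <- f$chisq_reduced
    if (n > 1L) {
      improve <- (chis[n - 1] - chis[n]) / chis[n - 1]
      if (!is.finite(improve) || improve < threshold) {
        n <- n - 1L
        break
      }
    }
    if (n == max_components)
      warning("chi-square still improving at the cap of ", max_components,
              " components")
  }
  trace <- data.frame(n = seq_len(max_components), chisq_reduced = chis)
  structure(as.integer(n), trace = trace[!is.na(trace$chisq_reduced), ])
}
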