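# Independent oracles used across the suite. Each one recomputes a
# quantity by a route disjoint from the implementation it checks.

gauss_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Build a Gaussian emission/absorptivity spectrum on an explicit grid
# without going through the synthetic-data generators.
make_gaussian_spectrum <- function(center, fwhm, peak = 1, wl,
                                   kind = "emission") {
  spectrum_curve(wl, peak * exp(-(wl - center)^2 / (2 * gauss_sd(fwhm)^2)),
                 kind = kind)
}

# Dense-grid quadrature oracle for the overlap integral of two Gaussian
# bands: >= 1e6 points, donor normalized over the same dense grid.
oracle_overlap_gaussian <- function(d_center, d_fwhm, a_center, a_fwhm,
                                    a_peak, lo, hi, n_points = 1e6 + 1) {
  wl <- seq(lo, hi, length.out = n_points)
  id <- exp(-(wl - d_center)^2 / (2 * gauss_sd(d_fwhm)^2))
  id <- id / pracma::trapz(wl, id)
  ea <- a_peak * exp(-(wl - a_center)^2 / (2 * gauss_sd(a_fwhm)^2))
  pracma::trapz(wl, id * ea * wl^4)
}

# Kinetic Monte-Carlo oracle for the three-node FRET network: each
# excitation trial branches at the donor (natural decay vs the two FRET
# edges, probabilities proportional to 1, gamma1, gamma2); trials that
# excite the relay branch again (emit vs onward transfer). The relay
# quench efficiency compares relay emission against a reference network
# with the competing and sequential edges removed.
oracle_network_kmc <- function(g1, g2, g3, n_trials = 1e6, seed = 1L) {
  set.seed(seed)
  u <- stats::runif(n_trials)
  p1 <- g1 / (1 + g1 + g2)
  p2 <- g2 / (1 + g1 + g2)
  to_relay <- u < p1
  to_acceptor <- !to_relay & u < p1 + p2
  relay_emits <- stats::runif(sum(to_relay)) >= g3 / (1 + g3)
  ref_excited <- stats::runif(n_trials) < g1 / (1 + g1)
  list(Q_donor = mean(to_relay | to_acceptor),
       Q_relay = 1 - (sum(relay_emits) / n_trials) / mean(ref_excited))
}

# Second-optimizer oracle for the decay fit: Nelder-Mead on
# log-parameterized amplitudes/lifetimes/background, same Neyman
# weighted loss, independent of the Levenberg-Marquardt route.
oracle_fit_decay <- function(curve, n_comp, seed = 1L) {
  peak_i <- which.max(curve$counts)
  start_i <- min(peak_i + 2L, length(curve$time_ns) - 3L)
  sel <- seq(start_i, length(curve$time_ns))
  t <- curve$time_ns[sel] - curve$time_ns[sel][1]
  y <- curve$counts[sel]
  loss <- function(lp) {
    a <- exp(lp[seq_len(n_comp)])
    tau <- exp(lp[n_comp + seq_len(n_comp)])
    bg <- exp(lp[2 * n_comp + 1])
    mu <- as.vector(outer(t, tau, function(tt, s) exp(-tt / s)) %*% a) + bg
    sum((mu - y)^2 / pmax(y, 1))
  }
  set.seed(seed)
  span <- max(t)
  best <- NULL
  for (k in 1:4) {
    tau0 <- exp(seq(log(span / 200), log(span / 3),
                    length.out = n_comp)) * exp(stats::rnorm(n_comp, 0, 0.2))
    lp0 <- log(c(rep(max(y) / n_comp, n_comp), tau0, max(mean(tail(y, 20)), 1e-3)))
    o <- stats::optim(lp0, loss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- exp(best$par[seq_len(n_comp)])
  tau <- exp(best$par[n_comp + seq_len(n_comp)])
  a <- a * exp(curve$time_ns[sel][1] / tau)  # refer to t = 0
  ord <- order(tau)
  list(fractions = (a / sum(a))[ord], taus = tau[ord],
       tau_aw = sum(a / sum(a) * tau))
}

# Wald-Wolfowitz-style runs test z-statistic on residual signs.
runs_z <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- (mu - 1) * (mu - 2) / (n1 + n2 - 1)
  (runs - mu) / sqrt(v)
}
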