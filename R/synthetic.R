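# Synthetic-data generators: every input the pipeline consumes, produced
# with known ground truth (stored alongside as attribute "ground_truth")
# so each analysis stage can be closed-loop tested without instrument
# data. Each generator is a pure function of its arguments and seed; one
# global seed fans out to per-generator substreams via a label hash so
# adding a generator does not shift existing streams.

substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

gaussian_band <- function(wl, center, fwhm) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(wl - center)^2 / (2 * sd^2))
}

#' Generate a Gaussian-band emission spectrum
#'
#' Sum of Gaussian bands on a regular wavelength grid, emulating QD (e.g.
#' 600/630/660 nm centers) or dye emission. Deterministic: no noise is
#' added; each band integrates to its requested area (up to grid
#' truncation, warned about when a band center falls off the grid).
#'
#' @param centers Band centers, nm.
#' @param fwhms Full widths at half maximum, nm (recycled).
#' @param areas Band areas (value x nm; recycled, default 1).
#' @param wl Wavelength grid, nm (default `seq(400, 900, 0.5)`).
#' @return An emission `qdfret_spectrum` with attribute `ground_truth`.
#' @export
gen_emission_spectrum <- function(centers, fwhms, areas = 1,
                                  wl = seq(400, 900, by = 0.5)) {
  k <- length(centers)
  fwhms <- rep_len(fwhms, k)
  areas <- rep_len(areas, k)
  if (any(fwhms <= 0) || any(areas <= 0))
    stop("fwhms and areas must be > 0")
  if (any(centers < min(wl) | centers > max(wl)))
    warning("band center outside the wavelength grid; band truncated")
  v <- rep(0, length(wl))
  for (i in seq_len(k)) {
    sd <- fwhms[i] / (2 * sqrt(2 * log(2)))
    v <- v + areas[i] / (sd * sqrt(2 * pi)) *
      gaussian_band(wl, centers[i], fwhms[i])
  }
  s <- spectrum_curve(wl, v, kind = "emission")
  attr(s, "ground_truth") <- list(centers = centers, fwhms = fwhms,
                                  areas = areas)
  s
}

#' Generate a molar absorptivity spectrum
#'
#' Gaussian absorption bands (peak heights in M^-1 cm^-1) plus an
#' optional power-law tail rising toward the UV, mimicking the broadband
#' absorption of a quantum dot:
#' eps_tail(lambda) = tail_peak x (tail_ref/lambda)^tail_exponent.
#'
#' @param centers Band centers, nm.
#' @param fwhms Full widths at half maximum, nm (recycled).
#' @param peaks Peak molar absorptivities, M^-1 cm^-1 (recycled).
#' @param wl Wavelength grid, nm.
#' @param tail_peak Tail amplitude at `tail_ref` nm, M^-1 cm^-1
#'   (default 0 = no tail).
#' @param tail_exponent Power-law exponent of the tail (default 3).
#' @param tail_ref Reference wavelength of the tail amplitude, nm
#'   (default 350).
#' @return An absorptivity `qdfret_spectrum` with attribute
#'   `ground_truth`.
#' @export
gen_absorptivity_spectrum <- function(centers, fwhms, peaks,
                                      wl = seq(400, 900, by = 0.5),
                                      tail_peak = 0, tail_exponent = 3,
                                      tail_ref = 350) {
  k <- length(centers)
  fwhms <- rep_len(fwhms, k)
  peaks <- rep_len(peaks, k)
  if (any(fwhms <= 0) || any(peaks <= 0))
    stop("fwhms and peaks must be > 0")
  if (tail_peak < 0) stop("tail_peak must be >= 0")
  v <- rep(0, length(wl))
  for (i in seq_len(k))
    v <- v + peaks[i] * gaussian_band(wl, centers[i], fwhms[i])
  if (tail_peak > 0) v <- v + tail_peak * (tail_ref / wl)^tail_exponent
  s <- spectrum_curve(wl, v, kind = "absorptivity")
  attr(s, "ground_truth") <- list(centers = centers, fwhms = fwhms,
                                  peaks = peaks, tail_peak = tail_peak,
                                  tail_exponent = tail_exponent)
  s
}

#' Generate a mixture absorbance spectrum from known components
#'
#' A(lambda) = sum_i c_i eps_i(lambda) l + Gaussian noise. The
#' ground-truth concentrations travel with the spectrum so unmixing can
#' be tested closed-loop.
#'
#' @param components Named list of absorptivity `qdfret_spectrum` objects
#'   sharing one wavelength grid.
#' @param concentrations Concentrations in M (same length, >= 0).
#' @param noise_sd Additive Gaussian noise sd in absorbance units
#'   (default 0).
#' @param seed Integer seed for the noise stream.
#' @param path_length Path length, cm (default 1).
#' @return An absorbance `qdfret_spectrum` with attribute `ground_truth`
#'   holding the concentrations. Negative noisy values are clamped at 0.
#' @export
gen_absorbance_mixture <- function(components, concentrations,
                                   noise_sd = 0, seed = 1L,
                                   path_length = 1) {
  if (length(components) != length(concentrations))
    stop("components and concentrations differ in length")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  wl <- components[[1]]$wavelengths
  for (cm in components) {
    stopifnot(inherits(cm, "qdfret_spectrum"))
    if (!isTRUE(all.equal(cm$wavelengths, wl)))
      stop("components must share one wavelength grid")
  }
  a <- rep(0, length(wl))
  for (i in seq_along(components))
    a <- a + concentrations[i] * components[[i]]$values * path_length
  if (noise_sd > 0) {
    set.seed(substream_seed(seed, "absorbance_mixture"))
    a <- pmax(a + stats::rnorm(length(a), 0, noise_sd), 0)
  }
  s <- spectrum_curve(wl, a, kind = "absorbance")
  attr(s, "ground_truth") <- list(concentrations = concentrations,
                                  noise_sd = noise_sd,
                                  path_length = path_length)
  s
}

#' Generate a TCSPC decay histogram with Poisson counting noise
#'
#' Expected counts per bin follow the multi-exponential decay model,
#' including wrap-around of incomplete decay between excitation pulses
#' (the geometric-series factor 1/(1 - exp(-T/tau)) for repetition period
#' T), plus a uniform background; observed counts are drawn Poisson per
#' bin.
#'
#' @param gammas Amplitude fractions, summing to 1.
#' @param taus_ns Lifetimes in ns, each < `repetition_period_ns`.
#' @param total_counts Expected total photon count (> 0).
#' @param bin_width_ns Histogram bin width, ns (default 0.5).
#' @param repetition_period_ns Excitation period, ns (default 400,
#'   i.e. 2.5 MHz).
#' @param background_fraction Fraction of counts in the uniform
#'   background, in [0, 1] (default 0).
#' @param seed Integer seed for the Poisson draw.
#' @return A `qdfret_decay` with attribute `ground_truth` (the generating
#'   parameters and the amplitude-weighted lifetime).
#' @export
gen_decay_histogram <- function(gammas, taus_ns, total_counts,
                                bin_width_ns = 0.5,
                                repetition_period_ns = 400,
                                background_fraction = 0, seed = 1L) {
  if (abs(sum(gammas) - 1) > 1e-9) stop("gammas must sum to 1")
  if (any(gammas < 0)) stop("gammas must be >= 0")
  if (length(gammas) != length(taus_ns))
    stop("gammas and taus_ns differ in length")
  if (any(taus_ns <= 0)) stop("lifetimes must be > 0")
  if (any(taus_ns >= repetition_period_ns))
    stop("lifetime ", max(taus_ns), " ns >= repetition period ",
         repetition_period_ns, " ns: wrap-around dominates")
  if (total_counts <= 0) stop("total_counts must be > 0")
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0, 1]")
  tt <- seq(bin_width_ns / 2, repetition_period_ns - bin_width_ns / 2,
            by = bin_width_ns)
  mu <- rep(0, length(tt))
  for (i in seq_along(gammas))
    mu <- mu + gammas[i] * exp(-tt / taus_ns[i]) /
      (1 - exp(-repetition_period_ns / taus_ns[i]))
  mu <- mu / sum(mu) * total_counts * (1 - background_fraction) +
    total_counts * background_fraction / length(tt)
  set.seed(substream_seed(seed, "decay_histogram"))
  counts <- stats::rpois(length(tt), mu)
  if (sum(counts) == 0) counts[1] <- 1  # degenerate ultra-low-count draw
  d <- decay_curve(tt, counts, repetition_period_ns = repetition_period_ns)
  attr(d, "ground_truth") <- list(
    gammas = gammas, taus_ns = taus_ns, total_counts = total_counts,
    background_fraction = background_fraction,
    tau_amplitude_weighted_ns = sum(gammas * taus_ns),
    expected = mu)
  d
}

#' Generate noisy intensity/lifetime FRET observable replicates
#'
#' Forward model of the intensity and lifetime efficiency relations:
#' I_DA = (1 - E) I_D and tau_DA = (1 - E) tau_D, with independent
#' multiplicative lognormal noise of coefficient of variation `noise_cv`
#' on every observable (unit mean, so recovered efficiencies are
#' asymptotically unbiased).
#'
#' @param E_true Ground-truth efficiency in [0, 1).
#' @param I_D_mean Donor-only mean intensity, a.u. (default 1e5).
#' @param tau_D_ns Donor-only lifetime, ns (default 20).
#' @param n_replicates Number of replicate measurements (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A data frame with columns `I_D`, `I_DA`, `tau_D_ns`,
#'   `tau_DA_ns` and attribute `ground_truth`.
#' @export
gen_fret_observables <- function(E_true, I_D_mean = 1e5, tau_D_ns = 20,
                                 n_replicates = 3, noise_cv = 0.02,
                                 seed = 1L) {
  if (E_true < 0 || E_true >= 1) stop("E_true must be in [0, 1)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (I_D_mean <= 0 || tau_D_ns <= 0)
    stop("I_D_mean and tau_D_ns must be > 0")
  set.seed(substream_seed(seed, "fret_observables"))
  noise <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sdl <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  n <- n_replicates
  out <- data.frame(
    I_D = I_D_mean * noise(n),
    I_DA = (1 - E_true) * I_D_mean * noise(n),
    tau_D_ns = tau_D_ns * noise(n),
    tau_DA_ns = (1 - E_true) * tau_D_ns * noise(n))
  attr(out, "ground_truth") <- list(E_true = E_true, I_D_mean = I_D_mean,
                                    tau_D_ns = tau_D_ns,
                                    noise_cv = noise_cv)
  out
}

#' Generate a bond-angle ensemble around a trimer design angle
#'
#' Gaussian draws around the design angle, reflected at the 0 and 180
#' degree boundaries so the support stays valid without truncation bias
#' at the center of the distribution.
#'
#' @param design_angle_deg Design angle in (0, 180].
#' @param sd_deg Angular spread, degrees (>= 0).
#' @param n Number of trimer observations (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of angles in [0, 180] with attribute
#'   `ground_truth`.
#' @export
gen_trimer_angles <- function(design_angle_deg, sd_deg, n, seed = 1L) {
  if (design_angle_deg <= 0 || design_angle_deg > 180)
    stop("design_angle_deg must be in (0, 180]")
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  if (n < 1) stop("n must be >= 1")
  set.seed(substream_seed(seed, "trimer_angles"))
  a <- stats::rnorm(n, design_angle_deg, sd_deg)
  # reflect into [0, 180]: fold over period 360, mirror the upper half
  a <- a %% 360
  a <- ifelse(a > 180, 360 - a, a)
  attr(a, "ground_truth") <- list(design_angle_deg = design_angle_deg,
                                  sd_deg = sd_deg)
  a
}
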