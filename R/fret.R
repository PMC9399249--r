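#' FRET efficiency from steady-state intensities
#'
#' E = 1 - I_DA / I_D, where I_D is the donor-only emission intensity and
#' I_DA the donor intensity in the presence of the acceptor.
#'
#' @param I_D Donor-only intensity (a.u., > 0).
#' @param I_DA Donor intensity with acceptor present (a.u., >= 0).
#' @return Efficiency (dimensionless). Negative values (I_DA > I_D) are
#'   returned with a warning: they signal measurement noise or emission
#'   enhancement, which should be surfaced rather than hidden.
#' @export
#' @examples
#' efficiency_from_intensity(100, 28) # 0.72
efficiency_from_intensity <- function(I_D, I_DA) {
  if (!is.finite(I_D) || I_D <= 0) stop("I_D must be > 0, got ", I_D)
  if (!is.finite(I_DA) || I_DA < 0) stop("I_DA must be >= 0, got ", I_DA)
  E <- 1 - I_DA / I_D
  if (E < 0)
    warning("I_DA > I_D gives negative efficiency (", format(E),
            "): non-FRET enhancement or noise")
  E
}

#' FRET efficiency from amplitude-weighted lifetimes
#'
#' E = 1 - tau_DA / tau_D, with tau the amplitude-weighted mean emission
#' lifetimes of the quenched (DA) and donor-only (D) samples.
#'
#' @param tau_D Donor-only lifetime, ns (> 0).
#' @param tau_DA Quenched lifetime, ns (> 0).
#' @return Efficiency (dimensionless); negative with a warning when
#'   tau_DA > tau_D.
#' @export
efficiency_from_lifetime <- function(tau_D, tau_DA) {
  if (!is.finite(tau_D) || tau_D <= 0) stop("tau_D must be > 0, got ", tau_D)
  if (!is.finite(tau_DA) || tau_DA <= 0)
    stop("tau_DA must be > 0, got ", tau_DA)
  E <- 1 - tau_DA / tau_D
  if (E < 0)
    warning("tau_DA > tau_D gives negative efficiency (", format(E), ")")
  E
}

#' FRET efficiency of one donor coupled to n equidistant acceptors
#'
#' E = n R0^6 / (n R0^6 + R^6): a single donor (here a QD) transferring to
#' n identical acceptors all at center-to-center distance R.
#'
#' @param n_acceptors Number of acceptors (>= 1; real values allowed for
#'   ensemble-average counts).
#' @param R0 Forster distance, nm (> 0).
#' @param R Donor-acceptor distance, nm (> 0).
#' @return Efficiency in (0, 1).
#' @export
#' @examples
#' efficiency_multi_acceptor(19, 7.0, 9.8) # ~0.716
efficiency_multi_acceptor <- function(n_acceptors, R0, R) {
  if (!is.finite(n_acceptors) || n_acceptors < 1)
    stop("n_acceptors must be >= 1, got ", n_acceptors)
  if (R0 <= 0 || R <= 0) stop("R0 and R must be > 0")
  n_acceptors * R0^6 / (n_acceptors * R0^6 + R^6)
}

#' Acceptor count from a measured multi-acceptor FRET efficiency
#'
#' Closed-form inverse of the multi-acceptor relation:
#' n = E R^6 / ((1 - E) R0^6). Used to count dyes per QD from a measured
#' ensemble efficiency, known Forster distance, and donor-acceptor
#' distance.
#'
#' @param E Measured efficiency, strictly inside (0, 1).
#' @param R0 Forster distance, nm (> 0).
#' @param R Donor-acceptor distance, nm (> 0).
#' @return A list with `n` (real-valued count) and `n_integer`
#'   (round-half-to-even integer, as by [round()]).
#' @export
#' @examples
#' invert_for_acceptor_count(0.72, 7.0, 9.8) # n ~ 19.4 -> 19
invert_for_acceptor_count <- function(E, R0, R) {
  if (!is.finite(E) || E <= 0 || E >= 1)
    stop("E must be strictly inside (0, 1) to invert, got ", E)
  if (R0 <= 0 || R <= 0) stop("R0 and R must be > 0")
  n <- E * R^6 / ((1 - E) * R0^6)
  list(n = n, n_integer = as.integer(round(n)))
}

#' Donor-acceptor distance from a measured FRET efficiency
#'
#' R = R0 * (n (1 - E) / E)^(1/6), the inverse of the multi-acceptor
#' relation solved for distance at a known acceptor count.
#'
#' @param E Measured efficiency, strictly inside (0, 1).
#' @param R0 Forster distance, nm (> 0).
#' @param n_acceptors Number of acceptors (default 1).
#' @return Distance R in nm.
#' @export
invert_for_distance <- function(E, R0, n_acceptors = 1) {
  if (!is.finite(E) || E <= 0 || E >= 1)
    stop("E must be strictly inside (0, 1) to invert, got ", E)
  if (R0 <= 0) stop("R0 must be > 0")
  if (n_acceptors < 1) stop("n_acceptors must be >= 1, got ", n_acceptors)
  R0 * (n_acceptors * (1 - E) / E)^(1 / 6)
}

#' FRET rate from the donor's natural relaxation rate
#'
#' k_DA = k_D (R0 / R)^6, with k_D = 1/tau_D the natural excited-state
#' relaxation rate of the donor.
#'
#' @param k_D Natural donor relaxation rate, ns^-1 (> 0).
#' @param R0 Forster distance, nm (> 0).
#' @param R Donor-acceptor distance, nm (> 0).
#' @return Transfer rate k_DA in ns^-1.
#' @export
fret_rate <- function(k_D, R0, R) {
  if (k_D <= 0 || R0 <= 0 || R <= 0)
    stop("k_D, R0 and R must all be > 0")
  k_D * (R0 / R)^6
}

#' Relative FRET rate
#'
#' gamma = k_DA / k_D; for a rate from [fret_rate()] this equals
#' (R0/R)^6 exactly.
#'
#' @param k_DA Transfer rate, ns^-1 (>= 0).
#' @param k_D Natural donor relaxation rate, ns^-1 (> 0).
#' @return Dimensionless relative rate gamma.
#' @export
relative_rate <- function(k_DA, k_D) {
  if (k_D <= 0) stop("k_D must be > 0, got ", k_D)
  if (k_DA < 0) stop("k_DA must be >= 0, got ", k_DA)
  k_DA / k_D
}

#' FRET efficiency from a relative rate
#'
#' E = gamma / (1 + gamma), algebraically identical to
#' k_DA / (k_D + k_DA).
#'
#' @param gamma Relative rate (>= 0).
#' @return Efficiency in [0, 1).
#' @export
efficiency_from_relative_rate <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("gamma must be finite and >= 0")
  gamma / (1 + gamma)
}

#' Describe a donor-acceptor FRET pair
#'
#' Convenience constructor tying a donor and acceptor to the pair context
#' (orientation factor and refractive index are fixed when R0 is computed
#' and never re-asked downstream).
#'
#' @param donor,acceptor `qdfret_fluorophore` objects or names.
#' @param R0 Forster distance, nm (> 0).
#' @param R Center-to-center separation, nm (> 0).
#' @param kappa_squared,refractive_index Context carried from the overlap
#'   calculation.
#' @return A `qdfret_pair` list.
#' @export
fret_pair <- function(donor, acceptor, R0, R,
                      kappa_squared = 2 / 3, refractive_index = 1.35) {
  if (R0 <= 0 || R <= 0) stop("R0 and R must be > 0")
  structure(list(donor = donor, acceptor = acceptor, R0 = R0, R = R,
                 kappa_squared = kappa_squared,
                 refractive_index = refractive_index),
            class = "qdfret_pair")
}
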