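# Three-node concentric FRET network: initial donor (QD) -> relay (AF647)
# -> terminal acceptor (AF750). The donor de-excites through its natural
# pathway plus two FRET edges (to relay and directly to acceptor); the
# relay de-excites through its natural pathway plus one onward edge. All
# quench efficiencies follow from the three relative rates alone.

check_gamma <- function(g, name) {
  if (!is.finite(g) || g < 0)
    stop(name, " must be finite and >= 0, got ", g)
  g
}

#' Donor (QD) quench efficiency in a three-node FRET network
#'
#' Q_QD = (gamma1 + gamma2) / (1 + gamma1 + gamma2): the summed efficiency
#' of the donor->relay and donor->acceptor pathways competing with the
#' donor's natural relaxation.
#'
#' @param gamma_d_relay Relative rate of the donor->relay edge (>= 0).
#' @param gamma_d_acceptor Relative rate of the donor->acceptor edge
#'   (>= 0).
#' @return Quench efficiency in [0, 1).
#' @export
donor_quench <- function(gamma_d_relay, gamma_d_acceptor) {
  g1 <- check_gamma(gamma_d_relay, "gamma_d_relay")
  g2 <- check_gamma(gamma_d_acceptor, "gamma_d_acceptor")
  (g1 + g2) / (1 + g1 + g2)
}

#' Competitive component of the relay quench efficiency
#'
#' Q_c = 1 - (1 + gamma1) / (1 + gamma1 + gamma2): the loss of relay
#' excitation caused by the donor->acceptor pathway competing with the
#' donor->relay pathway at the donor.
#'
#' @inheritParams donor_quench
#' @return Competitive quench efficiency in [0, 1).
#' @export
relay_quench_competitive <- function(gamma_d_relay, gamma_d_acceptor) {
  g1 <- check_gamma(gamma_d_relay, "gamma_d_relay")
  g2 <- check_gamma(gamma_d_acceptor, "gamma_d_acceptor")
  1 - (1 + g1) / (1 + g1 + g2)
}

#' Sequential component of the relay quench efficiency
#'
#' Q_s = gamma / (1 + gamma): the relay's own onward FRET to the terminal
#' acceptor. Identical in form to [efficiency_from_relative_rate()].
#'
#' @param gamma_relay_acceptor Relative rate of the relay->acceptor edge
#'   (>= 0).
#' @return Sequential quench efficiency in [0, 1).
#' @export
relay_quench_sequential <- function(gamma_relay_acceptor) {
  check_gamma(gamma_relay_acceptor, "gamma_relay_acceptor")
  efficiency_from_relative_rate(gamma_relay_acceptor)
}

#' Total relay quench efficiency from its two components
#'
#' Q_relay = 1 - (1 - Q_c)(1 - Q_s): independent competitive and
#' sequential losses compose multiplicatively in their survival fractions.
#'
#' @param Q_c Competitive component in [0, 1].
#' @param Q_s Sequential component in [0, 1].
#' @return Total relay quench efficiency in [0, 1].
#' @export
relay_quench_total <- function(Q_c, Q_s) {
  if (!is.finite(Q_c) || Q_c < 0 || Q_c > 1)
    stop("Q_c must be in [0, 1], got ", Q_c)
  if (!is.finite(Q_s) || Q_s < 0 || Q_s > 1)
    stop("Q_s must be in [0, 1], got ", Q_s)
  1 - (1 - Q_c) * (1 - Q_s)
}

#' Evaluate a three-node FRET network from its geometry
#'
#' Converts each (R0, R) edge to a relative rate gamma = (R0/R)^6 and
#' applies the quench-efficiency formulas for the donor and relay. Edges
#' may alternatively be given as gammas directly; when both a gamma and a
#' distance pair are supplied for the same edge the direct gamma wins and
#' a warning is issued.
#'
#' @param R_d_relay,R_d_acceptor,R_relay_acceptor Center-to-center
#'   distances in nm for the donor->relay, donor->acceptor and
#'   relay->acceptor edges.
#' @param R0_d_relay,R0_d_acceptor,R0_relay_acceptor Forster distances in
#'   nm for the same edges.
#' @param gamma_d_relay,gamma_d_acceptor,gamma_relay_acceptor Optional
#'   direct relative rates overriding the distance-derived values.
#' @return A `qdfret_network_result` list with `Q_donor`, `Q_competitive`,
#'   `Q_sequential`, `Q_relay`, and `gammas` (named vector with a
#'   `source` attribute recording whether each edge came from geometry or
#'   a direct rate).
#' @export
#' @examples
#' evaluate_network(R_d_relay = 7.0, R_d_acceptor = 7.8,
#'                  R_relay_acceptor = 7.1, R0_d_relay = 7.0,
#'                  R0_d_acceptor = 6.0, R0_relay_acceptor = 7.5)
evaluate_network <- function(R_d_relay = NULL, R_d_acceptor = NULL,
                             R_relay_acceptor = NULL,
                             R0_d_relay = NULL, R0_d_acceptor = NULL,
                             R0_relay_acceptor = NULL,
                             gamma_d_relay = NULL, gamma_d_acceptor = NULL,
                             gamma_relay_acceptor = NULL) {
  resolve_edge <- function(gamma, R0, R, name) {
    have_geom <- !is.null(R0) && !is.null(R)
    if (!is.null(gamma)) {
      if (have_geom)
        warning("edge ", name, ": both gamma and (R0, R) supplied; ",
                "using the direct gamma")
      return(list(g = check_gamma(gamma, name), src = "direct"))
    }
    if (!have_geom)
      stop("edge ", name, " needs either gamma or both R0 and R")
    if (R0 <= 0 || R <= 0) stop("edge ", name, ": R0 and R must be > 0")
    list(g = (R0 / R)^6, src = "geometry")
  }
  e1 <- resolve_edge(gamma_d_relay, R0_d_relay, R_d_relay, "donor->relay")
  e2 <- resolve_edge(gamma_d_acceptor, R0_d_acceptor, R_d_acceptor,
                     "donor->acceptor")
  e3 <- resolve_edge(gamma_relay_acceptor, R0_relay_acceptor,
                     R_relay_acceptor, "relay->acceptor")
  gammas <- c(d_relay = e1$g, d_acceptor = e2$g, relay_acceptor = e3$g)
  attr(gammas, "source") <- c(e1$src, e2$src, e3$src)
  Q_c <- relay_quench_competitive(e1$g, e2$g)
  Q_s <- relay_quench_sequential(e3$g)
  structure(list(
    Q_donor = donor_quench(e1$g, e2$g),
    Q_competitive = Q_c,
    Q_sequential = Q_s,
    Q_relay = relay_quench_total(Q_c, Q_s),
    gammas = gammas), class = "qdfret_network_result")
}

#' @export
print.qdfret_network_result <- function(x, ...) {
  cat("<three-node FRET network>\n")
  cat(sprintf("  gammas: d->relay %.4g, d->acceptor %.4g, relay->acceptor %.4g\n",
              x$gammas[["d_relay"]], x$gammas[["d_acceptor"]],
              x$gammas[["relay_acceptor"]]))
  cat(sprintf("  Q_donor %.4f | Q_competitive %.4f | Q_sequential %.4f | Q_relay %.4f\n",
              x$Q_donor, x$Q_competitive, x$Q_sequential, x$Q_relay))
  invisible(x)
}
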