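#' Build an idealized wireframe-polyhedron scaffold
#'
#' Models a DNA-origami wireframe as a regular polyhedron whose edge
#' length follows from the designed base-pair count at the B-DNA helical
#' rise. Supported solids: regular tetrahedron and equilateral pentagonal
#' pyramid (apex edges equal to base edges, ten edges total). Vertices
#' are centered so the centroid sits at the origin; coordinates are in nm.
#'
#' @param polyhedron `"tetrahedron"` or `"pentagonal_pyramid"`.
#' @param edge_bp Base pairs per edge (> 0), e.g. 52 (~18 nm) or 63
#'   (~21 nm).
#' @param rise_per_bp Helical rise in nm/bp (default 0.34, B-DNA).
#' @return A `qdfret_scaffold` with `polyhedron`, `edge_bp`,
#'   `rise_per_bp`, `edge_length_nm`, `vertices` (matrix, rows = vertices,
#'   nm), `edges` (two-column vertex-index matrix), and an empty site
#'   registry.
#' @export
#' @examples
#' tet <- build_scaffold("tetrahedron", 52)
#' tet$edge_length_nm # 17.68
build_scaffold <- function(polyhedron = c("tetrahedron",
                                          "pentagonal_pyramid"),
                           edge_bp, rise_per_bp = 0.34) {
  polyhedron <- match.arg(polyhedron)
  if (edge_bp <= 0) stop("edge_bp must be > 0, got ", edge_bp)
  if (rise_per_bp <= 0) stop("rise_per_bp must be > 0")
  a <- edge_bp * rise_per_bp

  if (polyhedron == "tetrahedron") {
    # vertices of a regular tetrahedron with edge 2*sqrt(2), scaled to a
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
      (a / (2 * sqrt(2)))
    edges <- t(utils::combn(4L, 2L))
  } else {
    # equilateral pentagonal pyramid: regular pentagon base edge a plus
    # an apex at height sqrt(a^2 - Rb^2) above the base center
    rb <- a / (2 * sin(pi / 5))
    ang <- 2 * pi * (0:4) / 5
    base <- cbind(rb * cos(ang), rb * sin(ang), 0)
    apex <- c(0, 0, sqrt(a^2 - rb^2))
    v <- rbind(base, apex)
    edges <- rbind(cbind(1:5, c(2:5, 1)), cbind(1:5, 6L))
  }
  v <- sweep(v, 2, colMeans(v))
  rownames(v) <- paste0("v", seq_len(nrow(v)))
  structure(list(polyhedron = polyhedron, edge_bp = edge_bp,
                 rise_per_bp = rise_per_bp, edge_length_nm = a,
                 vertices = v, edges = edges,
                 sites = list()), class = "qdfret_scaffold")
}

#' @export
print.qdfret_scaffold <- function(x, ...) {
  cat(sprintf("<%s scaffold: %d bp edges (%.2f nm), %d sites>\n",
              x$polyhedron, x$edge_bp, x$edge_length_nm, length(x$sites)))
  invisible(x)
}

# Resolve an anchor (vertex index, edge index + fraction, or centroid) to
# a 3D point on the scaffold.
resolve_anchor <- function(model, anchor) {
  type <- match.arg(anchor$type, c("vertex", "edge", "centroid"))
  switch(type,
    vertex = {
      i <- anchor$index
      if (is.null(i) || i < 1 || i > nrow(model$vertices))
        stop("vertex index out of range: ", i)
      model$vertices[i, ]
    },
    edge = {
      i <- anchor$index
      if (is.null(i) || i < 1 || i > nrow(model$edges))
        stop("edge index out of range: ", i)
      f <- if (is.null(anchor$fraction)) 0.5 else anchor$fraction
      if (f < 0 || f > 1) stop("edge fraction must be in [0, 1], got ", f)
      e <- model$edges[i, ]
      (1 - f) * model$vertices[e[1], ] + f * model$vertices[e[2], ]
    },
    centroid = c(0, 0, 0))
}

#' Register a labeled attachment site on a scaffold
#'
#' A site is anchored to a vertex, a fractional position along an edge, or
#' the centroid, then pushed radially outward from the centroid by
#' `radial_offset_nm` (modeling overhang protrusion; a centroid anchor
#' cannot carry a nonzero offset since its radial direction is undefined).
#'
#' @param model A `qdfret_scaffold`.
#' @param name Site name.
#' @param anchor A list `list(type = "vertex"|"edge"|"centroid",
#'   index = i, fraction = f)`.
#' @param radial_offset_nm Outward offset from the centroid in nm.
#' @return The scaffold with the site added.
#' @export
add_site <- function(model, name, anchor, radial_offset_nm = 0) {
  stopifnot(inherits(model, "qdfret_scaffold"))
  p <- resolve_anchor(model, anchor)
  if (radial_offset_nm != 0) {
    r <- sqrt(sum(p^2))
    if (r < 1e-12)
      stop("cannot apply a radial offset to a centroid-anchored site")
    p <- p * (1 + radial_offset_nm / r)
  }
  model$sites[[name]] <- p
  model
}

#' Resolved 3D coordinates of all registered sites
#'
#' @param model A `qdfret_scaffold`.
#' @return Matrix (sites x 3) of coordinates in nm.
#' @export
site_coordinates <- function(model) {
  stopifnot(inherits(model, "qdfret_scaffold"))
  if (length(model$sites) == 0L)
    return(matrix(numeric(0), 0, 3))
  do.call(rbind, model$sites)
}

#' Euclidean distance between two registered sites
#'
#' @param model A `qdfret_scaffold`.
#' @param site_a,site_b Site names.
#' @return Distance in nm.
#' @export
site_distance <- function(model, site_a, site_b) {
  stopifnot(inherits(model, "qdfret_scaffold"))
  for (s in c(site_a, site_b))
    if (is.null(model$sites[[s]]))
      stop("unknown site '", s, "'; registered sites: ",
           paste(names(model$sites), collapse = ", "))
  sqrt(sum((model$sites[[site_a]] - model$sites[[site_b]])^2))
}

#' Center-to-fluorophore distance of a dye tethered at a particle surface
#'
#' For a dye held off a spherical particle by a short spacer the
#' center-to-fluorophore distance is simply particle radius + spacer
#' extension (e.g. a 7.1 nm QD radius plus a 0.68 nm polyT spacer gives
#' 7.8 nm).
#'
#' @param particle_radius_nm Particle radius, nm (> 0).
#' @param spacer_nm Spacer extension, nm (>= 0).
#' @return Center-to-fluorophore distance in nm.
#' @export
radial_dye_distance <- function(particle_radius_nm, spacer_nm = 0) {
  if (particle_radius_nm <= 0) stop("particle_radius_nm must be > 0")
  if (spacer_nm < 0) stop("spacer_nm must be >= 0")
  particle_radius_nm + spacer_nm
}

#' Interior bond angle at the center of a particle trimer
#'
#' Angle at `p_center` between the directions to `p_left` and `p_right`,
#' via the normalized dot product clipped to [-1, 1]; always reported as
#' the interior angle in [0, 180] degrees.
#'
#' @param p_left,p_center,p_right Numeric length-3 coordinates (nm).
#' @return Angle in degrees.
#' @export
#' @examples
#' bond_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # 90
bond_angle <- function(p_left, p_center, p_right) {
  u <- as.numeric(p_left) - as.numeric(p_center)
  v <- as.numeric(p_right) - as.numeric(p_center)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("coincident points: bond angle undefined")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Gaussian summary of a bond-angle distribution
#'
#' Maximum-likelihood Gaussian fit (sample mean and sd) of an observed
#' angle set plus the empirical fraction falling inside a stated interval,
#' as used to classify trimer geometries against their design angle.
#'
#' @param angles Numeric vector of angles in degrees, all in [0, 180],
#'   length >= 10.
#' @param range Length-2 interval in degrees for the in-range fraction
#'   (default `c(0, 180)`).
#' @return A `qdfret_angle_stats` list: `mean_deg`, `sd_deg` (MLE, i.e.
#'   denominator n), `fraction_in_range`, `range_deg`, `n`, `angles`.
#' @export
angle_distribution_stats <- function(angles, range = c(0, 180)) {
  angles <- as.numeric(angles)
  if (length(angles) < 10L)
    stop("need at least 10 angles, got ", length(angles))
  if (any(angles < 0 | angles > 180))
    stop("angles must lie in [0, 180] degrees")
  if (length(range) != 2L || range[1] >= range[2])
    stop("range must be an increasing length-2 interval")
  n <- length(angles)
  m <- mean(angles)
  s <- sqrt(sum((angles - m)^2) / n)
  structure(list(mean_deg = m, sd_deg = s,
                 fraction_in_range = mean(angles >= range[1] &
                                            angles <= range[2]),
                 range_deg = range, n = n, angles = angles),
            class = "qdfret_angle_stats")
}

#' @export
print.qdfret_angle_stats <- function(x, ...) {
  cat(sprintf(
    "<angle stats: n=%d, mean %.1f deg, sd %.1f deg, %.0f%% in [%g, %g]>\n",
    x$n, x$mean_deg, x$sd_deg, 100 * x$fraction_in_range,
    x$range_deg[1], x$range_deg[2]))
  invisible(x)
}

#' Kuhn length of a wrapped ssDNA strand from its radius of gyration
#'
#' Inverts the self-avoiding-walk (SAW) scaling R_ee = b (L/b)^nu for the
#' Kuhn length b, where L = n_nucleotides x contour_per_nt is the contour
#' length and the end-to-end distance is taken as
#' R_ee = rg_to_ree x Rg. The persistence length is reported as b/2 under
#' the conventional Kuhn/persistence relation. Setting `flory_exponent =
#' 0.5` and `rg_to_ree = sqrt(6)` recovers the ideal-chain closed form
#' b = 6 Rg^2 / L.
#'
#' @param Rg Radius of gyration, nm (> 0).
#' @param n_nucleotides Number of nucleotides (>= 2).
#' @param contour_per_nt Contour length per nucleotide, nm (default 0.63).
#' @param flory_exponent Flory exponent nu (default 0.588, good-solvent
#'   SAW).
#' @param rg_to_ree Ratio R_ee/Rg (default sqrt(6.25) for a SAW; sqrt(6)
#'   in the ideal-chain limit).
#' @return A `qdfret_polymer` list echoing every convention:
#'   `kuhn_length_nm`, `persistence_length_nm`, `contour_length_nm`,
#'   `n_kuhn_segments`, `Rg_nm`, `end_to_end_nm`, `flory_exponent`,
#'   `rg_to_ree`, `contour_per_nt`.
#' @export
#' @examples
#' saw_kuhn_from_rg(6.2, 51) # b ~ 5.5 nm, lp ~ 2.7 nm
saw_kuhn_from_rg <- function(Rg, n_nucleotides, contour_per_nt = 0.63,
                             flory_exponent = 0.588,
                             rg_to_ree = sqrt(6.25)) {
  if (Rg <= 0) stop("Rg must be > 0, got ", Rg)
  if (n_nucleotides < 2) stop("n_nucleotides must be >= 2")
  if (contour_per_nt <= 0 || rg_to_ree <= 0)
    stop("contour_per_nt and rg_to_ree must be > 0")
  nu <- flory_exponent
  if (nu <= 0 || nu >= 1) stop("flory_exponent must be in (0, 1)")
  L <- n_nucleotides * contour_per_nt
  ree <- rg_to_ree * Rg
  b <- (ree / L^nu)^(1 / (1 - nu))
  if (b >= L)
    stop("inversion gives Kuhn length ", format(b, digits = 3),
         " nm >= contour length ", format(L, digits = 3),
         " nm: chain stiffer than its contour; check Rg and conventions")
  structure(list(kuhn_length_nm = b, persistence_length_nm = b / 2,
                 contour_length_nm = L, n_kuhn_segments = L / b,
                 Rg_nm = Rg, end_to_end_nm = ree,
                 flory_exponent = nu, rg_to_ree = rg_to_ree,
                 contour_per_nt = contour_per_nt),
            class = "qdfret_polymer")
}

#' Forward SAW radius of gyration from a Kuhn length
#'
#' Companion of [saw_kuhn_from_rg()]: Rg = b (L/b)^nu / rg_to_ree.
#'
#' @param kuhn_length_nm Kuhn length b, nm (> 0).
#' @param n_nucleotides Number of nucleotides (>= 2).
#' @inheritParams saw_kuhn_from_rg
#' @return Rg in nm.
#' @export
saw_rg_from_kuhn <- function(kuhn_length_nm, n_nucleotides,
                             contour_per_nt = 0.63,
                             flory_exponent = 0.588,
                             rg_to_ree = sqrt(6.25)) {
  if (kuhn_length_nm <= 0) stop("kuhn_length_nm must be > 0")
  L <- n_nucleotides * contour_per_nt
  kuhn_length_nm * (L / kuhn_length_nm)^flory_exponent / rg_to_ree
}
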