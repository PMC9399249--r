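test_that("scaffold edge lengths follow the bp count at B-DNA rise", {
  tet <- build_scaffold("tetrahedron", 52)
  expect_equal(tet$edge_length_nm, 17.68)
  expect_equal(round(tet$edge_length_nm), 18)
  pp <- build_scaffold("pentagonal_pyramid", 63)
  expect_equal(pp$edge_length_nm, 21.42)
  expect_equal(round(pp$edge_length_nm), 21)
  expect_error(build_scaffold("cube", 52), "arg")
  expect_error(build_scaffold("tetrahedron", 0), "edge_bp")
})

test_that("built polyhedra are regular with centroid at the origin", {
  for (kind in c("tetrahedron", "pentagonal_pyramid")) {
    m <- build_scaffold(kind, 52)
    expect_equal(unname(colMeans(m$vertices)), c(0, 0, 0),
                 tolerance = 1e-12)
    lens <- apply(m$edges, 1, function(e)
      sqrt(sum((m$vertices[e[1], ] - m$vertices[e[2], ])^2)))
    expect_equal(lens, rep(m$edge_length_nm, nrow(m$edges)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # tetrahedron: every vertex pair is an edge, so all pairwise distances
  # equal the edge length; circumradius is a*sqrt(3/8)
  tet <- build_scaffold("tetrahedron", 52)
  expect_equal(sqrt(sum(tet$vertices[1, ]^2)), 17.68 * sqrt(3 / 8),
               tolerance = 1e-9)
  expect_equal(nrow(build_scaffold("pentagonal_pyramid", 63)$edges), 10)
})

test_that("site resolution and distances obey the closed-form geometry", {
  tet <- build_scaffold("tetrahedron", 52)
  tet <- add_site(tet, "qd", list(type = "centroid"))
  tet <- add_site(tet, "v1", list(type = "vertex", index = 1))
  tet <- add_site(tet, "v2", list(type = "vertex", index = 2))
  tet <- add_site(tet, "mid12", list(type = "edge", index = 1,
                                     fraction = 0.5))
  expect_equal(site_distance(tet, "qd", "qd"), 0)
  expect_equal(site_distance(tet, "v1", "v2"), 17.68, tolerance = 1e-9)
  # centroid to edge midpoint of a regular tetrahedron: a / (2 sqrt(2))
  expect_equal(site_distance(tet, "qd", "mid12"), 17.68 / (2 * sqrt(2)),
               tolerance = 1e-9)
  expect_error(site_distance(tet, "qd", "nope"), "registered sites")
  # radial offset pushes a site outward along the centroid ray
  tet2 <- add_site(tet, "v1off", list(type = "vertex", index = 1),
                   radial_offset_nm = 2)
  expect_equal(site_distance(tet2, "qd", "v1off"),
               17.68 * sqrt(3 / 8) + 2, tolerance = 1e-9)
  expect_error(add_site(tet, "bad", list(type = "centroid"),
                        radial_offset_nm = 1), "centroid")
})

test_that("radial dye distance reproduces the TEM-based estimate", {
  expect_equal(radial_dye_distance(7.1, 0.68), 7.78)
  expect_equal(round(radial_dye_distance(7.1, 0.68), 1), 7.8)
  expect_error(radial_dye_distance(0), "radius")
})

test_that("bond angles are interior, clipped, and rigid-motion invariant", {
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0),
                          c(cos(pi / 3), sin(pi / 3), 0)), 60)
  expect_equal(bond_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
  # invariance under rotation and uniform scaling
  set.seed(13)
  for (k in 1:20) {
    p <- matrix(rnorm(9), 3)
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                   sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, byrow = TRUE)
    q <- 3.7 * p %*% t(Rz %*% Rx)
    expect_equal(bond_angle(p[1, ], p[2, ], p[3, ]),
                 bond_angle(q[1, ], q[2, ], q[3, ]), tolerance = 1e-9)
  }
})

test_that("angle-distribution statistics match the normal-CDF fraction", {
  set.seed(7)
  a <- pmin(pmax(rnorm(1000, 60, 15), 0), 180)
  st <- angle_distribution_stats(a, range = c(50, 100))
  # closed form: Phi((100-60)/15) - Phi((50-60)/15)
  expect_equal(st$fraction_in_range,
               pnorm(40 / 15) - pnorm(-10 / 15), tolerance = 0.03 /
                 (pnorm(40 / 15) - pnorm(-10 / 15)))
  expect_equal(st$mean_deg, mean(a))
  expect_equal(st$sd_deg, sqrt(mean((a - mean(a))^2)))

  const <- angle_distribution_stats(rep(90, 25), range = c(80, 100))
  expect_equal(const$sd_deg, 0)
  expect_equal(const$fraction_in_range, 1)
  expect_error(angle_distribution_stats(1:5), "at least 10")
  expect_error(angle_distribution_stats(c(rep(90, 10), 200)), "0, 180")

  # convergence of the empirical fraction at n = 1e4
  set.seed(8)
  big <- gen_trimer_angles(60, 15, 1e4, seed = 8)
  stb <- angle_distribution_stats(as.numeric(big), range = c(50, 100))
  expect_equal(stb$fraction_in_range, pnorm(40 / 15) - pnorm(-10 / 15),
               tolerance = 0.02 / 0.74)
})

test_that("SAW Kuhn-length inversion round-trips and has known limits", {
  pm <- saw_kuhn_from_rg(6.2, 51)
  expect_equal(pm$kuhn_length_nm, 5.476651, tolerance = 1e-5)
  expect_equal(pm$persistence_length_nm, pm$kuhn_length_nm / 2)
  expect_equal(pm$contour_length_nm, 51 * 0.63)

  # independent oracle: solve the forward relation numerically for b
  forward <- function(b) saw_rg_from_kuhn(b, 51) - 6.2
  b_oracle <- stats::uniroot(forward, c(0.1, 30), tol = 1e-12)$root
  expect_equal(pm$kuhn_length_nm, b_oracle, tolerance = 1e-9)

  # round trip through the forward model
  expect_equal(saw_rg_from_kuhn(pm$kuhn_length_nm, 51), 6.2,
               tolerance = 1e-9)

  # ideal-chain limit reduces to b = 6 Rg^2 / L exactly
  L <- 51 * 0.63
  ideal <- saw_kuhn_from_rg(2.5, 51, flory_exponent = 0.5,
                            rg_to_ree = sqrt(6))
  expect_equal(ideal$kuhn_length_nm, 6 * 2.5^2 / L, tolerance = 1e-12)

  # monotone increasing in Rg at fixed contour
  bs <- vapply(seq(3, 9, 0.5), function(r)
    saw_kuhn_from_rg(r, 51)$kuhn_length_nm, numeric(1))
  expect_true(all(diff(bs) > 0))

  # a chain stiffer than its contour is rejected
  expect_error(saw_kuhn_from_rg(14, 51), "contour")
})
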