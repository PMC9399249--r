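test_that("pair workflow reproduces the valence worked example", {
  rep <- run_pair_workflow(list(efficiency = 0.72, R0_nm = 7.0,
                                R_nm = 9.8))
  expect_equal(rep$results$n_inferred, 19.36166, tolerance = 1e-5)
  expect_identical(rep$results$n_inferred_integer, 19L)
  expect_equal(rep$results$R0_nm, 7.0)
})

test_that("pair workflow tolerates partial inputs and computes both routes", {
  # donor-only: no efficiencies, no inversions, no error
  rep <- run_pair_workflow(list(R0_nm = 7.0))
  expect_null(rep$results$E_intensity)
  expect_null(rep$results$n_inferred)

  # matched noiseless intensity and lifetime routes agree exactly
  obs <- gen_fret_observables(0.4, noise_cv = 0, seed = 1)
  rep2 <- run_pair_workflow(list(
    R0_nm = 7.0, n_acceptors = 1,
    intensities = list(I_D = obs$I_D[1], I_DA = obs$I_DA[1]),
    lifetimes = list(tau_D_ns = obs$tau_D_ns[1],
                     tau_DA_ns = obs$tau_DA_ns[1])))
  expect_equal(rep2$results$E_intensity, rep2$results$E_lifetime)
  expect_equal(rep2$results$R_inferred_nm,
               invert_for_distance(0.4, 7.0), tolerance = 1e-12)

  # spectra route: J and R0 from files
  dir <- withr::local_tempdir()
  write_spectrum(gen_emission_spectrum(600, 30),
                 file.path(dir, "donor.csv"))
  write_spectrum(gen_absorptivity_spectrum(650, 40, 2.4e5),
                 file.path(dir, "acceptor.csv"))
  rep3 <- run_pair_workflow(list(
    donor_emission = file.path(dir, "donor.csv"),
    acceptor_absorptivity = file.path(dir, "acceptor.csv"),
    quantum_yield = 0.3))
  d <- read_spectrum(file.path(dir, "donor.csv"), "emission")
  a <- read_spectrum(file.path(dir, "acceptor.csv"), "absorptivity")
  expect_equal(rep3$results$J, as.numeric(overlap_integral(d, a)))
  expect_equal(rep3$results$R0_nm,
               forster_distance(rep3$results$J, 0.3))
})

test_that("network workflow orders variants by relay-acceptor distance", {
  cfg <- list(
    R0_nm = list(d_relay = 7.0, d_acceptor = 6.0, relay_acceptor = 7.5),
    variants = list(
      list(name = "close", R_d_relay_nm = 9.5, R_d_acceptor_nm = 9.5,
           R_relay_acceptor_nm = 7.1),
      list(name = "medium", R_d_relay_nm = 9.5, R_d_acceptor_nm = 9.5,
           R_relay_acceptor_nm = 7.8),
      list(name = "far", R_d_relay_nm = 9.5, R_d_acceptor_nm = 9.5,
           R_relay_acceptor_nm = 12.2)))
  rep <- run_network_workflow(cfg)
  tab <- rep$results$table
  expect_equal(tab$name, c("close", "medium", "far"))
  expect_true(all(diff(tab$Q_sequential) < 0))
  # shared donor edges: Q_donor identical across variants
  expect_equal(diff(range(tab$Q_donor)), 0, tolerance = 1e-15)
})

test_that("geometry workflow reports edges, distances and angle stats", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(angle_deg = as.numeric(
    gen_trimer_angles(60, 15, 500, seed = 7))),
    file.path(dir, "angles.csv"), row.names = FALSE)
  cfg <- list(
    scaffold = list(
      polyhedron = "tetrahedron", edge_bp = 52,
      sites = list(
        list(name = "qd", anchor = list(type = "centroid")),
        list(name = "v1", anchor = list(type = "vertex", index = 1)))),
    angles_csv = file.path(dir, "angles.csv"),
    angle_range_deg = c(50, 100))
  rep <- run_geometry_workflow(cfg, out_dir = file.path(dir, "out"))
  expect_equal(rep$results$edge_length_nm, 17.68)
  expect_equal(rep$results$site_distances_nm["qd", "v1"],
               17.68 * sqrt(3 / 8), tolerance = 1e-9)
  expect_lt(abs(rep$results$angle_stats$mean_deg - 60), 2)
  expect_true(file.exists(file.path(dir, "out", "geometry.json")))
  expect_true(file.exists(file.path(dir, "out", "geometry.md")))
  # report embeds the resolved config and version
  expect_equal(rep$resolved_config$scaffold$edge_bp, 52)
  expect_match(rep$package_version, "^\\d+\\.\\d+")
})

test_that("synth workflow writes fixtures plus ground truth", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 5,
              emission = list(centers = 600, fwhms = 30, areas = 1),
              decay = list(gammas = c(0.6, 0.4), taus_ns = c(2, 10),
                           total_counts = 1e5),
              angles = list(design_angle_deg = 120, sd_deg = 12, n = 50))
  run_synth_workflow(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("emission.csv", "decay.csv", "angles.csv",
           "ground_truth.json")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$decay$tau_amplitude_weighted_ns, 5.2)
  # fixtures reload cleanly into the analysis path
  tab <- read.csv(file.path(dir, "decay.csv"))
  curve <- decay_curve(tab$time_ns, tab$counts)
  expect_equal(sum(curve$counts), 1e5, tolerance = 0.02)
})

test_that("config files parse from YAML and JSON alike", {
  dir <- withr::local_tempdir()
  cfgy <- file.path(dir, "c.yaml")
  writeLines(c("efficiency: 0.72", "R0_nm: 7.0", "R_nm: 9.8"), cfgy)
  expect_identical(run_pair_workflow(cfgy)$results$n_inferred_integer, 19L)
  cfgj <- file.path(dir, "c.json")
  jsonlite::write_json(list(efficiency = 0.72, R0_nm = 7.0, R_nm = 9.8),
                       cfgj, auto_unbox = TRUE)
  expect_identical(run_pair_workflow(cfgj)$results$n_inferred_integer, 19L)
  expect_error(read_run_config(file.path(dir, "c.txt")), "format")
})
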