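# Workflow orchestration: each run_*_workflow() takes a config (a list,
# or a path to a YAML/JSON file), resolves every default explicitly,
# runs the corresponding analysis, and returns a report list that embeds
# the fully resolved config and package version. With out_dir set, the
# report is written as machine-readable JSON plus a human-readable
# Markdown summary. Defaults that come from measured constants
# (kappa^2 = 2/3, n = 1.35, Phi_s = 0.92, 0.34 nm/bp) are the shipped
# defaults and are never silently altered.

#' Read a workflow configuration file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unrecognized config format: ", path,
            " (expected .yaml, .yml or .json)")
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  if (!is.list(config)) stop("config must be a list or a file path")
  config
}

default_of <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

write_report <- function(report, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  md <- c(paste0("# qdfret ", name, " report"), "",
          paste0("Package version: ", report$package_version), "",
          "## Results", "",
          vapply(names(report$results), function(k) {
            v <- report$results[[k]]
            paste0("- **", k, "**: ",
                   if (is.null(v) || length(v) == 0) "NA"
                   else paste(format(unlist(v), digits = 6),
                              collapse = ", "))
          }, character(1)))
  writeLines(md, file.path(out_dir, paste0(name, ".md")))
  invisible(report)
}

finish_report <- function(results, config, out_dir, name) {
  report <- list(
    workflow = name,
    package_version =
      as.character(utils::packageVersion("qdfret")),
    resolved_config = config,
    results = results)
  if (!is.null(out_dir)) write_report(report, out_dir, name)
  report
}

#' Run the donor-acceptor pair valence workflow
#'
#' From whatever subset of inputs is present, computes: the overlap
#' integral J and Forster distance R0 (when donor emission, acceptor
#' absorptivity and donor quantum yield are given, or R0 directly), the
#' intensity- and lifetime-route efficiencies, and the two inversions
#' (acceptor count from efficiency at known R; distance from efficiency
#' at known acceptor count). Absent inputs yield NULL fields, not errors.
#'
#' @param config List or config-file path. Recognized fields:
#'   `donor_emission` / `acceptor_absorptivity` (spectrum CSV paths),
#'   `quantum_yield`, `kappa_squared` (default 2/3), `refractive_index`
#'   (default 1.35), `R0_nm`, `R_nm`, `n_acceptors`,
#'   `intensities` (list `I_D`, `I_DA`), `lifetimes` (list `tau_D_ns`,
#'   `tau_DA_ns`), `efficiency` (direct measured value for inversions).
#' @param out_dir Optional output directory for JSON + Markdown reports.
#' @return Report list with `results` fields `J`, `R0_nm`,
#'   `E_intensity`, `E_lifetime`, `E_used`, `n_inferred`,
#'   `n_inferred_integer`, `R_inferred_nm`.
#' @export
run_pair_workflow <- function(config, out_dir = NULL) {
  config <- resolve_config(config)
  config$kappa_squared <- default_of(config, "kappa_squared", 2 / 3)
  config$refractive_index <- default_of(config, "refractive_index", 1.35)

  J <- NULL
  R0 <- config$R0_nm
  if (!is.null(config$donor_emission) &&
      !is.null(config$acceptor_absorptivity)) {
    d <- read_spectrum(config$donor_emission, "emission")
    a <- read_spectrum(config$acceptor_absorptivity, "absorptivity")
    J <- as.numeric(overlap_integral(d, a))
    if (is.null(R0)) {
      if (is.null(config$quantum_yield))
        stop("quantum_yield is required to compute R0 from spectra")
      R0 <- forster_distance(J, config$quantum_yield,
                             config$kappa_squared,
                             config$refractive_index)
    }
  }

  E_int <- if (!is.null(config$intensities))
    efficiency_from_intensity(config$intensities$I_D,
                              config$intensities$I_DA)
  E_life <- if (!is.null(config$lifetimes))
    efficiency_from_lifetime(config$lifetimes$tau_D_ns,
                             config$lifetimes$tau_DA_ns)
  E_used <- config$efficiency
  if (is.null(E_used)) E_used <- E_int
  if (is.null(E_used)) E_used <- E_life

  n_inf <- NULL; R_inf <- NULL
  if (!is.null(E_used) && !is.null(R0) && E_used > 0 && E_used < 1) {
    if (!is.null(config$R_nm))
      n_inf <- invert_for_acceptor_count(E_used, R0, config$R_nm)
    if (!is.null(config$n_acceptors))
      R_inf <- invert_for_distance(E_used, R0, config$n_acceptors)
  }

  finish_report(list(
    J = J, R0_nm = R0,
    E_intensity = E_int, E_lifetime = E_life, E_used = E_used,
    n_inferred = if (!is.null(n_inf)) n_inf$n,
    n_inferred_integer = if (!is.null(n_inf)) n_inf$n_integer,
    R_inferred_nm = R_inf), config, out_dir, "pair")
}

#' Run the multi-step network workflow over design variants
#'
#' Evaluates the three-node donor/relay/acceptor network for each variant
#' (e.g. close/medium/far relay->acceptor placements) sharing one set of
#' per-edge Forster distances, and tabulates the quench efficiencies.
#'
#' @param config List or config-file path with `R0_nm` (list `d_relay`,
#'   `d_acceptor`, `relay_acceptor`) and `variants` (list of lists with
#'   `name`, `R_d_relay_nm`, `R_d_acceptor_nm`, `R_relay_acceptor_nm`).
#' @param out_dir Optional output directory.
#' @return Report list; `results$table` is a data frame with one row per
#'   variant (Q_donor, Q_competitive, Q_sequential, Q_relay and the three
#'   gammas).
#' @export
run_network_workflow <- function(config, out_dir = NULL) {
  config <- resolve_config(config)
  if (is.null(config$R0_nm) || is.null(config$variants))
    stop("network config needs R0_nm and variants")
  r0 <- config$R0_nm
  rows <- lapply(config$variants, function(v) {
    res <- evaluate_network(
      R_d_relay = v$R_d_relay_nm, R_d_acceptor = v$R_d_acceptor_nm,
      R_relay_acceptor = v$R_relay_acceptor_nm,
      R0_d_relay = r0$d_relay, R0_d_acceptor = r0$d_acceptor,
      R0_relay_acceptor = r0$relay_acceptor)
    data.frame(name = if (is.null(v$name)) NA_character_ else v$name,
               R_relay_acceptor_nm = v$R_relay_acceptor_nm,
               Q_donor = res$Q_donor, Q_competitive = res$Q_competitive,
               Q_sequential = res$Q_sequential, Q_relay = res$Q_relay,
               gamma_d_relay = res$gammas[["d_relay"]],
               gamma_d_acceptor = res$gammas[["d_acceptor"]],
               gamma_relay_acceptor = res$gammas[["relay_acceptor"]])
  })
  finish_report(list(table = do.call(rbind, rows)), config, out_dir,
                "network")
}

#' Run the colloidal-geometry workflow
#'
#' Builds the configured wireframe scaffold (reporting its edge length
#' and the full site-to-site distance matrix) and/or summarizes a
#' bond-angle sample with a Gaussian fit and in-range fraction.
#'
#' @param config List or config-file path. Recognized fields: `scaffold`
#'   (list with `polyhedron`, `edge_bp`, optional `rise_per_bp` and
#'   `sites`, each site a list `name`, `anchor`, `radial_offset_nm`),
#'   `angles_csv` (single-column CSV of degrees) or `angles` (numeric),
#'   `angle_range_deg` (length-2).
#' @param out_dir Optional output directory.
#' @return Report list with `edge_length_nm`, `site_distances_nm`
#'   (matrix) and `angle_stats` fields as available.
#' @export
run_geometry_workflow <- function(config, out_dir = NULL) {
  config <- resolve_config(config)
  results <- list()
  if (!is.null(config$scaffold)) {
    sc <- config$scaffold
    model <- build_scaffold(sc$polyhedron, sc$edge_bp,
                            default_of(sc, "rise_per_bp", 0.34))
    for (site in sc$sites %||% list())
      model <- add_site(model, site$name, site$anchor,
                        default_of(site, "radial_offset_nm", 0))
    results$edge_length_nm <- model$edge_length_nm
    nm <- names(model$sites)
    if (length(nm) >= 2) {
      dm <- outer(nm, nm, Vectorize(function(a, b)
        site_distance(model, a, b)))
      dimnames(dm) <- list(nm, nm)
      results$site_distances_nm <- dm
    }
  }
  angles <- config$angles
  if (!is.null(config$angles_csv)) {
    tab <- utils::read.csv(config$angles_csv, comment.char = "#")
    angles <- as.numeric(tab[[1]])
  }
  if (!is.null(angles)) {
    st <- angle_distribution_stats(
      angles, default_of(config, "angle_range_deg", c(0, 180)))
    results$angle_stats <- list(
      mean_deg = st$mean_deg, sd_deg = st$sd_deg,
      fraction_in_range = st$fraction_in_range,
      range_deg = st$range_deg, n = st$n)
  }
  if (length(results) == 0L)
    stop("geometry config needs a scaffold and/or angles")
  finish_report(results, config, out_dir, "geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a directory of synthetic fixtures from a recipe
#'
#' Writes CSV fixtures (emission spectrum, absorbance mixture, decay
#' histogram, trimer angles — whichever the recipe requests) plus a
#' `ground_truth.json` collecting every generating parameter.
#'
#' @param config List or config-file path with a global `seed` and any of
#'   `emission` (list `centers`, `fwhms`, `areas`), `mixture` (list
#'   `components` = list of absorptivity band specs, `concentrations`,
#'   `noise_sd`), `decay` (list `gammas`, `taus_ns`, `total_counts`,
#'   `bin_width_ns`, `repetition_period_ns`, `background_fraction`),
#'   `angles` (list `design_angle_deg`, `sd_deg`, `n`).
#' @param out_dir Output directory (required).
#' @return Report list; files are written under `out_dir`.
#' @export
run_synth_workflow <- function(config, out_dir) {
  config <- resolve_config(config)
  if (missing(out_dir) || is.null(out_dir))
    stop("synth workflow requires an output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- default_of(config, "seed", 1L)
  truth <- list(seed = seed)

  if (!is.null(config$emission)) {
    e <- config$emission
    s <- gen_emission_spectrum(e$centers, e$fwhms, e$areas %||% 1)
    write_spectrum(s, file.path(out_dir, "emission.csv"))
    truth$emission <- attr(s, "ground_truth")
  }
  if (!is.null(config$mixture)) {
    m <- config$mixture
    comps <- lapply(m$components, function(cm)
      gen_absorptivity_spectrum(cm$centers, cm$fwhms, cm$peaks,
                                tail_peak = cm$tail_peak %||% 0))
    names(comps) <- vapply(m$components, function(cm)
      cm$name %||% "component", character(1))
    mix <- gen_absorbance_mixture(comps, m$concentrations,
                                  m$noise_sd %||% 0, seed = seed)
    write_spectrum(mix, file.path(out_dir, "mixture_absorbance.csv"))
    for (i in seq_along(comps))
      write_spectrum(comps[[i]],
                     file.path(out_dir, paste0("component_",
                                               names(comps)[i], ".csv")))
    truth$mixture <- attr(mix, "ground_truth")
  }
  if (!is.null(config$decay)) {
    d <- config$decay
    dc <- gen_decay_histogram(d$gammas, d$taus_ns, d$total_counts,
                              d$bin_width_ns %||% 0.5,
                              d$repetition_period_ns %||% 400,
                              d$background_fraction %||% 0, seed = seed)
    utils::write.csv(data.frame(time_ns = dc$time_ns, counts = dc$counts),
                     file.path(out_dir, "decay.csv"), row.names = FALSE,
                     quote = FALSE)
    gt <- attr(dc, "ground_truth"); gt$expected <- NULL
    truth$decay <- gt
  }
  if (!is.null(config$angles)) {
    an <- config$angles
    a <- gen_trimer_angles(an$design_angle_deg, an$sd_deg, an$n,
                           seed = seed)
    utils::write.csv(data.frame(angle_deg = as.numeric(a)),
                     file.path(out_dir, "angles.csv"), row.names = FALSE,
                     quote = FALSE)
    truth$angles <- attr(a, "ground_truth")
  }
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  finish_report(list(files = list.files(out_dir)), config, out_dir,
                "synth")
}
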