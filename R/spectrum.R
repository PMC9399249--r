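#' Construct a Spectrum object
#'
#' A `Spectrum` is a wavelength-indexed curve: either an emission spectrum
#' (arbitrary units, optionally area-normalized), a molar absorptivity
#' spectrum (M^-1 cm^-1), or a measured absorbance spectrum (dimensionless).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   ascending after sorting, length >= 2, all finite.
#' @param values Numeric vector of the same length. Must be finite; for
#'   `kind = "absorptivity"` or `"absorbance"` values must be >= 0.
#' @param kind One of `"emission"`, `"absorptivity"`, `"absorbance"`.
#' @param area_normalized Logical; flag that the trapezoidal integral of
#'   `values` over `wavelengths` is 1 (checked to 1e-6 relative tolerance).
#'
#' @return An object of class `qdfret_spectrum` with fields `wavelengths`,
#'   `values`, `kind`, `area_normalized`.
#' @export
#' @examples
#' s <- spectrum_curve(c(500, 600, 700), c(0, 1, 0), kind = "emission")
#' spectrum_area(s)
spectrum_curve <- function(wavelengths, values,
                           kind = c("emission", "absorptivity", "absorbance"),
                           area_normalized = FALSE) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 points, got ", length(wavelengths))
  if (length(values) != length(wavelengths))
    stop("wavelengths and values differ in length (",
         length(wavelengths), " vs ", length(values), ")")
  if (!all(is.finite(wavelengths)) || !all(is.finite(values)))
    stop("spectrum contains non-finite wavelengths or values")
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  values <- values[ord]
  if (any(diff(wavelengths) == 0))
    stop("duplicate wavelengths in spectrum: ",
         paste(unique(wavelengths[duplicated(wavelengths)]), collapse = ", "))
  if (kind %in% c("absorptivity", "absorbance") && any(values < 0))
    stop(kind, " spectrum has negative values")
  s <- structure(
    list(wavelengths = wavelengths, values = values, kind = kind,
         area_normalized = isTRUE(area_normalized)),
    class = "qdfret_spectrum")
  if (s$area_normalized) {
    a <- spectrum_area(s)
    if (abs(a - 1) > 1e-6)
      stop("spectrum flagged area-normalized but integral is ",
           format(a), " (must be 1 within 1e-6 relative)")
  }
  s
}

#' @export
print.qdfret_spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum: %d points, %.4g-%.4g nm%s>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (x$area_normalized) ", area-normalized" else ""))
  invisible(x)
}

#' Trapezoidal integral of a spectrum over its wavelength grid
#'
#' @param s A `qdfret_spectrum`.
#' @return The trapezoidal integral (units of value x nm).
#' @export
spectrum_area <- function(s) {
  stopifnot(inherits(s, "qdfret_spectrum"))
  pracma::trapz(s$wavelengths, s$values)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns `wavelength_nm,value` (header optional); lines starting
#' with `#` are ignored. Rows are sorted by wavelength; duplicated
#' wavelengths are rejected.
#'
#' @param path Path to the CSV file.
#' @param kind Spectrum kind passed to [spectrum_curve()].
#' @return A validated `qdfret_spectrum`.
#' @export
read_spectrum <- function(path,
                          kind = c("emission", "absorptivity", "absorbance")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  parse_row <- function(ln) suppressWarnings(as.numeric(strsplit(ln, ",")[[1]]))
  first <- parse_row(lines[1])
  has_header <- any(is.na(first))
  if (has_header) lines <- lines[-1]
  rows <- lapply(seq_along(lines), function(i) {
    v <- parse_row(lines[i])
    if (length(v) < 2L || any(is.na(v[1:2])))
      stop("malformed row at line ", i + has_header, " of ", path, ": '",
           lines[i], "'")
    v[1:2]
  })
  m <- do.call(rbind, rows)
  spectrum_curve(m[, 1], m[, 2], kind = kind)
}

#' Write a spectrum to a two-column CSV file
#'
#' @param s A `qdfret_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "qdfret_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelengths, value = s$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Area-normalize an emission spectrum
#'
#' Rescales so the trapezoidal integral over the grid equals 1, as required
#' for the donor emission term of the overlap integral.
#'
#' @param s A `qdfret_spectrum`; its integral must be > 0.
#' @return The rescaled spectrum with `area_normalized = TRUE`.
#' @export
area_normalize <- function(s) {
  stopifnot(inherits(s, "qdfret_spectrum"))
  a <- spectrum_area(s)
  if (!is.finite(a) || a <= 0)
    stop("cannot area-normalize: spectrum integral is ", format(a))
  spectrum_curve(s$wavelengths, s$values / a, kind = s$kind,
                 area_normalized = TRUE)
}

# Linear interpolation of a spectrum onto an arbitrary grid; zero outside
# its own support (no extrapolation).
interp_spectrum <- function(s, grid) {
  out <- stats::approx(s$wavelengths, s$values, xout = grid,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Spectral overlap integral J of a FRET pair
#'
#' Computes J = integral of I_D(lambda) * eps_A(lambda) * lambda^4 dlambda,
#' where I_D is the area-normalized donor emission spectrum and eps_A the
#' acceptor molar absorptivity in M^-1 cm^-1, with lambda in nm. The donor
#' spectrum is area-normalized internally if it is not flagged as such.
#' Integration is trapezoidal on the union of the two wavelength grids
#' restricted to their common support, with linear interpolation and no
#' extrapolation.
#'
#' @param donor_emission Donor emission `qdfret_spectrum`.
#' @param acceptor_absorptivity Acceptor molar absorptivity
#'   `qdfret_spectrum` (M^-1 cm^-1).
#' @return J in M^-1 cm^-1 nm^4 with attribute `grid` (the integration
#'   grid used). Disjoint spectra give 0 with a warning.
#' @export
#' @examples
#' d <- spectrum_curve(seq(550, 650, 1),
#'                     exp(-(seq(550, 650, 1) - 600)^2 / (2 * 12^2)),
#'                     "emission")
#' a <- spectrum_curve(seq(580, 700, 1),
#'                     1e5 * exp(-(seq(580, 700, 1) - 650)^2 / (2 * 15^2)),
#'                     "absorptivity")
#' overlap_integral(d, a)
overlap_integral <- function(donor_emission, acceptor_absorptivity) {
  stopifnot(inherits(donor_emission, "qdfret_spectrum"),
            inherits(acceptor_absorptivity, "qdfret_spectrum"))
  if (donor_emission$kind != "emission")
    stop("donor spectrum must be of kind 'emission'")
  if (acceptor_absorptivity$kind != "absorptivity")
    stop("acceptor spectrum must be of kind 'absorptivity'")
  if (!donor_emission$area_normalized)
    donor_emission <- area_normalize(donor_emission)
  lo <- max(min(donor_emission$wavelengths),
            min(acceptor_absorptivity$wavelengths))
  hi <- min(max(donor_emission$wavelengths),
            max(acceptor_absorptivity$wavelengths))
  if (lo >= hi) {
    warning("donor emission and acceptor absorptivity have disjoint ",
            "wavelength ranges; J = 0")
    return(structure(0, grid = numeric(0)))
  }
  grid <- sort(unique(c(
    donor_emission$wavelengths, acceptor_absorptivity$wavelengths, lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  integrand <- interp_spectrum(donor_emission, grid) *
    interp_spectrum(acceptor_absorptivity, grid) * grid^4
  j <- pracma::trapz(grid, integrand)
  structure(max(j, 0), grid = grid)
}

#' Forster distance from the overlap integral
#'
#' R0 = 0.0211 * (kappa^2 * Phi_D * n^-4 * J)^(1/6) in nm, with J in
#' M^-1 cm^-1 nm^4. Defaults are the dynamic-averaging orientation factor
#' kappa^2 = 2/3 and aqueous-buffer refractive index n = 1.35.
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4 (>= 0).
#' @param quantum_yield Donor quantum yield Phi_D in (0, 1].
#' @param kappa_squared Orientation factor (default 2/3).
#' @param refractive_index Medium refractive index (default 1.35).
#' @return R0 in nm.
#' @export
#' @examples
#' forster_distance(1e15, quantum_yield = 0.3) # ~4.18 nm
forster_distance <- function(J, quantum_yield, kappa_squared = 2 / 3,
                             refractive_index = 1.35) {
  if (!is.finite(J) || J < 0) stop("J must be finite and >= 0, got ", J)
  if (quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum_yield must be in (0, 1], got ", quantum_yield)
  if (refractive_index <= 0)
    stop("refractive_index must be > 0, got ", refractive_index)
  if (kappa_squared < 0)
    stop("kappa_squared must be >= 0, got ", kappa_squared)
  0.0211 * (kappa_squared * quantum_yield * refractive_index^-4 * J)^(1 / 6)
}

#' Beer-Lambert concentration from absorbance
#'
#' @param absorbance Measured absorbance (dimensionless, >= 0).
#' @param extinction Molar extinction coefficient, M^-1 cm^-1 (> 0). For
#'   the QDs used here the 350 nm values are 3.0e6 (QD600), 1.06e7 (QD630)
#'   and 2.9e7 (QD660) M^-1 cm^-1.
#' @param path_length Cuvette path length in cm (default 1).
#' @return Concentration in M.
#' @export
#' @examples
#' beer_lambert_concentration(0.3, 3e6) # 1e-7 M = 100 nM
beer_lambert_concentration <- function(absorbance, extinction,
                                       path_length = 1) {
  if (extinction <= 0) stop("extinction must be > 0, got ", extinction)
  if (path_length <= 0) stop("path_length must be > 0, got ", path_length)
  if (absorbance < 0) stop("absorbance must be >= 0, got ", absorbance)
  absorbance / (extinction * path_length)
}

#' Relative quantum yield against a fluorescence standard
#'
#' Single-point relative method:
#' Phi = Phi_s * (I/I_s) * (A_s/A) * (n^2/n_s^2), with integrated emission
#' intensities I, absorbances A at the excitation wavelength, and
#' refractive indices n. The rhodamine 101 / ethanol standard used here has
#' Phi_s = 0.92 at 480 nm excitation.
#'
#' @param sample_intensity_integral Integrated sample emission (a.u.).
#' @param sample_absorbance Sample absorbance at the excitation wavelength.
#' @param standard_intensity_integral Integrated standard emission (a.u.).
#' @param standard_absorbance Standard absorbance at excitation.
#' @param standard_qy Standard quantum yield in (0, 1] (default 0.92).
#' @param sample_ri,standard_ri Refractive indices of the two solvents.
#' @return Quantum yield (dimensionless). Values above 1 are returned as-is
#'   with a warning; absorbances above 0.2 trigger an inner-filter warning.
#' @export
relative_quantum_yield <- function(sample_intensity_integral,
                                   sample_absorbance,
                                   standard_intensity_integral,
                                   standard_absorbance,
                                   standard_qy = 0.92,
                                   sample_ri = 1.33, standard_ri = 1.36) {
  if (standard_intensity_integral <= 0)
    stop("standard intensity integral must be > 0")
  if (standard_absorbance <= 0 || sample_absorbance <= 0)
    stop("absorbances must be > 0")
  if (standard_qy <= 0 || standard_qy > 1)
    stop("standard_qy must be in (0, 1], got ", standard_qy)
  if (sample_absorbance > 0.2 || standard_absorbance > 0.2)
    warning("absorbance above 0.2: inner-filter effects may bias the ",
            "relative quantum yield")
  qy <- standard_qy *
    (sample_intensity_integral / standard_intensity_integral) *
    (standard_absorbance / sample_absorbance) *
    (sample_ri^2 / standard_ri^2)
  if (qy > 1)
    warning("relative quantum yield ", format(qy),
            " exceeds 1; reported unclipped")
  qy
}

#' Decompose a measured absorbance spectrum into known components
#'
#' Non-negative least squares (Lawson-Hanson) solution of
#' A(lambda) = sum_i c_i * eps_i(lambda) * l on the union wavelength grid
#' of all inputs, restricted to the measured spectrum's support. Used to
#' obtain dye/QD labeling ratios from a mixture absorption spectrum.
#'
#' @param measured Measured absorbance `qdfret_spectrum`.
#' @param components Named list of molar absorptivity `qdfret_spectrum`
#'   objects (>= 2 components, linearly independent on the shared grid).
#' @param path_length Path length in cm (default 1).
#' @param baseline If `TRUE`, include a constant offset column to absorb a
#'   flat scattering baseline.
#' @return A list with `concentrations` (named, M), `ratios` (all pairwise
#'   c_i/c_j as a named matrix), `residual_norm` (L2 norm of the fit
#'   residual), `baseline` (fitted offset or NA) and `grid`.
#' @export
unmix_absorbance <- function(measured, components, path_length = 1,
                             baseline = FALSE) {
  stopifnot(inherits(measured, "qdfret_spectrum"))
  if (measured$kind != "absorbance")
    stop("measured spectrum must be of kind 'absorbance'")
  if (length(components) < 2L)
    stop("need at least 2 components, got ", length(components))
  if (is.null(names(components)) || any(!nzchar(names(components))))
    names(components) <- paste0("component", seq_along(components))
  for (cm in components) {
    stopifnot(inherits(cm, "qdfret_spectrum"))
    if (cm$kind != "absorptivity")
      stop("components must be of kind 'absorptivity'")
  }
  grid <- sort(unique(c(measured$wavelengths,
                        unlist(lapply(components, `[[`, "wavelengths")))))
  grid <- grid[grid >= min(measured$wavelengths) &
                 grid <= max(measured$wavelengths)]
  X <- vapply(components, interp_spectrum, numeric(length(grid)),
              grid = grid) * path_length
  if (baseline) X <- cbind(X, baseline = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("component matrix is rank-deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  y <- interp_spectrum(measured, grid)
  fit <- pracma::lsqnonneg(X, y)
  coefs <- fit$x
  names(coefs) <- colnames(X)
  conc <- coefs[names(components)]
  k <- length(conc)
  ratios <- outer(conc, conc, function(a, b) ifelse(b > 0, a / b, NA_real_))
  dimnames(ratios) <- list(names(conc), names(conc))
  list(concentrations = conc,
       ratios = ratios,
       residual_norm = sqrt(sum((y - as.vector(X %*% coefs))^2)),
       baseline = if (baseline) unname(coefs["baseline"]) else NA_real_,
       grid = grid)
}

#' Bundle the photophysical description of a fluorophore
#'
#' @param name Identifier (e.g. "QD605", "AF647").
#' @param emission Emission `qdfret_spectrum`, or NULL.
#' @param absorptivity Molar absorptivity `qdfret_spectrum`, or NULL.
#' @param quantum_yield Quantum yield in (0, 1], or NA.
#' @param natural_lifetime_ns Unquenched excited-state lifetime in ns
#'   (> 0), or NA. The natural relaxation rate is 1/natural_lifetime_ns.
#' @param extinction_at_reference Extinction coefficient (M^-1 cm^-1) at
#'   `reference_wavelength_nm`, or NA.
#' @param reference_wavelength_nm Wavelength of the reference extinction
#'   (e.g. 350 for QDs).
#' @return A `qdfret_fluorophore` list.
#' @export
fluorophore <- function(name, emission = NULL, absorptivity = NULL,
                        quantum_yield = NA_real_,
                        natural_lifetime_ns = NA_real_,
                        extinction_at_reference = NA_real_,
                        reference_wavelength_nm = NA_real_) {
  if (!is.na(quantum_yield) &&
      (quantum_yield <= 0 || quantum_yield > 1))
    stop("quantum_yield must be in (0, 1], got ", quantum_yield)
  if (!is.na(natural_lifetime_ns) && natural_lifetime_ns <= 0)
    stop("natural_lifetime_ns must be > 0, got ", natural_lifetime_ns)
  if (!is.null(emission)) stopifnot(inherits(emission, "qdfret_spectrum"))
  if (!is.null(absorptivity))
    stopifnot(inherits(absorptivity, "qdfret_spectrum"))
  structure(list(name = name, emission = emission,
                 absorptivity = absorptivity,
                 quantum_yield = quantum_yield,
                 natural_lifetime_ns = natural_lifetime_ns,
                 extinction_at_reference = extinction_at_reference,
                 reference_wavelength_nm = reference_wavelength_nm),
            class = "qdfret_fluorophore")
}
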