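#' Scanner spectrum coefficients
#'
#' The two fitted ratios characterizing the scanner beam in the parametric
#' attenuation model: `k1` weights the coherent-scatter term (effective-Z
#' exponent 1.86) and `k2` the photoelectric term (exponent 3.62), both
#' relative to incoherent (Klein-Nishina) scattering.  The individual
#' weighting constants and the beam energy enter only through these ratios.
#'
#' @param k1,k2 Non-negative dimensionless coefficients.
#' @return An object of class `spectrum_coefficients`.
#' @export
spectrum_coefficients <- function(k1, k2) {
  stopifnot(is.numeric(k1), is.numeric(k2), length(k1) == 1, length(k2) == 1)
  if (k1 < 0 || k2 < 0) stop("spectrum coefficients must be non-negative")
  structure(list(k1 = k1, k2 = k2), class = "spectrum_coefficients")
}

#' @export
print.spectrum_coefficients <- function(x, ...) {
  cat(sprintf("<spectrum_coefficients> k1 = %.6g, k2 = %.6g\n", x$k1, x$k2))
  if (!is.null(attr(x, "fit"))) {
    f <- attr(x, "fit")
    cat(sprintf("  fitted on %d observations, residual norm %.4g HU\n",
                f$n_obs, f$residual_norm))
  }
  invisible(x)
}

# effective-Z exponents of the two spectrum terms
.Z_EXP_SCA <- 1.86
.Z_EXP_PE <- 3.62

# per-material ingredients of the forward HU model
.hu_model_terms <- function(material, water, elements) {
  list(rho_e = relative_electron_density(material, water, elements),
       a = effective_atomic_number(material, .Z_EXP_SCA, elements)^.Z_EXP_SCA,
       b = effective_atomic_number(material, .Z_EXP_PE, elements)^.Z_EXP_PE)
}

#' Forward-predict the CT number of a material
#'
#' Parametric attenuation model: with relative electron density
#' \eqn{\hat\rho_{e,w}} and effective atomic numbers \eqn{\hat Z}
#' (exponent 1.86 for the coherent-scatter term, 3.62 for the photoelectric
#' term),
#' \deqn{HU/1000 + 1 = \hat\rho_{e,w}\,
#'   \frac{1 + \hat Z^{1.86} k_1 + \hat Z^{3.62} k_2}
#'        {1 + \hat Z_w^{1.86} k_1 + \hat Z_w^{3.62} k_2}.}
#' Water maps to 0 HU for every coefficient pair.
#'
#' @param material A [ct_material()] (or a `material_library`, in which case
#'   a named vector of HU values is returned).
#' @param coeffs A [spectrum_coefficients()].
#' @param water Water reference material.
#' @param elements Element table.
#' @return Predicted CT number(s) in HU (float; no rounding).
#' @export
predicted_hu <- function(material, coeffs, water = water_material(),
                         elements = element_table()) {
  if (inherits(material, "material_library") || (is.list(material) &&
      !inherits(material, "ct_material"))) {
    return(vapply(material, predicted_hu, numeric(1),
                  coeffs = coeffs, water = water, elements = elements))
  }
  tm <- .hu_model_terms(material, water, elements)
  tw <- .hu_model_terms(water, water, elements)
  ratio <- tm$rho_e * (1 + tm$a * coeffs$k1 + tm$b * coeffs$k2) /
    (1 + tw$a * coeffs$k1 + tw$b * coeffs$k2)
  1000 * (ratio - 1)
}

#' Fit spectrum coefficients to measured insert CT numbers
#'
#' Non-negative nonlinear least squares of the forward HU model against the
#' measured mean CT number of each calibration insert (`nls` with the bounded
#' `port` algorithm; initial guess (1e-3, 1e-4)).  The design must contain at
#' least one material whose effective atomic number differs from water's,
#' otherwise the model ratio reduces to the relative electron density for
#' every coefficient pair and the fit is unidentifiable.
#'
#' @param materials List of [ct_material()] calibration inserts.
#' @param hu Numeric vector of measured mean CT numbers (HU), same length.
#' @param water,elements Reference material and element table.
#' @param start Initial guess `c(k1, k2)`.
#' @return A [spectrum_coefficients()] with a `fit` attribute carrying the
#'   residual norm and per-material residuals.
#' @export
fit_spectrum_coefficients <- function(materials, hu,
                                      water = water_material(),
                                      elements = element_table(),
                                      start = c(k1 = 1e-3, k2 = 1e-4)) {
  if (inherits(materials, "ct_material")) materials <- list(materials)
  if (length(materials) != length(hu)) {
    stop("materials and hu must have the same length")
  }
  ok <- is.finite(hu)
  materials <- materials[ok]
  hu <- hu[ok]
  if (length(hu) < 2) stop("need at least 2 usable (material, HU) observations")

  terms <- lapply(materials, .hu_model_terms, water = water, elements = elements)
  tw <- .hu_model_terms(water, water, elements)
  d <- data.frame(y = hu / 1000 + 1,
                  rho_e = vapply(terms, `[[`, numeric(1), "rho_e"),
                  a = vapply(terms, `[[`, numeric(1), "a"),
                  b = vapply(terms, `[[`, numeric(1), "b"))
  # identifiability: all-water-like compositions leave (k1,k2) undetermined
  if (all(abs(d$a - tw$a) < 1e-6 * tw$a) && all(abs(d$b - tw$b) < 1e-6 * tw$b)) {
    stop("unidentifiable fit: all calibration materials are water-like ",
         "(effective atomic numbers equal water's); the model ratio reduces ",
         "to the relative electron density for any coefficients")
  }
  fit <- stats::nls(
    y ~ rho_e * (1 + a * k1 + b * k2) / (1 + tw$a * k1 + tw$b * k2),
    data = d, start = as.list(start), algorithm = "port",
    lower = c(k1 = 0, k2 = 0),
    control = stats::nls.control(maxiter = 500, tol = 1e-12,
                                 minFactor = 1e-12, warnOnly = FALSE)
  )
  k <- stats::coef(fit)
  res_hu <- 1000 * stats::resid(fit)
  out <- spectrum_coefficients(unname(k["k1"]), unname(k["k2"]))
  attr(out, "fit") <- list(
    residual_norm = sqrt(sum(res_hu^2)),
    residuals_hu = as.numeric(res_hu),
    n_obs = length(hu),
    materials = vapply(materials, `[[`, character(1), "name")
  )
  out
}

#' Proton relative stopping power from the Bethe equation
#'
#' Stopping-power ratio to water at the configured proton energy:
#' \deqn{RSP = \hat\rho_{e,w}\,
#'   \frac{\ln[2 m_e c^2 \beta^2 / (I_m (1-\beta^2)) - \beta^2]}
#'        {\ln[2 m_e c^2 \beta^2 / (I_{water} (1-\beta^2)) - \beta^2]}.}
#' Vectorized over `rho_e` and `I_m`.
#'
#' @param rho_e Relative electron density (> 0).
#' @param I_m Mean excitation energy of the material in eV (> 0).
#' @param constants A [physics_constants()].
#' @return RSP (dimensionless).
#' @export
#' @examples
#' bethe_rsp(1.0, 75)   # water: exactly 1
bethe_rsp <- function(rho_e, I_m, constants = physics_constants()) {
  stopifnot(all(rho_e > 0), all(I_m > 0))
  b2 <- constants$beta2
  stopifnot(b2 > 0, b2 < 1)
  two_me_b2 <- 2 * constants$m_e_c2 * 1e6 * b2 / (1 - b2)  # eV
  arg_m <- two_me_b2 / I_m - b2
  arg_w <- two_me_b2 / constants$I_water - b2
  if (any(arg_m <= 1) || arg_w <= 1) {
    stop("Bethe logarithm argument <= 1; proton energy too low for the ",
         "given mean excitation energy")
  }
  rho_e * log(arg_m) / log(arg_w)
}

#' Build the stoichiometric HU -> (density, RSP) calibration curve
#'
#' For each tissue in the library the forward model predicts its CT number
#' at the fitted spectrum coefficients, the library mass density supplies
#' the density node, and the Bethe equation (with the Bragg-additivity mean
#' excitation energy of the composition) supplies the RSP node.  Nodes are
#' sorted by HU into a piecewise-linear curve with flat extrapolation beyond
#' the end nodes.  Duplicate HU nodes keep the denser material (with a
#' warning).
#'
#' @param tissues A `material_library` (or list of [ct_material()]).
#' @param coeffs [spectrum_coefficients()].
#' @param constants [physics_constants()].
#' @param water,elements Reference material and element table.
#' @param hu_tol HU distance under which two nodes count as duplicates.
#' @return An object of class `calibration_curve` with a `nodes` data frame
#'   (columns `hu`, `rho`, `rsp`, `material`).
#' @export
build_calibration_curve <- function(tissues, coeffs,
                                    constants = physics_constants(),
                                    water = water_material(),
                                    elements = element_table(),
                                    hu_tol = 1e-6) {
  if (inherits(tissues, "ct_material")) tissues <- list(tissues)
  if (length(tissues) == 0) stop("tissue library is empty")
  nodes <- do.call(rbind, lapply(tissues, function(m) {
    data.frame(
      hu = predicted_hu(m, coeffs, water, elements),
      rho = m$rho,
      rsp = bethe_rsp(relative_electron_density(m, water, elements),
                      mean_excitation_energy(m, elements), constants),
      material = m$name, stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$hu, nodes$rho), , drop = FALSE]
  dup <- which(diff(nodes$hu) <= hu_tol)
  if (length(dup) > 0) {
    # ordered by (hu, rho): the later of a duplicate pair is the denser one
    warning("duplicate HU nodes; keeping the denser material for: ",
            paste(nodes$material[dup], collapse = ", "))
    nodes <- nodes[-dup, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  if (is.unsorted(nodes$rho)) {
    warning("calibration curve density nodes are not monotone in HU")
  }
  structure(list(nodes = nodes), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> with", nrow(x$nodes), "nodes\n")
  print(x$nodes, digits = 4)
  invisible(x)
}

#' Apply a calibration curve to CT numbers
#'
#' Piecewise-linear interpolation between nodes, flat extrapolation beyond
#' the end nodes; a single-node curve maps every HU to that node.  NaN/NA
#' inputs propagate (with a message reporting the count).  Works on bare
#' numeric vectors/arrays or on a [phantom_volume()] (in which case a
#' congruent array is returned).
#'
#' @param curve A `calibration_curve`.
#' @param hu Numeric vector/array of CT numbers, or a `phantom_volume`.
#' @param property `"rho"` (mass density) or `"rsp"`.
#' @return Mapped values with the shape of the input.
#' @export
apply_curve <- function(curve, hu, property = c("rho", "rsp")) {
  property <- match.arg(property)
  if (inherits(hu, "phantom_volume")) hu <- hu$hu
  dims <- dim(hu)
  v <- as.numeric(hu)
  bad <- !is.finite(v)
  if (any(bad)) message(sum(bad), " non-finite HU voxel(s) propagated as NA")
  nodes <- curve$nodes
  out <- rep(NA_real_, length(v))
  if (nrow(nodes) == 1) {
    out[!bad] <- nodes[[property]][1]
  } else {
    out[!bad] <- stats::approx(nodes$hu, nodes[[property]], xout = v[!bad],
                               method = "linear", rule = 2)$y
  }
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Export / import a calibration curve as CSV
#'
#' Column layout `hu, rho, rsp, material`, comparable with treatment
#' planning system curve exports.
#'
#' @param curve A `calibration_curve`.
#' @param path CSV path.
#' @return `write_calibration_curve` returns `path` invisibly;
#'   `read_calibration_curve` returns a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  utils::write.csv(curve$nodes, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("hu", "rho", "rsp") %in% names(nodes)))
  if (is.null(nodes$material)) nodes$material <- NA_character_
  if (is.unsorted(nodes$hu, strictly = TRUE)) {
    stop("curve HU nodes must be strictly increasing")
  }
  structure(list(nodes = nodes), class = "calibration_curve")
}
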