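#' Define a material by density and elemental composition
#'
#' A material is a named mixture with a mass density and elemental weight
#' fractions; optional reference values (RSP, relative electron density)
#' carry manufacturer/measured ground truth alongside the composition.
#'
#' @param name Material name.
#' @param rho Mass density in g/cm^3 (> 0).
#' @param composition Named numeric vector or list of elemental weight
#'   fractions (names are element symbols); must sum to 1 within 1e-6.
#' @param rsp_ref Optional reference RSP (dimensionless).
#' @param rho_e_ref Optional reference relative electron density.
#' @param group Optional grouping tag (e.g. phantom family).
#' @return An object of class `ct_material`.
#' @export
#' @examples
#' water <- ct_material("Water", 1.0, c(H = 0.111894, O = 0.888106))
ct_material <- function(name, rho, composition, rsp_ref = NA_real_,
                        rho_e_ref = NA_real_, group = NA_character_) {
  composition <- unlist(composition)
  stopifnot(is.numeric(rho), length(rho) == 1, is.numeric(composition))
  if (rho <= 0) stop("material '", name, "': rho must be > 0")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("material '", name, "': composition must be a named vector")
  }
  if (length(composition) == 0) stop("material '", name, "': empty composition")
  if (any(composition < 0) || any(composition > 1)) {
    stop("material '", name, "': weight fractions must lie in [0, 1]")
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("material '", name, "': weight fractions sum to ",
         format(sum(composition), digits = 10), ", not 1")
  }
  structure(
    list(name = name, rho = rho, composition = composition,
         rsp_ref = rsp_ref, rho_e_ref = rho_e_ref, group = group),
    class = "ct_material"
  )
}

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("<ct_material> %s: rho = %.3f g/cm3, %d elements (%s)\n",
              x$name, x$rho, length(x$composition),
              paste(names(x$composition), collapse = " ")))
  invisible(x)
}

# electron-fraction weights lambda_i = w_i * Z_i / A_i, checked against the
# element table; unknown symbols fail loudly.
.electron_weights <- function(material, elements = element_table()) {
  sym <- names(material$composition)
  missing <- setdiff(sym, elements$symbol)
  if (length(missing) > 0) {
    stop("material '", material$name, "': unknown element symbol(s): ",
         paste(missing, collapse = ", "))
  }
  e <- elements[sym, ]
  w <- material$composition
  data.frame(symbol = sym, Z = e$Z, A = e$A, I_eV = e$I_eV, w = as.numeric(w),
             lambda = as.numeric(w) * e$Z / e$A, row.names = NULL)
}

#' Relative electron density of a material
#'
#' Electron density relative to water:
#' \eqn{\hat\rho_{e,w} = \rho \sum_i w_i Z_i / A_i \;/\; (\rho_w \sum_i w_i Z_i / A_i)_{water}}.
#' Linear in the mass density at fixed composition.
#'
#' @param material A [ct_material()].
#' @param water The water reference material.
#' @param elements Element table (see [element_table()]).
#' @return Dimensionless ratio (> 0).
#' @export
relative_electron_density <- function(material, water = water_material(),
                                      elements = element_table()) {
  num <- material$rho * sum(.electron_weights(material, elements)$lambda)
  den <- water$rho * sum(.electron_weights(water, elements)$lambda)
  num / den
}

#' Mean excitation energy by the Bragg additivity rule
#'
#' Log-weighted mean over the elemental I-values with electron-fraction
#' weights \eqn{\lambda_i = w_i Z_i / A_i}:
#' \eqn{\ln I_m = \sum_i \lambda_i \ln I_i / \sum_i \lambda_i}.
#'
#' @inheritParams relative_electron_density
#' @return Mean excitation energy in eV; always between the smallest and
#'   largest elemental I in the mixture.
#' @export
mean_excitation_energy <- function(material, elements = element_table()) {
  ew <- .electron_weights(material, elements)
  exp(sum(ew$lambda * log(ew$I_eV)) / sum(ew$lambda))
}

#' Effective atomic number (electron-fraction power mean)
#'
#' \eqn{\hat Z = (\sum_i \lambda_i Z_i^p / \sum_i \lambda_i)^{1/p}} with
#' electron-fraction weights.  The parametric attenuation model uses its own
#' exponent for each interaction term (1.86 for coherent scatter, 3.62 for
#' the photoelectric effect); DECT consoles conventionally report
#' Zeff at an exponent near 3.1.
#'
#' @inheritParams relative_electron_density
#' @param exponent Power-mean exponent p (> 0).
#' @return Dimensionless effective atomic number, bounded by the smallest
#'   and largest Z in the composition.
#' @export
effective_atomic_number <- function(material, exponent,
                                    elements = element_table()) {
  stopifnot(is.numeric(exponent), length(exponent) == 1)
  if (exponent <= 0) stop("exponent must be > 0")
  ew <- .electron_weights(material, elements)
  (sum(ew$lambda * ew$Z^exponent) / sum(ew$lambda))^(1 / exponent)
}

#' Read a material library from YAML
#'
#' The YAML format stores one entry per material with `name`, `rho`,
#' `composition` (symbol: weight fraction) and optional `rsp_ref`,
#' `rho_e_ref`, `group`.  The shipped library carries the CIRS 062M (9),
#' Gammex 467 (7) and ATOM torso (6) surrogates with manufacturer densities
#' and reference RSP values, plus water; its compositions are approximate
#' (the vendors do not publish them).
#'
#' @param path YAML file; defaults to the shipped library.
#' @return Named list of [ct_material()] objects (class `material_library`).
#' @export
#' @examples
#' lib <- read_material_library()
#' names(lib)
read_material_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.yaml", package = "sectmap")
  }
  doc <- yaml::read_yaml(path)
  mats <- lapply(doc$materials, function(m) {
    ct_material(m$name, m$rho, m$composition,
                rsp_ref = if (is.null(m$rsp_ref)) NA_real_ else m$rsp_ref,
                rho_e_ref = if (is.null(m$rho_e_ref)) NA_real_ else m$rho_e_ref,
                group = if (is.null(m$group)) NA_character_ else m$group)
  })
  names(mats) <- vapply(mats, `[[`, character(1), "name")
  structure(mats, class = "material_library")
}

#' Write a material library to YAML
#'
#' @param library A `material_library` (named list of [ct_material()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_material_library <- function(library, path) {
  doc <- list(version = 1, materials = lapply(unname(library), function(m) {
    out <- list(name = m$name, group = m$group, rho = m$rho,
                rsp_ref = m$rsp_ref, rho_e_ref = m$rho_e_ref,
                composition = as.list(m$composition))
    out[!vapply(out, function(v) length(v) == 1 && is.na(v), logical(1))]
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Subset a material library by group
#'
#' @param library A `material_library`.
#' @param groups Character vector of group tags to keep.
#' @return A `material_library` with the matching materials.
#' @export
filter_material_library <- function(library, groups) {
  keep <- vapply(library, function(m) isTRUE(m$group %in% groups), logical(1))
  structure(library[keep], class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat("<material_library> with", length(x), "materials\n")
  for (m in x) {
    cat(sprintf("  %-22s rho %.3f  RSP %s  [%s]\n", m$name, m$rho,
                ifelse(is.na(m$rsp_ref), "-", sprintf("%.3f", m$rsp_ref)),
                m$group))
  }
  invisible(x)
}

#' The water reference material
#'
#' @param rho Density of water in g/cm^3.
#' @return A [ct_material()] for water.
#' @export
water_material <- function(rho = 1.0) {
  ct_material("Water", rho, c(H = 0.111894, O = 0.888106),
              rsp_ref = 1.0, rho_e_ref = 1.0, group = "reference")
}
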