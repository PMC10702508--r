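#' @keywords internal
.sectmap_env <- new.env(parent = emptyenv())

#' Elemental reference data
#'
#' Atomic number, standard atomic weight (g/mol) and mean excitation energy
#' I (eV, ICRU-style values) for the elements occurring in tissue surrogates.
#' Shipped as a versioned CSV under `extdata` so it can be inspected or
#' replaced.
#'
#' @param path Optional path to an alternative element table (CSV with
#'   columns `symbol`, `Z`, `A`, `I_eV`).
#' @return A data frame with one row per element.
#' @export
#' @examples
#' head(element_table())
element_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sectmap_env$elements)) return(.sectmap_env$elements)
    path <- system.file("extdata", "elements.csv", package = "sectmap")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "Z", "A", "I_eV") %in% names(tab)))
  if (any(tab$Z < 1) || any(tab$A <= 0) || any(tab$I_eV <= 0)) {
    stop("invalid element table: require Z >= 1, A > 0, I > 0")
  }
  rownames(tab) <- tab$symbol
  .sectmap_env$elements <- tab
  tab
}

#' Physics constants for the Bethe stopping-power ratio
#'
#' Bundles the constants entering the stopping-power ratio: the mean
#' excitation energy of water (75 eV as recommended by ICRU 49), the electron
#' rest energy, and the proton kinetic energy used to evaluate beta.  The
#' proton energy is a modelling choice (a therapeutic mid-range 100 MeV by
#' default); the resulting RSP is only weakly energy dependent.
#'
#' @param I_water Mean excitation energy of water in eV.
#' @param proton_kinetic_energy Proton kinetic energy in MeV.
#' @param m_e_c2 Electron rest energy in MeV.
#' @param m_p_c2 Proton rest energy in MeV.
#' @return An object of class `physics_constants` with the inputs plus the
#'   derived relativistic `beta2` (= v^2/c^2).
#' @export
#' @examples
#' physics_constants()
physics_constants <- function(I_water = 75,
                              proton_kinetic_energy = 100,
                              m_e_c2 = 0.51099895,
                              m_p_c2 = 938.27208816) {
  stopifnot(I_water > 0, proton_kinetic_energy > 0, m_e_c2 > 0, m_p_c2 > 0)
  gamma <- 1 + proton_kinetic_energy / m_p_c2
  beta2 <- 1 - 1 / gamma^2
  structure(
    list(I_water = I_water,
         proton_kinetic_energy = proton_kinetic_energy,
         m_e_c2 = m_e_c2,
         m_p_c2 = m_p_c2,
         beta2 = beta2),
    class = "physics_constants"
  )
}

#' @export
print.physics_constants <- function(x, ...) {
  cat("Physics constants: I_water =", x$I_water, "eV, T_p =",
      x$proton_kinetic_energy, "MeV (beta^2 =", signif(x$beta2, 6), ")\n")
  invisible(x)
}
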