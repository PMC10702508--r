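#' DECT empirical mass-density model
#'
#' Affine map from relative electron density to mass density,
#' \eqn{\rho = -0.1746 + 1.176\,\rho_e}, with a fixed constant of
#' 0.26 g/cm^3 for voxels flagged as inflated lung.  The relative electron
#' density is taken as given (e.g. from a DECT scanner console); the model
#' does not apply to normal (non-inflated) lung tissue and such voxels are
#' conventionally excluded from evaluation.
#'
#' @param rho_e Relative electron density (vector/array, >= 0).
#' @param inflated_lung Logical scalar or vector/array congruent with
#'   `rho_e`; flagged voxels get the fixed lung constant.
#' @return Mass density in g/cm^3 with the shape of `rho_e`.
#' @export
#' @examples
#' empirical_density(1.0)                     # ~ water
#' empirical_density(0.2, inflated_lung = TRUE)
empirical_density <- function(rho_e, inflated_lung = FALSE) {
  stopifnot(all(rho_e >= 0, na.rm = TRUE))
  out <- -0.1746 + 1.176 * rho_e
  if (any(inflated_lung)) {
    if (length(inflated_lung) == 1) {
      out[] <- 0.26
    } else {
      stopifnot(length(inflated_lung) == length(rho_e))
      out[inflated_lung] <- 0.26
    }
  }
  out
}

#' DECT empirical RSP model
#'
#' Piecewise model in effective atomic number, homogeneous of degree 1 in
#' the relative electron density within each branch:
#' \deqn{RSP = \rho_e \quad (0 \le Z_{eff} < 0.5)}
#' \deqn{RSP = (1.1114 - 0.0148\,Z_{eff})\,\rho_e \quad (0.5 \le Z_{eff} < 8.5)}
#' \deqn{RSP = 0.9905\,\rho_e \quad (8.5 \le Z_{eff} < 10)}
#' \deqn{RSP = (1.1117 - 0.0116\,Z_{eff})\,\rho_e \quad (Z_{eff} \ge 10)}
#' Branch boundaries are left-closed/right-open.  The first branch
#' (Zeff below 0.5) is physically odd -- no element has an effective atomic
#' number below 1 -- but is implemented exactly as the model is defined.
#'
#' @param rho_e Relative electron density (vector/array, >= 0).
#' @param z_eff Effective atomic number, congruent with `rho_e` (>= 0).
#' @return RSP with the shape of `rho_e`.
#' @export
#' @examples
#' empirical_rsp(1.0, 7.45)   # soft-tissue branch
empirical_rsp <- function(rho_e, z_eff) {
  stopifnot(all(rho_e >= 0, na.rm = TRUE), all(z_eff >= 0, na.rm = TRUE))
  if (length(z_eff) == 1) z_eff <- rep(z_eff, length(rho_e))
  stopifnot(length(z_eff) == length(rho_e))
  factor <- ifelse(z_eff < 0.5, 1,
            ifelse(z_eff < 8.5, 1.1114 - 0.0148 * z_eff,
            ifelse(z_eff < 10, 0.9905,
                   1.1117 - 0.0116 * z_eff)))
  out <- factor * rho_e
  dim(out) <- dim(rho_e)
  out
}
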