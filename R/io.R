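#' Read a CT volume (NIfTI file or DICOM series directory)
#'
#' Returns a [phantom_volume()] with HU values, voxel spacing, an all-zero
#' label grid and an empty truth table.  Voxel indices are 0-based in world
#' terms: x is the fastest-varying array axis, axial slices run along z.
#' DICOM rescale slope/intercept are applied by the reader.
#'
#' @param path `.nii` file or directory of `.dcm` files.
#' @return A `phantom_volume` (HU only, no labels).
#' @export
read_ct <- function(path) {
  if (dir.exists(path)) {
    r <- read_dicom_series(path)
    hu <- r$hu
    sp <- r$spacing_mm
  } else if (grepl("\\.nii$", path)) {
    r <- read_nifti(path)
    hu <- r$data
    sp <- r$spacing_mm
  } else {
    stop("unsupported CT input: ", path,
         " (expect a .nii file or a DICOM series directory)")
  }
  phantom_volume(hu, array(0L, dim = dim(hu)), sp, .empty_truth())
}

.empty_truth <- function() {
  data.frame(label = integer(0), material = character(0), rho = numeric(0),
             rsp = numeric(0), rho_e = numeric(0), zeff = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read an integer label volume
#'
#' Labels arrive as a NIfTI integer volume congruent with the CT grid
#' (contours rasterized elsewhere); a grid mismatch is an error, never a
#' silent resample.
#'
#' @param path `.nii` file of integer labels.
#' @param ct Optional `phantom_volume` to check congruence against.
#' @return Integer array with attribute `inventory` (table of nonzero
#'   labels and voxel counts).
#' @export
read_labels <- function(path, ct = NULL) {
  r <- read_nifti(path)
  lab <- r$data
  if (any(lab != round(lab))) stop("label volume is not integer-valued: ", path)
  lab <- array(as.integer(lab), dim = dim(lab))
  if (!is.null(ct)) {
    if (!identical(dim(lab), dim(ct$hu))) {
      stop("label grid ", paste(dim(lab), collapse = "x"),
           " does not match CT grid ", paste(dim(ct$hu), collapse = "x"))
    }
    if (max(abs(r$spacing_mm - ct$spacing_mm)) > 1e-6) {
      stop("label spacing (", paste(r$spacing_mm, collapse = ", "),
           ") does not match CT spacing (",
           paste(ct$spacing_mm, collapse = ", "), ")")
    }
  }
  nz <- lab[lab != 0L]
  inv <- table(nz)
  attr(lab, "inventory") <- data.frame(label = as.integer(names(inv)),
                                       n_voxels = as.integer(inv))
  lab
}

#' Write / load a phantom volume as NIfTI + CSV
#'
#' Writes `hu.nii` (float64), `labels.nii` (int32) and `truth.csv` into a
#' directory; `load_phantom_volume` reverses it.
#'
#' @param volume A `phantom_volume`.
#' @param dir Output directory.
#' @return `write_phantom_volume` returns `dir` invisibly;
#'   `load_phantom_volume` returns the `phantom_volume`.
#' @export
write_phantom_volume <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(volume$hu, file.path(dir, "hu.nii"), volume$spacing_mm)
  write_nifti(volume$labels, file.path(dir, "labels.nii"), volume$spacing_mm)
  utils::write.csv(volume$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_phantom_volume
#' @export
load_phantom_volume <- function(dir) {
  hu <- read_nifti(file.path(dir, "hu.nii"))
  lab <- read_nifti(file.path(dir, "labels.nii"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  phantom_volume(hu$data, array(as.integer(lab$data), dim = dim(lab$data)),
                 hu$spacing_mm, truth)
}

# stable short hash of a configuration list (order-sensitive, text-based)
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 512))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# structured run log: config hash, seeds, versions
.write_run_log <- function(path, config, seed, extra = list()) {
  lines <- c(
    sprintf("sectmap run log"),
    sprintf("r_version: %s", R.version.string),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("sectmap"))),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", .config_hash(config)),
    vapply(names(extra), function(k) sprintf("%s: %s", k, extra[[k]]),
           character(1)))
  writeLines(lines, path)
  invisible(path)
}
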