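#' Noise model for simulated SECT volumes
#'
#' Additive zero-mean Gaussian voxel noise (standard deviation in HU) plus
#' an optional smooth multiplicative bias field (a low-order random cosine
#' field) emulating cupping/shading artifacts.  Amplitude 0 disables the
#' bias field.
#'
#' @param sigma_hu Voxel noise standard deviation in HU (>= 0).
#' @param bias_amplitude Relative amplitude of the multiplicative bias field
#'   (0 disables).
#' @param bias_scale_mm Spatial length scale of the bias field in mm.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_hu = 15, bias_amplitude = 0,
                        bias_scale_mm = 60, seed = 1L) {
  stopifnot(sigma_hu >= 0, bias_amplitude >= 0, bias_scale_mm > 0)
  structure(list(sigma_hu = sigma_hu, bias_amplitude = bias_amplitude,
                 bias_scale_mm = bias_scale_mm, seed = as.integer(seed)),
            class = "noise_model")
}

#' Phantom layouts
#'
#' Cylinder-and-insert cartoons of the physical phantoms, in mm coordinates
#' centered on the grid:
#' \describe{
#'   \item{EDP_062M}{electron-density phantom: water-equivalent disc body
#'     with the nine CIRS 062M tissue surrogates in a ring.}
#'   \item{GAMMEX_467}{disc body with the seven Gammex 467 surrogates.}
#'   \item{TORSO_M701 / TORSO_M702}{elliptical soft-tissue body with lung,
#'     bone, spinal cord, brain-surrogate and breast regions — simplified
#'     emulations of the anthropomorphic phantoms, not geometric replicas.
#'     M702 has a slightly smaller body and larger breast inserts.}
#'   \item{CUSTOM}{body and inserts supplied via `overrides`.}
#' }
#' The default grid is 128 x 128 in-plane at 1 mm with 8 axial slices
#' (identical slices: all downstream methods are voxel-wise).
#'
#' @param template Layout template name.
#' @param overrides Named list overriding `grid`, `body` or `inserts`.
#' @return An object of class `phantom_layout` with `name`, `body`
#'   (ellipse `semi_mm`, `material`), `inserts` (data frame with `material`,
#'   `x_mm`, `y_mm`, `radius_mm`) and `grid` (`n`, `spacing_mm`).
#' @export
#' @examples
#' make_layout("EDP_062M")
make_layout <- function(template = c("EDP_062M", "GAMMEX_467", "TORSO_M701",
                                     "TORSO_M702", "CUSTOM"),
                        overrides = list()) {
  template <- match.arg(template)
  grid <- list(n = c(128L, 128L, 8L), spacing_mm = c(1, 1, 1))
  ring <- function(materials, r_ring, r_insert) {
    ang <- 2 * pi * (seq_along(materials) - 1) / length(materials)
    data.frame(material = materials,
               x_mm = r_ring * cos(ang), y_mm = r_ring * sin(ang),
               radius_mm = r_insert, stringsAsFactors = FALSE)
  }
  lay <- switch(template,
    EDP_062M = list(
      body = list(semi_mm = c(60, 60), material = "Water"),
      inserts = ring(c("Lung (Inhale)", "Lung (Exhale)", "Adipose",
                       "Breast Tissue", "Muscle", "Liver", "Bone 200 mg/cc",
                       "Bone 800 mg/cc", "Bone 1250 mg/cc"), 42, 13)),
    GAMMEX_467 = list(
      body = list(semi_mm = c(60, 60), material = "Water"),
      inserts = ring(c("LN450 Lung", "Breast", "Brain", "Liver LV1",
                       "B200 Bone Mineral", "CB2-50% CaCO3 Bone",
                       "SB3 Cortical Bone"), 40, 13)),
    TORSO_M701 = list(
      body = list(semi_mm = c(60, 44), material = "Torso Soft Tissue"),
      inserts = data.frame(
        material = c("Torso Lung", "Torso Lung", "Torso Bone",
                     "Torso Spinal Cord", "Torso Brain", "Torso Breast",
                     "Torso Soft Tissue"),
        x_mm = c(-28, 28, 0, 0, 0, -38, 38),
        y_mm = c(8, 8, -30, -16, 16, -18, -18),
        radius_mm = c(16, 16, 8, 3, 12, 9, 10),
        stringsAsFactors = FALSE)),
    TORSO_M702 = list(
      body = list(semi_mm = c(56, 40), material = "Torso Soft Tissue"),
      inserts = data.frame(
        material = c("Torso Lung", "Torso Lung", "Torso Bone",
                     "Torso Spinal Cord", "Torso Brain", "Torso Breast",
                     "Torso Breast"),
        x_mm = c(-25, 25, 0, 0, 0, -34, 34),
        y_mm = c(7, 7, -26, -14, 14, -16, -16),
        radius_mm = c(14, 14, 7, 3, 11, 10, 10),
        stringsAsFactors = FALSE)),
    CUSTOM = list(
      body = list(semi_mm = c(60, 60), material = "Water"),
      inserts = data.frame(material = character(0), x_mm = numeric(0),
                           y_mm = numeric(0), radius_mm = numeric(0),
                           stringsAsFactors = FALSE))
  )
  lay$name <- template
  lay$grid <- grid
  for (nm in names(overrides)) lay[[nm]] <- overrides[[nm]]
  lay <- structure(lay, class = "phantom_layout")
  .validate_layout(lay)
  lay
}

.validate_layout <- function(lay) {
  ins <- lay$inserts
  if (nrow(ins) == 0) return(invisible(lay))
  # insert disc inside the body ellipse: conservative shrunken-ellipse test
  a <- lay$body$semi_mm[1]; b <- lay$body$semi_mm[2]
  ok_in <- ins$radius_mm < pmin(a, b) &
    (ins$x_mm / (a - ins$radius_mm))^2 +
    (ins$y_mm / (b - ins$radius_mm))^2 <= 1 + 1e-9
  if (!all(ok_in)) {
    stop("layout error: insert(s) outside the body: ",
         paste(ins$material[!ok_in], collapse = ", "))
  }
  if (nrow(ins) > 1) {
    dmat <- as.matrix(stats::dist(ins[, c("x_mm", "y_mm")]))
    rsum <- outer(ins$radius_mm, ins$radius_mm, "+")
    diag(dmat) <- Inf
    if (any(dmat < rsum)) stop("layout error: overlapping inserts")
  }
  invisible(lay)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %s: %dx%dx%d grid, body %s, %d inserts\n",
              x$name, x$grid$n[1], x$grid$n[2], x$grid$n[3],
              x$body$material, nrow(x$inserts)))
  invisible(x)
}

#' Construct a phantom volume container
#'
#' @param hu 3D numeric array of CT numbers.
#' @param labels 3D integer array congruent with `hu` (0 = unlabeled).
#' @param spacing_mm Voxel spacing (length 3).
#' @param truth Data frame with one row per nonzero label: `label`,
#'   `material`, `rho`, `rsp`, `rho_e`, `zeff`.
#' @return An object of class `phantom_volume`.
#' @export
phantom_volume <- function(hu, labels, spacing_mm, truth) {
  stopifnot(identical(dim(hu), dim(labels)), length(spacing_mm) == 3)
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing <- setdiff(present, truth$label)
  if (length(missing) > 0) {
    stop("labels without truth entries: ", paste(missing, collapse = ", "))
  }
  structure(list(hu = hu, labels = labels,
                 spacing_mm = as.numeric(spacing_mm), truth = truth),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<phantom_volume> %dx%dx%d @ %s mm, %d labeled regions\n",
              d[1], d[2], d[3], paste(x$spacing_mm, collapse = "x"),
              nrow(x$truth)))
  invisible(x)
}

#' Render a layout into a simulated SECT volume
#'
#' Each voxel is assigned by center-point membership (innermost insert wins;
#' no partial-volume mixing); its noiseless HU is the forward-model
#' prediction for the material at the given spectrum coefficients.  Voxels
#' outside the body are air at -1000 HU (label 0).  Gaussian voxel noise and
#' the optional multiplicative bias field are then applied, seeded by the
#' noise model.  The truth table carries each label's library mass density,
#' reference RSP, relative electron density and effective atomic number
#' (exponent 3.1, the DECT-console convention).
#'
#' @param layout A [make_layout()] result.
#' @param materials A `material_library` containing every layout material.
#' @param coeffs [spectrum_coefficients()] of the simulated scanner.
#' @param noise A [noise_model()].
#' @param constants [physics_constants()].
#' @return A [phantom_volume()]; the body region is label 1, inserts are
#'   labels 2, 3, ... in layout order.
#' @export
render_phantom <- function(layout, materials = read_material_library(),
                           coeffs, noise = noise_model(),
                           constants = physics_constants()) {
  stopifnot(inherits(layout, "phantom_layout"))
  mat_names <- unique(c(layout$body$material, layout$inserts$material))
  missing <- setdiff(mat_names, names(materials))
  if (length(missing) > 0) {
    stop("layout materials missing from the library: ",
         paste(missing, collapse = ", "))
  }
  n <- layout$grid$n
  sp <- layout$grid$spacing_mm
  x <- (seq_len(n[1]) - (n[1] + 1) / 2) * sp[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2) * sp[2]
  X <- matrix(x, n[1], n[2])
  Y <- matrix(y, n[1], n[2], byrow = TRUE)

  lab2d <- matrix(0L, n[1], n[2])
  inbody <- (X / layout$body$semi_mm[1])^2 + (Y / layout$body$semi_mm[2])^2 <= 1
  lab2d[inbody] <- 1L
  ins <- layout$inserts
  for (i in seq_len(nrow(ins))) {
    inside <- (X - ins$x_mm[i])^2 + (Y - ins$y_mm[i])^2 <= ins$radius_mm[i]^2
    lab2d[inside] <- i + 1L
  }

  label_mats <- c(layout$body$material, ins$material)
  hu_mat <- vapply(label_mats, function(nm) {
    predicted_hu(materials[[nm]], coeffs, elements = element_table())
  }, numeric(1))
  hu2d <- matrix(-1000, n[1], n[2])
  sel <- lab2d > 0L
  hu2d[sel] <- hu_mat[lab2d[sel]]

  labels <- array(rep(lab2d, n[3]), dim = n)
  hu <- array(rep(hu2d, n[3]), dim = n)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  if (noise$bias_amplitude > 0) {
    hu <- hu * .bias_field(x, y, n, noise)
  }
  if (noise$sigma_hu > 0) {
    hu <- hu + array(stats::rnorm(prod(n), 0, noise$sigma_hu), dim = n)
  }

  truth <- do.call(rbind, lapply(seq_along(label_mats), function(i) {
    m <- materials[[label_mats[i]]]
    data.frame(label = i, material = m$name, rho = m$rho,
               rsp = m$rsp_ref,
               rho_e = relative_electron_density(m),
               zeff = effective_atomic_number(m, 3.1),
               stringsAsFactors = FALSE)
  }))
  phantom_volume(hu, labels, sp, truth)
}

# smooth multiplicative bias field: sum of a few low-frequency cosines
.bias_field <- function(x, y, n, noise) {
  k <- 2 * pi / noise$bias_scale_mm
  f2d <- matrix(0, n[1], n[2])
  for (i in 1:3) {
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    f2d <- f2d + cos(k * (outer(x, rep(1, n[2])) * cos(th) +
                            outer(rep(1, n[1]), y) * sin(th)) + ph)
  }
  f2d <- 1 + noise$bias_amplitude * f2d / 3
  array(rep(f2d, n[3]), dim = n)
}

#' Partition rendered volumes into training and test sets
#'
#' @param volumes Named list of `phantom_volume`s (names identify their
#'   layouts, e.g. `"EDP_062M"`, `"TORSO_M701"`).
#' @param scheme `"study"` (the train-on-electron-density-phantom, test-on-torso study design) sends volumes
#'   (names starting `EDP`/`GAMMEX`) to training and torso volumes to test;
#'   `"self"` uses the single given volume on both sides (with a warning);
#'   `"random"` splits at random under `seed` with at least one volume per
#'   side.
#' @param seed Seed for the random scheme.
#' @return List with elements `train` and `test` (named lists of volumes).
#' @export
split_train_test <- function(volumes, scheme = c("study", "self", "random"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(volumes) >= 1, !is.null(names(volumes)))
  if (scheme == "self") {
    if (length(volumes) != 1) stop("scheme 'self' expects a single volume")
    warning("scheme 'self': the same volume is used for training and test")
    return(list(train = volumes, test = volumes))
  }
  if (scheme == "study") {
    is_train <- grepl("^(EDP|GAMMEX)", names(volumes))
    if (!any(is_train) || all(is_train)) {
      stop("study split needs at least one EDP/GAMMEX volume and one other")
    }
    return(list(train = volumes[is_train], test = volumes[!is_train]))
  }
  if (length(volumes) < 2) stop("random split needs at least 2 volumes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_train <- sample(seq_len(length(volumes) - 1L), 1)
  tr <- sample(names(volumes), n_train)
  list(train = volumes[tr], test = volumes[setdiff(names(volumes), tr)])
}
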