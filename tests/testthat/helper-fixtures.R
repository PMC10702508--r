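# Shared fixtures: tiny materials and toy volumes built in code.

fix_water <- function() water_material()

# water composition at a different density (water-like Zeff)
fix_scaled_water <- function(rho) {
  ct_material(paste0("Water x", rho), rho, c(H = 0.111894, O = 0.888106))
}

fix_bonelike <- function() {
  ct_material("BoneLike", 1.52,
              c(H = 0.0490, C = 0.4030, N = 0.0150, O = 0.3210,
                P = 0.0450, Cl = 0.0010, Ca = 0.1660))
}

# a small labeled volume with constant HU per label
fix_toy_volume <- function(nx = 6, ny = 5, nz = 2,
                           hu_by_label = c(`1` = 0, `2` = 500),
                           truth = data.frame(label = 1:2,
                                              material = c("a", "b"),
                                              rho = c(1, 1.5),
                                              rsp = c(1, 1.4),
                                              rho_e = c(1, 1.45),
                                              zeff = c(7.45, 12))) {
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[2:3, 2:3, ] <- 1L
  labels[5:6, 2:3, ] <- 2L
  hu <- array(NA_real_, dim = c(nx, ny, nz))
  hu[labels == 0L] <- -1000
  for (lb in names(hu_by_label)) {
    hu[labels == as.integer(lb)] <- hu_by_label[[lb]]
  }
  phantom_volume(hu, labels, c(1, 1, 1), truth)
}

# random compositions over a fixed element set (normalized weight fractions)
fix_random_material <- function(rho = 1, n_elem = 4) {
  syms <- sample(c("H", "C", "N", "O", "P", "Cl", "Ca", "Mg"), n_elem)
  w <- stats::runif(n_elem)
  w <- w / sum(w)
  ct_material("rand", rho, stats::setNames(w, syms))
}
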