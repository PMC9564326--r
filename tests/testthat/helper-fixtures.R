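# Shared fixtures for the test suite. Everything is generated in code;
# no binary fixtures are stored.

# parameter table for a set of identical pseudo-ions
ion_params <- function(n, charge = 1, gb_radius = 2.0, eps_int = 3.0,
                       eps_solv = 78.5) {
  tab <- data.frame(resname = "ION", name = paste0("I", seq_len(n)),
                    charge = charge, rmin_half = 1.7, epsilon = 0.1,
                    mass = 23, gb_radius = gb_radius,
                    stringsAsFactors = FALSE)
  ff_params(tab, eps_int = eps_int, eps_solv = eps_solv)
}

ion_topology <- function(n) {
  topology(data.frame(serial = seq_len(n), name = paste0("I", seq_len(n)),
                      element = "NA", resno = seq_len(n), resname = "ION",
                      stringsAsFactors = FALSE),
           groups = list(all = seq_len(n)))
}

# ideal chair ring coordinates: hexagon with alternating +/- z.
# Wound clockwise viewed from +z so the Cremer-Pople normal
# (R' x R'') points along +z, as for a Haworth-drawn beta-D-pyranose;
# z = (+,-,+,-,+,-) over (O5, C1, ..., C5) is then the 4C1 chair.
chair_ring <- function(z0 = 0.25, r = 1.45, flip = FALSE) {
  j <- 0:5
  z <- z0 * (-1)^j
  if (flip) z <- -z
  cbind(r * cos(-2 * pi * j / 6), r * sin(-2 * pi * j / 6), z)
}

# toy chi registry with two analytic curves
toy_chi_registry <- function() {
  grid <- seq(-180, 170, by = 10)
  gphi <- data.frame(angle = grid, energy = 1 - cos((grid - 60) * pi / 180))
  gpsi <- data.frame(angle = grid, energy = 2 - 2 * cos(grid * pi / 180))
  chi_registry("b1-4" = list(phi = gphi, psi = gpsi),
               "a1-3" = list(phi = gphi, psi = gpsi))
}
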