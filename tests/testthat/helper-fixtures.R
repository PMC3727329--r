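# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk.

# ideal straight-helix bead chain: consecutive Ca spacing exactly `bond`,
# Cb directions radially outward
helix_chain <- function(n, id = "A", bond = 3.8, rho = 2.3,
                        resid = rep("ALA", n)) {
  rise <- 1.5
  chord_xy <- sqrt(bond^2 - rise^2)
  dphi <- 2 * asin(chord_xy / (2 * rho))
  k <- seq_len(n) - 1
  xyz <- cbind(rho * cos(k * dphi), rho * sin(k * dphi), rise * k)
  cb <- cbind(cos(k * dphi), sin(k * dphi), 0)
  cb[resid == "GLY", ] <- NA_real_
  bead_chain(xyz, cb = cb, resno = seq_len(n), resid = resid, id = id)
}

# a straight rod chain along +z with Cb pointing +x
rod_chain <- function(n, id = "A", origin = c(0, 0, 0), bond = 3.8,
                      resid = rep("ALA", n)) {
  xyz <- cbind(origin[1], origin[2], origin[3] + bond * (seq_len(n) - 1))
  cb <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  cb[resid == "GLY", ] <- NA_real_
  bead_chain(xyz, cb = cb, resno = seq_len(n), resid = resid, id = id)
}

# random rotation matrix (proper) from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# minimal PDB text: one serine with 3 atoms
pdb_line <- function(serial, elety, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ") {
  elename <- substr(trimws(elety), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", elety), alt, resid, chain, resno,
          x, y, z, occ, 0, elename)
}

tiny_pdb_text <- function() {
  paste(c(
    pdb_line(1, "N",  "SER", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", "SER", "A", 1, 1.458, 0.0, 0.0),
    pdb_line(3, "CB", "SER", "A", 1, 2.0, 1.4, 0.0),
    "END"
  ), collapse = "\n")
}

# brute-force clash oracle: direct O(n^2) double loop in R
clash_oracle <- function(xyz, chain, idx, cutoff = 5, s_min = 4,
                         count_mode = FALSE) {
  n <- nrow(xyz)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (chain[i] == chain[j] && abs(idx[i] - idx[j]) <= s_min) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < cutoff) e <- e + if (count_mode) 1 else (cutoff - d)
    }
  }
  e
}

# small two-chain conformation with label sites on both chains, used by
# sampler tests: two parallel rods 30 Angstrom apart
two_rod_conformation <- function(n = 12, sep = 30) {
  a <- rod_chain(n, id = "A")
  b <- rod_chain(n, id = "B", origin = c(sep, 0, 0))
  sites <- list(label_site("A", 6), label_site("B", 6))
  conformation(list(a, b), sites)
}

# Gaussian distance distribution on a grid
gaussian_dd <- function(r0, width = 2, r_grid = default_r_grid()) {
  distance_distribution(r_grid, exp(-(r_grid - r0)^2 / (2 * width^2)))
}
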