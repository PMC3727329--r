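test_that("label placement is periodic and keeps the tether geometry", {
  ch <- helix_chain(6)
  site <- label_site("A", 3)
  p0 <- place_label(ch, site, 0)
  p2pi <- place_label(ch, site, 2 * pi)
  expect_equal(p0, p2pi, tolerance = 1e-12)
  # |label - Ca| is constant over psi: law of cosines with the 1.53
  # Angstrom pseudo-Cb offset, tether L and cone half-angle theta_c
  L <- site$L; th <- site$theta_c * pi / 180
  expected <- sqrt(1.53^2 + L^2 + 2 * 1.53 * L * cos(th))
  for (psi in seq(0, 2 * pi, length.out = 17)) {
    d <- sqrt(sum((place_label(ch, site, psi) - ch$xyz[3, ])^2))
    expect_equal(d, expected, tolerance = 1e-9)
  }
})

test_that("label placement is rigid-body equivariant", {
  ch <- helix_chain(6)
  site <- label_site("A", 3)
  R <- random_rotation(17); shift <- c(4, -7, 2)
  chr <- bead_chain(ch$xyz %*% t(R) + matrix(shift, 6, 3, byrow = TRUE),
                    cb = ch$cb %*% t(R), resno = ch$resno,
                    resid = ch$resid, id = "A", check = FALSE)
  for (psi in c(0, 1.1, 4.4)) {
    p <- place_label(ch, site, psi)
    pr <- place_label(chr, site, psi)
    expect_equal(pr, as.numeric(R %*% p + shift), tolerance = 1e-9)
  }
})

test_that("glycine sites cannot carry a label", {
  ch <- helix_chain(4, resid = c("ALA", "GLY", "ALA", "ALA"))
  expect_error(place_label(ch, label_site("A", 2), 0), "glycine|C-beta")
})

test_that("rotamer sampling: free site gives a uniform circle", {
  ch <- rod_chain(1)
  cloud <- sample_rotamers(ch, label_site("A", 1), n = 36)
  expect_equal(nrow(cloud$positions), 36L)
  expect_equal(cloud$weights, rep(1 / 36, 36))
  # all points equidistant from the pseudo-Cb: a circle
  pcb <- pseudo_cbeta(ch, list(resno = 1))
  d <- sqrt(rowSums(sweep(cloud$positions, 2, pcb)^2))
  expect_equal(d, rep(6, 36), tolerance = 1e-9)
})

test_that("rotamer sampling matches a brute-force clash oracle", {
  ch <- rod_chain(6)
  site <- label_site("A", 3)
  # blocking bead on one side of the label circle, on a separate chain
  ref <- place_label(ch, site, 0)
  blocker <- bead_chain(matrix(ref + c(0.5, 0, 0), 1, 3), id = "X",
                        check = FALSE)
  cloud <- sample_rotamers(list(ch, blocker), site, n = 72)
  # oracle: re-derive the surviving set point by point
  psi <- 2 * pi * (0:71) / 72
  ok <- vapply(psi, function(p) {
    pos <- place_label(ch, site, p)
    all(sqrt(sum((pos - (ref + c(0.5, 0, 0)))^2)) >= site$exclusion)
  }, logical(1))
  expect_equal(nrow(cloud$positions), sum(ok))
  expect_lt(nrow(cloud$positions), 72L)   # the blocker removes an arc
})

test_that("fully buried sites are reported as an error", {
  ch <- rod_chain(3)
  # cage of blockers all around the label circle of residue 2
  site <- label_site("A", 2)
  circle <- t(vapply(2 * pi * (0:11) / 12,
                     function(p) place_label(ch, site, p), numeric(3)))
  cage <- bead_chain(circle, id = "X", check = FALSE)
  expect_error(sample_rotamers(list(ch, cage), site, n = 24), "buried")
})

test_that("pair distance distribution: delta case and brute-force mean", {
  g <- default_r_grid()
  one_point <- function(x, site) {
    structure(list(positions = matrix(x, 1, 3), weights = 1, site = site),
              class = "label_cloud")
  }
  ca <- one_point(c(0, 0, 0), label_site("A", 1))
  cb <- one_point(c(20, 0, 0), label_site("B", 1))
  dd <- pair_distance_distribution(ca, cb, g)
  expect_equal(dist_mode(dd), 20)
  expect_equal(sum(dd$p > 0), 1L)          # single delta bin
  expect_equal(sum(dd$p) * dd$dr, 1, tolerance = 1e-12)

  # weighted mean against a direct double loop
  set.seed(23)
  mk_cloud <- function(center, m, site) {
    pos <- matrix(stats::rnorm(3 * m, sd = 2), m, 3) +
      matrix(center, m, 3, byrow = TRUE)
    w <- stats::runif(m); w <- w / sum(w)
    structure(list(positions = pos, weights = w, site = site),
              class = "label_cloud")
  }
  c1 <- mk_cloud(c(0, 0, 0), 15, label_site("A", 1))
  c2 <- mk_cloud(c(40, 3, -2), 21, label_site("B", 1))
  dd2 <- pair_distance_distribution(c1, c2, g)
  oracle <- 0
  for (i in 1:15) for (j in 1:21) {
    oracle <- oracle + c1$weights[i] * c2$weights[j] *
      sqrt(sum((c1$positions[i, ] - c2$positions[j, ])^2))
  }
  # histogram bin centres quantize each distance to dr/2 = 0.25 Angstrom
  expect_equal(dist_mean(dd2), oracle, tolerance = 0.25)
  # symmetry in the arguments
  dd2r <- pair_distance_distribution(c2, c1, g)
  expect_equal(dd2$p, dd2r$p, tolerance = 1e-12)
})

test_that("distributions are invariant under a joint rigid transform", {
  ch <- helix_chain(8)
  s1 <- label_site("A", 2); s2 <- label_site("A", 7)
  c1 <- sample_rotamers(ch, s1); c2 <- sample_rotamers(ch, s2)
  dd <- pair_distance_distribution(c1, c2)
  R <- random_rotation(31)
  rot_cloud <- function(cl) {
    cl$positions <- cl$positions %*% t(R) +
      matrix(c(1, 2, 3), nrow(cl$positions), 3, byrow = TRUE)
    cl
  }
  ddr <- pair_distance_distribution(rot_cloud(c1), rot_cloud(c2))
  expect_equal(dd$p, ddr$p, tolerance = 1e-9)
})

test_that("rotamer distribution means converge as n doubles", {
  ch <- helix_chain(30)
  s1 <- label_site("A", 2); s2 <- label_site("A", 28)
  means <- vapply(c(36, 72, 144, 288), function(n) {
    dd <- pair_distance_distribution(sample_rotamers(ch, s1, n),
                                     sample_rotamers(ch, s2, n))
    dist_mean(dd)
  }, numeric(1))
  expect_lt(max(abs(diff(means))), 0.1)
})

test_that("two-column text round trips distributions and traces", {
  g <- default_r_grid()
  dd <- gaussian_dd(35)
  f <- tempfile(fileext = ".dat")
  write_xy(dd, f)
  m <- read_xy(f)
  expect_equal(m[, 1], dd$r)
  expect_equal(m[, 2], dd$p, tolerance = 1e-12)
  unlink(f)
})
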