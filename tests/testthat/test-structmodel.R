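test_that("PDB parsing: identity parse of a minimal structure", {
  s <- read_structure(tiny_pdb_text())
  expect_s3_class(s, "atomic_structure")
  expect_equal(length(unique(s$atoms$chain)), 1L)
  expect_equal(length(unique(s$atoms$resno)), 1L)
  expect_equal(nrow(s$atoms), 3L)
})

test_that("PDB parsing: only the first MODEL is retained", {
  two_models <- paste(c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(3, "CA", "ALA", "A", 1, 99, 0, 0),
    pdb_line(4, "CA", "ALA", "A", 2, 102.8, 0, 0),
    pdb_line(5, "CA", "ALA", "A", 3, 106.6, 0, 0),
    "ENDMDL", "END"), collapse = "\n")
  s <- read_structure(two_models)
  # hand-count: model 1 has exactly 2 atoms, model 2 has 3
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x, c(0, 3.8))
})

test_that("PDB parsing: altlocs resolve to highest occupancy", {
  alt <- paste(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.6, alt = "B"),
    "END"), collapse = "\n")
  s <- read_structure(alt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 2)
})

test_that("PDB parsing errors name the offending line", {
  bad <- paste(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ATOM      2  CA  ALA A   2      bad.coord   0.000"), collapse = "\n")
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure("REMARK no coordinates\nEND"), "empty")
})

test_that("coarse graining produces one bead per residue at the Ca", {
  n <- 5
  ch <- helix_chain(n)
  # write the helix out as PDB-ish text with Ca and Cb atoms, re-read
  lines <- character()
  serial <- 0
  for (i in seq_len(n)) {
    serial <- serial + 1
    lines <- c(lines, pdb_line(serial, "CA", "ALA", "A", i,
                               ch$xyz[i, 1], ch$xyz[i, 2], ch$xyz[i, 3]))
    cbp <- ch$xyz[i, ] + 1.53 * ch$cb[i, ]
    serial <- serial + 1
    lines <- c(lines, pdb_line(serial, "CB", "ALA", "A", i,
                               cbp[1], cbp[2], cbp[3]))
  }
  s <- read_structure(paste(c(lines, "END"), collapse = "\n"))
  bc <- coarse_grain(s, "A")
  expect_equal(nrow(bc$xyz), n)
  d <- sqrt(rowSums((bc$xyz[-1, ] - bc$xyz[-n, ])^2))
  expect_equal(d, rep(3.8, n - 1), tolerance = 1e-3)
  expect_equal(sqrt(rowSums(bc$cb^2)), rep(1, n), tolerance = 1e-6)
})

test_that("coarse graining: glycine gets no Cb direction; bad chain errors", {
  gly <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "END"),
               collapse = "\n")
  bc <- coarse_grain(read_structure(gly), "A")
  expect_true(all(is.na(bc$cb[1, ])))
  expect_error(coarse_grain(read_structure(gly), "B"), "chain not found")
})

test_that("the parser agrees with bio3d on a multi-residue fixture", {
  ch <- helix_chain(8)
  lines <- character(); serial <- 0
  for (i in 1:8) {
    serial <- serial + 1
    lines <- c(lines, pdb_line(serial, "CA", "ALA", "A", i,
                               ch$xyz[i, 1], ch$xyz[i, 2], ch$xyz[i, 3]))
  }
  txt <- paste(c(lines, "END"), collapse = "\n")
  f <- tempfile(fileext = ".pdb")
  writeLines(txt, f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f, verbose = FALSE)
  ref_ca <- ref$atom[ref$atom$elety == "CA", ]
  expect_equal(ours$atoms$x, ref_ca$x, tolerance = 1e-6)
  expect_equal(ours$atoms$y, ref_ca$y, tolerance = 1e-6)
  expect_equal(ours$atoms$resno, ref_ca$resno)
  unlink(f)
})

test_that("superposition recovers a known rigid transform", {
  set.seed(42)
  a <- matrix(stats::rnorm(30, sd = 10), 10, 3)
  # identical sets: zero rmsd, identity rotation
  sp0 <- superpose(a, a)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  # known 37-degree rotation about z plus translation
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  b <- a %*% t(R) + matrix(c(5, -3, 11), 10, 3, byrow = TRUE)
  sp <- superpose(a, b)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  rec_ang <- acos((sum(diag(sp$rotation)) - 1) / 2) * 180 / pi
  expect_equal(rec_ang, 37, tolerance = 1e-6)
})

test_that("superposition excludes reflections and rejects degenerate input", {
  set.seed(7)
  a <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  mirrored <- a %*% diag(c(-1, 1, 1))
  sp <- superpose(a, mirrored)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0)
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(collinear, collinear), "degenerate")
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("superpose cross-checks against bio3d fitting", {
  set.seed(3)
  a <- matrix(stats::rnorm(60, sd = 8), 20, 3)
  b <- a %*% t(random_rotation(5)) + 2 +
    matrix(stats::rnorm(60, sd = 0.3), 20, 3)
  sp <- superpose(a, b)
  ref <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(sp$rmsd, ref, tolerance = 2e-3)
})

test_that("pairwise Ca RMSD matches a direct residual oracle", {
  set.seed(11)
  ch1 <- helix_chain(30)
  jitter <- matrix(stats::rnorm(90, sd = 0.5), 30, 3)
  ch2 <- bead_chain(ch1$xyz + jitter, cb = ch1$cb, resno = ch1$resno,
                    resid = ch1$resid, id = "B", check = FALSE)
  m <- pairwise_ca_rmsd(list(ch1, ch2))
  expect_equal(diag(m), c(A = 0, B = 0))
  expect_equal(m[1, 2], m[2, 1])
  # oracle: superpose explicitly and recompute the residual directly
  sp <- superpose(ch1$xyz, ch2$xyz)
  fitted <- apply_superposition(sp, ch1$xyz)
  oracle <- sqrt(mean(rowSums((fitted - ch2$xyz)^2)))
  expect_equal(m[1, 2], oracle, tolerance = 1e-9)
  # identical chains give zero
  m0 <- pairwise_ca_rmsd(list(ch1, ch1))
  expect_equal(m0[1, 2], 0, tolerance = 1e-9)
})

test_that("pairwise Ca RMSD is invariant under global rigid transforms", {
  set.seed(13)
  ch1 <- helix_chain(25)
  ch2 <- bead_chain(ch1$xyz + matrix(stats::rnorm(75, sd = 0.4), 25, 3),
                    cb = ch1$cb, resno = ch1$resno, resid = ch1$resid,
                    id = "B", check = FALSE)
  m <- pairwise_ca_rmsd(list(ch1, ch2))
  R <- random_rotation(21)
  ch2r <- bead_chain(ch2$xyz %*% t(R) + 7, cb = ch2$cb %*% t(R),
                     resno = ch2$resno, resid = ch2$resid, id = "B",
                     check = FALSE)
  mr <- pairwise_ca_rmsd(list(ch1, ch2r))
  expect_equal(m[1, 2], mr[1, 2], tolerance = 1e-9)
})

test_that("domain rotation recovers a constructed hinge angle", {
  # two-domain chain: rigid reference block + moving block (helical, so
  # neither block is collinear)
  ch <- helix_chain(20)
  part <- domain_partition(list(ref = 1:10, mov = 11:20), hinge = 10:11)
  expect_equal(domain_rotation(ch, ch, part, "ref", "mov")$angle, 0,
               tolerance = 1e-9)
  # rotate the moving block by 90 degrees about an axis through bead 10
  ang <- pi / 2
  R <- matrix(c(1, 0, 0, 0, cos(ang), -sin(ang), 0, sin(ang), cos(ang)),
              3, 3, byrow = TRUE)
  xyz2 <- ch$xyz
  pivot <- ch$xyz[10, ]
  xyz2[11:20, ] <- sweep(sweep(ch$xyz[11:20, ], 2, pivot) %*% t(R), 2,
                         pivot, "+")
  ch2 <- bead_chain(xyz2, cb = ch$cb, resno = ch$resno, resid = ch$resid,
                    id = "B", check = FALSE)
  dr <- domain_rotation(ch, ch2, part, "ref", "mov")
  expect_equal(dr$angle, 90, tolerance = 1e-6)
  expect_equal(sqrt(sum(dr$axis^2)), 1, tolerance = 1e-9)
  # angle is symmetric in the argument order
  dr_rev <- domain_rotation(ch2, ch, part, "ref", "mov")
  expect_equal(dr$angle, dr_rev$angle, tolerance = 1e-9)
})

test_that("interdomain hydrogen bonds follow the distance criterion", {
  mk <- function(d_og_oe) {
    paste(c(
      pdb_line(1, "CA", "SER", "A", 10, 0, 0, 0),
      pdb_line(2, "OG", "SER", "A", 10, 1.4, 0, 0),
      pdb_line(3, "CA", "GLU", "A", 80, d_og_oe + 2.8, 0, 0),
      pdb_line(4, "OE1", "GLU", "A", 80, 1.4 + d_og_oe, 0, 0),
      "END"), collapse = "\n")
  }
  part <- domain_partition(list(J = 1:74, GF = 75:107))
  hb <- interdomain_hbond_pairs(read_structure(mk(2.8)), "A", part,
                                "J", "GF", cutoff = 3.5)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dist, 2.8, tolerance = 1e-6)
  expect_equal(hb$atom_a, "OG")
  hb2 <- interdomain_hbond_pairs(read_structure(mk(4.2)), "A", part,
                                 "J", "GF", cutoff = 3.5)
  expect_equal(nrow(hb2), 0L)
  # monotone in the cutoff
  hb3 <- interdomain_hbond_pairs(read_structure(mk(4.2)), "A", part,
                                 "J", "GF", cutoff = 4.5)
  expect_gte(nrow(hb3), nrow(hb2))
})

test_that("average mass reproduces hand sums and is additive", {
  expect_equal(average_mass(""), 18.0153)
  # hand sum: 2 x Gly (57.0519) + water
  expect_equal(average_mass("GG"), 132.12, tolerance = 0.01)
  s1 <- "ACDEFG"; s2 <- "HIKLMNPQRSTVWY"
  expect_equal(average_mass(paste0(s1, s2)),
               average_mass(s1) + average_mass(s2) - 18.0153,
               tolerance = 1e-9)
  expect_error(average_mass("AXZ"), "unknown residue")
})
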