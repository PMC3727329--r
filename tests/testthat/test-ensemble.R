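test_that("clash energy: pair arithmetic and the s_min exemption", {
  params <- energy_params()
  mk2 <- function(sep) {
    a <- bead_chain(matrix(c(0, 0, 0), 1, 3), id = "A", check = FALSE)
    b <- bead_chain(matrix(c(sep, 0, 0), 1, 3), id = "B", check = FALSE)
    conformation(list(a, b))
  }
  expect_equal(clash_energy(mk2(10), params), 0)
  expect_equal(clash_energy(mk2(3), params), 2.0)  # 5 - 3
  # local backbone pairs are exempt: an ideal rod has no self-clash
  expect_equal(clash_energy(conformation(list(rod_chain(10)))), 0)
  # count mode counts pairs instead of overlaps
  expect_equal(clash_energy(mk2(3), energy_params(clash_mode = "count")), 1)
})

test_that("clash energy matches the brute-force oracle on random beads", {
  set.seed(61)
  for (rep in 1:3) {
    xyz <- matrix(stats::runif(180, 0, 25), 60, 3)
    chain <- rep(1:2, each = 30)
    idx <- rep(1:30, 2)
    chains <- list(
      bead_chain(xyz[1:30, ], id = "A", check = FALSE),
      bead_chain(xyz[31:60, ], id = "B", check = FALSE))
    conf <- conformation(chains)
    e <- clash_energy(conf, energy_params())
    expect_equal(e, clash_oracle(xyz, chain, idx), tolerance = 1e-12)
    xyz <- xyz + stats::rnorm(180)
  }
})

test_that("EPR energy: mode gives zero, uniform target is flat", {
  g <- default_r_grid()
  conf <- two_rod_conformation(sep = 30)
  keys <- names(conf$sites)
  d0 <- sqrt(sum((conf$labels[1, ] - conf$labels[2, ])^2))
  # target with its mode exactly at the current distance
  tg <- gaussian_dd(round(d0 * 2) / 2, width = 3)
  rs <- epr_restraint(conf$sites[[1]], conf$sites[[2]], tg)
  e <- epr_energy(conf, list(rs), energy_params())
  # interpolation between bins makes this approximate at the 1e-3 level
  expect_lt(e, 5e-3)
  # uniform target: energy 0 whatever the distance
  uni <- distance_distribution(g, rep(1, length(g)))
  rsu <- epr_restraint(conf$sites[[1]], conf$sites[[2]], uni)
  expect_equal(epr_energy(conf, list(rsu), energy_params()), 0,
               tolerance = 1e-12)
})

test_that("EPR energy reproduces a hand-computed two-restraint case", {
  params <- energy_params()
  conf <- two_rod_conformation(n = 12, sep = 30)
  k1 <- names(conf$sites)[1]; k2 <- names(conf$sites)[2]
  d <- sqrt(sum((conf$labels[k1, ] - conf$labels[k2, ])^2))
  g <- default_r_grid()
  tg1 <- gaussian_dd(25, width = 2); tg2 <- gaussian_dd(40, width = 5)
  rs <- list(epr_restraint(conf$sites[[1]], conf$sites[[2]], tg1),
             epr_restraint(conf$sites[[1]], conf$sites[[2]], tg2))
  # hand computation: linear interpolation of each target at d
  interp <- function(tg, x) stats::approx(tg$r, tg$p, xout = x)$y
  expected <- -log(max(interp(tg1, d), 1e-6) / max(tg1$p)) -
    log(max(interp(tg2, d), 1e-6) / max(tg2$p))
  expect_equal(epr_energy(conf, rs, params), expected, tolerance = 1e-12)
  # distances beyond the grid fall to the probability floor
  far <- two_rod_conformation(n = 12, sep = 150)
  rs_far <- epr_restraint(far$sites[[1]], far$sites[[2]], tg1)
  expect_equal(epr_energy(far, list(rs_far), params),
               -log(1e-6 / max(tg1$p)), tolerance = 1e-9)
})

test_that("rigid segment rotations preserve internal geometry", {
  ch <- helix_chain(20)
  conf <- conformation(list(ch), list(label_site("A", 16)))
  el <- list(type = "backbone", chain = "A", i = 10)
  expect_equal(apply_rotation(conf, el, 0)$chains$A$xyz, conf$chains$A$xyz)
  c2pi <- apply_rotation(conf, el, 2 * pi)
  expect_equal(c2pi$chains$A$xyz, conf$chains$A$xyz, tolerance = 1e-9)
  set.seed(5)
  ang <- stats::runif(1, -pi, pi)
  cr <- apply_rotation(conf, el, ang)
  # axis endpoints fixed
  expect_equal(cr$chains$A$xyz[10, ], conf$chains$A$xyz[10, ],
               tolerance = 1e-12)
  expect_equal(cr$chains$A$xyz[11, ], conf$chains$A$xyz[11, ],
               tolerance = 1e-9)
  # upstream untouched; pairwise distances preserved within both segments
  expect_equal(cr$chains$A$xyz[1:10, ], conf$chains$A$xyz[1:10, ])
  dmat <- function(x) as.matrix(stats::dist(x))
  expect_equal(dmat(cr$chains$A$xyz[11:20, ]),
               dmat(conf$chains$A$xyz[11:20, ]), tolerance = 1e-9)
  # the attached label moves rigidly with its segment: distance from the
  # label to every downstream bead is unchanged
  d_before <- sqrt(rowSums(sweep(conf$chains$A$xyz[11:20, ], 2,
                                 conf$labels[1, ])^2))
  d_after <- sqrt(rowSums(sweep(cr$chains$A$xyz[11:20, ], 2,
                                cr$labels[1, ])^2))
  expect_equal(d_after, d_before, tolerance = 1e-9)
  expect_error(apply_rotation(conf, list(type = "backbone", chain = "A",
                                         i = 25), 1), "unknown element")
})

test_that("label moves advance the dihedral and nothing else", {
  conf <- two_rod_conformation()
  k1 <- names(conf$sites)[1]
  c2 <- apply_rotation(conf, list(type = "label", key = k1), 0.7)
  expect_equal(c2$psi[[k1]], 0.7)
  expect_equal(c2$chains$A$xyz, conf$chains$A$xyz)
  expect_false(isTRUE(all.equal(c2$labels[k1, ], conf$labels[k1, ])))
  expect_equal(c2$labels[names(conf$sites)[2], ],
               conf$labels[names(conf$sites)[2], ])
})

test_that("the sampler is deterministic and decomposes its energy", {
  conf <- two_rod_conformation()
  tg <- gaussian_dd(28, width = 3)
  rs <- list(epr_restraint(conf$sites[[1]], conf$sites[[2]], tg))
  ms <- move_set(backbone = data.frame(chain = "A", i = 4), labels = TRUE)
  mc <- mc_config(n_trials = 400, seed = 12, stride = 40)
  e1 <- run_mc(conf, ms, rs, energy_params(), mc)
  e2 <- run_mc(conf, ms, rs, energy_params(), mc)
  expect_identical(e1$samples[[5]]$xyz, e2$samples[[5]]$xyz)
  expect_identical(e1$energy_trace, e2$energy_trace)
  expect_equal(nrow(e1$energy_trace), 400L)
  expect_lte(e1$acceptance, 400L)
  # E_total = w * E_clash + E_epr at every snapshot, and the cached
  # snapshot energies match a fresh recomputation
  for (s in e1$samples) {
    expect_equal(s$e_total, s$e_clash + s$e_epr, tolerance = 1e-9)
  }
  last <- e1$samples[[length(e1$samples)]]
  rebuilt <- conformation(
    list(bead_chain(last$xyz[1:12, ], cb = last$cb[1:12, ],
                    resno = 1:12, id = "A", check = FALSE),
         bead_chain(last$xyz[13:24, ], cb = last$cb[13:24, ],
                    resno = 1:12, id = "B", check = FALSE)),
    conf$sites, psi = last$psi)
  rebuilt <- score_conformation(rebuilt, rs, energy_params())
  expect_equal(rebuilt$e_clash, last$e_clash, tolerance = 1e-9)
  expect_equal(rebuilt$e_epr, last$e_epr, tolerance = 1e-9)
})

test_that("greedy limit only goes downhill; free moves always accepted", {
  conf <- two_rod_conformation()
  tg <- gaussian_dd(45, width = 2)   # pull the rods' labels apart
  rs <- list(epr_restraint(conf$sites[[1]], conf$sites[[2]], tg))
  ms <- move_set(labels = TRUE)
  greedy <- run_mc(conf, ms, rs, energy_params(),
                   mc_config(n_trials = 500, seed = 4, temperature = 0))
  expect_true(all(diff(greedy$energy_trace$e_total) <= 1e-12))
  # no restraints, no possible clashes: every move is accepted
  free <- run_mc(conf, ms, list(), energy_params(),
                 mc_config(n_trials = 300, seed = 4))
  expect_equal(free$acceptance, 300L)
})

test_that("hinge-only move sets keep intramonomer label pairs rigid", {
  m <- make_two_domain_dimer(synthetic_spec(seed = 1))
  conf <- conformation(m$chains, m$sites)
  ms <- move_set(backbone = m$hinge_bonds, labels = FALSE,
                 delta_deg = 25)
  ens <- run_mc(conf, ms, list(), energy_params(),
                mc_config(n_trials = 300, seed = 2, stride = 30))
  for (pair in list(c("A.J18", "A.GF86"), c("A.GF86", "A.GF95"),
                    c("A.J50", "A.V90"))) {
    ka <- site_key(m$sites[[pair[1]]]); kb <- site_key(m$sites[[pair[2]]])
    d <- ensemble_label_distances(ens, ka, kb)
    expect_lt(max(d) - min(d), 1e-9)
  }
})

test_that("multi-model CA ensembles re-read as valid structures", {
  conf <- two_rod_conformation()
  ens <- run_mc(conf, move_set(labels = TRUE), list(), energy_params(),
                mc_config(n_trials = 60, seed = 8, stride = 10))
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f, max_models = 3)
  s <- read_structure(f)      # first MODEL only
  # 24 beads across chains A/B plus 2 label pseudo-atoms in chain Z
  expect_equal(nrow(s$atoms), 26L)
  expect_setequal(unique(s$atoms$chain), c("A", "B", "Z"))
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3L)
  unlink(f)
})

test_that("move sets validate their elements", {
  conf <- two_rod_conformation()
  expect_error(
    run_mc(conf, move_set(backbone = data.frame(chain = "C", i = 1)),
           list(), energy_params(), mc_config(n_trials = 10, seed = 1)),
    "unknown chain")
  expect_error(
    run_mc(conf, move_set(labels = "A:99"), list(), energy_params(),
           mc_config(n_trials = 10, seed = 1)),
    "unknown label site")
  expect_error(mc_config(n_trials = 10), "seed")
})
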