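#' Parameters for the synthetic V-shaped dimer
#'
#' Describes a coarse-grained homodimer emulating the architecture of a
#' DnaJ-type cochaperone: per monomer a rod-like C-terminal domain (CTD)
#' stalk that dimerizes at the base into a V, an 8-residue hinge linker,
#' and a compact J/GF head at the end of each stalk. Chains are indexed
#' from the CTD so that the dimerized stalks form the fixed frame and
#' hinge rotations swing the J/GF heads.
#'
#' @param n_jgf Residues in the J/GF head (default 100).
#' @param n_ctd Residues in the CTD stalk (default 160).
#' @param n_hinge Hinge linker residues (default 8).
#' @param opening_angle Angle between the two stalk axes (degrees,
#'   default 8): sets the static separation of the heads, placing
#'   intermonomer label pairs in the 40--60 Angstrom window.
#' @param hinge_flex True hinge flexibility: standard deviation of each
#'   hinge dihedral (degrees, default 10).
#' @param label_positions Named integer vector of nominal label/cross-link
#'   positions within the J/GF head. Names tag the classic J-domain and
#'   GF-domain sites being emulated; the default positions are
#'   coordinates in the synthetic head chosen so that each labelled pair
#'   reproduces its experimental distance window (intramonomer pairs
#'   20--30 Angstrom, intermonomer pairs 40--60 Angstrom).
#' @param lambda,k,sigma DEER simulation parameters: modulation depth,
#'   background rate (1/us), noise sd.
#' @param seed Integer seed (mandatory; funnels all downstream
#'   randomness).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_jgf = 100, n_ctd = 160, n_hinge = 8,
                           opening_angle = 8, hinge_flex = 10,
                           label_positions = c(J18 = 18, J50 = 36,
                                               J58 = 58, GF86 = 86,
                                               V90 = 90, GF95 = 96),
                           lambda = 0.3, k = 0.05, sigma = 0.005, seed) {
  stopifnot(n_jgf >= 3, n_ctd >= 3, n_hinge >= 3,
            opening_angle > 0, opening_angle < 90, hinge_flex >= 0,
            all(label_positions >= 1), all(label_positions <= n_jgf))
  if (missing(seed)) stop("an integer seed is mandatory")
  structure(list(n_jgf = n_jgf, n_ctd = n_ctd, n_hinge = n_hinge,
                 opening_angle = opening_angle, hinge_flex = hinge_flex,
                 label_positions = label_positions, lambda = lambda,
                 k = k, sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## solenoid beads: exact consecutive chord `bond`, radius rho, rise per
## residue, around axis a_hat with transverse frame (e1, e2), bead 1 at
## phase 0 on the line through `origin`
.solenoid <- function(n, origin, a_hat, e1, e2, rho, rise, bond = 3.8) {
  chord_xy <- sqrt(bond^2 - rise^2)
  dphi <- 2 * asin(chord_xy / (2 * rho))
  k <- seq_len(n) - 1
  phi <- k * dphi
  t(sapply(seq_len(n), function(i) {
    origin + rise * k[i] * a_hat +
      rho * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
  }))
}

## compact serpentine helix bundle: straight anti-parallel rods of beads
## (spacing `bond` along the rod) on a 3-column lattice of `spacing`
## Angstrom, rods joined by single turn beads; mimics a compact folded
## domain at one-bead-per-residue resolution. Only sequence neighbours
## come closer than `spacing`, so the construct is clash-free under the
## default 5 Angstrom cutoff.
.bundle <- function(n, first_bead, a_hat, e1, e2, rod_len = 10,
                    spacing = 5.4, bond = 3.8, n_cols = 3) {
  xyz <- matrix(NA_real_, n, 3)
  lat <- matrix(NA_real_, n, 2)          # lattice offsets, for cb dirs
  is_turn <- logical(n)
  height <- bond * (rod_len - 1)
  k <- 0L; m <- 0L                       # bead count, rod count
  while (k < n) {
    row <- m %/% n_cols
    col <- m %% n_cols
    if (row %% 2 == 1) col <- n_cols - 1 - col
    up <- m %% 2 == 0
    off <- spacing * (col * e1 + row * e2)
    for (p in seq_len(rod_len)) {
      if (k >= n) break
      k <- k + 1L
      h <- if (up) bond * (p - 1) else height - bond * (p - 1)
      xyz[k, ] <- first_bead + off + h * a_hat
      lat[k, ] <- spacing * c(col, row)
    }
    m <- m + 1L
    if (k >= n) break
    ## turn bead between this rod's end and the next rod's start
    row2 <- m %/% n_cols
    col2 <- m %% n_cols
    if (row2 %% 2 == 1) col2 <- n_cols - 1 - col2
    off2 <- spacing * (col2 * e1 + row2 * e2)
    end_h <- if (up) height else 0
    outward <- if (up) 2.07 else -2.07
    k <- k + 1L
    xyz[k, ] <- first_bead + (off + off2) / 2 + (end_h + outward) * a_hat
    lat[k, ] <- spacing * c((col + col2) / 2, (row + row2) / 2)
    is_turn[k] <- TRUE
  }
  centre_lat <- colMeans(lat)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    v <- (lat[i, 1] - centre_lat[1]) * e1 + (lat[i, 2] - centre_lat[2]) * e2
    nv <- sqrt(sum(v^2))
    if (is_turn[i] || nv < 1e-6) {
      ## turn beads (and exactly central rods) point axially outward
      sgn <- if (sum((xyz[i, ] - first_bead) * a_hat) > height / 2) 1 else -1
      cb[i, ] <- sgn * a_hat
    } else {
      cb[i, ] <- v / nv
    }
  }
  list(xyz = xyz, cb = cb)
}

## one arm (chain) of the dimer; mirror = -1 reflects x -> -x for chain B
.build_arm <- function(spec, mirror = 1, id = "A",
                       rho_ctd = 6.0, rise_ctd = 0.625,
                       core_offset = 9.0) {
  half <- spec$opening_angle / 2 * pi / 180
  a_hat <- c(mirror * sin(half), 0, cos(half))
  e1 <- c(mirror * cos(half), 0, -sin(half))   # outward transverse
  e2 <- c(0, 1, 0)
  origin <- c(mirror * core_offset, 0, 0)

  ctd <- .solenoid(spec$n_ctd, origin, a_hat, e1, e2, rho_ctd, rise_ctd)
  ctd_axis <- function(k) origin + rise_ctd * (k - 1) * a_hat

  ## hinge: zig-zag along the arm axis (alternating transverse offsets so
  ## the virtual bond axes are not collinear and hinge rotations span
  ## bending as well as torsion)
  E <- ctd[spec$n_ctd, ]
  step <- 2.95; zig_amp <- 1.2
  hinge <- t(sapply(seq_len(spec$n_hinge), function(j) {
    E + j * step * a_hat + zig_amp * (-1)^j * e2
  }))

  attach <- hinge[spec$n_hinge, ] + 3.5 * a_hat -
    zig_amp * (-1)^spec$n_hinge * e2
  jgf <- .bundle(spec$n_jgf, attach, a_hat, e1, e2)

  xyz <- rbind(ctd, hinge, jgf$xyz)
  n <- nrow(xyz)
  ## outward Cb directions: radially away from the local segment centre
  cb <- matrix(NA_real_, n, 3)
  for (k in seq_len(spec$n_ctd)) {
    v <- ctd[k, ] - ctd_axis(k)
    cb[k, ] <- v / sqrt(sum(v^2))
  }
  for (j in seq_len(spec$n_hinge)) {
    v <- zig_amp * (-1)^j * e2
    cb[spec$n_ctd + j, ] <- v / sqrt(sum(v^2))
  }
  cb[spec$n_ctd + spec$n_hinge + seq_len(spec$n_jgf), ] <- jgf$cb
  resid <- rep("ALA", n)
  resid[spec$n_ctd + spec$n_hinge + spec$label_positions] <- "CYS"
  bead_chain(xyz, cb = cb, resno = seq_len(n), resid = resid, id = id)
}

#' Generate the synthetic V-shaped two-domain dimer
#'
#' Builds two mirror-image arms (CTD stalk + hinge + J/GF head), returns
#' them with their domain partition and label sites, and verifies the
#' construction is clash-free under the default pseudo-energy parameters.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `chains` (two `bead_chain`s, "A" and "B"),
#'   `partition` (a `domain_partition`; hinge = the linker residues),
#'   `sites` (named list of `label_site`s on both chains, names like
#'   `"A.GF86"`), `site_map` (data.frame: name, chain, resno, nominal
#'   position) and `hinge_bonds` (data.frame chain/i of the rotatable
#'   hinge backbone bonds).
#' @export
make_two_domain_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  chA <- .build_arm(spec, mirror = 1, id = "A")
  chB <- .build_arm(spec, mirror = -1, id = "B")
  n_ctd <- spec$n_ctd; n_hinge <- spec$n_hinge
  partition <- domain_partition(
    domains = list(CTD = 1:n_ctd,
                   linker = (n_ctd + 1):(n_ctd + n_hinge),
                   JGF = (n_ctd + n_hinge + 1):(n_ctd + n_hinge +
                                                  spec$n_jgf)),
    hinge = (n_ctd + 1):(n_ctd + n_hinge))
  site_map <- do.call(rbind, lapply(names(spec$label_positions), function(nm) {
    data.frame(name = paste(c("A", "B"), nm, sep = "."),
               chain = c("A", "B"),
               resno = n_ctd + n_hinge + spec$label_positions[[nm]],
               nominal = nm, stringsAsFactors = FALSE)
  }))
  sites <- stats::setNames(
    lapply(seq_len(nrow(site_map)),
           function(i) label_site(site_map$chain[i], site_map$resno[i])),
    site_map$name)
  ## rotatable bonds: one per hinge residue, bond (i, i+1) for each
  ## linker residue i so rotations act on everything from the linker out
  hinge_bonds <- data.frame(
    chain = rep(c("A", "B"), each = n_hinge),
    i = rep(n_ctd:(n_ctd + n_hinge - 1), 2))
  model <- list(chains = list(A = chA, B = chB), partition = partition,
                sites = sites, site_map = site_map,
                hinge_bonds = hinge_bonds, spec = spec)
  conf <- conformation(model$chains, model$sites)
  ec <- clash_energy(conf, energy_params())
  if (ec > 0) {
    stop("geometric infeasibility: generated dimer has clash energy ",
         signif(ec, 4), "; widen the opening angle")
  }
  model
}

#' Ground-truth ensemble from known hinge flexibility
#'
#' Draws conformers by perturbing every hinge dihedral with independent
#' Gaussian rotations of the stated standard deviation, rejecting
#' clashing conformers, and histograms the label-label distances of the
#' requested pairs. With the default `label_mobility = FALSE` labels stay
#' at their reference tether dihedral, so intramonomer pairs (rigid
#' within the head) give zero-width distributions and all spread comes
#' from the hinge; set it to `TRUE` to additionally draw every tether
#' dihedral uniformly per conformer.
#'
#' @param model Output of [make_two_domain_dimer()].
#' @param flexibility Std dev of each hinge dihedral (degrees).
#' @param n_conformers Number of accepted conformers (>= 100).
#' @param seed Integer seed.
#' @param pairs List of site-name pairs (defaults: the three intramonomer
#'   pairs on chain A plus the intermonomer GF86-GF86 and J58-J58 pairs).
#' @param r_grid Distance grid for the truth distributions (default
#'   2--160 Angstrom: wider than the DEER analysis grid, since
#'   large-amplitude hinge excursions can push intermonomer distances
#'   beyond the measurable window).
#' @param label_mobility Randomize tether dihedrals per conformer
#'   (default `FALSE`).
#' @return List with `distances` (matrix n_conformers x n_pairs),
#'   `distributions` (named list of `distance_distribution`),
#'   `n_rejected`, and `conformers` (list of per-conformer chain
#'   coordinate lists).
#' @export
simulate_truth_ensemble <- function(model, flexibility, n_conformers = 500,
                                    seed, pairs = NULL,
                                    r_grid = seq(2, 160, by = 0.5),
                                    label_mobility = FALSE) {
  stopifnot(n_conformers >= 100)
  if (missing(seed)) stop("an integer seed is mandatory")
  if (is.null(pairs)) {
    pairs <- list(c("A.J18", "A.GF86"), c("A.GF86", "A.GF95"),
                  c("A.J50", "A.V90"), c("A.GF86", "B.GF86"),
                  c("A.J58", "B.J58"))
    pairs <- Filter(function(p) all(p %in% names(model$sites)), pairs)
  }
  pair_labels <- vapply(pairs, paste, "", collapse = "-")
  ## translate friendly site names to canonical conformation keys
  pairs <- lapply(pairs, function(p) {
    vapply(p, function(nm) {
      if (!is.null(model$sites[[nm]])) site_key(model$sites[[nm]]) else nm
    }, "")
  })
  set.seed(seed)
  base <- conformation(model$chains, model$sites)
  params <- energy_params()
  flex_rad <- flexibility * pi / 180
  nb <- nrow(model$hinge_bonds)
  d_mat <- matrix(NA_real_, n_conformers, length(pairs),
                  dimnames = list(NULL, pair_labels))
  conformers <- vector("list", n_conformers)
  n_acc <- 0L; n_rej <- 0L
  while (n_acc < n_conformers) {
    conf <- base
    if (flex_rad > 0) {
      for (b in seq_len(nb)) {
        ang <- stats::rnorm(1, 0, flex_rad)
        conf <- apply_rotation(conf, list(type = "backbone",
                                          chain = model$hinge_bonds$chain[b],
                                          i = model$hinge_bonds$i[b]), ang)
      }
      if (clash_energy(conf, params) > 0) {
        n_rej <- n_rej + 1L
        if (n_rej > 99 * (n_acc + 1L) && n_rej > 200L) {
          stop("rejection rate above 99%: reduce the hinge flexibility")
        }
        next
      }
    }
    if (label_mobility) {
      for (k in names(conf$sites)) {
        conf$psi[[k]] <- stats::runif(1, 0, 2 * pi)
      }
    }
    conf$labels <- .place_all_labels(conf)
    n_acc <- n_acc + 1L
    for (q in seq_along(pairs)) {
      d_mat[n_acc, q] <- sqrt(sum((conf$labels[pairs[[q]][1], ] -
                                     conf$labels[pairs[[q]][2], ])^2))
    }
    conformers[[n_acc]] <- lapply(conf$chains, function(ch) ch$xyz)
  }
  dists <- lapply(seq_along(pairs), function(q) {
    hist_from_samples(d_mat[, q], 1, r_grid)
  })
  names(dists) <- pair_labels
  list(distances = d_mat, distributions = dists, n_rejected = n_rej,
       conformers = conformers)
}

#' Write a set of noisy DEER traces for truth distributions
#'
#' One trace file per distribution per seed, in two-column text, each
#' with a key = value metadata sidecar recording the generating
#' parameters.
#'
#' @param distributions Named list of `distance_distribution`.
#' @param lambda,k,sigma DEER parameters (see [simulate_trace()]).
#' @param seeds Integer vector of noise seeds.
#' @param dir Output directory (created if needed).
#' @param t_grid Time grid (us).
#' @return Manifest data.frame (pair, seed, trace path, metadata path).
#' @export
make_deer_dataset <- function(distributions, lambda = 0.3, k = 0.05,
                              sigma = 0.005, seeds = 1L, dir,
                              t_grid = seq(0, 4, by = 0.016)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(distributions)) {
    kern <- dipolar_kernel(t_grid, distributions[[nm]]$r)
    for (s in seeds) {
      tr <- simulate_trace(distributions[[nm]], lambda, k, d = 3,
                           sigma = sigma, seed = s, t_grid = t_grid,
                           kernel = kern)
      safe <- gsub("[^A-Za-z0-9.-]", "_", nm)
      tp <- file.path(dir, sprintf("trace_%s_seed%d.dat", safe, s))
      mp <- file.path(dir, sprintf("trace_%s_seed%d.meta", safe, s))
      write_xy(tr, tp)
      write_metadata(list(pair = nm, lambda = lambda, k = k, d = 3,
                          sigma = sigma, seed = s), mp)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = nm, seed = s, trace = tp, meta = mp,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Write a key = value metadata sidecar
#' @param x Named list of scalar values.
#' @param path Output path.
#' @export
write_metadata <- function(x, path) {
  writeLines(paste(names(x), unlist(x), sep = " = "), path)
  invisible(path)
}

#' Read a key = value metadata sidecar
#' @param path Input path.
#' @return Named list (numeric where possible).
#' @export
read_metadata <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, " = ", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[`, "", 1)
  out
}
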