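#' Pseudo-energy parameters
#'
#' The conformational score combines (i) a soft-sphere C-alpha clash
#' penalty, summing `(cutoff - d)` over all residue pairs closer than the
#' cutoff, and (ii) an inverse-Boltzmann term derived from EPR distance
#' distributions (see [epr_energy()]).
#'
#' @param clash_cutoff Clash cutoff c (Angstrom, default 5.0).
#' @param s_min Minimum intra-chain sequence separation for a pair to
#'   count as a clash (default 4): consecutive and helical i,i+3/i,i+4
#'   C-alpha pairs sit naturally below 5 Angstrom and must not be
#'   penalized.
#' @param clash_weight Weight w of the clash term (energy per Angstrom of
#'   overlap, default 1).
#' @param kT Thermal energy scale (energy units, default 1).
#' @param p_floor Probability floor for the inverse-Boltzmann term
#'   (default 1e-6).
#' @param clash_mode `"overlap"` (default; penalty `c - d` per pair, a
#'   continuous score that grows with overlap depth) or `"count"` (one
#'   unit per clashing pair, for sensitivity checks).
#' @return An `energy_params` object.
#' @export
energy_params <- function(clash_cutoff = 5.0, s_min = 4L, clash_weight = 1,
                          kT = 1, p_floor = 1e-6,
                          clash_mode = c("overlap", "count")) {
  clash_mode <- match.arg(clash_mode)
  stopifnot(clash_cutoff > 0, s_min >= 1, kT > 0,
            p_floor > 0, p_floor < 1)
  structure(list(clash_cutoff = clash_cutoff, s_min = as.integer(s_min),
                 clash_weight = clash_weight, kT = kT, p_floor = p_floor,
                 clash_mode = clash_mode),
            class = "energy_params")
}

#' An EPR distance restraint between two label sites
#'
#' @param site_a,site_b `label_site` objects (distinct; possibly on the
#'   two different monomers of a dimer).
#' @param target A `distance_distribution` (e.g. a Tikhonov-inverted DEER
#'   distribution) the label-label distance should be consistent with.
#' @return An `epr_restraint` object.
#' @export
epr_restraint <- function(site_a, site_b, target) {
  stopifnot(inherits(target, "distance_distribution"))
  ka <- .site_key(site_a); kb <- .site_key(site_b)
  if (identical(ka, kb)) stop("restraint sites must be distinct")
  structure(list(site_a = site_a, site_b = site_b, key_a = ka, key_b = kb,
                 target = target, p_max = max(target$p)),
            class = "epr_restraint")
}

.site_key <- function(site) paste0(site$chain, ":", site$resno)

#' Canonical key of a label site within a conformation
#' @param site A `label_site`.
#' @return String `"<chain>:<resno>"`, the row key used for the site's
#'   label throughout the sampler.
#' @export
site_key <- function(site) .site_key(site)

## shared label-placement math: ca position, unit Cb direction u,
## neighbouring Ca (or NULL) for the frame reference
.label_point <- function(ca, u, ca_ref, L, theta_deg, psi) {
  if (is.null(ca_ref)) {
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  } else {
    w <- ca_ref - ca
  }
  v1 <- w - sum(w * u) * u
  nv <- sqrt(sum(v1^2))
  if (nv < 1e-9) stop("degenerate label frame")
  v1 <- v1 / nv
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  th <- theta_deg * pi / 180
  ca + 1.53 * u + L * (cos(th) * u + sin(th) * (cos(psi) * v1 + sin(psi) * v2))
}

#' Assemble a conformation from bead chains and label sites
#'
#' @param chains List of `bead_chain` objects (names taken from chain
#'   ids).
#' @param sites List of `label_site` objects; each becomes a mobile label
#'   keyed `"<chain>:<resno>"`.
#' @param psi Named numeric of initial label dihedrals (radians), keyed
#'   like the sites; missing entries default to 0.
#' @return A `conformation`: list with `chains`, `sites`, `psi`, `labels`
#'   (matrix of current label positions, one row per site key) and cached
#'   energies `e_clash`, `e_epr`, `e_total` (`NA` until scored).
#' @export
conformation <- function(chains, sites = list(), psi = numeric()) {
  if (inherits(chains, "bead_chain")) chains <- list(chains)
  names(chains) <- vapply(chains, function(ch) ch$id, "")
  keys <- vapply(sites, .site_key, "")
  names(sites) <- keys
  psi_full <- stats::setNames(rep(0, length(keys)), keys)
  psi_full[names(psi)] <- psi
  conf <- structure(list(chains = chains, sites = sites, psi = psi_full,
                         labels = NULL, e_clash = NA_real_,
                         e_epr = NA_real_, e_total = NA_real_),
                    class = "conformation")
  conf$labels <- .place_all_labels(conf)
  conf
}

.place_all_labels <- function(conf) {
  keys <- names(conf$sites)
  m <- matrix(NA_real_, length(keys), 3, dimnames = list(keys, NULL))
  for (k in keys) {
    site <- conf$sites[[k]]
    ch <- conf$chains[[site$chain]]
    if (is.null(ch)) stop("site chain not in conformation: ", site$chain)
    m[k, ] <- place_label(ch, site, conf$psi[[k]])
  }
  m
}

## flatten chains to matrices for the C++ kernels
.flatten <- function(conf) {
  xyz <- do.call(rbind, lapply(conf$chains, function(ch) ch$xyz))
  cb <- do.call(rbind, lapply(conf$chains, function(ch) ch$cb))
  chain_id <- rep(seq_along(conf$chains),
                  vapply(conf$chains, function(ch) nrow(ch$xyz), 0L))
  idx <- unlist(lapply(conf$chains,
                       function(ch) seq_len(nrow(ch$xyz))), use.names = FALSE)
  offsets <- c(0L, cumsum(vapply(conf$chains,
                                 function(ch) nrow(ch$xyz), 0L)))
  list(xyz = xyz, cb = cb, chain = as.integer(chain_id),
       idx = as.integer(idx), offsets = offsets,
       chain_names = names(conf$chains))
}

#' C-alpha clash energy of a conformation
#'
#' Sum of `(cutoff - d)` over all unordered bead pairs with `d < cutoff`,
#' where intra-chain pairs only qualify when their sequence separation
#' exceeds `s_min`; inter-chain pairs always qualify.
#'
#' @param conf A `conformation`.
#' @param params An `energy_params`.
#' @return Clash energy (unweighted; [run_mc()] applies `clash_weight`).
#' @export
clash_energy <- function(conf, params = energy_params()) {
  fl <- .flatten(conf)
  clash_energy_cpp(fl$xyz, fl$chain, fl$idx, params$clash_cutoff,
                   params$s_min, params$clash_mode == "count")
}

## interpolated target density at distance d, floored
.restraint_density <- function(restraint, d, p_floor) {
  tg <- restraint$target
  if (d < tg$r[1] || d > tg$r[length(tg$r)]) return(p_floor)
  p <- stats::approx(tg$r, tg$p, xout = d, rule = 2)$y
  max(p, p_floor)
}

#' Inverse-Boltzmann EPR restraint energy
#'
#' For each restraint with current label-label distance d and target
#' density p(r) (maximum p_max),
#' \deqn{E = -kT \log(\max(p(d), p_{floor}) / p_{max}),}
#' so a conformation at the target mode contributes zero and improbable
#' distances are penalized logarithmically, floored at `p_floor`.
#'
#' @param conf A `conformation` (labels placed).
#' @param restraints List of `epr_restraint` objects.
#' @param params An `energy_params`.
#' @return Total EPR energy (>= 0).
#' @export
epr_energy <- function(conf, restraints, params = energy_params()) {
  if (!length(restraints)) return(0)
  e <- 0
  for (rs in restraints) {
    d <- sqrt(sum((conf$labels[rs$key_a, ] - conf$labels[rs$key_b, ])^2))
    p <- .restraint_density(rs, d, params$p_floor)
    e <- e - params$kT * log(p / rs$p_max)
  }
  e
}

#' Score a conformation (fills the cached energy fields)
#' @param conf A `conformation`.
#' @param restraints List of `epr_restraint`.
#' @param params An `energy_params`.
#' @return The conformation with `e_clash`, `e_epr`, `e_total` set
#'   (`e_total = clash_weight * e_clash + e_epr`).
#' @export
score_conformation <- function(conf, restraints = list(),
                               params = energy_params()) {
  conf$e_clash <- clash_energy(conf, params)
  conf$e_epr <- epr_energy(conf, restraints, params)
  conf$e_total <- params$clash_weight * conf$e_clash + conf$e_epr
  conf
}

#' Define a move set
#'
#' @param backbone data.frame with columns `chain` and `i`: each row is a
#'   virtual backbone bond between beads `i` and `i + 1` (1-based indices
#'   along that chain); a move rotates every bead with index `> i`
#'   rigidly about the axis through C-alpha(i), C-alpha(i+1).
#' @param labels Character vector of site keys (`"<chain>:<resno>"`)
#'   whose tether dihedral may rotate, `TRUE` for all sites, or `FALSE`
#'   for none (backbone-only move sets).
#' @param delta_deg Maximum rotation per move (degrees, default 10).
#' @return A `move_set` object.
#' @export
move_set <- function(backbone = NULL, labels = TRUE, delta_deg = 10) {
  if (!is.null(backbone)) {
    backbone <- as.data.frame(backbone)
    stopifnot(all(c("chain", "i") %in% names(backbone)))
  }
  stopifnot(delta_deg > 0)
  structure(list(backbone = backbone, labels = labels,
                 delta = delta_deg * pi / 180),
            class = "move_set")
}

## canonical element ids, for nesting checks
.moveset_labels <- function(ms, conf) {
  if (isTRUE(ms$labels)) return(names(conf$sites))
  if (is.character(ms$labels)) return(ms$labels)
  character()
}

.moveset_ids <- function(ms, conf) {
  ids <- paste0("lab:", .moveset_labels(ms, conf))
  if (!is.null(ms$backbone) && nrow(ms$backbone)) {
    ids <- c(ids, paste0("bb:", ms$backbone$chain, ":", ms$backbone$i))
  }
  ids
}

## resolve a move set against a conformation into executable elements
.build_elements <- function(conf, ms, fl) {
  elems <- list()
  for (k in .moveset_labels(ms, conf)) {
    if (is.null(conf$sites[[k]])) stop("unknown label site in move set: ", k)
    elems[[length(elems) + 1L]] <- list(type = "label", key = k)
  }
  if (!is.null(ms$backbone)) {
    for (r in seq_len(nrow(ms$backbone))) {
      chn <- as.character(ms$backbone$chain[r])
      i <- as.integer(ms$backbone$i[r])
      ci <- match(chn, fl$chain_names)
      if (is.na(ci)) stop("move set names unknown chain: ", chn)
      nres <- fl$offsets[ci + 1L] - fl$offsets[ci]
      if (i < 1L || i >= nres) {
        stop("backbone bond index ", i, " out of range for chain ", chn)
      }
      off <- fl$offsets[ci]
      moved <- (off + i + 1L):(off + nres)
      ## labels attached to moved residues (their frames rotate rigidly:
      ## the frame reference at i+1 is the axis point C-alpha(i+1))
      moved_labels <- character()
      for (k in names(conf$sites)) {
        s <- conf$sites[[k]]
        if (s$chain == chn &&
            match(s$resno, conf$chains[[chn]]$resno) > i) {
          moved_labels <- c(moved_labels, k)
        }
      }
      total <- fl$offsets[length(fl$offsets)]
      elems[[length(elems) + 1L]] <- list(
        type = "backbone", chain = chn, i = i,
        ax1 = off + i, ax2 = off + i + 1L, moved = moved,
        fixed = setdiff(seq_len(total), moved),
        moved_labels = moved_labels)
    }
  }
  if (!length(elems)) stop("move set resolves to no rotatable elements")
  elems
}

## Rodrigues rotation matrix about unit axis
.rodrigues <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a single rotation move to a conformation
#'
#' For a backbone element at bond (i, i+1) on a chain, every bead with
#' index greater than i (together with any labels attached to those
#' residues) rotates rigidly about the axis through C-alpha(i) and
#' C-alpha(i+1); upstream beads are untouched. For a label element only
#' that label point rotates about its C-alpha to C-beta axis (its
#' dihedral advances by `angle`).
#'
#' @param conf A `conformation`.
#' @param element Either `list(type = "backbone", chain =, i =)` or
#'   `list(type = "label", key =)`.
#' @param angle Rotation angle (radians).
#' @return The rotated `conformation` (energies invalidated).
#' @export
apply_rotation <- function(conf, element, angle) {
  stopifnot(is.finite(angle))
  if (identical(element$type, "label")) {
    k <- element$key
    if (is.null(conf$sites[[k]])) stop("unknown element: label ", k)
    conf$psi[[k]] <- conf$psi[[k]] + angle
    site <- conf$sites[[k]]
    conf$labels[k, ] <- place_label(conf$chains[[site$chain]], site,
                                    conf$psi[[k]])
  } else if (identical(element$type, "backbone")) {
    ch <- conf$chains[[element$chain]]
    if (is.null(ch)) stop("unknown element: chain ", element$chain)
    i <- element$i
    n <- nrow(ch$xyz)
    if (i < 1 || i >= n) stop("unknown element: bond index ", i)
    p0 <- ch$xyz[i, ]
    axis <- ch$xyz[i + 1, ] - p0
    R <- .rodrigues(axis, angle)
    mov <- (i + 1):n
    ch$xyz[mov, ] <- sweep(sweep(ch$xyz[mov, , drop = FALSE], 2, p0) %*%
                             t(R), 2, p0, "+")
    has <- mov[!is.na(ch$cb[mov, 1])]
    if (length(has)) {
      ch$cb[has, ] <- ch$cb[has, , drop = FALSE] %*% t(R)
    }
    conf$chains[[element$chain]] <- ch
    for (k in names(conf$sites)) {
      s <- conf$sites[[k]]
      if (s$chain == element$chain && match(s$resno, ch$resno) > i) {
        conf$labels[k, ] <- place_label(ch, s, conf$psi[[k]])
      }
    }
  } else {
    stop("unknown element type: ", element$type)
  }
  conf$e_clash <- conf$e_epr <- conf$e_total <- NA_real_
  conf
}

#' Monte Carlo sampler configuration
#' @param n_trials Number of trial moves (default 20000).
#' @param seed Integer seed (mandatory).
#' @param temperature Temperature factor multiplying `kT` (default 1; 0
#'   gives greedy, downhill-only acceptance).
#' @param stride Record a conformation snapshot every `stride` trials
#'   (default: ~1000 snapshots across the run).
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_trials = 20000, seed, temperature = 1,
                      stride = max(1L, n_trials %/% 1000L)) {
  stopifnot(n_trials >= 1, temperature >= 0, stride >= 1)
  if (missing(seed)) stop("an integer seed is mandatory")
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 temperature = temperature, stride = as.integer(stride)),
            class = "mc_config")
}

#' Run the Metropolis Monte Carlo sampler
#'
#' Each trial picks a rotatable element uniformly at random, draws a
#' rotation angle uniformly in `[-delta, +delta]`, and accepts by the
#' Metropolis rule on the pseudo-energy
#' `E = clash_weight * E_clash + E_EPR` (accept if the energy does not
#' increase, otherwise with probability `exp(-dE / (kT * temperature))`).
#' Rigid-segment moves leave all distances within the moved and within
#' the fixed segment untouched, so the clash-energy change is computed
#' only over moved-vs-fixed bead pairs.
#'
#' @param initial A `conformation`.
#' @param moveset A `move_set`.
#' @param restraints List of `epr_restraint` (may be empty).
#' @param params An `energy_params`.
#' @param mc An `mc_config`.
#' @return A `conformation_ensemble`: list with
#'   \describe{
#'     \item{samples}{snapshots (each: `xyz`, `cb`, `labels`, `psi`,
#'       `e_clash`, `e_epr`, `e_total`, `trial`).}
#'     \item{energy_trace}{data.frame(trial, e_clash, e_epr, e_total,
#'       accepted), one row per trial.}
#'     \item{distance_trace}{matrix (n_trials x n_restraints) of current
#'       label-label distances, one column per restraint.}
#'     \item{site_trace}{matrix (n_trials x n_tracked_pairs) of
#'       pseudo-C-beta pair distances for `track_pairs`, one value per
#'       generated trial structure (the proposal of that trial, whether
#'       or not it was accepted).}
#'     \item{acceptance}{number of accepted trials.}
#'     \item{flat}{the final state's flattened coordinate bundle.}
#'   }
#' @param track_pairs Optional list of site pairs whose pseudo-C-beta
#'   distance is recorded at every trial (for cross-link feasibility);
#'   each entry `list(a = c(chain, resno), b = c(chain, resno))`.
#' @export
run_mc <- function(initial, moveset, restraints = list(),
                   params = energy_params(), mc, track_pairs = list()) {
  stopifnot(inherits(initial, "conformation"), inherits(moveset, "move_set"),
            inherits(mc, "mc_config"))
  set.seed(mc$seed)
  conf <- initial
  fl <- .flatten(conf)
  elems <- .build_elements(conf, moveset, fl)
  xyz <- fl$xyz; cb <- fl$cb
  chain_vec <- fl$chain; idx_vec <- fl$idx
  count_mode <- params$clash_mode == "count"
  lab_pts <- conf$labels
  psi <- conf$psi
  keys <- names(conf$sites)
  ## site lookup into flat rows
  site_row <- integer(length(keys)); names(site_row) <- keys
  site_ref_row <- integer(length(keys)); names(site_ref_row) <- keys
  for (k in keys) {
    s <- conf$sites[[k]]
    ci <- match(s$chain, fl$chain_names)
    li <- match(s$resno, conf$chains[[s$chain]]$resno)
    site_row[k] <- fl$offsets[ci] + li
    nres <- fl$offsets[ci + 1L] - fl$offsets[ci]
    site_ref_row[k] <- if (nres == 1L) NA_integer_ else
      fl$offsets[ci] + (if (li > 1L) li - 1L else li + 1L)
  }
  place_flat <- function(k) {
    s <- conf$sites[[k]]
    rr <- site_ref_row[k]
    .label_point(xyz[site_row[k], ], cb[site_row[k], ],
                 if (is.na(rr)) NULL else xyz[rr, ],
                 s$L, s$theta_c, psi[[k]])
  }
  rest_d <- function(pts) {
    vapply(restraints, function(rs) {
      sqrt(sum((pts[rs$key_a, ] - pts[rs$key_b, ])^2))
    }, numeric(1))
  }
  epr_of <- function(dvec) {
    if (!length(restraints)) return(0)
    e <- 0
    for (q in seq_along(restraints)) {
      p <- .restraint_density(restraints[[q]], dvec[q], params$p_floor)
      e <- e - params$kT * log(p / restraints[[q]]$p_max)
    }
    e
  }
  flat_row <- function(chain, resno) {
    ci <- match(chain, fl$chain_names)
    if (is.na(ci)) stop("tracked site names unknown chain: ", chain)
    li <- match(as.integer(resno), conf$chains[[chain]]$resno)
    if (is.na(li)) stop("tracked site residue ", resno,
                        " not in chain ", chain)
    fl$offsets[ci] + li
  }
  track_rows <- lapply(track_pairs, function(tp) {
    c(flat_row(tp$a[1], tp$a[2]), flat_row(tp$b[1], tp$b[2]))
  })
  ## pseudo-C-beta pair distances of the *proposed* trial structure:
  ## rows in `mov` take the rotated coordinates
  site_dist_proposal <- function(mov = integer(), new_xyz = NULL, R = NULL) {
    vapply(track_rows, function(rw) {
      pt <- function(r) {
        hit <- match(r, mov)
        if (!is.na(hit)) {
          new_xyz[hit, ] + 1.53 * as.numeric(cb[r, ] %*% t(R))
        } else {
          xyz[r, ] + 1.53 * cb[r, ]
        }
      }
      sqrt(sum((pt(rw[1]) - pt(rw[2]))^2))
    }, numeric(1))
  }
  e_clash <- clash_energy_cpp(xyz, chain_vec, idx_vec, params$clash_cutoff,
                              params$s_min, count_mode)
  d_cur <- rest_d(lab_pts)
  e_epr <- epr_of(d_cur)
  w <- params$clash_weight
  kT_eff <- params$kT * mc$temperature
  nt <- mc$n_trials
  tr_clash <- numeric(nt); tr_epr <- numeric(nt); tr_acc <- logical(nt)
  dist_trace <- matrix(NA_real_, nt, length(restraints))
  site_trace <- matrix(NA_real_, nt, length(track_rows))
  samples <- vector("list", nt %/% mc$stride + 1L)
  n_samp <- 0L; n_acc <- 0L
  nel <- length(elems)

  for (trial in seq_len(nt)) {
    el <- elems[[sample.int(nel, 1L)]]
    angle <- stats::runif(1, -moveset$delta, moveset$delta)
    if (el$type == "label") {
      k <- el$key
      old_psi <- psi[[k]]
      psi[[k]] <- old_psi + angle
      new_pt <- place_flat(k)
      new_lab <- lab_pts; new_lab[k, ] <- new_pt
      d_new <- rest_d(new_lab)
      de <- epr_of(d_new) - e_epr
      accept <- de <= 0 ||
        (kT_eff > 0 && stats::runif(1) < exp(-de / kT_eff))
      if (accept) {
        lab_pts <- new_lab
        e_epr <- e_epr + de
        d_cur <- d_new
        n_acc <- n_acc + 1L
      } else {
        psi[[k]] <- old_psi
      }
    } else {
      p0 <- xyz[el$ax1, ]
      R <- .rodrigues(xyz[el$ax2, ] - p0, angle)
      mov <- el$moved
      old_xyz_m <- xyz[mov, , drop = FALSE]
      new_xyz_m <- sweep(sweep(old_xyz_m, 2, p0) %*% t(R), 2, p0, "+")
      fix <- el$fixed
      e_old_cross <- clash_cross_cpp(old_xyz_m, chain_vec[mov], idx_vec[mov],
                                     xyz[fix, , drop = FALSE], chain_vec[fix],
                                     idx_vec[fix], params$clash_cutoff,
                                     params$s_min, count_mode)
      e_new_cross <- clash_cross_cpp(new_xyz_m, chain_vec[mov], idx_vec[mov],
                                     xyz[fix, , drop = FALSE], chain_vec[fix],
                                     idx_vec[fix], params$clash_cutoff,
                                     params$s_min, count_mode)
      de_clash <- e_new_cross - e_old_cross
      if (length(track_rows)) {
        site_prop <- site_dist_proposal(mov, new_xyz_m, R)
      }
      de_epr <- 0; new_lab <- NULL; d_new <- d_cur
      if (length(el$moved_labels)) {
        old_xyz_save <- xyz; old_cb_save <- cb
        xyz[mov, ] <- new_xyz_m
        has <- mov[!is.na(cb[mov, 1])]
        if (length(has)) cb[has, ] <- cb[has, , drop = FALSE] %*% t(R)
        new_lab <- lab_pts
        for (k in el$moved_labels) new_lab[k, ] <- place_flat(k)
        d_new <- rest_d(new_lab)
        de_epr <- epr_of(d_new) - e_epr
        xyz <- old_xyz_save; cb <- old_cb_save
      }
      de <- w * de_clash + de_epr
      accept <- de <= 0 ||
        (kT_eff > 0 && stats::runif(1) < exp(-de / kT_eff))
      if (accept) {
        xyz[mov, ] <- new_xyz_m
        has <- mov[!is.na(cb[mov, 1])]
        if (length(has)) cb[has, ] <- cb[has, , drop = FALSE] %*% t(R)
        if (!is.null(new_lab)) lab_pts <- new_lab
        e_clash <- e_clash + de_clash
        e_epr <- e_epr + de_epr
        d_cur <- d_new
        n_acc <- n_acc + 1L
      }
    }
    tr_clash[trial] <- e_clash
    tr_epr[trial] <- e_epr
    tr_acc[trial] <- accept
    if (length(restraints)) dist_trace[trial, ] <- d_cur
    if (length(track_rows)) {
      if (el$type == "label") site_prop <- site_dist_proposal()
      site_trace[trial, ] <- site_prop
    }
    if (trial %% mc$stride == 0L) {
      n_samp <- n_samp + 1L
      samples[[n_samp]] <- list(
        xyz = xyz, cb = cb, labels = lab_pts, psi = psi,
        e_clash = e_clash, e_epr = e_epr,
        e_total = w * e_clash + e_epr, trial = trial)
    }
  }
  structure(list(
    samples = samples[seq_len(n_samp)],
    energy_trace = data.frame(trial = seq_len(nt), e_clash = tr_clash,
                              e_epr = tr_epr,
                              e_total = w * tr_clash + tr_epr,
                              accepted = tr_acc),
    distance_trace = dist_trace,
    site_trace = site_trace,
    acceptance = n_acc,
    n_trials = nt,
    seed = mc$seed,
    stride = mc$stride,
    flat = list(chain = chain_vec, idx = idx_vec,
                offsets = fl$offsets, chain_names = fl$chain_names,
                resno = unlist(lapply(conf$chains, function(ch) ch$resno),
                               use.names = FALSE)),
    sites = conf$sites
  ), class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("conformation_ensemble:", x$n_trials, "trials,",
      length(x$samples), "snapshots, acceptance",
      sprintf("%.1f%%", 100 * x$acceptance / x$n_trials), "\n")
  invisible(x)
}

#' Per-snapshot label-label distances in an ensemble
#' @param ens A `conformation_ensemble`.
#' @param key_a,key_b Site keys (`"<chain>:<resno>"`).
#' @return Numeric vector, one distance per snapshot (Angstrom).
#' @export
ensemble_label_distances <- function(ens, key_a, key_b) {
  vapply(ens$samples, function(s) {
    sqrt(sum((s$labels[key_a, ] - s$labels[key_b, ])^2))
  }, numeric(1))
}

#' Write an ensemble as a multi-model CA-only PDB file
#'
#' Beads are written as CA atoms of their chains inside MODEL/ENDMDL
#' blocks; label points go into pseudo-chain "Z" as atoms named "NO1".
#'
#' @param ens A `conformation_ensemble`.
#' @param path Output path.
#' @param max_models Cap on the number of MODEL blocks (default 100,
#'   evenly thinned).
#' @export
write_ensemble_pdb <- function(ens, path, max_models = 100) {
  pick <- unique(round(seq(1, length(ens$samples),
                           length.out = min(max_models,
                                            length(ens$samples)))))
  con <- file(path, "w")
  on.exit(close(con))
  fl <- ens$flat
  for (mi in seq_along(pick)) {
    s <- ens$samples[[pick[mi]]]
    writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (ci in seq_along(fl$chain_names)) {
      rows <- which(fl$chain == ci)
      for (r in rows) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, substr(fl$chain_names[ci], 1, 1), fl$resno[r],
          s$xyz[r, 1], s$xyz[r, 2], s$xyz[r, 3]), con)
      }
    }
    if (!is.null(s$labels) && nrow(s$labels)) {
      for (li in seq_len(nrow(s$labels))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  NO1 NIT Z%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
          serial, li, s$labels[li, 1], s$labels[li, 2], s$labels[li, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
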