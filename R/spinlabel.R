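#' Declare a spin-label site
#'
#' A geometric tether-cone model of a nitroxide label (MTSL-like)
#' attached at a residue: the unpaired electron sits at tether length `L`
#' from a pseudo-C-beta, on a cone of half-angle `theta_c` about the
#' C-alpha to C-beta axis, parameterized by a single dihedral.
#'
#' @param chain Chain identifier.
#' @param resno Author residue number of the labelled residue.
#' @param L Tether length from the pseudo-C-beta (Angstrom, default 6.0).
#' @param theta_c Cone half-angle off the C-alpha to C-beta axis
#'   (degrees, default 55; must be in (0, 90)).
#' @param exclusion Clash exclusion radius against bead centres
#'   (Angstrom, default 3.5).
#' @return A `label_site` object.
#' @details Defaults give a mean C-alpha to label distance of about 7
#'   Angstrom, typical of MTSL rotamer clouds. This single-dihedral model
#'   replaces a full rotamer library: the bead representation carries no
#'   side-chain atoms, and the distance distributions it feeds are only
#'   compared with EPR distributions at the Angstrom scale.
#' @export
label_site <- function(chain, resno, L = 6.0, theta_c = 55, exclusion = 3.5) {
  stopifnot(L > 0, theta_c > 0, theta_c < 90, exclusion >= 0)
  structure(list(chain = chain, resno = as.integer(resno), L = L,
                 theta_c = theta_c, exclusion = exclusion),
            class = "label_site")
}

## local orthonormal frame at a labelled residue; rigid-body equivariant
## (built from the Cb direction and the direction to a neighbouring Ca)
.site_frame <- function(chain, idx) {
  u <- chain$cb[idx, ]
  if (anyNA(u)) stop("residue ", chain$resno[idx],
                     " has no C-beta direction (glycine?)")
  n <- nrow(chain$xyz)
  if (n > 1) {
    ref_idx <- if (idx > 1) idx - 1L else idx + 1L
    w <- chain$xyz[ref_idx, ] - chain$xyz[idx, ]
  } else {
    ## isolated residue: arbitrary but deterministic reference
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  v1 <- w - sum(w * u) * u
  nv <- sqrt(sum(v1^2))
  if (nv < 1e-9) stop("degenerate frame: neighbour C-alpha along Cb axis")
  v1 <- v1 / nv
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  list(u = u, v1 = v1, v2 = v2)
}

#' Place a spin label for a given dihedral
#'
#' Deterministically positions the label point: pseudo-C-beta at 1.53
#' Angstrom from the C-alpha along the C-beta direction, then the label at
#' distance `L` from it, at cone half-angle `theta_c` off the axis,
#' rotated by dihedral `psi` about the axis.
#'
#' @param chain A `bead_chain` containing the site's residue.
#' @param site A `label_site`.
#' @param psi Dihedral angle about the C-alpha to C-beta axis (radians).
#' @return Length-3 numeric label position (Angstrom).
#' @export
place_label <- function(chain, site, psi) {
  idx <- match(site$resno, chain$resno)
  if (is.na(idx)) stop("site residue ", site$resno,
                       " not found in chain ", chain$id)
  fr <- .site_frame(chain, idx)
  th <- site$theta_c * pi / 180
  pcb <- chain$xyz[idx, ] + 1.53 * fr$u
  dir <- cos(th) * fr$u + sin(th) * (cos(psi) * fr$v1 + sin(psi) * fr$v2)
  as.numeric(pcb + site$L * dir)
}

#' Pseudo-C-beta attachment point of a site
#' @param chain A `bead_chain`.
#' @param site A `label_site` (or a list with `resno`).
#' @return Length-3 numeric position (Angstrom).
#' @export
pseudo_cbeta <- function(chain, site) {
  idx <- match(site$resno, chain$resno)
  if (is.na(idx)) stop("site residue ", site$resno,
                       " not found in chain ", chain$id)
  u <- chain$cb[idx, ]
  if (anyNA(u)) stop("residue ", site$resno, " has no C-beta direction")
  as.numeric(chain$xyz[idx, ] + 1.53 * u)
}

#' Sample a sterically allowed rotamer cloud
#'
#' Evaluates the label position on a uniform grid of the tether dihedral
#' and removes positions clashing with any bead (other than the site's own
#' residue and its two sequence neighbours). Surviving positions get equal
#' weight.
#'
#' @param chains A single `bead_chain` or a list of them (the whole
#'   environment the label can clash with).
#' @param site A `label_site`; its residue must live in one of `chains`.
#' @param n Number of dihedral grid points (default 36).
#' @return A `label_cloud` object: list with `positions` (M x 3),
#'   `weights` (length M, summing to 1) and `site`.
#' @export
sample_rotamers <- function(chains, site, n = 36) {
  stopifnot(n >= 1)
  if (inherits(chains, "bead_chain")) chains <- list(chains)
  host <- NULL
  for (ch in chains) {
    if (ch$id == site$chain && site$resno %in% ch$resno) host <- ch
  }
  if (is.null(host)) stop("site chain/residue not found among chains")
  psi <- 2 * pi * (seq_len(n) - 1) / n
  pos <- t(vapply(psi, function(p) place_label(host, site, p), numeric(3)))
  keep <- rep(TRUE, n)
  idx <- match(site$resno, host$resno)
  for (ch in chains) {
    exempt <- if (identical(ch$id, host$id)) {
      which(abs(seq_len(nrow(ch$xyz)) - idx) <= 1)
    } else integer()
    beads <- ch$xyz
    if (length(exempt)) beads <- beads[-exempt, , drop = FALSE]
    if (!nrow(beads)) next
    for (m in which(keep)) {
      d2 <- min(colSums((t(beads) - pos[m, ])^2))
      if (d2 < site$exclusion^2) keep[m] <- FALSE
    }
  }
  if (!any(keep)) stop("all rotamers clash: site ", site$resno,
                       " on chain ", site$chain, " appears buried")
  structure(list(positions = pos[keep, , drop = FALSE],
                 weights = rep(1 / sum(keep), sum(keep)),
                 site = site),
            class = "label_cloud")
}

#' Construct a distance distribution on a uniform grid
#'
#' @param r Strictly increasing, uniformly spaced distance grid (Angstrom).
#' @param p Non-negative density values; renormalized so that
#'   `sum(p) * dr == 1`.
#' @return A `distance_distribution` object: list with `r`, `p`, `dr`.
#' @export
distance_distribution <- function(r, p) {
  stopifnot(length(r) == length(p), length(r) >= 2)
  dr <- diff(r)
  if (any(dr <= 0) || max(abs(dr - dr[1])) > 1e-8 * dr[1]) {
    stop("grid must be strictly increasing and uniform")
  }
  if (any(p < 0)) stop("density must be non-negative")
  s <- sum(p) * dr[1]
  if (s <= 0) stop("density must have positive mass")
  structure(list(r = r, p = p / s, dr = dr[1]),
            class = "distance_distribution")
}

#' Default distance grid, 10--100 Angstrom in 0.5 Angstrom steps
#'
#' Covers the intramonomer (20--30 A), intermonomer (40--60 A) and
#' crystal-dimer (>= 80 A) distance regimes.
#' @return Numeric grid vector.
#' @export
default_r_grid <- function() seq(10, 100, by = 0.5)

#' Mean of a distance distribution
#' @param d A `distance_distribution`.
#' @return Mean distance (Angstrom).
#' @export
dist_mean <- function(d) sum(d$r * d$p) * d$dr

#' Mode(s) of a distance distribution
#' @param d A `distance_distribution`.
#' @param all If `TRUE` return all local maxima above `min_height` times
#'   the global maximum; otherwise the single global mode.
#' @param min_height Relative height threshold for secondary modes.
#' @return Distance(s) at the mode(s) (Angstrom).
#' @export
dist_mode <- function(d, all = FALSE, min_height = 0.2) {
  if (!all) return(d$r[which.max(d$p)])
  p <- d$p; n <- length(p)
  loc <- which(p > c(-Inf, p[-n]) & p >= c(p[-1], -Inf) &
                 p >= min_height * max(p))
  d$r[loc]
}

#' Label-label distance distribution from two rotamer clouds
#'
#' Weighted histogram of all pairwise distances between two clouds, with
#' product weights, binned onto a uniform grid.
#'
#' @param cloud_a,cloud_b `label_cloud` objects.
#' @param r_grid Uniform distance grid (default [default_r_grid()]).
#' @return A `distance_distribution`.
#' @export
pair_distance_distribution <- function(cloud_a, cloud_b,
                                       r_grid = default_r_grid()) {
  pa <- cloud_a$positions; pb <- cloud_b$positions
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  w <- outer(cloud_a$weights, cloud_b$weights)
  hist_from_samples(as.numeric(d), as.numeric(w), r_grid)
}

#' Histogram weighted distance samples onto a distribution grid
#' @param d Distance samples (Angstrom).
#' @param w Non-negative weights (recycled to length of `d`).
#' @param r_grid Uniform grid; samples must fall within half a bin of it.
#' @return A `distance_distribution`.
#' @export
hist_from_samples <- function(d, w = 1, r_grid = default_r_grid()) {
  w <- rep_len(w, length(d))
  dr <- r_grid[2] - r_grid[1]
  if (any(d < r_grid[1] - dr / 2 | d > r_grid[length(r_grid)] + dr / 2)) {
    stop("distance(s) outside grid [", r_grid[1], ", ",
         r_grid[length(r_grid)], "] Angstrom: extend the grid")
  }
  bin <- pmin(pmax(round((d - r_grid[1]) / dr) + 1L, 1L), length(r_grid))
  p <- as.numeric(tapply(w, factor(bin, levels = seq_along(r_grid)), sum))
  p[is.na(p)] <- 0
  distance_distribution(r_grid, p)
}

#' Write a distribution (or any x/y pair) as two-column text
#' @param x Object with two columns to write: a `distance_distribution`
#'   (r, p), a `deer_trace` (t, V) or a 2-column matrix.
#' @param path Output file path.
#' @param col_names Column header, written as a `#`-prefixed comment.
#' @export
write_xy <- function(x, path, col_names = NULL) {
  if (inherits(x, "distance_distribution")) {
    m <- cbind(x$r, x$p)
    if (is.null(col_names)) col_names <- c("r_angstrom", "p")
  } else if (inherits(x, "deer_trace")) {
    m <- cbind(x$t, x$V)
    if (is.null(col_names)) col_names <- c("t_us", "V")
  } else {
    m <- as.matrix(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(col_names)) {
    writeLines(paste0("# ", paste(col_names, collapse = "\t")), con)
  }
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' Read a two-column text file written by [write_xy()]
#' @param path Input file path.
#' @return 2-column numeric matrix.
#' @export
read_xy <- function(path) {
  as.matrix(utils::read.table(path, comment.char = "#"))
}
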