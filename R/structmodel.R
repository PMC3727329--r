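#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM coordinate records of the first MODEL of a PDB file
#' into an `atomic_structure` object. Alternate locations are resolved to
#' the highest-occupancy conformer, and SEQRES records are retained so the
#' construct mass can be computed from the deposited sequence.
#'
#' @param path Path to a PDB-format file, or a character vector of PDB
#'   lines (anything containing a newline, or of length > 1, is treated as
#'   literal content).
#' @return An object of class `atomic_structure`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with columns `chain`, `resno`, `resid`,
#'       `elety`, `x`, `y`, `z`, `o` (occupancy), one row per atom.}
#'     \item{seqres}{named list, 3-letter residue codes per chain (may be
#'       empty if the file carries no SEQRES records).}
#'   }
#' @details Only the first MODEL block is used: the deposited structures
#'   this analysis targets are single-model crystal structures, and NCS
#'   copies live in separate chains, not MODEL blocks. HETATM records are
#'   dropped (waters, ions and ligands carry no backbone).
#' @export
read_structure <- function(path) {
  if (length(path) > 1L || grepl("\n", path, fixed = TRUE)) {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE))
  } else {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    lines <- readLines(path, warn = FALSE)
  }
  .validate_pdb_lines(lines)

  ## first MODEL only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) >= 1L) {
    endmdl <- grep("^ENDMDL", lines)
    stop_at <- if (length(endmdl)) endmdl[1] else length(lines)
    coord_region <- seq(model_starts[1], stop_at)
  } else {
    coord_region <- seq_along(lines)
  }

  seqres <- .parse_seqres(lines)

  sel <- coord_region[grepl("^ATOM  ", lines[coord_region])]
  if (!length(sel)) stop("no ATOM records found: empty structure")
  atoms <- .parse_atom_lines(lines[sel])

  ## altloc: keep highest occupancy per (chain, resno, elety)
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, seqres = seqres), class = "atomic_structure")
}

.validate_pdb_lines <- function(lines) {
  coord <- grep("^(ATOM  |HETATM)", lines)
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed coordinate line ", i, ": shorter than 54 columns")
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      stop("malformed coordinate line ", i, ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

.parse_atom_lines <- function(ln) {
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(substr(ln, 23, 26)),
    resid = trimws(substr(ln, 18, 20)),
    elety = trimws(substr(ln, 13, 16)),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    o = occ,
    stringsAsFactors = FALSE
  )
}

.parse_seqres <- function(lines) {
  sr <- lines[grepl("^SEQRES", lines)]
  if (!length(sr)) return(list())
  ch <- trimws(substr(sr, 12, 12))
  out <- lapply(split(sr, ch), function(blk) {
    unlist(lapply(blk, function(l) {
      strsplit(trimws(substr(l, 20, 70)), "\\s+")[[1]]
    }))
  })
  out
}

#' Coarse-grain one chain to a bead model
#'
#' Reduces a chain to one sphere per residue centred at the C-alpha atom,
#' keeping the C-alpha to C-beta direction as a unit vector so that
#' spin-label tethers can be attached later. Glycine carries no C-beta and
#' gets an undefined direction.
#'
#' @param struct An `atomic_structure` from [read_structure()].
#' @param chain_id Single chain identifier.
#' @return A `bead_chain` object: list with `id` (chain id), `xyz`
#'   (N x 3 matrix of C-alpha positions, Angstrom), `cb` (N x 3 matrix of
#'   unit C-alpha to C-beta directions, `NA` rows where undefined),
#'   `resno` (author residue numbers) and `resid` (3-letter residue types).
#' @export
coarse_grain <- function(struct, chain_id) {
  stopifnot(inherits(struct, "atomic_structure"))
  at <- struct$atoms[struct$atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop("chain not found: ", chain_id)
  resnos <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(resnos, ca$resno)
  if (length(missing_ca) > 0.2 * length(resnos)) {
    stop("chain ", chain_id, ": more than 20% of residues lack CA; ",
         "likely not a protein chain")
  }
  if (length(missing_ca)) {
    warning("chain ", chain_id, ": skipping ", length(missing_ca),
            " residue(s) lacking CA: ",
            paste(utils::head(missing_ca, 5), collapse = ", "))
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  cb <- at[at$elety == "CB", , drop = FALSE]
  n <- nrow(ca)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  cbm <- matrix(NA_real_, n, 3)
  m <- match(ca$resno, cb$resno)
  has <- !is.na(m)
  if (any(has)) {
    v <- as.matrix(cb[m[has], c("x", "y", "z")]) - xyz[has, , drop = FALSE]
    cbm[has, ] <- v / sqrt(rowSums(v^2))
  }
  bead_chain(xyz, cb = cbm, resno = ca$resno, resid = ca$resid,
             id = chain_id)
}

#' Construct a bead chain
#'
#' @param xyz N x 3 matrix of C-alpha positions (Angstrom).
#' @param cb N x 3 matrix of unit C-alpha to C-beta directions; rows of
#'   `NA` mark residues (glycine) without a defined direction.
#' @param resno Author residue numbers (strictly increasing integers).
#' @param resid 3-letter residue type codes.
#' @param id Chain identifier.
#' @param check Validate geometric invariants (consecutive C-alpha spacing
#'   in 2.8--4.3 Angstrom, unit `cb` rows). Default `TRUE`.
#' @return A `bead_chain` object.
#' @export
bead_chain <- function(xyz, cb = NULL, resno = seq_len(nrow(xyz)),
                       resid = rep("ALA", nrow(xyz)), id = "A",
                       check = TRUE) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  n <- nrow(xyz)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3)
  cb <- as.matrix(cb)
  resno <- as.integer(resno)
  if (check) {
    if (any(!is.finite(xyz))) stop("non-finite bead coordinates")
    if (any(diff(resno) <= 0L)) stop("residue numbers must strictly increase")
    if (n > 1) {
      d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
      if (any(d < 2.8 | d > 4.3)) {
        stop("consecutive C-alpha spacing outside [2.8, 4.3] Angstrom ",
             "(worst: ", signif(d[which.max(abs(d - 3.8))], 4), ")")
      }
    }
    has <- !is.na(cb[, 1])
    if (any(has)) {
      nn <- sqrt(rowSums(cb[has, , drop = FALSE]^2))
      if (any(abs(nn - 1) > 1e-6)) stop("cb directions must have unit norm")
    }
  }
  structure(list(id = id, xyz = xyz, cb = cb, resno = resno, resid = resid),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat("bead_chain", x$id, ":", nrow(x$xyz), "residues, resno",
      x$resno[1], "-", x$resno[length(x$resno)], "\n")
  invisible(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of point
#' set `a` onto point set `b`. Reflections are excluded: the rotation
#' always has determinant +1, so a mirrored set yields the best proper
#' rotation with a non-zero residual.
#'
#' @param a,b N x 3 coordinate matrices (Angstrom), matched row-by-row,
#'   N >= 3.
#' @return A `superposition` object: list with `rotation` (3 x 3),
#'   `translation` (length-3), `rmsd` (Angstrom) and `n` (atoms used).
#'   The transform maps `a` onto `b` as `a %*% t(rotation) + translation`
#'   (row-vector convention).
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) {
    stop("coordinate sets must be N x 3 matrices of equal size")
  }
  n <- nrow(a)
  if (n < 3) stop("need at least 3 points to superpose")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (max(svd(ac)$d[2], svd(bc)$d[2]) < 1e-8) {
    stop("degenerate (collinear) point set")
  }
  h <- crossprod(ac, bc)               # sum over i of a_i b_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cb - r %*% ca)
  fitted <- ac %*% t(r)                # centred fit
  rmsd <- sqrt(mean(rowSums((fitted - bc)^2)))
  structure(list(rotation = r, translation = t_vec, rmsd = rmsd, n = n),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param sp A `superposition`.
#' @param x N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, x) {
  sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Pairwise C-alpha RMSD matrix across NCS copies
#'
#' For every pair of chains, superposes the C-alpha positions of residues
#' present in both chains (matched by author residue number) and records
#' the superposition RMSD. This is the standard measure of how similar
#' independent copies of a molecule in one asymmetric unit are.
#'
#' @param chains List of `bead_chain` objects (>= 2).
#' @return Symmetric matrix of RMSD values (Angstrom) with zero diagonal;
#'   entries with fewer than 3 shared residues are `NA`.
#' @export
pairwise_ca_rmsd <- function(chains) {
  stopifnot(length(chains) >= 2)
  k <- length(chains)
  ids <- vapply(chains, function(ch) ch$id, "")
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      shared <- intersect(chains[[i]]$resno, chains[[j]]$resno)
      if (length(shared) < 3) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      ai <- chains[[i]]$xyz[match(shared, chains[[i]]$resno), , drop = FALSE]
      bj <- chains[[j]]$xyz[match(shared, chains[[j]]$resno), , drop = FALSE]
      m[i, j] <- m[j, i] <- superpose(ai, bj)$rmsd
    }
  }
  m
}

#' Define a domain partition
#'
#' @param domains Named list mapping a domain label (e.g. `"J"`, `"GF"`,
#'   `"CTD"`, `"linker"`) to the author residue numbers it contains.
#'   Labels must not overlap.
#' @param hinge Integer vector of author residue numbers whose backbone
#'   virtual bonds are rotatable; must be contiguous.
#' @return A `domain_partition` object.
#' @export
domain_partition <- function(domains, hinge = integer()) {
  stopifnot(is.list(domains), !is.null(names(domains)))
  all_res <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(all_res)) stop("domain labels overlap")
  hinge <- as.integer(hinge)
  if (length(hinge) && any(diff(sort(hinge)) != 1L)) {
    stop("hinge residues must be contiguous")
  }
  structure(list(domains = lapply(domains, as.integer), hinge = hinge),
            class = "domain_partition")
}

#' Interdomain rotation angle between two conformers
#'
#' Superposes conformer `a` onto conformer `b` on the C-alpha atoms of a
#' reference domain, then finds the residual rotation carrying the moving
#' domain of `a` onto that of `b`. The angle is extracted from the
#' rotation-matrix trace. This is a fixed-partition analysis: the hinge
#' location is an input, not searched for.
#'
#' @param chain_a,chain_b `bead_chain` conformers of the same molecule.
#' @param partition A `domain_partition` keyed by author residue number.
#' @param reference,moving Domain labels in `partition`.
#' @return A `domain_rotation` object: list with `angle` (degrees, in
#'   `[0, 180]`), `axis` (unit 3-vector), `reference`, `moving`.
#' @export
domain_rotation <- function(chain_a, chain_b, partition, reference, moving) {
  stopifnot(inherits(partition, "domain_partition"))
  get_dom <- function(ch, lab) {
    shared <- intersect(intersect(chain_a$resno, chain_b$resno),
                        partition$domains[[lab]])
    if (length(shared) < 3) stop("fewer than 3 shared residues in domain ", lab)
    ch$xyz[match(shared, ch$resno), , drop = FALSE]
  }
  ref_a <- get_dom(chain_a, reference); ref_b <- get_dom(chain_b, reference)
  mov_a <- get_dom(chain_a, moving);    mov_b <- get_dom(chain_b, moving)
  sp_ref <- superpose(ref_a, ref_b)
  mov_a_fit <- apply_superposition(sp_ref, mov_a)
  sp_mov <- superpose(mov_a_fit, mov_b)
  r <- sp_mov$rotation
  cosang <- (sum(diag(r)) - 1) / 2
  angle <- acos(max(-1, min(1, cosang))) * 180 / pi
  axis <- .rotation_axis(r)
  structure(list(angle = angle, axis = axis,
                 reference = reference, moving = moving),
            class = "domain_rotation")
}

.rotation_axis <- function(r) {
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    ## angle ~ 0 or 180: take dominant eigenvector of (R + I)
    e <- eigen(r + diag(3), symmetric = FALSE)
    v <- Re(e$vectors[, which.max(abs(Re(e$values)))])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(c(0, 0, 1))
  }
  v / nv
}

## side-chain polar heavy atoms: donor (carries H) / acceptor capability
.POLAR_SIDECHAIN <- list(
  SER = list(OG  = c(TRUE,  TRUE)),
  THR = list(OG1 = c(TRUE,  TRUE)),
  TYR = list(OH  = c(TRUE,  TRUE)),
  CYS = list(SG  = c(TRUE,  TRUE)),
  ASN = list(OD1 = c(FALSE, TRUE), ND2 = c(TRUE, FALSE)),
  GLN = list(OE1 = c(FALSE, TRUE), NE2 = c(TRUE, FALSE)),
  ASP = list(OD1 = c(FALSE, TRUE), OD2 = c(FALSE, TRUE)),
  GLU = list(OE1 = c(FALSE, TRUE), OE2 = c(FALSE, TRUE)),
  LYS = list(NZ  = c(TRUE,  FALSE)),
  ARG = list(NE  = c(TRUE, FALSE), NH1 = c(TRUE, FALSE),
             NH2 = c(TRUE, FALSE)),
  HIS = list(ND1 = c(TRUE,  TRUE), NE2 = c(TRUE, TRUE)),
  TRP = list(NE1 = c(TRUE,  FALSE))
)

#' Enumerate interdomain side-chain hydrogen-bond pairs
#'
#' Lists residue pairs lying in two different domains whose side-chain
#' polar heavy atoms (N*, O* and the cysteine S) approach within a cutoff,
#' with one atom able to donate and the other to accept. A purely
#' distance-based criterion is used (no donor-H angle term); each residue
#' pair is reported once with its closest qualifying atom pair.
#'
#' @param struct An `atomic_structure`.
#' @param chain_id Chain to analyse.
#' @param partition A `domain_partition` keyed by author residue number.
#' @param domain_a,domain_b The two domain labels to bridge.
#' @param cutoff Heavy-atom distance cutoff (Angstrom, default 3.5).
#' @return data.frame with columns `resno_a`, `resid_a`, `atom_a`,
#'   `resno_b`, `resid_b`, `atom_b`, `dist`.
#' @export
interdomain_hbond_pairs <- function(struct, chain_id, partition,
                                    domain_a, domain_b, cutoff = 3.5) {
  stopifnot(inherits(struct, "atomic_structure"))
  at <- struct$atoms[struct$atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop("chain not found: ", chain_id)
  polar <- .polar_atoms(at)
  pa <- polar[polar$resno %in% partition$domains[[domain_a]], , drop = FALSE]
  pb <- polar[polar$resno %in% partition$domains[[domain_b]], , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      dvec <- c(pa$x[i] - pb$x[j], pa$y[i] - pb$y[j], pa$z[i] - pb$z[j])
      d <- sqrt(sum(dvec^2))
      ok_chem <- (pa$donor[i] && pb$acceptor[j]) ||
                 (pb$donor[j] && pa$acceptor[i])
      if (d <= cutoff && ok_chem) {
        key <- paste(pa$resno[i], pb$resno[j])
        if (is.null(out[[key]]) || d < out[[key]]$dist) {
          out[[key]] <- data.frame(
            resno_a = pa$resno[i], resid_a = pa$resid[i], atom_a = pa$elety[i],
            resno_b = pb$resno[j], resid_b = pb$resid[j], atom_b = pb$elety[j],
            dist = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(resno_a = integer(), resid_a = character(),
                      atom_a = character(), resno_b = integer(),
                      resid_b = character(), atom_b = character(),
                      dist = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$resno_a, res$resno_b), , drop = FALSE]
}

.polar_atoms <- function(at) {
  keep <- logical(nrow(at))
  donor <- logical(nrow(at)); acceptor <- logical(nrow(at))
  for (i in seq_len(nrow(at))) {
    tab <- .POLAR_SIDECHAIN[[at$resid[i]]]
    if (!is.null(tab) && !is.null(tab[[at$elety[i]]])) {
      keep[i] <- TRUE
      donor[i] <- tab[[at$elety[i]]][1]
      acceptor[i] <- tab[[at$elety[i]]][2]
    }
  }
  cbind(at[keep, , drop = FALSE],
        donor = donor[keep], acceptor = acceptor[keep])
}

## ExPASy average residue masses (Da); peptide-bonded residues
.RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water, as used to check
#' a construct's identity against mass spectrometry.
#'
#' @param sequence 1-letter amino-acid string (standard residues).
#' @return Mass in Dalton.
#' @export
average_mass <- function(sequence) {
  if (nchar(sequence) == 0) return(.WATER_MASS)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  sum(.RESIDUE_MASS[aa]) + .WATER_MASS
}

## 3-letter -> 1-letter for SEQRES-derived sequences
.AA3TO1 <- c(
  GLY = "G", ALA = "A", SER = "S", PRO = "P", VAL = "V", THR = "T",
  CYS = "C", LEU = "L", ILE = "I", ASN = "N", ASP = "D", GLN = "Q",
  LYS = "K", GLU = "E", MET = "M", HIS = "H", PHE = "F", ARG = "R",
  TYR = "Y", TRP = "W"
)

#' Extract a chain's 1-letter sequence from SEQRES records
#' @param struct An `atomic_structure`.
#' @param chain_id Chain identifier.
#' @return 1-letter amino-acid string.
#' @export
seqres_sequence <- function(struct, chain_id) {
  sr <- struct$seqres[[chain_id]]
  if (is.null(sr)) stop("no SEQRES records for chain ", chain_id)
  one <- .AA3TO1[sr]
  if (anyNA(one)) stop("non-standard residue in SEQRES: ",
                       paste(unique(sr[is.na(one)]), collapse = ", "))
  paste(one, collapse = "")
}
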