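#' Specify a cross-link between two sites
#'
#' Models a short bifunctional Cys-Cys linker (nominally ~11 Angstrom,
#' e.g. bismaleimidobutane) as a feasibility threshold on the distance
#' between the two attachment points: a conformation can be cross-linked
#' when the sites' pseudo-C-beta positions are within the threshold.
#'
#' @param site_a,site_b Each `c(chain, resno)` (or a `label_site`);
#'   typically the same residue number on the two monomers of a dimer.
#' @param threshold Feasibility threshold T (Angstrom, default 12).
#' @param linker Linker name (default `"BMB"`).
#' @param linker_length Nominal linker span (Angstrom, default 11).
#' @return A `crosslink_spec` object.
#' @export
crosslink_spec <- function(site_a, site_b, threshold = 12,
                           linker = "BMB", linker_length = 11) {
  norm_site <- function(s) {
    if (inherits(s, "label_site")) c(s$chain, s$resno)
    else c(as.character(s[1]), as.character(s[2]))
  }
  a <- norm_site(site_a); b <- norm_site(site_b)
  if (identical(a, b)) stop("cross-link sites must be distinct")
  stopifnot(threshold > 0)
  structure(list(a = a, b = b, threshold = threshold, linker = linker,
                 linker_length = linker_length),
            class = "crosslink_spec")
}

#' Distance between the two cross-link attachment points
#'
#' Scored at the pseudo-C-beta positions (1.53 Angstrom from the C-alpha
#' along the C-beta direction), where the maleimide chemistry attaches.
#'
#' @param conf A `conformation`.
#' @param spec A `crosslink_spec`.
#' @return Distance (Angstrom).
#' @export
site_distance <- function(conf, spec) {
  pt <- function(s) {
    ch <- conf$chains[[s[1]]]
    if (is.null(ch)) stop("cross-link site chain missing: ", s[1])
    pseudo_cbeta(ch, list(resno = as.integer(s[2])))
  }
  sqrt(sum((pt(spec$a) - pt(spec$b))^2))
}

## per-trial (preferred) or per-snapshot distances for a spec
.ensemble_site_distances <- function(ens, spec) {
  key <- paste(spec$a[1], spec$a[2], spec$b[1], spec$b[2])
  if (!is.null(ens$site_trace) && ncol(ens$site_trace) &&
      !is.null(colnames(ens$site_trace))) {
    hit <- match(key, colnames(ens$site_trace))
    if (!is.na(hit)) return(ens$site_trace[, hit])
  }
  fl <- ens$flat
  row_of <- function(s) {
    ci <- match(s[1], fl$chain_names)
    if (is.na(ci)) stop("cross-link site chain missing: ", s[1])
    rows <- which(fl$chain == ci)
    r <- rows[match(as.integer(s[2]), fl$resno[rows])]
    if (is.na(r)) stop("cross-link site residue missing: ", s[2])
    r
  }
  ra <- row_of(spec$a); rb <- row_of(spec$b)
  vapply(ens$samples, function(sm) {
    pa <- sm$xyz[ra, ] + 1.53 * sm$cb[ra, ]
    pb <- sm$xyz[rb, ] + 1.53 * sm$cb[rb, ]
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
}

#' Cross-link feasibility of an ensemble
#'
#' Checks the occurrence of conformations in which the two cross-linking
#' sites approach within the linker threshold during the Monte Carlo run.
#' Per-trial distances are used when the run tracked this pair
#' (`track_pairs` in [run_mc()]); otherwise the recorded snapshots.
#'
#' @param ens A `conformation_ensemble`.
#' @param spec A `crosslink_spec`.
#' @return List with `fraction` (of structures with `d <= threshold`),
#'   `feasible` (`fraction > 0`), `min_dist` (Angstrom) and `n` (number
#'   of structures examined).
#' @export
feasibility <- function(ens, spec) {
  d <- .ensemble_site_distances(ens, spec)
  if (!length(d)) stop("ensemble holds no structures to examine")
  frac <- mean(d <= spec$threshold)
  list(fraction = frac, feasible = frac > 0, min_dist = min(d),
       n = length(d))
}

#' Progressive-flexibility cross-link scan
#'
#' Runs one Monte Carlo simulation per move set, from the most
#' constrained (label dihedrals only) to progressively more backbone
#' freedom, and reports which move sets produce conformations with the
#' cross-linking sites within the linker threshold. Each move set is run
#' with several seeds and a majority consensus stabilizes the stochastic
#' feasibility verdict; the move sets must be strictly nested (each a
#' superset of the previous).
#'
#' @param initial A `conformation`.
#' @param movesets Named list of `move_set` objects, ordered, nested.
#' @param restraints List of `epr_restraint`.
#' @param params An `energy_params`.
#' @param spec A `crosslink_spec`.
#' @param mc An `mc_config` (its seed is the base; run s uses
#'   `seed + s - 1`).
#' @param n_seeds Seeds per move set (default 5).
#' @return A `flexibility_scan` object: `per_run` data.frame (moveset,
#'   seed, fraction, min_dist, feasible), `consensus` data.frame
#'   (moveset, feasible runs, consensus verdict, pooled fraction, min
#'   distance), and `first_feasible` (label of the first move set whose
#'   consensus is feasible, or `NA`).
#' @export
flexibility_scan <- function(initial, movesets, restraints = list(),
                             params = energy_params(), spec, mc,
                             n_seeds = 5) {
  if (!length(movesets)) stop("empty move-set list")
  if (is.null(names(movesets)) || any(names(movesets) == "")) {
    names(movesets) <- paste0("moveset_", seq_along(movesets))
  }
  ids <- lapply(movesets, .moveset_ids, conf = initial)
  for (m in seq_along(ids)[-1]) {
    if (!all(ids[[m - 1]] %in% ids[[m]])) {
      stop("move sets must be nested: '", names(movesets)[m],
           "' does not contain '", names(movesets)[m - 1], "'")
    }
  }
  tp <- list(list(a = spec$a, b = spec$b))
  key <- paste(spec$a[1], spec$a[2], spec$b[1], spec$b[2])
  per_run <- list()
  for (m in seq_along(movesets)) {
    for (s in seq_len(n_seeds)) {
      mcs <- mc_config(n_trials = mc$n_trials, seed = mc$seed + s - 1L,
                       temperature = mc$temperature, stride = mc$stride)
      ens <- run_mc(initial, movesets[[m]], restraints, params, mcs,
                    track_pairs = tp)
      colnames(ens$site_trace) <- key
      fz <- feasibility(ens, spec)
      per_run[[length(per_run) + 1L]] <- data.frame(
        moveset = names(movesets)[m], seed = mcs$seed,
        fraction = fz$fraction, min_dist = fz$min_dist,
        feasible = fz$feasible, stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, per_run)
  consensus <- do.call(rbind, lapply(split(per_run, per_run$moveset), function(g) {
    data.frame(moveset = g$moveset[1], n_feasible = sum(g$feasible),
               n_runs = nrow(g),
               feasible = sum(g$feasible) > nrow(g) / 2,
               mean_fraction = mean(g$fraction),
               min_dist = min(g$min_dist), stringsAsFactors = FALSE)
  }))
  consensus <- consensus[match(names(movesets), consensus$moveset), ]
  rownames(consensus) <- NULL
  ff <- names(movesets)[which(consensus$feasible)[1]]
  structure(list(per_run = per_run, consensus = consensus,
                 first_feasible = if (length(ff)) ff else NA_character_,
                 threshold = spec$threshold),
            class = "flexibility_scan")
}

#' @export
print.flexibility_scan <- function(x, ...) {
  cat("Progressive-flexibility cross-link scan (threshold",
      x$threshold, "Angstrom)\n")
  print(x$consensus, row.names = FALSE)
  cat("first feasible move set:", x$first_feasible, "\n")
  invisible(x)
}
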