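## Dipolar coupling constant for a nitroxide pair: 52.04 MHz nm^3.
## With t in microseconds and r in Angstrom, omega = 2*pi*52.04/(r/10)^3
## is in rad/us.
.DIP_CONST_MHZ_NM3 <- 52.04

#' Angular dipolar frequency for a spin-spin distance
#' @param r Distance (Angstrom).
#' @return Angular frequency (rad/us).
#' @export
dipolar_omega <- function(r) {
  if (any(r <= 0)) stop("distance must be positive")
  2 * pi * .DIP_CONST_MHZ_NM3 / (r / 10)^3
}

#' Dipolar kernel matrix for DEER/ELDOR
#'
#' The orientation-averaged four-pulse DEER signal of an isolated spin
#' pair at distance r is
#' \deqn{K(t, r) = \int_0^1 \cos[(1 - 3u^2)\,\omega_{dd}(r)\, t]\, du,}
#' evaluated here either in closed form via Fresnel integrals or by
#' direct quadrature (the two agree to numerical precision and the
#' quadrature path serves as an internal cross-check).
#'
#' @param t_grid Time grid (microseconds, >= 0).
#' @param r_grid Distance grid (Angstrom, > 0).
#' @param method `"fresnel"` (closed form, default) or `"quadrature"`
#'   (composite Simpson over the orientation variable).
#' @param n_quad Number of quadrature points for `method = "quadrature"`.
#' @return A `dipolar_kernel` object: list with `K` (length(t) x
#'   length(r) matrix), `t`, `r`.
#' @export
dipolar_kernel <- function(t_grid, r_grid, method = c("fresnel", "quadrature"),
                           n_quad = 2001) {
  method <- match.arg(method)
  if (!length(t_grid) || !length(r_grid)) stop("empty grid")
  if (any(r_grid <= 0)) stop("distances must be positive")
  om <- dipolar_omega(r_grid)
  K <- matrix(1, length(t_grid), length(r_grid))
  if (method == "fresnel") {
    for (j in seq_along(om)) {
      phi <- om[j] * t_grid
      nz <- phi > 1e-12
      z <- sqrt(6 * phi[nz] / pi)
      K[nz, j] <- (cos(phi[nz]) * pracma::fresnelC(z) +
                     sin(phi[nz]) * pracma::fresnelS(z)) / z
    }
  } else {
    u <- seq(0, 1, length.out = n_quad)
    wts <- .simpson_weights(n_quad)
    a <- 1 - 3 * u^2
    for (j in seq_along(om)) {
      K[, j] <- vapply(t_grid, function(tt) sum(wts * cos(a * om[j] * tt)),
                       numeric(1))
    }
  }
  structure(list(K = K, t = t_grid, r = r_grid), class = "dipolar_kernel")
}

## composite Simpson weights on [0, 1] for n (odd) equally spaced points
.simpson_weights <- function(n) {
  stopifnot(n %% 2 == 1, n >= 3)
  w <- c(1, rep(c(4, 2), length.out = n - 2))
  w[n] <- 1
  w * (1 / (n - 1)) / 3
}

#' Time grid sized to a target distance
#'
#' A practical measurement window: DEER traces must span several dipolar
#' oscillation periods of the longest distance of interest for the
#' background and distribution to separate cleanly (long windows for
#' large distances).
#'
#' @param r_target Longest distance of interest (Angstrom).
#' @param periods Number of dipolar periods to cover (default 4).
#' @param dt Time step (us, default 0.02).
#' @return Time grid (us) from 0.
#' @export
deer_time_grid <- function(r_target, periods = 4, dt = 0.02) {
  t_max <- max(periods * (r_target / 10)^3 / .DIP_CONST_MHZ_NM3, 1.5)
  seq(0, t_max, by = dt)
}

#' Construct a DEER trace object
#' @param t Time grid (us), starting at 0, strictly increasing.
#' @param V Normalized signal.
#' @param lambda,k,d,sigma Generating parameters, if known (kept as
#'   metadata; `NA` for measured data).
#' @return A `deer_trace` object.
#' @export
deer_trace <- function(t, V, lambda = NA, k = NA, d = 3, sigma = NA) {
  stopifnot(length(t) == length(V), t[1] == 0, all(diff(t) > 0),
            all(is.finite(V)))
  structure(list(t = t, V = V, lambda = lambda, k = k, d = d, sigma = sigma),
            class = "deer_trace")
}

#' Simulate a four-pulse DEER time trace
#'
#' \deqn{V(t) = [1 - \lambda + \lambda (Kp)(t)] \exp(-k t^{d/3})
#'   + \epsilon(t)}
#' with modulation depth lambda, stretched-exponential background from
#' isotropically distributed surrounding spins (rate k, dimensionality d),
#' and i.i.d. Gaussian noise of standard deviation sigma.
#'
#' @param p A `distance_distribution` (the intramolecular pair
#'   distribution).
#' @param lambda Modulation depth in (0, 1).
#' @param k Background rate (1/us on the t^(d/3) scale).
#' @param d Background dimensionality (default 3).
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed (required when `sigma > 0`).
#' @param t_grid Time grid (us, from 0).
#' @param kernel Optional precomputed `dipolar_kernel` on (`t_grid`,
#'   `p$r`).
#' @return A `deer_trace`.
#' @export
simulate_trace <- function(p, lambda, k, d = 3, sigma = 0, seed = NULL,
                           t_grid = seq(0, 4, by = 0.016), kernel = NULL) {
  stopifnot(inherits(p, "distance_distribution"),
            lambda > 0, lambda < 1, sigma >= 0)
  if (is.null(kernel)) {
    kernel <- dipolar_kernel(t_grid, p$r)
  } else {
    if (!isTRUE(all.equal(kernel$t, t_grid)) ||
        !isTRUE(all.equal(kernel$r, p$r))) {
      stop("kernel grids do not match the trace/distribution grids")
    }
  }
  s <- as.numeric(kernel$K %*% (p$p * p$dr))
  V <- (1 - lambda + lambda * s) * exp(-k * t_grid^(d / 3))
  if (sigma > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    set.seed(seed)
    V <- V + stats::rnorm(length(V), 0, sigma)
  }
  deer_trace(t_grid, V, lambda = lambda, k = k, d = d, sigma = sigma)
}

#' Separate a DEER trace from its intermolecular background
#'
#' Fits the background model `(1 - lambda) * exp(-k t^(d/3))` to the tail
#' of the trace (log-linear least squares in `t^(d/3)`), where the
#' intramolecular dipolar oscillation has decayed, then divides it out.
#'
#' @param trace A `deer_trace`.
#' @param fit_start_fraction Tail start as a fraction of the trace length
#'   (default 0.5).
#' @param d Background dimensionality used in the fit (default 3).
#' @return A `form_factor` object: list with `t`, `s` (the
#'   background-divided signal, sitting on `1 - lambda + lambda*(Kp)`),
#'   `lambda` (fitted modulation depth), `k` (fitted rate), `d`.
#' @export
background_correct <- function(trace, fit_start_fraction = 0.5, d = 3) {
  stopifnot(inherits(trace, "deer_trace"),
            fit_start_fraction > 0, fit_start_fraction < 1)
  t <- trace$t; V <- trace$V
  tail_idx <- which(t >= fit_start_fraction * max(t))
  if (length(tail_idx) < 3) stop("tail too short for background fit")
  if (any(V[tail_idx] <= 0)) {
    stop("non-positive signal values in the background window")
  }
  x <- t[tail_idx]^(d / 3)
  fit <- stats::lm.fit(cbind(1, x), log(V[tail_idx]))
  k_hat <- -fit$coefficients[[2]]
  lambda_hat <- 1 - exp(fit$coefficients[[1]])
  lambda_hat <- min(max(lambda_hat, 1e-6), 1 - 1e-6)
  s <- V / exp(-k_hat * t^(d / 3))
  structure(list(t = t, s = s, lambda = lambda_hat, k = k_hat, d = d),
            class = "form_factor")
}

#' Invert a form factor to a distance distribution (Tikhonov)
#'
#' Solves the ill-posed inversion `Kp = D` (with
#' `D = (s - (1 - lambda)) / lambda` the dipolar evolution function) as
#' the non-negative Tikhonov problem
#' \deqn{\hat p = \arg\min_{p \ge 0} \|Kp - D\|^2 + \alpha \|Lp\|^2,}
#' where L is the second-difference operator, via non-negative least
#' squares on the stacked system. The result is normalized to unit area.
#'
#' @param ff A `form_factor` from [background_correct()], or a
#'   `deer_trace` already background-free (then `lambda` must be given).
#' @param alpha Regularization parameter (> 0). Use ~10 for
#'   short-window data dominated by 20--30 Angstrom distances and ~100
#'   for long-window data probing large distances.
#' @param r_grid Distance grid (default [default_r_grid()]).
#' @param lambda Modulation depth override (defaults to the fitted value
#'   carried by `ff`).
#' @return A `tikhonov_result`: list with `p` (a
#'   `distance_distribution`), `alpha`, `residual` (`||Kp - D||`),
#'   `roughness` (`||Lp||`).
#' @export
tikhonov_invert <- function(ff, alpha = 10, r_grid = default_r_grid(),
                            lambda = NULL) {
  stopifnot(alpha > 0)
  if (inherits(ff, "form_factor")) {
    t <- ff$t; s <- ff$s
    if (is.null(lambda)) lambda <- ff$lambda
  } else {
    stop("ff must be a form_factor (see background_correct)")
  }
  D <- (s - (1 - lambda)) / lambda
  kern <- dipolar_kernel(t, r_grid)
  nr <- length(r_grid)
  K <- kern$K * (r_grid[2] - r_grid[1])  # absorb dr so p is a density
  L <- .second_difference(nr)
  A <- rbind(K, sqrt(alpha) * L)
  b <- c(D, rep(0, nrow(L)))
  sol <- pracma::lsqnonneg(A, b)
  p_raw <- sol$x
  if (sum(p_raw) <= 0) stop("inversion returned an empty distribution")
  resid <- sqrt(sum((K %*% p_raw - D)^2))
  rough <- sqrt(sum((L %*% p_raw)^2))
  structure(list(p = distance_distribution(r_grid, p_raw),
                 alpha = alpha, residual = resid, roughness = rough),
            class = "tikhonov_result")
}

.second_difference <- function(n) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}
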