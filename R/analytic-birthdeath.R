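#' Series coefficients of the inherited-molecule distribution
#'
#' For the birth-death model (synthesis `k0`, first-order degradation
#' `k1`) the generating function of molecules inherited at birth, expanded
#' about \eqn{z = 1} as \eqn{G_0(z) = \sum_n a_n (z-1)^n}, satisfies a
#' recursion derived from the binomial-partitioning boundary condition:
#' each \eqn{a_m} is a positive combination of lower coefficients and
#' Laplace transforms of the division-time law at integer multiples of
#' `k1`, starting from \eqn{a_0 = 1}. Passing the ancestral law \eqn{\rho}
#' gives the population/history solution; passing \eqn{\phi} itself gives
#' the forward-lineage solution. The coefficients are scaled factorial
#' moments (so \eqn{a_1} is the mean inherited count); the computation
#' runs in quad precision because recovering probabilities from them is
#' severely ill-conditioned (see [birthdeath_pmf()]).
#'
#' @param k0 Synthesis rate (molecules per time).
#' @param k1 Degradation rate (per time), `> 0`.
#' @param law The division-time `division_model` to use in the boundary
#'   condition: \eqn{\rho} for the population/history ensemble, \eqn{\phi}
#'   for forward lineages.
#' @param n_trunc Truncation order of the series (default 150).
#' @return Numeric vector `a[0..n_trunc]` (length `n_trunc + 1`).
#' @export
birthdeath_coefficients <- function(k0, k1, law, n_trunc = 150L) {
  birthdeath_series(k0, k1, law, n_trunc, taus = numeric(0), x_max = 0L)$a
}

# shared dispatcher into the quad-precision core
birthdeath_series <- function(k0, k1, law, n_trunc, taus, x_max) {
  stopifnot(inherits(law, "division_model"), k1 > 0, k0 >= 0,
            n_trunc >= 1L)
  fam <- switch(law$family, exponential = 0L, gamma = 1L,
                deterministic = 2L, 3L)
  par1 <- par2 <- 0
  Ltab <- numeric(0)
  if (fam == 0L) par1 <- law$params$rate
  if (fam == 1L) { par1 <- law$params$shape; par2 <- law$params$rate }
  if (fam == 2L) par1 <- law$atom
  if (fam == 3L) {
    # lognormal/tabulated laws: double-precision transform values; fine
    # for the coefficients (positive recursion) and for small means, but
    # the pmf inversion loses accuracy at large inherited means
    Ltab <- Re(laplace_transform(law, (0:n_trunc) * k1))
  }
  birthdeath_series_cpp(k0, k1, fam, par1, par2, Ltab, as.integer(n_trunc),
                        taus, as.integer(x_max))
}

#' Age-resolved molecule-number distribution for the birth-death model
#'
#' The count of a cell of age \eqn{\tau} is the independent sum of (i)
#' molecules newly made since birth, Poisson with mean
#' \eqn{\mu(\tau) = (k_0/k_1)(1 - e^{-k_1\tau})}, and (ii) surviving
#' inherited molecules, whose distribution follows from the series
#' solution evaluated along \eqn{(z-1)e^{-k_1\tau}} (inherited molecules
#' decay over the cell cycle). `tau = 0` gives the inherited-molecule
#' distribution itself. For `ensemble = "population"` the boundary uses
#' the ancestral law \eqn{\rho}; `"forward"` substitutes \eqn{\phi}.
#'
#' The inclusion-exclusion recovery of probabilities from the series has
#' condition number of order \eqn{e^{2\mu}}; it is evaluated in quad
#' precision, which keeps truncation/rounding residues below \eqn{10^{-12}}
#' for inherited means up to roughly 45 (ample for the regimes studied
#' here). Residual negatives beyond `-1e-8` raise an error; smaller ones
#' are clipped to zero.
#'
#' @inheritParams birthdeath_coefficients
#' @param division The interdivision-time law \eqn{\phi}.
#' @param tau Cell ages (vector allowed).
#' @param ensemble `"population"` (equivalently histories) or
#'   `"forward"`.
#' @param x_max Largest count in the returned pmf (default: mean + 12 sd).
#' @param lambda Optional precomputed growth rate of `division`.
#' @return Matrix of probabilities (`x_max + 1` rows, one column per age);
#'   a vector if a single age is requested.
#' @export
birthdeath_pmf <- function(k0, k1, division, tau = 0,
                           ensemble = c("population", "forward"),
                           x_max = NULL, n_trunc = 150L, lambda = NULL) {
  ensemble <- match.arg(ensemble)
  stopifnot(inherits(division, "division_model"))
  law <- if (ensemble == "population")
    ancestral_distribution(division, lambda) else division
  # moments from the coefficients set the default support
  a <- birthdeath_coefficients(k0, k1, law, n_trunc)
  m_inh <- a[2]
  v_inh <- max(2 * a[3] + a[2] - a[2]^2, a[2])
  if (is.null(x_max)) {
    mu_max <- k0 / k1
    x_max <- ceiling(m_inh + mu_max + 12 * sqrt(v_inh + mu_max)) + 5
  }
  sol <- birthdeath_series(k0, k1, law, n_trunc, taus = tau,
                           x_max = min(x_max, n_trunc))
  out <- matrix(0, x_max + 1L, length(tau))
  for (j in seq_along(tau)) {
    p_inh <- sol$pmf[, j]
    if (any(p_inh < -1e-8))
      stop(sprintf(
        "series truncation insufficient: negative probability %.3g; increase n_trunc",
        min(p_inh)), call. = FALSE)
    p_inh <- pmax(p_inh, 0)
    mu <- (k0 / k1) * (1 - exp(-k1 * tau[j]))
    p_new <- stats::dpois(0:x_max, mu)
    out[, j] <- pmf_convolve(p_new, p_inh, x_max)
  }
  rownames(out) <- 0:x_max
  if (length(tau) == 1L) out[, 1] else out
}

# truncated convolution of two pmfs on 0..x_max
pmf_convolve <- function(p, q, x_max) {
  out <- numeric(x_max + 1L)
  for (i in seq_along(q)) {
    v <- q[i]
    if (v == 0) next
    hi <- min(x_max + 2L - i, length(p))
    if (hi < 1L) break
    idx <- i:(i + hi - 1L)
    out[idx] <- out[idx] + v * p[seq_len(hi)]
  }
  out
}

#' Age-marginalized molecule distribution across the population
#'
#' Integrates the age-resolved solution over the age distribution of the
#' chosen ensemble (\eqn{\Pi(\tau)} for the population, the renewal age
#' density for forward lineages) by Gauss-Legendre quadrature up to the
#' \eqn{1 - 10^{-10}} age quantile. This is the molecule-number
#' distribution measured across a snapshot irrespective of cell age.
#'
#' @inheritParams birthdeath_pmf
#' @param n_nodes Number of quadrature nodes over age.
#' @return Named probability vector over `0..x_max`.
#' @export
birthdeath_population_pmf <- function(k0, k1, division,
                                      ensemble = c("population",
                                                   "forward"),
                                      x_max = NULL, n_trunc = 150L,
                                      n_nodes = 160L) {
  ensemble <- match.arg(ensemble)
  lambda <- solve_growth_rate(division)
  struct <- age_distributions(division, lambda)
  dens <- if (ensemble == "population") struct$age_pdf_population
          else struct$age_pdf_forward
  gq <- age_quadrature(division, lambda, dens, ensemble, n_nodes)
  pm <- birthdeath_pmf(k0, k1, division, tau = gq$x, ensemble = ensemble,
                       x_max = x_max, n_trunc = n_trunc, lambda = lambda)
  out <- as.numeric(pm %*% gq$w)
  names(out) <- rownames(pm)
  out
}

# Quadrature over an ensemble age density. The snapshot age density is
# bounded by 2 lambda e^{-lambda tau}, so its support is effectively
# capped regardless of the division-law tail; the forward/history
# renewal densities inherit the division-law tail, which gets a sparse
# extra panel (the survival function is smooth and small out there).
age_quadrature <- function(division, lambda, dens,
                           ensemble = c("population", "forward",
                                        "history"),
                           n_nodes = 160L) {
  ensemble <- match.arg(ensemble)
  q_far <- division_upper_quantile(division, 1 - 1e-10)
  if (ensemble == "population") {
    up <- min(q_far, (log(2) + 26 * log(10)) / lambda)
    gq <- gauss_nodes(0, up, n_nodes)
  } else {
    bulk <- min(division_upper_quantile(division, 1 - 1e-3), q_far)
    gq <- gauss_nodes(0, bulk, n_nodes)
    if (q_far > bulk * 1.01) {
      tail <- gauss_nodes(bulk, q_far, 64L)
      gq <- list(x = c(gq$x, tail$x), w = c(gq$w, tail$w))
    }
  }
  w <- gq$w * dens(gq$x)
  list(x = gq$x, w = w / sum(w))
}

# Gauss-Legendre nodes/weights on [a, b] from panels of the 16-point rule
gauss_nodes <- function(a, b, n_nodes) {
  panels <- max(1L, ceiling(n_nodes / 16))
  edges <- seq(a, b, length.out = panels + 1L)
  x <- numeric(0); w <- numeric(0)
  for (i in seq_len(panels)) {
    mid <- (edges[i] + edges[i + 1L]) / 2
    half <- (edges[i + 1L] - edges[i]) / 2
    x <- c(x, mid + half * gl_nodes_16$x)
    w <- c(w, half * gl_nodes_16$w)
  }
  list(x = x, w = w)
}

#' Mean inherited molecules at birth: population vs forward lineages
#'
#' Evaluates the exact mean inherited count
#' \eqn{E[x\,|\,0] = (k_0/k_1)\,(1 - L(k_1))/(2 - L(k_1))} under the
#' ancestral law (population/histories) and under \eqn{\phi} (forward
#' lineages), together with the leading-order expansion of their
#' difference for slow degradation and small timing variability,
#' \eqn{-k_0 \ln 2\, \mathrm{CV}^2_\phi}: the population mean falls below
#' the forward mean because fast-dividing ancestors are over-represented
#' in the growing population.
#'
#' @inheritParams birthdeath_pmf
#' @return List with `population`, `forward`, `difference` and
#'   `leading_order`.
#' @export
mean_at_birth_expansion <- function(k0, k1, division) {
  stopifnot(inherits(division, "division_model"))
  rho <- ancestral_distribution(division)
  mean_from <- function(law) {
    L <- Re(laplace_transform(law, k1))
    (k0 / k1) * (1 - L) / (2 - L)
  }
  Ep <- mean_from(rho)
  Ef <- mean_from(division)
  list(population = Ep, forward = Ef, difference = Ep - Ef,
       leading_order = -k0 * log(2) * division$cv^2)
}
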