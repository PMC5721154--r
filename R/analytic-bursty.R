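#' Generating function of the bursty protein model in a growing population
#'
#' Proteins are produced in bursts arriving at rate `k0`, each adding a
#' geometric number of stable molecules with mean `b` and probability
#' generating function \eqn{h(z) = 1/(1 + b(1-z))} (the short
#' mRNA-lifetime reduction of the two-stage expression model, with
#' \eqn{b = k_2/k_1}). The age-\eqn{\tau} generating function factorizes
#' into newly made molecules, \eqn{\exp(k_0 \tau (h(z) - 1))}, and
#' inherited molecules
#' \deqn{G_0(z) = \prod_{j \ge 1} L\big(k_0 (1 - h(B^j(z)))\big),}
#' where \eqn{B^j(z) = 1 + (z-1)/2^j} is the \eqn{j}-fold binomial
#' thinning map and \eqn{L} the Laplace transform of the division law
#' (\eqn{\rho} for population/histories, \eqn{\phi} for forward
#' lineages). The product (a logarithmic sum, accumulated in log domain)
#' converges geometrically; it is truncated once the last factor deviates
#' from one by less than `tol`, starting from `j_min` factors.
#'
#' @param z Complex or real arguments on or inside the unit circle
#'   (vectorized).
#' @param tau Cell age.
#' @param k0 Burst arrival rate (per time).
#' @param b Mean burst size (molecules).
#' @param law Division-time `division_model` used in the boundary
#'   condition (\eqn{\rho} or \eqn{\phi}).
#' @param j_min Minimum number of product factors (default 10).
#' @param j_max Hard limit on factors.
#' @param tol Convergence tolerance on the last factor.
#' @return Generating-function values, same length as `z`.
#' @export
bursty_generating_function <- function(z, tau, k0, b, law,
                                       j_min = 10L, j_max = 64L,
                                       tol = 1e-12) {
  stopifnot(inherits(law, "division_model"), k0 >= 0, b >= 0, tau >= 0)
  h <- function(u) 1 / (1 + b * (1 - u))
  logG0 <- rep(0 + 0i, length(z))
  for (j in seq_len(j_max)) {
    Bj <- 1 + (z - 1) / 2^j
    fac <- laplace_transform(law, k0 * (1 - h(Bj)))
    logG0 <- logG0 + log(as.complex(fac))
    if (j >= j_min && max(abs(fac - 1)) < tol) break
    if (j == j_max && max(abs(fac - 1)) >= tol)
      stop("inherited-factor product did not converge; increase j_max",
           call. = FALSE)
  }
  out <- exp(k0 * tau * (h(z) - 1) + logG0)
  simplify_if_real(out)
}

#' Invert a probability generating function numerically
#'
#' Cauchy-integral inversion by uniform sampling of the unit circle:
#' probabilities are the discrete Fourier coefficients of
#' \eqn{G(e^{i\theta})}, computed with an FFT over
#' \eqn{M \ge 4\,x_{max}} circle points (rounded up to a power of two).
#' Imaginary residues and negative mass below `tol` are discarded;
#' anything larger signals an inversion failure.
#'
#' @param G Function taking a complex vector and returning
#'   generating-function values; must be analytic on the closed unit
#'   disk.
#' @param x_max Largest count required.
#' @param tol Tolerance on imaginary/negative residues.
#' @return Named probability vector over `0..x_max`.
#' @examples
#' p <- pgf_invert(function(z) exp(5 * (z - 1)), 20)
#' max(abs(p - dpois(0:20, 5)))  # ~1e-16
#' @export
pgf_invert <- function(G, x_max, tol = 1e-8) {
  M <- 2^ceiling(log2(max(2 * (x_max + 1L), 8)))
  zk <- exp(2i * pi * (0:(M - 1L)) / M)
  vals <- G(zk)
  coef <- stats::fft(vals) / M
  p <- coef[seq_len(x_max + 1L)]
  if (max(abs(Im(p))) > tol)
    stop(sprintf("inversion failed: imaginary residue %.3g",
                 max(abs(Im(p)))), call. = FALSE)
  p <- Re(p)
  if (min(p) < -tol)
    stop(sprintf("inversion failed: negative mass %.3g", min(p)),
         call. = FALSE)
  p <- pmax(p, 0)
  names(p) <- 0:x_max
  p
}

# default support: mean + 12 sd, from numerical log-derivatives of G at 1
pgf_support <- function(G, floor_x = 32L) {
  eps <- 1e-5
  g0 <- Re(G(1)); g1 <- Re(G(1 - eps)); g2 <- Re(G(1 - 2 * eps))
  m <- (g0 - g1) / eps / g0
  d2 <- (g0 - 2 * g1 + g2) / eps^2
  v <- max(d2 + m - m^2, m)
  max(floor_x, ceiling(m + 12 * sqrt(v)))
}

#' Molecule-number distributions for the bursty protein model
#'
#' `bursty_pmf` inverts the age-\eqn{\tau} generating function for the
#' chosen ensemble (`tau = 0` gives the inherited-protein distribution);
#' `bursty_population_pmf` first marginalizes the generating function over
#' the age distribution of the ensemble (population snapshot age law
#' \eqn{\Pi(\tau)}, or the renewal age density along forward lineages) by
#' Gauss-Legendre quadrature, giving the distribution across cells
#' irrespective of age.
#'
#' @inheritParams bursty_generating_function
#' @param division The interdivision-time law \eqn{\phi}.
#' @param ensemble `"population"` (equivalently histories) or
#'   `"forward"`.
#' @param x_max Largest count in the returned pmf (default from the
#'   moments of the generating function).
#' @param lambda Optional precomputed growth rate.
#' @param n_nodes Number of age-quadrature nodes.
#' @return Named probability vector over `0..x_max`.
#' @export
bursty_pmf <- function(k0, b, division, tau = 0,
                       ensemble = c("population", "forward"),
                       x_max = NULL, lambda = NULL) {
  ensemble <- match.arg(ensemble)
  stopifnot(inherits(division, "division_model"))
  law <- if (ensemble == "population")
    ancestral_distribution(division, lambda) else division
  G <- function(z) bursty_generating_function(z, tau, k0, b, law)
  if (is.null(x_max)) x_max <- pgf_support(G)
  pgf_invert(G, x_max)
}

#' @rdname bursty_pmf
#' @export
bursty_population_pmf <- function(k0, b, division,
                                  ensemble = c("population", "forward"),
                                  x_max = NULL, lambda = NULL,
                                  n_nodes = 160L) {
  ensemble <- match.arg(ensemble)
  stopifnot(inherits(division, "division_model"))
  if (is.null(lambda)) lambda <- solve_growth_rate(division)
  struct <- age_distributions(division, lambda)
  law <- if (ensemble == "population") struct$ancestral else division
  dens <- if (ensemble == "population") struct$age_pdf_population
          else struct$age_pdf_forward
  gq <- age_quadrature(division, lambda, dens, ensemble, n_nodes)
  h <- function(u) 1 / (1 + b * (1 - u))
  G <- function(z) {
    G0 <- bursty_generating_function(z, 0, k0, b, law)
    acc <- 0
    for (i in seq_along(gq$x))
      acc <- acc + gq$w[i] * exp(k0 * gq$x[i] * (h(z) - 1))
    G0 * acc
  }
  if (is.null(x_max)) x_max <- pgf_support(G)
  pgf_invert(G, x_max)
}
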