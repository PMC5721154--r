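#' Truncated chemical master equation propagator
#'
#' Solves the master equation \eqn{dp/d\tau = Q p} for a single-species
#' reaction network on the truncated state space `0..x_max`, via a
#' scaling-and-squaring matrix exponential of the generator. Transitions
#' that would leave the truncated range are switched off so probability
#' is conserved exactly; the result is checked for boundary mass, which
#' must stay below `boundary_tol` for the truncation to be valid. Burst
#' reactions place their geometric increment distribution directly in the
#' generator (the tail beyond the boundary is lumped into the last
#' state). This solver is deliberately independent of the series and
#' product solutions and serves as their numerical oracle.
#'
#' @param network A single-species `reaction_network`.
#' @param p_init Probability vector over `0..x_max` (or shorter; padded).
#' @param tau Propagation time.
#' @param x_max State-space truncation.
#' @param boundary_tol Maximum tolerated mass in the top three states.
#' @return Probability vector over `0..x_max`.
#' @export
cme_propagate <- function(network, p_init, tau, x_max = NULL,
                          boundary_tol = 1e-8) {
  stopifnot(inherits(network, "reaction_network"),
            length(network$species) == 1L, tau >= 0)
  if (is.null(x_max)) x_max <- length(p_init) - 1L
  p0 <- numeric(x_max + 1L)
  p0[seq_len(min(length(p_init), x_max + 1L))] <-
    p_init[seq_len(min(length(p_init), x_max + 1L))]
  Q <- cme_generator(network, x_max)
  p <- as.numeric(expm_action(Q, tau) %*% p0)
  if (sum(p[(x_max - 1L):(x_max + 1L)]) > boundary_tol)
    warning(sprintf("boundary mass %.3g above tolerance: increase x_max",
                    sum(p[(x_max - 1L):(x_max + 1L)])))
  p
}

# generator matrix for a single-species network (columns sum to zero)
cme_generator <- function(network, x_max) {
  n <- x_max + 1L
  states <- 0:x_max
  Q <- matrix(0, n, n)
  for (r in seq_len(nrow(network$reactants))) {
    m <- network$reactants[r, 1]
    w <- network$rates[r]
    if (m > 0L)
      for (k in 0:(m - 1L)) w <- w * pmax(states - k, 0)
    else w <- rep(w, n)
    if (!is.na(network$burst_mean[r])) {
      b <- network$burst_mean[r]
      pr <- 1 / (1 + b)
      for (j in seq_len(n)) {
        if (w[j] == 0) next
        ms <- 0:(n - j)
        nu <- stats::dgeom(ms, pr)
        nu[length(nu)] <- 1 - sum(nu[-length(nu)])  # lump the tail
        Q[j + ms, j] <- Q[j + ms, j] + w[j] * nu
        Q[j, j] <- Q[j, j] - w[j]
      }
    } else {
      c_ <- network$change[r, 1]
      ok <- states + c_ >= 0 & states + c_ <= x_max & w > 0
      idx <- which(ok)
      Q[cbind(idx + c_, idx)] <- Q[cbind(idx + c_, idx)] + w[idx]
      Q[cbind(idx, idx)] <- Q[cbind(idx, idx)] - w[idx]
    }
  }
  Q
}

# e^{Q tau} by Taylor series with scaling and squaring
expm_action <- function(Q, tau) {
  n <- nrow(Q)
  if (tau == 0) return(diag(n))
  nrm <- max(colSums(abs(Q))) * tau
  s <- max(0L, ceiling(log2(nrm / 0.5)))
  A <- Q * (tau / 2^s)
  E <- diag(n)
  term <- diag(n)
  for (k in 1:30) {
    term <- term %*% A / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Inherited-molecule distribution by boundary fixed-point iteration
#'
#' General-purpose solver for the distribution of inherited molecules
#' under any single-species chemistry: iterates the division boundary
#' condition in pmf space,
#' \deqn{p_0 \leftarrow \int d\tau_d\, \mathrm{law}(\tau_d)\,
#'       \mathrm{Split}\big(\mathrm{Propagate}(p_0, \tau_d)\big),}
#' with binomial splitting and master-equation propagation, until the
#' total-variation change between iterates falls below `tol`. The
#' division-time integral is discretized by Gauss-Legendre quadrature
#' (the deterministic atom needs a single node). Passing \eqn{\rho} gives
#' the population/history inherited distribution, \eqn{\phi} the
#' forward-lineage one. The iteration is a strict contraction in practice
#' (the binomial split mixes states); convergence from any normalized
#' start is part of the test suite.
#'
#' @param network A single-species `reaction_network`.
#' @param law Division-time `division_model` (\eqn{\rho} or \eqn{\phi}).
#' @param x_max State-space truncation.
#' @param tol Total-variation convergence tolerance.
#' @param max_iter Iteration cap.
#' @param n_nodes Quadrature nodes over the division-time law.
#' @param p_init Starting pmf (default: point mass at zero).
#' @return Probability vector over `0..x_max`.
#' @export
cme_boundary_fixed_point <- function(network, law, x_max, tol = 1e-10,
                                     max_iter = 400L, n_nodes = 32L,
                                     p_init = NULL) {
  stopifnot(inherits(network, "reaction_network"),
            length(network$species) == 1L,
            inherits(law, "division_model"))
  n <- x_max + 1L
  if (law$family == "deterministic") {
    nodes <- law$atom; w <- 1
  } else {
    up <- division_upper_quantile(law, 1 - 1e-10)
    gq <- gauss_nodes(0, up, n_nodes)
    nodes <- gq$x
    w <- gq$w * law$pdf(nodes)
    w <- w / sum(w)
  }
  Q <- cme_generator(network, x_max)
  Tm <- outer(0:x_max, 0:x_max,
              function(x, xp) stats::dbinom(x, xp, 0.5))
  # per-node one-generation operator: split after propagating to division
  A <- matrix(0, n, n)
  for (i in seq_along(nodes))
    A <- A + w[i] * (Tm %*% expm_action(Q, nodes[i]))
  p <- if (is.null(p_init)) c(1, numeric(x_max)) else {
    stopifnot(length(p_init) == n)
    p_init / sum(p_init)
  }
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(A %*% p)
    p_new <- pmax(p_new, 0)
    p_new <- p_new / sum(p_new)
    d <- sum(abs(p_new - p)) / 2
    p <- p_new
    if (d < tol) return(p)
  }
  warning("boundary fixed point did not reach tolerance")
  p
}
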