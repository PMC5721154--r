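test_that("deterministic division gives a Poisson inherited distribution", {
  k0 <- 50; k1 <- 1; Td <- 1
  mu_p <- (k0 / k1) * (1 - exp(-k1 * Td)) / (2 - exp(-k1 * Td))
  p <- birthdeath_pmf(k0, k1, division_deterministic(Td), tau = 0)
  xs <- as.integer(names(p))
  expect_lt(max(abs(p - dpois(xs, mu_p))), 1e-6)
  # at age tau the inherited part decays and new production adds up
  tau <- 0.4
  p_tau <- birthdeath_pmf(k0, k1, division_deterministic(Td), tau = tau)
  mean_expected <- mu_p * exp(-k1 * tau) + (k0 / k1) * (1 - exp(-k1 * tau))
  expect_equal(sum(as.integer(names(p_tau)) * p_tau), mean_expected,
               tolerance = 1e-8)
})

test_that("zero synthesis empties the series", {
  a <- birthdeath_coefficients(0, 1, division_gamma(1, 0.5), 40)
  expect_equal(a[1], 1)
  expect_equal(max(abs(a[-1])), 0)
})

test_that("series solution agrees with the master-equation fixed point", {
  g <- division_gamma(1, 0.5)
  rho <- ancestral_distribution(g)
  p_fix <- cme_boundary_fixed_point(rn_birth_death(50, 1), rho,
                                    x_max = 140)
  p_ser <- birthdeath_pmf(50, 1, g, tau = 0, ensemble = "population",
                          x_max = 140, n_trunc = 150)
  expect_lt(tv_pmf(p_ser, p_fix), 1e-3)
  # convergence is independent of the starting distribution
  p_fix2 <- cme_boundary_fixed_point(rn_birth_death(50, 1), rho,
                                     x_max = 140,
                                     p_init = rep(1 / 141, 141))
  expect_lt(tv_pmf(p_fix, p_fix2), 1e-9)
})

test_that("old cells forget their inheritance", {
  # large tau: Poisson(k0/k1) regardless of the division law
  for (m in list(division_gamma(1, 0.5), division_deterministic(1))) {
    p <- birthdeath_pmf(50, 1, m, tau = 12)
    expect_lt(tv_pmf(p, dpois(0:(length(p) - 1), 50)), 1e-4)
  }
})

test_that("fast degradation erases the ensemble difference", {
  # with k0/k1 fixed, increasing degradation makes the population and
  # forward solutions converge (timing fluctuations are averaged out);
  # the relative mean gap must vanish as k1 grows
  gap <- function(k1) {
    p_rho <- birthdeath_pmf(50 * k1, k1, division_gamma(1, 1), tau = 0,
                            ensemble = "population", n_trunc = 250)
    p_phi <- birthdeath_pmf(50 * k1, k1, division_gamma(1, 1), tau = 0,
                            ensemble = "forward", n_trunc = 250)
    c(tv = tv_pmf(p_rho, p_phi),
      dmean = abs(pmf_mean(p_rho) - pmf_mean(p_phi)))
  }
  g01 <- gap(0.1); g1 <- gap(1); g10 <- gap(10)
  expect_gt(g1[["tv"]], 3 * g10[["tv"]])
  expect_lt(g10[["tv"]], 0.1)
  # relative mean gaps shrink monotonically toward the k0/k1 limit
  rel <- c(g01[["dmean"]] / 5, g1[["dmean"]] / 50, g10[["dmean"]] / 500)
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.01)
})

test_that("age-marginalized distribution has the mixture mean", {
  g <- division_gamma(1, 0.5)
  p <- birthdeath_population_pmf(50, 1, g)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # mixture mean equals the age-integrated conditional mean
  st <- age_distributions(g)
  a1 <- birthdeath_coefficients(50, 1, st$ancestral, 150)[2]
  mean_tau <- function(tau)
    50 * (1 - exp(-tau)) + a1 * exp(-tau)
  up <- snapclone:::division_upper_quantile(g, 1 - 1e-10)
  m_expected <- stats::integrate(function(t)
    mean_tau(t) * st$age_pdf_population(t), 0, up,
    rel.tol = 1e-10)$value
  expect_equal(pmf_mean(p), m_expected, tolerance = 1e-4)
  # population marginal differs from the forward marginal even for the
  # memoryless law, whose age distributions share their form
  e <- division_exponential(1)
  pe <- birthdeath_population_pmf(50, 1, e, n_trunc = 250)
  fe <- birthdeath_population_pmf(50, 1, e, ensemble = "forward",
                                  n_trunc = 250)
  expect_gt(tv_pmf(pe, fe), 0.05)
})

test_that("mean-at-birth expansion tracks -k0 ln2 CV^2", {
  # no variability: no difference
  m0 <- mean_at_birth_expansion(50, 0.01, division_deterministic(1))
  expect_equal(m0$difference, 0, tolerance = 1e-10)
  expect_equal(m0$leading_order, 0)
  # small CV, slow degradation: within 15% of the leading order
  m <- mean_at_birth_expansion(50, 0.01, division_gamma(1, 0.1))
  expect_lt(abs(m$difference - m$leading_order),
            0.15 * abs(m$leading_order))
  # difference grows with timing variability
  d <- vapply(c(0.1, 0.5, 1.0), function(cv)
    abs(mean_at_birth_expansion(50, 0.01,
                                division_gamma(1, cv))$difference),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("generating-function inversion recovers known laws", {
  p <- pgf_invert(function(z) exp(5 * (z - 1)), 30)
  expect_lt(max(abs(p - dpois(0:30, 5))), 1e-10)
  p2 <- pgf_invert(function(z) z^7, 12)
  expect_equal(unname(p2), c(rep(0, 7), 1, rep(0, 5)))
  # signed coefficients are rejected, not silently clipped
  expect_error(pgf_invert(function(z) 2 - z, 4), "negative mass")
})

test_that("bursty generating function is a proper PGF", {
  ln <- division_lognormal(1, cv = sqrt(3))
  rho <- ancestral_distribution(ln)
  expect_equal(Mod(bursty_generating_function(1 + 0i, 0, 20, 5, rho)), 1,
               tolerance = 1e-12)
  # vanishing burst size with k0 b fixed: Poisson accumulation limit
  det <- division_deterministic(1)
  rate <- 20
  p_small_b <- bursty_pmf(rate / 0.05, 0.05, det, tau = 0,
                          ensemble = "forward", x_max = 120)
  # forward inherited mean must equal k0 b <tau>_phi = rate in any case;
  # the variance of the thinned compound-Poisson cascade is
  # k0 b (2b + 3)/3, approaching the pure-Poisson cascade value as b -> 0
  expect_equal(pmf_mean(p_small_b), rate, tolerance = 1e-6)
  v <- sum((as.numeric(names(p_small_b)) - rate)^2 * p_small_b)
  expect_equal(v, rate * (2 * 0.05 + 3) / 3, tolerance = 0.01)
})

test_that("bursty product solution matches the boundary fixed point", {
  det <- division_deterministic(1)
  pp <- bursty_pmf(20, 5, det, tau = 0, ensemble = "population",
                   x_max = 600)
  pf <- cme_boundary_fixed_point(rn_bursty(20, 5), det, x_max = 600)
  expect_lt(tv_pmf(pp, pf), 1e-5)
})

test_that("bursty means follow the division-time laws", {
  ln <- division_lognormal(1, cv = sqrt(3))
  lam <- solve_growth_rate(ln)
  rho <- ancestral_distribution(ln, lam)
  ph <- bursty_pmf(20, 5, ln, tau = 0, ensemble = "population",
                   x_max = 600)
  expect_equal(pmf_mean(ph), 20 * 5 * rho$mean, tolerance = 1e-3)
  pf <- bursty_pmf(20, 5, ln, tau = 0, ensemble = "forward",
                   x_max = 3000)
  expect_equal(pmf_mean(pf), 20 * 5 * 1, tolerance = 0.02)
  # population marginal mean: inherited plus production over mean age
  ppop <- bursty_population_pmf(20, 5, ln, x_max = 900)
  st <- age_distributions(ln, lam)
  grid <- sort(unique(c(seq(0, 40, length.out = 2e5),
                        seq(40, 900, length.out = 2e4))))
  age_mean <- snapclone:::trapz(grid, grid * st$age_pdf_population(grid))
  expect_equal(pmf_mean(ppop), 20 * 5 * rho$mean + 20 * 5 * age_mean,
               tolerance = 1e-3)
})

test_that("master-equation propagator handles canonical cases", {
  p0 <- c(1, numeric(80))
  expect_equal(cme_propagate(rn_none(), p0, 3), p0)
  p <- cme_propagate(rn_birth_death(50, 1), p0, 10, x_max = 120)
  mu <- 50 * (1 - exp(-10))
  expect_lt(max(abs(p - dpois(0:120, mu))), 1e-8)
})
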