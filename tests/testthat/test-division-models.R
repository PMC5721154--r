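test_that("hazards follow phi/S for closed-form and tabulated laws", {
  # memoryless law: constant hazard
  m <- division_exponential(1)
  expect_equal(division_hazard(m, c(0.1, 1, 5)), rep(1, 3))

  # uniform density on [0,1]: hazard 1/(1 - tau)
  u <- hazard_from_pdf(function(t) stats::dunif(t, 0, 1), upper = 1)
  expect_equal(division_hazard(u, c(0.2, 0.5, 0.9)),
               1 / (1 - c(0.2, 0.5, 0.9)), tolerance = 1e-3)
  expect_true(is.infinite(division_hazard(u, 1.5)))

  # gamma: hazard at tau = 1 against an independent quadrature of the pdf
  g <- division_gamma(1, 0.5)
  S1 <- 1 - stats::integrate(function(t) division_pdf(g, t), 0, 1,
                             rel.tol = 1e-12)$value
  expect_equal(division_hazard(g, 1), division_pdf(g, 1) / S1,
               tolerance = 1e-9)

  # deterministic atom: no density, all-or-nothing survival
  d <- division_deterministic(2)
  expect_equal(division_survival(d, c(1.9, 2.1)), c(1, 0))
  expect_equal(division_hazard(d, 1), 0)
  expect_true(is.infinite(division_hazard(d, 2)))
})

test_that("pdf validation rejects bad densities", {
  expect_error(hazard_from_pdf(function(t) t - 0.5, upper = 1),
               "nonnegative")
  expect_error(division_tabulated(c(0, 1, 2), c(1, 1, 1)),
               "integrates")
})

test_that("growth rate matches closed forms and the lognormal benchmark", {
  for (g in c(0.5, 1, 2.7))
    expect_equal(solve_growth_rate(division_exponential(g)), g,
                 tolerance = 1e-10)
  for (tau in c(0.5, 1, 3))
    expect_equal(solve_growth_rate(division_deterministic(tau)),
                 log(2) / tau, tolerance = 1e-10)
  # lognormal with unit mean and variance 3: growth rate about 1.25
  ln <- division_lognormal(1, cv = sqrt(3))
  expect_equal(solve_growth_rate(ln), 1.2527, tolerance = 1e-3)
})

test_that("Euler-Lotka self-consistency holds across model families", {
  models <- list(division_gamma(1, 0.1), division_gamma(2, 0.7),
                 division_gamma(1, 1.0), division_lognormal(1, cv = 0.4),
                 division_lognormal(1, cv = sqrt(3)),
                 hazard_from_pdf(function(t) stats::dunif(t, 0.2, 1.2),
                                 upper = 1.2))
  for (m in models) {
    lam <- solve_growth_rate(m)
    expect_lt(abs(2 * Re(laplace_transform(m, lam)) - 1), 1e-8)
  }
})

test_that("ancestral law is the exponentially tilted division law", {
  # exponential rate 1: rho is exponential with rate 2
  rho <- ancestral_distribution(division_exponential(1), 1)
  expect_equal(division_pdf(rho, c(0.3, 1)), 2 * exp(-2 * c(0.3, 1)),
               tolerance = 1e-12)

  # deterministic atom: unchanged (tilt weight 2 e^{-ln 2} = 1)
  d <- division_deterministic(1.5)
  rho_d <- ancestral_distribution(d, log(2) / 1.5)
  expect_identical(rho_d$atom, 1.5)

  # inconsistent (phi, lambda) pair is flagged
  expect_error(ancestral_distribution(division_exponential(1), 0.4),
               "inconsistent")
})

test_that("fast dividers are over-represented in the ancestral law", {
  models <- list(division_gamma(1, 0.3), division_gamma(1, 0.7),
                 division_gamma(1, 1.0), division_lognormal(1, cv = 0.5),
                 division_lognormal(1, cv = sqrt(3)))
  for (m in models) {
    lam <- solve_growth_rate(m)
    rho <- ancestral_distribution(m, lam)
    thr <- log(2) / lam
    mass_phi <- 1 - division_survival(m, thr)
    mass_rho <- 1 - division_survival(rho, thr)
    expect_gt(mass_rho, mass_phi)
    # mean ordering, equality only for the deterministic atom
    expect_lt(rho$mean, m$mean)
  }
  d <- division_deterministic(2)
  expect_equal(ancestral_distribution(d)$mean, 2)
})

test_that("the three age densities are normalized and correctly related", {
  # memoryless law: history age density equals the population one
  st <- age_distributions(division_exponential(1), 1)
  tau <- seq(0, 3, by = 0.1)
  expect_equal(st$age_pdf_population(tau), 2 * exp(-2 * tau),
               tolerance = 1e-9)
  expect_equal(st$age_pdf_history(tau), st$age_pdf_population(tau),
               tolerance = 1e-6)

  # deterministic law: truncated exponential age profile
  std <- age_distributions(division_deterministic(1))
  lam <- log(2)
  expect_equal(std$age_pdf_population(c(0.2, 0.9)),
               2 * lam * exp(-lam * c(0.2, 0.9)), tolerance = 1e-12)
  expect_equal(std$age_pdf_population(1.2), 0)

  for (m in list(division_gamma(1, 0.5), division_lognormal(1, cv = 1))) {
    s <- age_distributions(m)
    up <- snapclone:::division_upper_quantile(m, 1 - 1e-13)
    grid <- sort(unique(c(seq(0, min(up, 30), length.out = 2e5),
                          seq(min(up, 30), up, length.out = 2e4))))
    for (f in list(s$age_pdf_population, s$age_pdf_history,
                   s$age_pdf_forward))
      expect_equal(snapclone:::trapz(grid, f(grid)), 1, tolerance = 1e-6)
  }

  # forward and history age laws near-coincide only at low variability
  dist_fh <- function(cv) {
    s <- age_distributions(division_gamma(1, cv))
    tau <- seq(0, 5, by = 0.01)
    max(abs(s$age_pdf_forward(tau) - s$age_pdf_history(tau)))
  }
  expect_lt(dist_fh(0.1), dist_fh(1.0))
})

test_that("Laplace transforms match closed forms and handle atoms", {
  expect_equal(laplace_transform(division_exponential(2), 1), 2 / 3)
  expect_equal(laplace_transform(division_deterministic(1.5), 2),
               exp(-3))
  # Euler-Lotka self-consistency as transform check for the lognormal
  ln <- division_lognormal(1, cv = sqrt(3))
  lam <- solve_growth_rate(ln)
  expect_equal(Re(laplace_transform(ln, lam)), 0.5, tolerance = 1e-8)
  # complex argument: |L(s)| <= 1 on Re(s) >= 0
  zz <- laplace_transform(ln, 0.3 + 2i)
  expect_lt(Mod(zz), 1)
  # below the abscissa of convergence
  expect_error(laplace_transform(division_exponential(1), -2), "abscissa")
})

test_that("tabulated laws reproduce their construction and sample correctly", {
  g <- division_gamma(1, 0.5)
  tb <- hazard_from_pdf(function(t) division_pdf(g, t), upper = 8)
  expect_equal(tb$mean, 1, tolerance = 1e-3)
  expect_equal(tb$cv, 0.5, tolerance = 1e-2)
  expect_equal(Re(laplace_transform(tb, 1.3)),
               Re(laplace_transform(g, 1.3)), tolerance = 1e-4)
  set.seed(1)
  xs <- division_sample(tb, 20000)
  expect_equal(mean(xs), 1, tolerance = 0.02)
})
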