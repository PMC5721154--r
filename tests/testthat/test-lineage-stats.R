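# hand-built tree: founder 1 -> (2, 3); 2 -> (4, 5); 3, 4, 5 alive.
# division ages: cell 1 at 1.0, cell 2 at 0.8; observed to t_f = 2.5
hand_tree <- function() {
  cells <- data.frame(
    cell_id = 1:5,
    parent_id = c(NA, 1L, 1L, 2L, 2L),
    birth_time = c(0, 1, 1, 1.8, 1.8),
    division_age = c(1, 0.8, 4, 3, 2),
    divided = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  xb <- matrix(c(10L, 6L, 4L, 2L, 4L), ncol = 1,
               dimnames = list(NULL, "x"))
  xd <- matrix(c(10L, 6L, NA, NA, NA), ncol = 1,
               dimnames = list(NULL, "x"))
  structure(list(cells = cells, x_birth = xb, x_division = xd,
                 x_final = xb, species = "x", t_f = 2.5, seed = 0L,
                 network = rn_none(), division = NULL,
                 truncated = FALSE),
            class = "population_tree")
}

test_that("forward lineage weights are 2^-D and sum to one", {
  # single undivided cell
  tr1 <- simulate_population(rn_none(), division_deterministic(2),
                             t_f = 1, seed = 1)
  ln1 <- enumerate_lineages(tr1)
  expect_length(ln1, 1L)
  expect_equal(ln1[[1]]$D, 0L)
  expect_equal(ln1[[1]]$weight, 1)

  # complete tree of depth 3
  tr3 <- simulate_population(rn_none(), division_deterministic(1),
                             t_f = 3.5, seed = 1)
  ln3 <- enumerate_lineages(tr3)
  expect_length(ln3, 8L)
  expect_equal(unique(vapply(ln3, `[[`, numeric(1), "weight")), 1 / 8)

  # asymmetric tree: weights 1/4, 1/4, 1/2
  lna <- enumerate_lineages(hand_tree())
  w <- sort(vapply(lna, `[[`, numeric(1), "weight"))
  expect_equal(w, c(0.25, 0.25, 0.5))
  expect_equal(sum(w), 1)

  # random trees: exact weight normalization
  for (s in 1:3) {
    tr <- simulate_population(rn_none(), division_gamma(1, 0.7),
                              n_max = 64, seed = 20 + s)
    expect_equal(sum(vapply(enumerate_lineages(tr), `[[`, numeric(1),
                            "weight")), 1)
  }
})

test_that("histories trace ancestry back to the founder", {
  tr1 <- simulate_population(rn_none(), division_deterministic(2),
                             t_f = 1, seed = 1)
  h <- sample_histories(tr1, 3)
  for (ln in h) expect_identical(ln$cells, 1L)

  tr <- hand_tree()
  set.seed(1)
  h <- sample_histories(tr, 50)
  for (ln in h) {
    expect_equal(ln$cells[1], 1L)  # every history ends at the founder
    expect_true(!tr$cells$divided[ln$cells[length(ln$cells)]])
  }
})

test_that("lineage averages count only cells reaching the age", {
  tr <- hand_tree()
  lns <- enumerate_lineages(tr)
  # lineage ending in cell 3 (born at 1, alive to 2.5, x = 4)
  l3 <- lns[[which(vapply(lns, function(l) l$cells[length(l$cells)] == 3L,
                          logical(1)))]]
  # at age 0 all cells qualify: mean of (10, 4)
  expect_equal(lineage_age_average(tr, l3, tau = 0), 7)
  # at age 0.9: cell 1 divided at age 1 >= 0.9 qualifies, cell 3 has
  # current age 1.5 >= 0.9: both qualify (no chemistry: counts unchanged)
  expect_equal(lineage_age_average(tr, l3, tau = 0.9), 7)
  # age 1.2: cell 1 divided younger; only cell 3 qualifies
  expect_equal(lineage_age_average(tr, l3, tau = 1.2), 4)
  # age beyond every division/current age
  expect_true(is.na(lineage_age_average(tr, l3, tau = 2)))
  # brute force on the 4-lineage: cells 1, 2, 4 at age 0
  l4 <- lns[[which(vapply(lns, function(l) l$cells[length(l$cells)] == 4L,
                          logical(1)))]]
  expect_equal(lineage_age_average(tr, l4, tau = 0), mean(c(10, 6, 2)))
})

test_that("ensemble averages weight lineages correctly", {
  tr <- hand_tree()
  lns <- enumerate_lineages(tr)
  vals <- vapply(lns, function(l) lineage_age_average(tr, l, tau = 0),
                 numeric(1))
  w <- vapply(lns, `[[`, numeric(1), "weight")
  expect_equal(ensemble_average(tr, lns, tau = 0, ensemble = "forward"),
               sum(w * vals))
  expect_equal(ensemble_average(tr, lns, tau = 0, ensemble = "history"),
               mean(vals))
  expect_error(ensemble_average(tr, lns, tau = 9), "reaches")
})

test_that("forward exceeds history means for stable molecules", {
  # slow degradation: ancestors carry fewer molecules than forward
  # lineages; deterministic division makes the two ensembles coincide
  fwd <- hx <- fwd_d <- hx_d <- integer(0)
  for (s in 1:15) {
    tr <- simulate_population(rn_birth_death(50, 1),
                              division_gamma(1, 1), n_max = 200,
                              seed = 300 + s)
    burn <- 0.25 * tr$t_f
    hx <- c(hx, inherited_counts(tr, "history", min_birth_time = burn))
    fwd <- c(fwd, inherited_counts(tr, "forward", min_birth_time = burn,
                                   n_lineages = 50))
    trd <- simulate_population(rn_birth_death(5, 0.1),
                               division_deterministic(1), n_max = 200,
                               seed = 600 + s)
    burn <- 0.25 * trd$t_f
    hx_d <- c(hx_d, inherited_counts(trd, "history",
                                     min_birth_time = burn))
    fwd_d <- c(fwd_d, inherited_counts(trd, "forward",
                                       min_birth_time = burn,
                                       n_lineages = 50))
  }
  expect_gt(mean(fwd) - mean(hx), 2)
  expect_lt(abs(mean(fwd_d) - mean(hx_d)), 1)
})

test_that("history division times follow the ancestral law", {
  g <- division_gamma(1, 0.5)
  lam <- solve_growth_rate(g)
  rho <- ancestral_distribution(g, lam)
  up <- snapclone:::division_upper_quantile(g, 1 - 1e-12)
  rho_cdf <- cdf_fun(function(t) division_pdf(rho, t), up)
  phi_cdf <- function(t) 1 - division_survival(g, t)
  td <- c()
  for (s in 1:30) {
    tr <- simulate_population(rn_none(), g, n_max = 200, seed = 800 + s)
    td <- c(td, division_times(tr, "history",
                               min_birth_time = 0.25 * tr$t_f))
  }
  ks_rho <- suppressWarnings(stats::ks.test(td, rho_cdf))
  ks_phi <- suppressWarnings(stats::ks.test(td, phi_cdf))
  expect_gt(ks_rho$p.value, 0.01)
  expect_gt(ks_phi$statistic, 4 * ks_rho$statistic)
  # forward division times follow phi instead; guard the window against
  # right-censoring (slow dividers near the end are still alive) and
  # pool few walks per tree to limit shared-ancestry dependence
  set.seed(1)
  td_f <- c()
  for (s in 1:60) {
    tr <- simulate_population(rn_none(), g, n_max = 200, seed = 800 + s)
    td_f <- c(td_f, division_times(tr, "forward", n_lineages = 4,
                                   min_birth_time = 0.25 * tr$t_f,
                                   max_birth_time = tr$t_f - 3))
  }
  ks_f_phi <- suppressWarnings(stats::ks.test(td_f, phi_cdf))
  ks_f_rho <- suppressWarnings(stats::ks.test(td_f, rho_cdf))
  expect_gt(ks_f_phi$p.value, 0.01)
  expect_gt(ks_f_rho$statistic, 2 * ks_f_phi$statistic)
})

test_that("age sorting builds conditional distributions per bin", {
  snap <- data.frame(age = rep(0.3, 5), x_x = rep(5L, 5))
  d <- age_sorted(snap, breaks = c(0, 1))
  expect_equal(unname(d$bins[[1]]$pmf["5"]), 1)
  expect_equal(d$bins[[1]]$n, 5L)

  snap2 <- data.frame(age = c(0.1, 0.1, 0.9, 0.9),
                      x_x = c(1L, 3L, 7L, 7L))
  d2 <- age_sorted(snap2, breaks = c(0, 0.5, 1))
  expect_equal(sort(as.integer(names(d2$bins[[1]]$pmf))), c(1L, 3L))
  expect_equal(unname(d2$bins[[2]]$pmf["7"]), 1)
  # empty bin flagged absent
  d3 <- age_sorted(snap2, breaks = c(0, 0.5, 0.6, 1))
  expect_null(d3$bins[[2]])
})

test_that("reproductive value is one for identical distributions", {
  x <- rep(c(0L, 1L, 2L), c(10, 30, 20))
  rv <- reproductive_value(counts_distribution(x),
                           counts_distribution(x), min_count = 1)
  expect_equal(rv$nu_x[[1]]$nu, rep(1, 3))
  expect_equal(rv$nu_age$nu, 1)
})

test_that("ergodic test accepts identical samples and flags distinct ones", {
  x <- rep(c(2L, 3L, 5L), c(20, 30, 10))
  set.seed(1)
  et <- ergodic_test(counts_distribution(x), counts_distribution(x),
                     n_perm = 100)
  expect_equal(et$bins$tv[1], 0)
  expect_gt(et$bins$p[1], 0.5)
  expect_false(et$violated)
  set.seed(2)
  y <- rep(c(2L, 3L, 5L), c(5, 10, 45))
  et2 <- ergodic_test(counts_distribution(x), counts_distribution(y),
                      n_perm = 200)
  expect_true(et2$violated)
})
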