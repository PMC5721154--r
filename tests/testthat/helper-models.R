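# shared helpers: distances, CDF builders and pooled-simulation utilities

tv_pmf <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, numeric(n - length(p)))
  q <- c(q, numeric(n - length(q)))
  sum(abs(p - q)) / 2
}

tv_sample_pmf <- function(x, pmf) snapclone:::tv_to_pmf(x, pmf)

# numeric CDF of a density function on [0, up]
cdf_fun <- function(dens, up, n = 4096L) {
  grid <- seq(0, up, length.out = n)
  cdf <- snapclone:::trapz_cum(grid, dens(grid))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(grid, cdf, yleft = 0, yright = 1)
}

pmf_mean <- function(p) sum(as.numeric(names(p)) * p)

# pool inherited-molecule samples over independent trees
pool_inherited <- function(network, division, n_trees, n_max, seed0,
                           ensembles = c("history", "population"),
                           initial = NULL, burn_fraction = 0.25) {
  out <- stats::setNames(vector("list", length(ensembles)), ensembles)
  per_tree <- stats::setNames(vector("list", length(ensembles)), ensembles)
  for (i in seq_len(n_trees)) {
    tr <- simulate_population(network, division, initial = initial,
                              n_max = n_max, seed = seed0 + i)
    burn <- burn_fraction * tr$t_f
    for (e in ensembles) {
      xs <- inherited_counts(tr, e, min_birth_time = burn)
      out[[e]] <- c(out[[e]], xs)
      per_tree[[e]] <- c(per_tree[[e]], list(xs))
    }
  }
  out$per_tree <- per_tree
  out
}

# Fig-6a-like selection scenario tree
selection_tree <- function(seed, n_max = 1000) {
  simulate_population(rn_production(100), hill_division_rule(50, 10, 10),
                      initial = list(list(x = 17L)),
                      n_max = n_max, seed = seed)
}
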