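#' Preconfigured simulation scenarios
#'
#' Builds a run configuration and a small pre-simulated tree for one of
#' the canonical study scenarios:
#' \describe{
#'   \item{`synchronous`}{no chemistry, deterministic unit division time,
#'     one founder: a deterministic doubling tree (8 cells at
#'     `t_f = 3.5`).}
#'   \item{`neutral_birthdeath`}{birth-death chemistry (`k0 = 50`,
#'     `k1 = 1`) with gamma-distributed division times (unit mean,
#'     CV 0.5): a trait that does not affect division timing, so the
#'     ergodic principle holds.}
#'   \item{`bursty_protein`}{stable protein made in geometric bursts
#'     (`k0 = 20`, `b = 5`, the short mRNA-lifetime reduction of the
#'     two-stage model with `k1 = 20`, `k2 = 100`) under lognormal
#'     division times with unit mean and CV\eqn{^2} = 3.}
#'   \item{`selection_hill`}{production at rate `k0 = 100` of a molecule
#'     that shortens the division period through a steep Hill function,
#'     \eqn{\tau_d = 50 K^{10}/(K^{10} + x_0^{10})}, `K = 10`: expression
#'     under positive selection, so the ergodic principle is violated.}
#' }
#'
#' @param kind Scenario name.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, the config (YAML) and tree
#'   (CSV) are written there.
#' @return List with `config` (a run configuration list), `tree` (a
#'   `population_tree`) and, if `dir` was given, the file `paths`.
#' @export
generate_fixture <- function(kind = c("neutral_birthdeath",
                                      "bursty_protein", "selection_hill",
                                      "synchronous"),
                             seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  config <- switch(kind,
    synchronous = list(
      schema = 1L, kind = kind,
      model = list(type = "none"),
      division = list(family = "deterministic", tau = 1),
      sim = list(seed = seed, t_f = 3.5)),
    neutral_birthdeath = list(
      schema = 1L, kind = kind,
      model = list(type = "birth_death", k0 = 50, k1 = 1),
      division = list(family = "gamma", mean = 1, cv = 0.5),
      sim = list(seed = seed, n_max = 250L)),
    bursty_protein = list(
      schema = 1L, kind = kind,
      model = list(type = "bursty", k0 = 20, b = 5),
      division = list(family = "lognormal", mean = 1, cv = sqrt(3)),
      sim = list(seed = seed, n_max = 250L)),
    selection_hill = list(
      schema = 1L, kind = kind,
      model = list(type = "production", k0 = 100),
      division = list(rule = "hill", tau_max = 50, K = 10, h = 10),
      sim = list(seed = seed, n_max = 1000L,
                 initial_x = 17L)))
  tree <- simulate_from_config(config)
  out <- list(config = config, tree = tree)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cfg_path <- file.path(dir, paste0(kind, ".yaml"))
    tree_path <- file.path(dir, paste0(kind, "_tree.csv"))
    write_config(config, cfg_path)
    write_tree_csv(tree, tree_path)
    out$paths <- c(config = cfg_path, tree = tree_path)
  }
  out
}

#' Read and write run configurations
#'
#' Configurations are plain lists serialized as YAML (JSON is also
#' accepted on read); a round trip is lossless. Every configuration
#' carries a `schema` version field and the full seed, so any run is
#' reproducible from its file.
#'
#' @param config Configuration list.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$schema)) stop("config lacks a schema field",
                                call. = FALSE)
  cfg
}

#' Build model objects from a configuration
#'
#' @param config Configuration list (see [generate_fixture()] for the
#'   schema).
#' @return `network_from_config` a `reaction_network`;
#'   `division_from_config` a `division_model` or selection-rule
#'   function; `simulate_from_config` a simulated `population_tree`.
#' @export
network_from_config <- function(config) {
  m <- config$model
  switch(m$type,
    none = rn_none(),
    birth_death = rn_birth_death(m$k0, m$k1),
    production = rn_production(m$k0),
    bursty = rn_bursty(m$k0, m$b),
    two_stage = rn_two_stage(m$k0, m$k1, m$k2),
    stop("unknown model type: ", m$type, call. = FALSE))
}

#' @rdname network_from_config
#' @export
division_from_config <- function(config) {
  d <- config$division
  if (!is.null(d$rule)) {
    if (d$rule != "hill") stop("unknown division rule: ", d$rule,
                               call. = FALSE)
    return(hill_division_rule(d$tau_max, d$K, d$h))
  }
  switch(d$family,
    exponential = division_exponential(d$rate),
    gamma = division_gamma(d$mean, d$cv),
    lognormal = if (!is.null(d$cv))
      division_lognormal(d$mean, cv = d$cv) else
      division_lognormal(d$mean, sd = d$sd),
    deterministic = division_deterministic(d$tau),
    tabulated = {
      tb <- utils::read.csv(d$table)
      division_tabulated(tb[[1]], tb[[2]])
    },
    stop("unknown division family: ", d$family, call. = FALSE))
}

#' @rdname network_from_config
#' @export
simulate_from_config <- function(config) {
  net <- network_from_config(config)
  div <- division_from_config(config)
  s <- config$sim
  initial <- if (!is.null(s$initial_x))
    list(list(x = rep(as.integer(s$initial_x),
                      length(net$species)))) else NULL
  simulate_population(net, div, initial = initial,
                      t_f = s$t_f, n_max = s$n_max, seed = s$seed)
}

#' Run a full simulate-analyse-compare experiment
#'
#' Orchestrates the pipeline for a configuration: simulates `n_trees`
#' population trees, pools inherited-molecule samples for the history and
#' population ensembles, computes the growth rate and (for the
#' birth-death and bursty models) the analytic inherited distribution,
#' runs the ergodic permutation test, and returns a structured report.
#' With an output directory the report is written as JSON alongside tidy
#' CSVs of the pooled distributions.
#'
#' @param config Configuration list.
#' @param n_trees Number of independent trees (seeds derived from the
#'   config seed).
#' @param out Optional output directory.
#' @param burn_fraction Fraction of each tree's time span discarded as
#'   burn-in when pooling history samples.
#' @return Report list with elements `lambda` (NA for selection rules),
#'   `means` (history/population/forward inherited means), `analytic`
#'   (named pmf or NULL), `test` (the [ergodic_test()] result) and
#'   `verdict` (`"ergodic: rejected"` or `"ergodic: not rejected"`).
#' @export
run_experiment <- function(config, n_trees = 10L, out = NULL,
                           burn_fraction = 0.25) {
  set.seed(as.integer(config$sim$seed))
  div <- division_from_config(config)
  hist_x <- pop_x <- fwd_x <- integer(0)
  for (i in seq_len(n_trees)) {
    cfg_i <- config
    cfg_i$sim$seed <- cell_seed_cpp(as.integer(config$sim$seed), i)
    tree <- simulate_from_config(cfg_i)
    burn <- burn_fraction * tree$t_f
    hist_x <- c(hist_x, inherited_counts(tree, "history",
                                         min_birth_time = burn))
    pop_x <- c(pop_x, inherited_counts(tree, "population",
                                       min_birth_time = burn))
    fwd_x <- c(fwd_x, inherited_counts(tree, "forward", n_lineages = 50L,
                                       min_birth_time = burn))
  }
  lambda <- if (inherits(div, "division_model"))
    solve_growth_rate(div) else NA_real_
  analytic <- switch(config$model$type,
    birth_death = birthdeath_pmf(config$model$k0, config$model$k1,
                                 div, tau = 0),
    bursty = bursty_pmf(config$model$k0, config$model$b, div, tau = 0),
    NULL)
  test <- ergodic_test(counts_distribution(hist_x),
                       counts_distribution(pop_x))
  report <- list(
    kind = config$kind,
    seed = config$sim$seed,
    n_trees = n_trees,
    lambda = lambda,
    means = list(history = mean(hist_x), population = mean(pop_x),
                 forward = mean(fwd_x)),
    analytic = analytic,
    test = test,
    verdict = if (test$violated) "ergodic: rejected"
              else "ergodic: not rejected")
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.csv(
      data.frame(ensemble = rep(c("history", "population", "forward"),
                                c(length(hist_x), length(pop_x),
                                  length(fwd_x))),
                 x = c(hist_x, pop_x, fwd_x)),
      file.path(out, "inherited_counts.csv"), row.names = FALSE)
    jsonlite::write_json(
      report[c("kind", "seed", "n_trees", "lambda", "means", "verdict")],
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    message(sprintf("run_experiment: kind=%s seed=%d lambda=%s %s",
                    config$kind, config$sim$seed, format(lambda),
                    report$verdict))
  }
  report
}
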