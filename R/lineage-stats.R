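#' Enumerate the forward lineages of a population tree
#'
#' A forward lineage runs from a root to one terminal cell; following
#' either daughter with probability 1/2 at each division selects lineage
#' \eqn{j} with probability \eqn{2^{-D_j}}, where \eqn{D_j} is the number
#' of completed divisions on the path. On a tree grown from a single
#' founder these weights sum to one.
#'
#' @param tree A `population_tree`.
#' @return List of `lineage` objects with fields `cells` (cell ids, root
#'   first), `D` and `weight`.
#' @export
enumerate_lineages <- function(tree) {
  stopifnot(inherits(tree, "population_tree"))
  validate_tree(tree)
  term <- tree$cells$cell_id[!tree$cells$divided]
  lapply(term, function(cid) {
    path <- ancestry_path(tree, cid)
    structure(list(cells = path, D = length(path) - 1L,
                   weight = 2^-(length(path) - 1L)),
              class = "lineage")
  })
}

ancestry_path <- function(tree, cid) {
  pid <- tree$cells$parent_id
  path <- integer(0)
  cur <- cid
  while (!is.na(cur)) { path <- c(cur, path); cur <- pid[cur] }
  path
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> %d cells, %d divisions, weight %.4g\n",
              length(x$cells), x$D, x$weight))
  invisible(x)
}

#' Sample cell histories from a population tree
#'
#' A history picks a cell alive at the final time uniformly at random and
#' traces its ancestry back to the founder; every history therefore has
#' the same sampling weight \eqn{1/N(t_f)}. Division times along
#' histories follow the ancestral law \eqn{\rho}, not \eqn{\phi}.
#'
#' @param tree A `population_tree`.
#' @param n Number of histories to sample (with replacement).
#' @return List of `lineage` objects with uniform weights.
#' @export
sample_histories <- function(tree, n) {
  stopifnot(inherits(tree, "population_tree"), n >= 1)
  term <- tree$cells$cell_id[!tree$cells$divided]
  if (length(term) == 0L) stop("no cells alive at the final time",
                               call. = FALSE)
  picks <- term[sample.int(length(term), n, replace = TRUE)]
  lapply(picks, function(cid) {
    path <- ancestry_path(tree, cid)
    structure(list(cells = path, D = length(path) - 1L, weight = 1 / n),
              class = "lineage")
  })
}

# molecule state of one cell at a given age (exact substream replay)
x_at_age <- function(tree, cid, tau) {
  if (tau == 0) return(tree$x_birth[cid, ])
  if (is.null(tree$network))
    stop("state reconstruction requires a simulated tree", call. = FALSE)
  if (nrow(tree$network$reactants) == 0L) return(tree$x_birth[cid, ])
  set.seed(cell_seed_cpp(tree$seed, cid))
  ssa_advance(tree$x_birth[cid, ], tree$network, tau)
}

#' Average of a trait over one lineage at a fixed age
#'
#' Averages `f(x)` over the cells of the lineage that reach age `tau`
#' before dividing (for the terminal cell: before the end of observation),
#' evaluating each cell's molecule state at that age. Returns `NA` when no
#' cell in the lineage qualifies.
#'
#' @param tree A `population_tree`.
#' @param lineage A `lineage`.
#' @param f Function of the molecule-count vector; default: count of the
#'   first species.
#' @param tau Age at which cells are evaluated.
#' @return Scalar average, or `NA` if undefined.
#' @export
lineage_age_average <- function(tree, lineage, f = NULL, tau = 0) {
  stopifnot(inherits(lineage, "lineage"), tau >= 0)
  if (is.null(f)) f <- function(x) x[1]
  vals <- numeric(0)
  for (cid in lineage$cells) {
    reach <- if (tree$cells$divided[cid]) tree$cells$division_age[cid] >= tau
             else (tree$t_f - tree$cells$birth_time[cid]) >= tau
    if (reach) vals <- c(vals, f(x_at_age(tree, cid, tau)))
  }
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

#' Ensemble average of a trait at a fixed age
#'
#' Weighted average of [lineage_age_average()] across lineages: forward
#' lineages carry weights \eqn{2^{-D}}, histories are uniform. Lineages
#' undefined at `tau` are dropped (with their weight); an error is raised
#' if none qualifies.
#'
#' @param tree A `population_tree`.
#' @param lineages List of `lineage` objects.
#' @param f Trait function of the molecule-count vector.
#' @param tau Age.
#' @param ensemble `"forward"` (use the stored \eqn{2^{-D}} weights) or
#'   `"history"` (uniform).
#' @return Scalar ensemble average.
#' @export
ensemble_average <- function(tree, lineages, f = NULL, tau = 0,
                             ensemble = c("forward", "history")) {
  ensemble <- match.arg(ensemble)
  stopifnot(length(lineages) >= 1L)
  vals <- vapply(lineages, function(ln)
    lineage_age_average(tree, ln, f, tau), numeric(1))
  w <- switch(ensemble,
              forward = vapply(lineages, `[[`, numeric(1), "weight"),
              history = rep(1, length(lineages)))
  ok <- !is.na(vals)
  if (!any(ok)) stop("no lineage reaches age tau", call. = FALSE)
  sum(w[ok] * vals[ok]) / sum(w[ok])
}

#' Inherited-molecule samples from the three ensembles
#'
#' Extracts molecule counts at birth (the inherited molecules, age
#' \eqn{\tau = 0}) under the different weightings of a population tree:
#' \describe{
#'   \item{`population`}{counts inherited by the cells alive at the final
#'     time (the age-sorted snapshot ensemble; for a trait that is not
#'     degraded the inherited count is age-independent).}
#'   \item{`history`}{counts along cell histories. With
#'     `multiplicity = "distinct"` (default) the distinct cells appearing
#'     in the histories of all final cells are pooled, each once; with
#'     `"descendant"` cells are pooled over `n_lineages` sampled
#'     histories, so an ancestor appears once per sampled descendant.
#'     The two weightings agree when the trait does not affect division
#'     timing.}
#'   \item{`forward`}{counts along `n_lineages` forward lineages (random
#'     daughter walks from the root), excluding the terminal unfinished
#'     cell.}
#' }
#'
#' @param tree A `population_tree`.
#' @param ensemble Which weighting to use.
#' @param species Species index or name.
#' @param min_birth_time Discard cells born before this time (burn-in).
#' @param n_lineages Number of sampled lineages where sampling is needed.
#' @param multiplicity Weighting of ancestral cells in histories.
#' @return Integer vector of inherited molecule counts.
#' @export
inherited_counts <- function(tree,
                             ensemble = c("population", "history",
                                          "forward"),
                             species = 1L, min_birth_time = 0,
                             n_lineages = 200L,
                             multiplicity = c("distinct", "descendant")) {
  ensemble <- match.arg(ensemble)
  multiplicity <- match.arg(multiplicity)
  stopifnot(inherits(tree, "population_tree"))
  xb <- tree$x_birth[, species]
  b <- tree$cells$birth_time
  switch(ensemble,
    population = xb[!tree$cells$divided & b >= min_birth_time],
    history = {
      if (multiplicity == "distinct") {
        # union of the histories of all final cells = every recorded cell
        xb[b >= min_birth_time]
      } else {
        hs <- sample_histories(tree, n_lineages)
        ids <- unlist(lapply(hs, `[[`, "cells"))
        xb[ids[b[ids] >= min_birth_time]]
      }
    },
    forward = {
      ids <- unlist(lapply(seq_len(n_lineages), function(i) {
        path <- forward_walk(tree)
        path[-length(path)]  # drop the censored terminal cell
      }))
      xb[ids[b[ids] >= min_birth_time]]
    })
}

# one forward lineage: random daughter walk from a root
forward_walk <- function(tree) {
  roots <- tree$cells$cell_id[is.na(tree$cells$parent_id)]
  cur <- if (length(roots) == 1L) roots else
    roots[sample.int(length(roots), 1L)]
  path <- cur
  pid <- tree$cells$parent_id
  repeat {
    kids <- tree$cells$cell_id[!is.na(pid) & pid == cur]
    if (length(kids) == 0L) break
    cur <- kids[sample.int(2L, 1L)]
    path <- c(path, cur)
  }
  path
}

#' Realized division times from a population tree
#'
#' Division times of completed cells under the history weighting (they
#' follow the ancestral law \eqn{\rho}) or along forward lineages (they
#' follow \eqn{\phi}). For forward lineages, cells born close to the
#' final observation time are right-censored (slow dividers are still
#' alive and drop out), so `max_birth_time` should be set a few division
#' times before the end when unbiased draws from \eqn{\phi} are wanted.
#' Walks from one tree share early ancestry, so pooled draws are not
#' independent; pool few walks from many trees for testing.
#'
#' @inheritParams inherited_counts
#' @param max_birth_time Discard cells born after this time (forward
#'   ensemble; guards against right-censoring).
#' @return Numeric vector of realized division times.
#' @export
division_times <- function(tree, ensemble = c("history", "forward"),
                           min_birth_time = 0,
                           max_birth_time = Inf, n_lineages = 200L) {
  ensemble <- match.arg(ensemble)
  b <- tree$cells$birth_time
  switch(ensemble,
    history = tree$cells$division_age[tree$cells$divided &
                                      b >= min_birth_time &
                                      b <= max_birth_time],
    forward = {
      ids <- unlist(lapply(seq_len(n_lineages), function(i) {
        path <- forward_walk(tree)
        path[-length(path)]
      }))
      ids <- ids[b[ids] >= min_birth_time & b[ids] <= max_birth_time &
                 tree$cells$divided[ids]]
      tree$cells$division_age[ids]
    })
}

#' Sort a population snapshot into age bins
#'
#' Builds the empirical conditional distributions of molecule count given
#' cell age: for each age bin the pmf of the counts of the cells in it.
#' The first bin is the estimator of the inherited-molecule distribution
#' at age zero. Empty bins are flagged absent rather than zero-filled.
#'
#' @param snap A snapshot data frame from [snapshot()], or any data frame
#'   with an `age` column and a count column.
#' @param breaks Age bin edges (strictly increasing).
#' @param trait Name of the count column (default: first `x_` column).
#' @return An `age_sorted_distribution`: list with `breaks` and `bins`, a
#'   list per bin with elements `n`, `x` (raw counts) and `pmf`
#'   (named table), or `NULL` for empty bins.
#' @export
age_sorted <- function(snap, breaks, trait = NULL) {
  stopifnot(nrow(snap) >= 1L, !is.unsorted(breaks, strictly = TRUE))
  if (is.null(trait)) trait <- grep("^x_", names(snap), value = TRUE)[1]
  idx <- findInterval(snap$age, breaks, rightmost.closed = TRUE)
  bins <- vector("list", length(breaks) - 1L)
  for (b in seq_along(bins)) {
    xs <- snap[[trait]][idx == b]
    bins[[b]] <- if (length(xs) == 0L) NULL else
      list(n = length(xs), x = xs,
           pmf = table(xs) / length(xs))
  }
  structure(list(breaks = breaks, bins = bins, trait = trait),
            class = "age_sorted_distribution")
}

#' Build a single-bin age-sorted distribution from raw counts
#'
#' Convenience wrapper for count samples that are already conditioned on
#' an age (e.g. inherited molecules at birth).
#'
#' @param x Integer counts.
#' @return An `age_sorted_distribution` with one bin.
#' @export
counts_distribution <- function(x) {
  structure(list(breaks = c(0, Inf),
                 bins = list(list(n = length(x), x = x,
                                  pmf = table(x) / length(x))),
                 trait = "x"),
            class = "age_sorted_distribution")
}

#' @export
print.age_sorted_distribution <- function(x, ...) {
  ns <- vapply(x$bins, function(b) if (is.null(b)) 0L else b$n, integer(1))
  cat(sprintf("<age_sorted_distribution> %d bins, counts: %s\n",
              length(x$bins), paste(ns, collapse = ", ")))
  invisible(x)
}

#' Fisher's reproductive value from history and population distributions
#'
#' The reproductive value of a phenotypic state measures the relative
#' number of future offspring of cells in that state. It factorizes into a
#' trait part, estimated per age bin as the ratio of the history
#' conditional pmf to the age-sorted population conditional pmf, and an
#' age part \eqn{\nu(\tau) = \Pi_h(\tau)/\Pi(\tau)}. Under trait-blind
#' division timing the trait part is identically one (the ergodic
#' principle); when high expression is selected it increases with the
#' count. States where the population pmf falls below `min_count / n` are
#' masked (`NA`) because the ratio estimator explodes on tails.
#'
#' @param history,population `age_sorted_distribution` objects on matched
#'   bins.
#' @param min_count Support threshold (expected population count below
#'   which the ratio is masked).
#' @return List with `nu_x` (one data frame `x`, `nu` per bin, or `NULL`)
#'   and `nu_age` (data frame with per-bin occupancy ratio).
#' @export
reproductive_value <- function(history, population, min_count = 5) {
  stopifnot(inherits(history, "age_sorted_distribution"),
            inherits(population, "age_sorted_distribution"),
            isTRUE(all.equal(history$breaks, population$breaks)))
  nb <- length(population$bins)
  nu_x <- vector("list", nb)
  nh_tot <- sum(vapply(history$bins, function(b)
    if (is.null(b)) 0L else b$n, integer(1)))
  np_tot <- sum(vapply(population$bins, function(b)
    if (is.null(b)) 0L else b$n, integer(1)))
  occ_h <- occ_p <- numeric(nb)
  for (b in seq_len(nb)) {
    hb <- history$bins[[b]]; pb <- population$bins[[b]]
    occ_h[b] <- if (is.null(hb)) 0 else hb$n / nh_tot
    occ_p[b] <- if (is.null(pb)) 0 else pb$n / np_tot
    if (is.null(hb) || is.null(pb)) next
    states <- sort(unique(c(as.integer(names(hb$pmf)),
                            as.integer(names(pb$pmf)))))
    ph <- as.numeric(hb$pmf[as.character(states)]); ph[is.na(ph)] <- 0
    pp <- as.numeric(pb$pmf[as.character(states)]); pp[is.na(pp)] <- 0
    nu <- ifelse(pp >= min_count / pb$n, ph / pp, NA_real_)
    nu_x[[b]] <- data.frame(x = states, nu = nu)
  }
  list(nu_x = nu_x,
       nu_age = data.frame(bin = seq_len(nb),
                           nu = ifelse(occ_p > 0, occ_h / occ_p,
                                       NA_real_)))
}

#' Permutation test of the ergodic principle
#'
#' Tests whether the history distribution equals the age-sorted population
#' distribution, per age bin, using the total-variation distance between
#' the empirical pmfs as statistic with a pooled-resampling permutation
#' null; the Kolmogorov-Smirnov distance is reported alongside. With
#' several bins the per-bin p-values are Bonferroni-adjusted, and the
#' principle is flagged violated when any adjusted p-value falls below
#' `alpha`. Equality is expected exactly when the trait does not influence
#' division timing, so rejection is evidence of selection on the trait.
#'
#' @param history,population `age_sorted_distribution` objects on matched
#'   bins (e.g. from [counts_distribution()]).
#' @param n_perm Number of permutation resamples.
#' @param alpha Significance level applied to adjusted p-values.
#' @return List with a per-bin data frame `bins` (TV and KS distances,
#'   raw and adjusted p-values) and the overall logical `violated`.
#' @export
ergodic_test <- function(history, population, n_perm = 500L,
                         alpha = 0.01) {
  stopifnot(inherits(history, "age_sorted_distribution"),
            inherits(population, "age_sorted_distribution"))
  nb <- length(population$bins)
  res <- data.frame(bin = seq_len(nb), n_history = NA_integer_,
                    n_population = NA_integer_, tv = NA_real_,
                    ks = NA_real_, p = NA_real_)
  for (b in seq_len(nb)) {
    hb <- history$bins[[b]]; pb <- population$bins[[b]]
    if (is.null(hb) || is.null(pb)) next
    res$n_history[b] <- hb$n; res$n_population[b] <- pb$n
    res$tv[b] <- tv_distance(hb$x, pb$x)
    res$ks[b] <- ks_distance(hb$x, pb$x)
    pooled <- c(hb$x, pb$x)
    nh <- hb$n
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), nh)
      if (tv_distance(pooled[idx], pooled[-idx]) >= res$tv[b])
        exceed <- exceed + 1L
    }
    res$p[b] <- (exceed + 1) / (n_perm + 1)
  }
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- pmin(res$p[tested] * sum(tested), 1)
  list(bins = res,
       violated = any(res$p_adj[tested] < alpha))
}

# total variation between two empirical pmfs over integer support
tv_distance <- function(x, y) {
  states <- sort(unique(c(x, y)))
  px <- tabulate(match(x, states), length(states)) / length(x)
  py <- tabulate(match(y, states), length(states)) / length(y)
  sum(abs(px - py)) / 2
}

ks_distance <- function(x, y) {
  states <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(states)
  Fy <- stats::ecdf(y)(states)
  max(abs(Fx - Fy))
}

# total variation between an empirical sample and a reference pmf
# (reference given as a vector over 0..length-1)
tv_to_pmf <- function(x, pmf) {
  k <- length(pmf)
  px <- tabulate(x + 1L, k) / length(x)
  extra <- mean(x > k - 1L)
  (sum(abs(px - pmf)) + extra + abs(1 - sum(pmf))) / 2
}
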