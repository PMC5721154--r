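#' Division-time draw for a newborn cell
#'
#' Under trait-independent timing the division time is drawn from the
#' division-time law \eqn{\phi}. Under an expression-coupled (selection)
#' rule the division time is a function of the molecule counts at birth,
#' evaluated at the moment of birth.
#'
#' @param division A `division_model`, or a function of the molecule-count
#'   vector at birth returning a division time (a selection rule).
#' @param x_birth Molecule counts at birth (used only by selection rules).
#' @return A single division time.
#' @export
draw_division_time <- function(division, x_birth = NULL) {
  if (inherits(division, "division_model")) {
    tau <- division_sample(division, 1L)
  } else if (is.function(division)) {
    tau <- division(x_birth)
  } else stop("`division` must be a division_model or a function",
              call. = FALSE)
  if (!is.finite(tau) || tau < 0)
    stop("drawn division time is negative or non-finite", call. = FALSE)
  tau
}

#' Hill-type selection rule for division timing
#'
#' Division occurs after a period
#' \eqn{\tau_d = \tau_{max} K^h / (K^h + x_0^h)} where \eqn{x_0} is the
#' count of the selected species at birth: high expression shortens the
#' interdivision time, so the trait is under positive selection.
#'
#' @param tau_max Maximal division period (at zero expression).
#' @param K Half-saturation count.
#' @param h Hill exponent.
#' @param species Index of the selected species.
#' @return A function usable as the `division` argument of
#'   [simulate_population()].
#' @export
hill_division_rule <- function(tau_max = 50, K = 10, h = 10, species = 1L) {
  force(tau_max); force(K); force(h); force(species)
  function(x_birth) tau_max * K^h / (K^h + as.numeric(x_birth[species])^h)
}

#' Partition a mother's molecules between two daughters
#'
#' Binomial partitioning assigns each molecule independently to daughter 1
#' with probability 1/2; daughter 2 always receives the remainder, so
#' total molecule numbers are conserved exactly at every division.
#'
#' @param x_mother Integer vector of mother molecule counts at division.
#' @param kernel Partitioning kernel; only `"binomial"` is built in.
#' @return List with integer vectors `x1` and `x2`.
#' @export
partition_molecules <- function(x_mother, kernel = "binomial") {
  if (any(x_mother != round(x_mother)) || any(x_mother < 0))
    stop("molecule counts must be nonnegative integers", call. = FALSE)
  kernel <- match.arg(kernel, "binomial")
  x1 <- stats::rbinom(length(x_mother), as.integer(round(x_mother)), 0.5)
  list(x1 = as.integer(x1), x2 = as.integer(round(x_mother)) - as.integer(x1))
}

#' Advance a cell's chemistry by exact stochastic simulation
#'
#' Runs the Gillespie algorithm for `duration` time units from state `x`.
#' With zero total propensity the state is frozen until the end of the
#' interval. Optionally samples the state at a set of intermediate ages.
#'
#' @param x Integer state vector.
#' @param network A `reaction_network`.
#' @param duration Nonnegative time interval.
#' @param record_ages Optional sorted ages in `[0, duration]` at which to
#'   record the state.
#' @return Integer final state, or (with `record_ages`) a list with the
#'   final state `x` and a `trajectory` matrix.
#' @export
ssa_advance <- function(x, network, duration, record_ages = NULL) {
  stopifnot(inherits(network, "reaction_network"), duration >= 0)
  rec <- if (is.null(record_ages)) numeric(0) else as.numeric(record_ages)
  out <- ssa_advance_cpp(as.integer(x), network$reactants, network$change,
                         network$rates, network$burst_mean, duration, rec)
  if (is.null(record_ages)) out$x else out
}

#' Simulate a growing cell population (first division algorithm)
#'
#' Event-driven exact simulation of a clonal population: the next dividing
#' cell is the one minimizing residual time to division; all chemistry is
#' advanced by the stochastic simulation algorithm; at division the mother
#' is replaced by two age-zero daughters with binomially partitioned
#' molecules and freshly drawn division times. Because chemistry in
#' different cells is independent between divisions, each cell's reactions
#' are simulated over its whole lifetime in one pass from a per-cell RNG
#' substream keyed on the cell id, which makes trees bit-reproducible for
#' a given seed and lets [snapshot()] reconstruct states at arbitrary
#' times exactly. Ties in the next-divider ordering (possible for
#' deterministic timing) are broken by lowest cell id.
#'
#' @param network A `reaction_network` for the intracellular chemistry.
#' @param division A `division_model` or a selection rule (see
#'   [hill_division_rule()]).
#' @param initial List of founder cells, each a list with elements `x`
#'   (integer counts) and optionally `tau_d`; default a single founder
#'   with all counts zero.
#' @param t_f Final time; give either `t_f` or `n_max`.
#' @param n_max Stop when the number of living cells reaches `n_max`; the
#'   final time is then the time of the last division.
#' @param seed Integer seed (required: every run is reproducible).
#' @param n_cap Hard cap on total simulated cells; exceeding it stops the
#'   simulation gracefully with the partial tree flagged.
#' @return An object of class `population_tree`.
#' @examples
#' tr <- simulate_population(rn_none(), division_deterministic(1),
#'                           t_f = 3.5, seed = 1)
#' sum(alive_cells(tr))  # 8 cells after 3 synchronous doublings
#' @export
simulate_population <- function(network, division, initial = NULL,
                                t_f = NULL, n_max = NULL, seed,
                                n_cap = 1e5) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(t_f) == is.null(n_max))
    stop("give exactly one of `t_f` or `n_max`", call. = FALSE)
  if (!is.null(t_f)) stopifnot(t_f > 0)
  if (!is.null(n_max)) stopifnot(n_max >= 2)
  seed <- as.integer(seed)
  ns <- length(network$species)
  no_chem <- nrow(network$reactants) == 0L

  if (is.null(initial))
    initial <- list(list(x = integer(ns)))

  cap <- 1024L
  parent <- rep(NA_integer_, cap); birth <- numeric(cap)
  tau_d <- numeric(cap); divided <- logical(cap)
  xb <- matrix(NA_integer_, cap, ns); xd <- matrix(NA_integer_, cap, ns)
  n <- 0L
  grow <- function(k) {
    while (k > cap) {
      cap <<- cap * 2L
      parent <<- c(parent, rep(NA_integer_, cap / 2L))
      birth <<- c(birth, numeric(cap / 2L))
      tau_d <<- c(tau_d, numeric(cap / 2L))
      divided <<- c(divided, logical(cap / 2L))
      xb <<- rbind(xb, matrix(NA_integer_, cap / 2L, ns))
      xd <<- rbind(xd, matrix(NA_integer_, cap / 2L, ns))
    }
  }

  # binary min-heap on (division event time, cell id)
  ht <- numeric(0); hid <- integer(0)
  heap_less <- function(i, j)
    ht[i] < ht[j] || (ht[i] == ht[j] && hid[i] < hid[j])
  heap_push <- function(tm, id) {
    ht <<- c(ht, tm); hid <<- c(hid, id)
    i <- length(ht)
    while (i > 1L) {
      p <- i %/% 2L
      if (heap_less(i, p)) {
        tmp <- ht[p]; ht[p] <<- ht[i]; ht[i] <<- tmp
        tmpi <- hid[p]; hid[p] <<- hid[i]; hid[i] <<- tmpi
        i <- p
      } else break
    }
  }
  heap_pop <- function() {
    res <- c(ht[1], hid[1])
    k <- length(ht)
    ht[1] <<- ht[k]; hid[1] <<- hid[k]
    ht <<- ht[-k]; hid <<- hid[-k]
    i <- 1L; k <- k - 1L
    repeat {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= k && heap_less(l, m)) m <- l
      if (r <= k && heap_less(r, m)) m <- r
      if (m == i) break
      tmp <- ht[m]; ht[m] <<- ht[i]; ht[i] <<- tmp
      tmpi <- hid[m]; hid[m] <<- hid[i]; hid[i] <<- tmpi
      i <- m
    }
    res
  }

  add_cell <- function(pid, tm, x, td) {
    n <<- n + 1L; grow(n)
    parent[n] <<- pid; birth[n] <<- tm; tau_d[n] <<- td
    xb[n, ] <<- as.integer(x)
    heap_push(tm + td, n)
    n
  }

  # founders: division times drawn (if absent) from the founder stream
  set.seed(cell_seed_cpp(seed, 0L))
  for (cell in initial) {
    x0 <- as.integer(cell$x)
    stopifnot(length(x0) == ns, all(x0 >= 0))
    td <- if (!is.null(cell$tau_d)) cell$tau_d else
      draw_division_time(division, x0)
    add_cell(NA_integer_, 0, x0, td)
  }

  n_alive <- length(initial)
  t_now <- 0
  truncated <- FALSE
  repeat {
    if (length(ht) == 0L) break
    t_next <- ht[1]
    if (!is.null(t_f) && t_next > t_f) { t_now <- t_f; break }
    ev <- heap_pop()
    t_now <- ev[1]; cid <- as.integer(ev[2])
    # mother's substream: chemistry over her lifetime, then partitioning
    # and the daughters' division-time draws
    set.seed(cell_seed_cpp(seed, cid))
    x_div <- if (no_chem) xb[cid, ] else
      ssa_advance(xb[cid, ], network, tau_d[cid])
    xd[cid, ] <- x_div
    divided[cid] <- TRUE
    halves <- partition_molecules(x_div)
    td1 <- draw_division_time(division, halves$x1)
    td2 <- draw_division_time(division, halves$x2)
    add_cell(cid, t_now, halves$x1, td1)
    add_cell(cid, t_now, halves$x2, td2)
    n_alive <- n_alive + 1L
    if (!is.null(n_max) && n_alive >= n_max) break
    if (n > n_cap) { truncated <- TRUE; warning(
      "population cap reached; returning partial tree"); break }
  }
  t_final <- if (!is.null(t_f) && !truncated && is.null(n_max)) t_f else t_now

  idx <- seq_len(n)
  cells <- data.frame(cell_id = idx, parent_id = parent[idx],
                      birth_time = birth[idx], division_age = tau_d[idx],
                      divided = divided[idx])
  xb <- xb[idx, , drop = FALSE]; xd <- xd[idx, , drop = FALSE]
  xd[!divided[idx], ] <- NA_integer_
  colnames(xb) <- colnames(xd) <- network$species

  tree <- structure(list(cells = cells, x_birth = xb, x_division = xd,
                         x_final = NULL, species = network$species,
                         t_f = t_final, seed = seed, network = network,
                         division = division, truncated = truncated),
                    class = "population_tree")
  tree$x_final <- reconstruct_states(tree, t_final)
  tree
}

# exact per-cell state reconstruction at time t via substream replay
reconstruct_states <- function(tree, t) {
  al <- which(alive_at(tree, t))
  ns <- length(tree$species)
  out <- matrix(NA_integer_, nrow(tree$cells), ns)
  colnames(out) <- tree$species
  net <- tree$network
  no_chem <- nrow(net$reactants) == 0L
  for (cid in al) {
    if (no_chem) { out[cid, ] <- tree$x_birth[cid, ]; next }
    set.seed(cell_seed_cpp(tree$seed, cid))
    out[cid, ] <- ssa_advance(tree$x_birth[cid, ], net,
                              t - tree$cells$birth_time[cid])
  }
  out
}

alive_at <- function(tree, t) {
  b <- tree$cells$birth_time
  b <= t & b + tree$cells$division_age > t
}

#' Which cells are alive at the final time?
#'
#' @param tree A `population_tree`.
#' @return Logical vector over cells.
#' @export
alive_cells <- function(tree) {
  stopifnot(inherits(tree, "population_tree"))
  !tree$cells$divided
}

#' @export
print.population_tree <- function(x, ...) {
  cat(sprintf(
    "<population_tree> %d cells (%d alive at t_f = %.4g), seed %d%s\n",
    nrow(x$cells), sum(!x$cells$divided), x$t_f, x$seed,
    if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Population snapshot at a time point
#'
#' Returns one row per cell alive at `t` with its age and exact molecule
#' counts, reconstructed from the per-cell RNG substreams. The joint
#' (age, count) sample is the empirical analogue of the age-sorted
#' population distribution.
#'
#' @param tree A simulated `population_tree`.
#' @param t Time point, at most the final time (default: final time).
#' @return Data frame with `cell_id`, `age` and one `x_<species>` column
#'   per species.
#' @export
snapshot <- function(tree, t = NULL) {
  stopifnot(inherits(tree, "population_tree"))
  if (is.null(t)) t <- tree$t_f
  if (t > tree$t_f) stop("t beyond the simulated horizon", call. = FALSE)
  x <- if (t == tree$t_f && !is.null(tree$x_final)) tree$x_final else {
    if (is.null(tree$network))
      stop("state reconstruction requires a simulated tree", call. = FALSE)
    reconstruct_states(tree, t)
  }
  al <- which(alive_at(tree, t))
  out <- data.frame(cell_id = al, age = t - tree$cells$birth_time[al])
  xs <- x[al, , drop = FALSE]
  colnames(xs) <- paste0("x_", tree$species)
  cbind(out, as.data.frame(xs))
}

#' Write and read population trees as CSV tables
#'
#' One row per cell with columns `cell_id`, `parent_id`, `birth_time`,
#' `division_time_drawn`, `divided`, and `x_birth_<species>` /
#' `x_division_<species>` count columns; a `#` comment header carries the
#' final time, seed and species so a round trip is lossless for the
#' genealogy and recorded states (trajectory reconstruction requires the
#' original simulation object). The same reader ingests external
#' lineage-tree tables with these columns, e.g. from cell tracking.
#'
#' @param tree A `population_tree`.
#' @param path File path.
#' @return `read_tree_csv` returns a `population_tree` (without
#'   reconstruction support); `write_tree_csv` returns `path` invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  stopifnot(inherits(tree, "population_tree"))
  df <- tree$cells
  df <- df[, c("cell_id", "parent_id", "birth_time", "division_age",
               "divided")]
  names(df)[4] <- "division_time_drawn"
  xb <- tree$x_birth; colnames(xb) <- paste0("x_birth_", tree$species)
  xd <- tree$x_division; colnames(xd) <- paste0("x_division_", tree$species)
  df <- cbind(df, as.data.frame(xb), as.data.frame(xd))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# snapclone_tree t_f=%.17g seed=%d species=%s",
                     tree$t_f, tree$seed,
                     paste(tree$species, collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(t_f = NA_real_, seed = NA_integer_, species = NULL)
  skip <- 0L
  if (startsWith(first, "# snapclone_tree")) {
    skip <- 1L
    kv <- strsplit(sub("^# snapclone_tree ", "", first), " ")[[1]]
    for (item in kv) {
      p <- strsplit(item, "=")[[1]]
      if (p[1] == "t_f") meta$t_f <- as.numeric(p[2])
      if (p[1] == "seed") meta$seed <- as.integer(p[2])
      if (p[1] == "species") meta$species <- strsplit(p[2], ",")[[1]]
    }
  }
  df <- utils::read.csv(path, skip = skip)
  req <- c("cell_id", "parent_id", "birth_time", "division_time_drawn")
  if (!all(req %in% names(df)))
    stop("tree table lacks required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  xbc <- grep("^x_birth_", names(df), value = TRUE)
  species <- if (!is.null(meta$species)) meta$species else
    sub("^x_birth_", "", xbc)
  xb <- as.matrix(df[, paste0("x_birth_", species), drop = FALSE])
  colnames(xb) <- species
  xdc <- paste0("x_division_", species)
  xd <- if (all(xdc %in% names(df)))
    as.matrix(df[, xdc, drop = FALSE]) else
    matrix(NA_integer_, nrow(df), length(species))
  colnames(xd) <- species
  t_f <- if (is.finite(meta$t_f)) meta$t_f else max(df$birth_time)
  divided <- if ("divided" %in% names(df)) as.logical(df$divided) else
    df$cell_id %in% df$parent_id
  cells <- data.frame(cell_id = df$cell_id, parent_id = df$parent_id,
                      birth_time = df$birth_time,
                      division_age = df$division_time_drawn,
                      divided = divided)
  validate_tree(structure(
    list(cells = cells, x_birth = xb, x_division = xd, x_final = NULL,
         species = species, t_f = t_f, seed = meta$seed, network = NULL,
         division = NULL, truncated = FALSE),
    class = "population_tree"))
}

# structural invariants: binary divisions, conservation where recorded
validate_tree <- function(tree) {
  kids <- table(factor(tree$cells$parent_id,
                       levels = tree$cells$cell_id))
  nd <- kids[as.character(tree$cells$cell_id[tree$cells$divided])]
  if (length(nd) && any(nd != 2L))
    stop("malformed tree: a divided cell must have exactly 2 children",
         call. = FALSE)
  und <- kids[as.character(tree$cells$cell_id[!tree$cells$divided])]
  if (length(und) && any(und != 0L))
    stop("malformed tree: an undivided cell cannot have children",
         call. = FALSE)
  for (i in which(tree$cells$divided)) {
    if (any(is.na(tree$x_division[i, ]))) next
    ch <- which(tree$cells$parent_id == tree$cells$cell_id[i])
    if (length(ch) == 2L && !any(is.na(tree$x_birth[ch, ]))) {
      if (!all(colSums(tree$x_birth[ch, , drop = FALSE]) ==
               tree$x_division[i, ]))
        stop("molecule conservation violated at a division", call. = FALSE)
    }
  }
  tree
}
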