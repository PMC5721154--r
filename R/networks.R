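#' Intracellular reaction networks
#'
#' A `reaction_network` collects the species names, the reactant and
#' product stoichiometry matrices and the mass-action rate constants of
#' the chemistry running inside each cell. Propensities follow the
#' stochastic mass-action convention: a reaction with reactant
#' stoichiometry \eqn{\nu^-} has propensity
#' \eqn{w_r(x) = k_r \prod_i x_i (x_i - 1) \cdots (x_i - \nu^-_{ir} + 1)}.
#' A reaction may optionally produce a geometric burst of its (single)
#' product, which is how the bursty protein model enters the simulator.
#'
#' @param species Character vector of species names.
#' @param reactants,products Integer matrices (reactions in rows, species
#'   in columns) of reactant and product stoichiometric coefficients.
#' @param rates Numeric vector of rate constants, one per reaction.
#' @param burst_mean Numeric vector, one per reaction: `NA` for an
#'   ordinary reaction, or the mean `b` of a geometric burst-size
#'   distribution on \{0, 1, 2, ...\} applied to the reaction's product.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactants, products, rates,
                             burst_mean = NULL) {
  species <- as.character(species)
  ns <- length(species)
  reactants <- matrix(as.integer(reactants), ncol = ns)
  products <- matrix(as.integer(products), ncol = ns)
  nr <- nrow(reactants)
  stopifnot(nrow(products) == nr, length(rates) == nr, all(rates >= 0),
            all(reactants >= 0), all(products >= 0))
  if (is.null(burst_mean)) burst_mean <- rep(NA_real_, nr)
  stopifnot(length(burst_mean) == nr)
  for (r in which(!is.na(burst_mean))) {
    if (sum(products[r, ]) != 1L)
      stop("a burst reaction must have a single unit product", call. = FALSE)
  }
  structure(list(species = species,
                 reactants = reactants, products = products,
                 change = products - reactants,
                 rates = as.numeric(rates),
                 burst_mean = as.numeric(burst_mean)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              nrow(x$reactants)))
  invisible(x)
}

#' Stoichiometric change vectors
#'
#' @param network A `reaction_network`.
#' @return Matrix of net stoichiometric changes (reactions in rows).
#' @export
stoichiometry <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  network$change
}

#' Mass-action propensities at a state
#'
#' @param network A `reaction_network`.
#' @param x Integer state vector (molecule counts).
#' @return Numeric vector of reaction propensities.
#' @export
propensities <- function(network, x) {
  stopifnot(inherits(network, "reaction_network"),
            length(x) == length(network$species))
  vapply(seq_len(nrow(network$reactants)), function(r) {
    w <- network$rates[r]
    for (i in seq_along(x)) {
      m <- network$reactants[r, i]
      if (m > 0L) w <- w * prod(x[i] - seq_len(m) + 1L)
    }
    max(w, 0)
  }, numeric(1))
}

#' Canonical model networks
#'
#' Convenience constructors for the gene-expression models studied with
#' the population framework:
#' \itemize{
#'   \item `rn_birth_death(k0, k1)`: synthesis at constant rate `k0`,
#'     first-order degradation at rate `k1`.
#'   \item `rn_production(k0)`: pure synthesis (a stable molecule).
#'   \item `rn_bursty(k0, b)`: bursts arriving at rate `k0`, each adding a
#'     geometric number of stable proteins with mean `b` (the short
#'     mRNA-lifetime reduction of the two-stage model, with
#'     `b = k2 / k1`).
#'   \item `rn_two_stage(k0, k1, k2)`: full transcription-translation
#'     model (mRNA made at `k0`, degraded at `k1`, translated at `k2`).
#' }
#'
#' @param k0,k1,k2,b Rate constants and mean burst size.
#' @return A `reaction_network`.
#' @name model_networks
NULL

#' @rdname model_networks
#' @export
rn_birth_death <- function(k0, k1) {
  reaction_network("x",
                   reactants = rbind(0L, 1L),
                   products = rbind(1L, 0L),
                   rates = c(k0, k1))
}

#' @rdname model_networks
#' @export
rn_production <- function(k0) {
  reaction_network("x", reactants = rbind(0L), products = rbind(1L),
                   rates = k0)
}

#' @rdname model_networks
#' @export
rn_bursty <- function(k0, b) {
  reaction_network("protein", reactants = rbind(0L), products = rbind(1L),
                   rates = k0, burst_mean = b)
}

#' @rdname model_networks
#' @export
rn_two_stage <- function(k0, k1, k2) {
  reaction_network(
    c("mrna", "protein"),
    reactants = rbind(c(0L, 0L), c(1L, 0L), c(1L, 0L)),
    products = rbind(c(1L, 0L), c(0L, 0L), c(1L, 1L)),
    rates = c(k0, k1, k2))
}

#' Empty network (no reactions)
#'
#' Cells whose traits do not change between divisions; useful for pure
#' division-timing studies.
#' @param species Species names to carry through divisions.
#' @return A `reaction_network` with zero reactions.
#' @export
rn_none <- function(species = "x") {
  ns <- length(species)
  reaction_network(species,
                   reactants = matrix(integer(0), 0, ns),
                   products = matrix(integer(0), 0, ns),
                   rates = numeric(0))
}
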