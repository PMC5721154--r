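---
title: "Lineages, histories and snapshots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineages, histories and snapshots: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snapclone)
```

# The model

snapclone studies stochastic biochemical reactions inside the cells of an
exponentially growing clonal population. Each cell carries a molecule
count vector $x$ evolving by mass-action chemistry (simulated exactly with
the Gillespie algorithm), lives for a random interdivision time
$\tau_d \sim \varphi$, and at division is replaced by two age-zero
daughters that partition its molecules binomially (each molecule goes to
either daughter with probability 1/2; totals are conserved exactly).

Three statistical ensembles can be read off a population tree, and they
differ whenever division timing is variable:

* **Forward lineages** follow one daughter at random at every division.
  A lineage with $D$ divisions is selected with probability $2^{-D}$, and
  division times along it follow $\varphi$.
* **Histories** pick a cell of the *final* population uniformly and trace
  its ancestry. Division times along histories follow the ancestral law
  $\rho(\tau_d) = 2 e^{-\lambda \tau_d} \varphi(\tau_d)$: ancestors that
  divided faster than $\ln 2/\lambda$ are over-represented because they
  left more descendants.
* **Age-sorted snapshots** condition the final population on cell age
  $\tau$, giving $\Pi(x \mid \tau)$.

The population growth rate $\lambda$ is the largest root of the
Euler–Lotka equation $2\int_0^\infty e^{-\lambda\tau}\varphi(\tau)\,
d\tau = 1$; since $2 L_\varphi(s)$ is strictly decreasing, the root is
found by bracketed search with geometric bracket expansion (closed forms
are used for the exponential, gamma and deterministic families).
Normalization of $\rho$ *is* the Euler–Lotka condition, so
`ancestral_distribution()` asserts it instead of renormalizing — a
consistency check on the $(\varphi, \lambda)$ pair.

The central statement connecting the ensembles is an ergodic principle:
*when the trait does not influence division timing*, the statistics of
histories at age $\tau$ equal the age-sorted snapshot statistics
$\Pi(x \mid \tau)$ at any time, while forward lineages generally differ.
Fisher's reproductive value factorizes accordingly: the trait part
$\nu(x \mid \tau)$ is the ratio of the history conditional distribution
to the snapshot conditional distribution, flat under neutrality and
increasing in a positively selected trait, and the age part is
$\nu(\tau) = \Pi_h(\tau)/\Pi(\tau)$ with
$\Pi_h(\tau) = S_\rho(\tau)/\langle\tau_d\rangle_\rho$ the history age
density and $\Pi(\tau) = 2\lambda e^{-\lambda\tau} S_\varphi(\tau)$ the
snapshot age density.

# Age densities: a derived choice

The forward-lineage age density is implemented as the renewal-theory age
density along a single isolated lineage,
$S_\varphi(\tau)/\langle\tau_d\rangle_\varphi$. We treat this as a
*derived* modelling choice rather than a quoted result, and validate it
empirically: the test suite checks that pooled simulated snapshot ages
follow $\Pi(\tau)$ (and are far from the forward density), and that the
forward density nearly coincides with the history density only at small
division-time variability.

# The simulator

`simulate_population()` implements the exact event-driven scheme: find
the cell with the smallest residual time to division, advance chemistry,
divide, repeat. Two design choices matter:

* **Per-cell RNG substreams.** Because chemistry in different cells is
  independent between divisions, each cell's whole-lifetime trajectory is
  generated from a substream keyed on (root seed, cell id) by a 64-bit
  hash. Trees are therefore bit-reproducible for a given seed regardless
  of event interleaving, and `snapshot(tree, t)` reconstructs molecule
  states at *any* time exactly, by replaying the prefix of the cell's
  substream — no trajectory storage is needed.
* **Tie-breaking.** Simultaneous division instants (probability zero for
  continuous laws, routine for deterministic atoms) are ordered by lowest
  cell id, keeping replay deterministic.

Founders default to a single age-zero cell with all counts zero; the
long-run regime is reached after a few mean division times, so ensemble
statistics discard cells born in the first 25% of the simulated span
(the `min_birth_time` / `burn_fraction` arguments). A hard cap of
$10^5$ stored cells guards against runaway exponential growth; hitting
it returns a flagged partial tree.

# Analytic solutions

## Birth–death model

For synthesis at rate $k_0$ and degradation at rate $k_1$, the count of a
cell of age $\tau$ is the independent sum of newly made molecules,
Poisson with mean $\mu(\tau) = (k_0/k_1)(1 - e^{-k_1\tau})$, and
surviving inherited molecules. Writing the inherited-molecule generating
function as $G_0(z) = \sum_n a_n (z-1)^n$ and inserting it into the
binomial-partitioning boundary condition gives, upon matching powers of
$z - 1$, the all-positive recursion

$$a_m\,(2^m - L(m k_1)) \;=\; \sum_{n<m} a_n\,
  \Big(\frac{k_0}{k_1}\Big)^{m-n} \frac{d_{m-n,n}}{(m-n)!},\qquad a_0=1,$$

where $L$ is the Laplace transform of the division law used in the
boundary ($\rho$ for population/histories, $\varphi$ for forward
lineages — one code path, two inputs) and
$d_{j,n} = \int \mathrm{law}(\tau)\,(1-e^{-k_1\tau})^j e^{-n k_1\tau}
d\tau$ is evaluated stably as a finite-difference table of $L$ at
integer multiples of $k_1$ ($d_{j,n} = d_{j-1,n} - d_{j-1,n+1}$, all
entries positive and decreasing, so no cancellation).

The $a_n$ are scaled factorial moments; recovering probabilities,
$p(x) = \sum_{n \ge x} a_n e^{-n k_1 \tau} \binom{n}{x} (-1)^{n-x}$, is
an inclusion–exclusion sum with condition number of order $e^{2\mu}$ at
inherited mean $\mu$. At the canonical parameters $k_0 = 50$, $k_1 = 1$
($\mu \approx 20$) double precision would lose about 13 of its 16
digits, so the whole chain — Laplace values, difference table, recursion
and inversion — runs in IEEE quad precision (`__float128`) in compiled
code. Gamma, exponential and deterministic laws use closed-form
transforms in quad precision; tabulated and lognormal laws fall back to
double-precision transform values, which is ample for the coefficients
and for small means but limits the inversion accuracy at large inherited
means (the bursty route below covers the lognormal case exactly where it
is needed). The default truncation is 150 terms; heavy-tailed laws such
as the exponential (CV 1) need about 250 for residues below $10^{-8}$,
and the error message says so. Truncation residues in $(-10^{-8}, 0)$
are clipped to zero; anything larger raises an error.

Two closed-form limits anchor the implementation: for deterministic
division times the inherited distribution is Poisson with mean
$(k_0/k_1)(1-e^{-k_1\tau_d})/(2-e^{-k_1\tau_d})$ (checked to $10^{-6}$),
and the mean difference between snapshot and forward ensembles obeys
$E[x \mid 0] - E_{fw}[x \mid 0] = -k_0 \ln 2\, \mathrm{CV}^2_\varphi +
O(\mathrm{CV}^4)$ in the slow-degradation limit.

## Bursty protein model

A stable protein made in geometric bursts (arrival rate $k_0$, mean size
$b$, the short-mRNA-lifetime reduction of the two-stage model with
$b = k_2/k_1$) admits the exact inherited-molecule generating function
$G_0(z) = \prod_{j\ge1} L\!\big(k_0(1 - h(B^j(z)))\big)$ with
$h(z) = 1/(1+b(1-z))$ and $B^j(z) = 1 + (z-1)/2^j$. The product is
accumulated in log domain and truncated adaptively (at least 10 factors,
then until the last factor is within $10^{-12}$ of one). Probabilities
come from Cauchy-integral inversion on the unit circle with an FFT over
$M \ge 2(x_{\max}+1)$ points; all factors are bounded by one, so the
route is numerically benign and works for the lognormal law, whose
Laplace transform is computed by vectorized Gauss–Legendre quadrature in
log-space (truncated at the $1-10^{-12}$ quantile; worst-case error
about $10^{-3}$ on strongly oscillatory complex arguments, far below the
sampling tolerances it is compared against). Age-marginalized
distributions integrate the age-resolved generating function over the
ensemble's age density by Gauss–Legendre quadrature before inversion.

## Master-equation oracle

`cme_propagate()` (truncated generator, scaling-and-squaring matrix
exponential, probability-conserving boundary) and
`cme_boundary_fixed_point()` (iterating propagate-then-split over the
division-law quadrature until the total-variation change is below
$10^{-10}$) form an independent numerical route to the same
distributions for *any* single-species chemistry. The fixed-point map is
a strict contraction in practice; the suite checks convergence from two
different starting distributions and agreement with both analytic routes
(series: TV $< 10^{-3}$; product: TV $< 10^{-5}$).

# Division-time parameterizations

The heavy-tailed lognormal law used with the bursty model has unit mean
and $\mathrm{CV}^2 = 3$ (variance 3, sd $\approx 1.73$), which yields a
growth rate $\lambda \approx 1.25$ — the self-consistent reading of the
scenario this reproduces. Gamma laws are parameterized by mean and CV
(shape $= 1/\mathrm{CV}^2$); their ancestral law is again gamma with
rate shifted by $\lambda$, which the package exploits in closed form.
Deterministic atoms are first-class objects (never narrow densities), so
the closed-form limits above are exact test oracles.

# The selection scenario

The breakdown of the ergodic principle is exercised on a
production-only chemistry (rate $k_0 = 100$) whose division period is an
expression-coupled Hill function of the count inherited at birth,
$\tau_d = 50\,K^{10}/(K^{10} + x_0^{10})$ with $K = 10$, evaluated
deterministically at birth. These dynamics are self-limiting but
intermittent: a daughter falling below $x_0 \approx 13$ waits long,
accumulates hundreds of molecules, and its descendants then halve
rapidly back into the bulk. Choices the package makes and documents:

* **Founder and burn-in.** The founder starts at $x_0 = 17$, near the
  deterministic fixed point of $x^\ast = k_0\,\tau_d(x^\ast)$, and
  ensemble statistics discard the first 25% of each tree's span; the
  stationary means are insensitive to the founder once burn-in is
  applied.
* **History estimator.** The history inherited-molecule distribution is
  pooled over the *distinct* cells appearing in the histories of all
  final cells (each ancestral cell counted once). The alternative —
  counting an ancestor once per surviving descendant — weights the
  transient cascade cells heavily and is available via
  `multiplicity = "descendant"`. The two coincide exactly in the neutral
  case (where both equal the age-sorted newborn distribution, by the
  ergodic principle); they differ under selection, and the distinct-cell
  pooling is the default reported by the package.
* **Snapshot estimator.** For a stable molecule the inherited count is
  age-independent, so the population-side estimator uses all cells alive
  at the final time rather than an arbitrarily narrow newborn age bin
  (whose $\varepsilon \to 0$ limit is discontinuous here: the birth flux
  includes the near-instantaneous cascade divisions).

Under these conventions 20 trees of $10^3$ cells give history and
snapshot means of about 21 and 13 molecules — clearly separated — while
the neutral fixtures give coinciding means; the reproductive value
$\nu(x\mid 0)$ is flat under neutrality and increases monotonically with
$x$ under selection. `ergodic_test()` quantifies the comparison with a
pooled-permutation null on the total-variation distance, Bonferroni
adjusted across age bins (a simple, conservative choice); the ratio
estimator in `reproductive_value()` masks states with expected
population counts below 5, where it would explode.

# What the generators do and do not emulate

The synthetic fixtures emulate genealogically complete, error-free
tracking data: exact division times, exact molecule counts, no cell
death, no measurement noise, symmetric binomial partitioning, and
division times independent across generations. Passing tests therefore
validate the mathematical machinery, not robustness to features of real
tracking data such as fluorescence calibration error, asymmetric
division, mother–daughter correlated cycles, or lineage loss — all
outside the package's scope (as are size- and concentration-based
division control). External tree tables with the package's CSV columns
can be analysed with the same estimators via `read_tree_csv()`.

# Problem sizes and determinism

Simulation-backed checks use pooled samples of 1–2 × 10^4 cells (40
trees of 250 final cells for the neutral models, 20 trees of 1000 for
the selection scenario, 30 trees of 200–600 cells for distributional
KS checks), sizes at which the Monte-Carlo error of a total-variation
comparison sits near 0.01–0.03, comfortably inside the 0.05 bands the
checks assert. Every stochastic entry point takes an explicit seed, and
identical seeds reproduce trees bit-for-bit.

# Known limitations

* Analytic solutions cover the birth–death and bursty models; other
  networks go through `cme_propagate()` or simulation.
* The birth-death series inversion for tabulated/lognormal laws is
  double-precision limited (see above).
* Heritable (mother–daughter correlated) division times, asymmetric
  partitioning, cell death and spatial structure are not modelled.
* Permutation p-values treat pooled cells as exchangeable; within-tree
  dependence makes them mildly anticonservative, which the test suite
  absorbs by pooling across many independent trees.
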