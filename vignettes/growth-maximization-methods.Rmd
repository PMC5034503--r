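---
title: "Methods: extended-precision growth-rate maximization for ME models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extended-precision growth-rate maximization for ME models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memax)
```

## The model

A metabolism-and-expression (ME) model couples a stoichiometric network
$Sv = 0$, $v^L \le v \le v^U$ to the machinery that synthesizes its own
catalysts. At steady exponential growth every macromolecule pool is diluted
at the specific growth rate $\mu$ (1/h), so synthesis must keep pace with
dilution. Each such requirement is a row

$$ b_i^T v - \mu\, c_i^T v \;\{\ge, =\}\; 0, $$

bilinear in $(\mu, v)$: $b$ carries the dimensionless part (synthesis and
the growth-independent turnover term), $c$ (units of h) multiplies $\mu$.
`build_dilution_rows()` expands four families from annotations and the
machinery constants $c_{ribo}$, $\kappa_\tau$, $r_0$, $k^{eff}_{ij}$,
$c_{tRNA,j}$: ribosome capacity over translation reactions (weighted by
peptide length $l_{p,i}$), RNA-polymerase capacity over transcription
reactions (weighted by $l_{TU,i}/3$, three nucleotides per codon), per-tRNA
charging, and enzyme usage ($c$-coefficient $1/k^{eff}_{ij}$ on each flux
the enzyme carries). A constant $c_{mRNA,j}$ is accepted and stored for
completeness, but no displayed family consumes it; the generic row family is
the extension hook for additional constraints whose coefficients are affine
in $\mu$. Non-affine $\mu$-dependence (e.g. empirical protein-per-RNA
curves) is out of scope.

Maximizing $\mu$ subject to these rows is a nonlinear program, but a
well-behaved one: each row's $\mu$-level set is the zero set of a linear
function of $v$, so the constraints are quasilinear, the feasible growth
rates form an interval $[0, \mu^*]$, and any local optimum is global. All
solution methods in this package exploit exactly this structure.

## Why extended precision

Expression fluxes (transcription of a weakly expressed unit) can be 13–15
orders of magnitude smaller than the largest exchange fluxes. A
double-precision simplex carries roughly 16 significant digits, so a
feasibility tolerance of $10^{-9}$ on a problem with unit-scale rows leaves
*no* correct digits in a $10^{-13}$ flux — which is how double-precision
variability analysis can report a maximum flux smaller than the minimum.
memax therefore runs the entire simplex in IEEE binary128 (~34 significant
digits) via `__float128`, with feasibility and optimality tolerances of
$10^{-15}$ (`me_context()`). Every solution reports residuals — primal row
violation, bound violation, dual infeasibility, complementarity —
recomputed from scratch at the returned point; on the bundled fixtures these
come out near $10^{-30}$, i.e. the tolerances are met with thirteen orders
of headroom. A `"double"` mode with $10^{-9}$ tolerances exists for
comparison. Coefficients travel as decimal strings end to end (model JSON,
LP containers, MPS export): a double round-trip would silently truncate
them to 53 bits and defeat the precision claims.

## The LP core

`solve_lp()` is a bounded-variable two-phase revised simplex:

* **Phase 1** starts from the slack basis (or a warm basis) and minimizes
  the summed bound violations of the basic variables directly — no
  artificial columns and no big-M, since a big-M constant would have to
  dominate coefficients that already span 15 orders of magnitude.
* **Pricing** is Dantzig (most negative reduced cost), switching to Bland's
  rule after 50 consecutive degenerate pivots; ratio-test ties break toward
  the lowest variable index. Together these make every solve deterministic
  given (problem, context, warm basis, scaling).
* **Factorization** is a dense LU with partial pivoting plus product-form
  (eta) updates, refactorized every 40 pivots. Dense is a deliberate choice:
  the package targets desk-scale models (tens to a few thousand columns),
  where dense binary128 LU is both simple and fast enough. Rank-deficient
  warm bases are repaired by replacing dependent basic columns with slacks
  in row order, never rejected.
* **Scaling** (`scale_problem()`, mode 2) alternates row and column
  geometric-mean passes (up to 10, or until factors change by <10%) and
  finishes with a column pass normalizing the largest entry per column
  toward 1. Factors are rounded to powers of two, so scaling is exactly
  invertible in binary floating point. A scaled solve is followed by a
  warm-started polish on the *unscaled* data, so certified residuals always
  refer to the original problem; the polish typically takes zero pivots.

`vertex_oracle()` is the independent certificate: for LPs with at most 8
variables and 8 rows it enumerates every candidate vertex (each choice of
$n$ active constraints among rows and bounds) in exact rational arithmetic
on 128-bit integers, with overflow detection that fails loudly. Infinite
bounds are boxed at $\pm 2^{40}$ and the enumeration repeated at
$\pm 2^{44}$; a moved optimum means unbounded. The test suite checks
simplex-vs-oracle agreement of status and objective to $10^{-20}$ relative
on hundreds of random instances.

## Growth-rate search

At fixed $\mu$, `fix_mu()` substitutes $(b_i - \mu c_i)^T v$ in extended
precision and pins the growth reaction's flux to $\mu$ through an explicit
equality row. The pinning matters twice: it keeps the declared growth bound
active (a $\mu$ beyond it is correctly infeasible), and it makes the
feasibility question non-trivial ($v = 0$ would otherwise satisfy every
homogeneous row).

`bisect_me()` exploits the interval structure. Binary search from $[a, b]$
performs exactly $\lceil \log_2((b-a)/\varepsilon) \rceil$ halvings, one
feasibility LP each, every LP warm-started from the previous basis. The
default bracket $[0, 2]$ covers realistic specific growth rates; a feasible
upper endpoint triggers doubling extensions (at most 4, with a warning).
The golden-section variant needs a scalar objective, which a pure
feasibility sequence does not provide; this package defines the surrogate
$f(\mu) = \mu - K\cdot\text{infeas}(\mu)$ with $K = 10^6$, where
infeas is the phase-1 objective. On the interval structure above, $f$
increases on $[0, \mu^*]$ (where infeas $= 0$) and decreases beyond it, so
it is unimodal with maximizer $\mu^*$ and the classic
$(\sqrt 5 - 1)/2$-reduction applies. The surrogate is this package's
construction; its fixed point, not its path, is what the tests pin down.
Accuracy can be given as `decimals` ($\varepsilon = 10^{-d}$).

## The sequential-linearization solver

`solve_me()` combines a coarse search with a Newton-like refinement:

1. A golden-section run to one decimal (the speed sweet spot; zero decimals
   starts the refinement too far out, more decimals waste LPs in the
   search) returns a proven-feasible $\mu^0 < \mu^*$ and its basis.
2. Each major iteration linearizes every bilinear row about the iterate
   $(\mu_k, v_k)$ — `linearize_at()`; the expansion of a bilinear function
   is exact at the point and its error at $(\mu, v)$ is
   $-(\mu - \mu_k)\,c_i^T(v - v_k)$ — and maximizes $\mu$ as an explicit
   column inside a trust region $|\mu - \mu_k| \le \Delta$, warm-started
   from the previous basis.
3. A candidate $(\mu_c, v_c)$ is accepted if the true bilinear rows hold at
   it (this is the exact test at the fixed point, where $\Delta\mu = 0$
   makes the linearization exact). Otherwise a warm-started **feasibility
   restoration** solves the fixed-$\mu_c$ LP with a parsimonious objective
   — minimize total flux over bounded-below reactions — and the step is
   accepted with the restored fluxes if that LP is feasible. Parsimony is
   load-bearing: it lands on a tight vertex where the dilution rows bind,
   so the next linearization carries the optimal active set and the
   candidate $\mu$ becomes Newton-quality (observed: correct to ~15 digits
   within a few iterations of the coarse start).
4. Because the linearized bound is one-sided, a candidate can overshoot
   $\mu^*$ by less than the convergence tolerance; before rejecting, the
   solver retries the restoration at $\mu_c - \mu_{tol}\max(1, |\mu_c|)$.
   Only if that also fails does the trust region halve. The trust region
   doubles after two consecutive full steps; convergence is declared when
   an accepted interior step changes $\mu$ by at most `mu_tol`
   ($10^{-15}$ by default, mirroring ~15-digit growth rates).

A pure violation-threshold acceptance with trust halving — the textbook SLP
step rule — stalls far from the optimum on this problem class: at a
linearized-LP vertex the bilinear violation is $O(|\Delta\mu|\,|c^T\Delta
v|)$, so the trust region would have to shrink to the feasibility tolerance
before the first accept. The restoration-based rule above has the same
fixed points (at convergence the linearization is exact in $v$ and
$\Delta\mu = 0$) and replaces the augmented-Lagrangian machinery a
general-purpose NLP code would bring to bear; with a single scalar
nonlinearity that machinery is unnecessary.

Safeguards, both exercised in tests: a user-supplied $\mu^0 > \mu^*$ makes
the initial restoration infeasible and triggers automatic restarts from
$\mu^0/2$ (at most 5); $\mu^0 = 0$ converges but spends extra major
iterations climbing by trust-region steps, which is why the coarse search
is the default. `certify_optimum()` independently certifies a candidate by
one feasible LP at $\mu^* - \delta$ and one infeasible LP at
$\mu^* + \delta$.

## Variability, knockouts, and the design scan

`vary_me()` fixes $\mu$ to a fraction of $\mu^*$ (growth flux pinned as an
equality) and minimizes/maximizes each reaction in model column order — two
LPs per reaction, each warm-started from the previous basis, the first from
the growth solve. Warm and cold runs return identical ranges; warm runs
need a small fraction of the iterations (about 2% on the bundled multiscale
fixture). `knockout_screen()` zeroes the translation bounds of one gene at
a time and solves one feasibility LP per gene at a fixed test growth rate;
essential means infeasible. The test growth rate is a user choice (the
screen's accounting is one LP per gene regardless); half the wild-type
optimum is a reasonable default for fixtures, and the choice is deliberately
exposed rather than hard-coded because no canonical cutoff exists.

`expression_grid_scan()` chains the tools into the strain-design protocol:
growth maximization of the knockout strain; variability of the two pathway
complex-formation fluxes at a small fraction (default 0.05) of that
optimum; then a grid (default $11 \times 11$ over fractions 0.05–0.95) of
forced lower bounds with a growth maximization at each point, recording
product flux, yield, the pathway-1 share of pathway translation flux, and
proteome sector mass fractions ($\sum_i v_{tr,i}\,MW_i$ per sector,
normalized). Yield is defined molar — product exchange flux over absolute
substrate uptake flux — a determinism choice where both molar and mass
conventions exist. Infeasible grid points are recorded and skipped, not
errors.

`flux_magnitude_summary()` floor-filters fluxes at the context's
feasibility tolerance and reports integer $\lfloor\log_{10}|v|\rfloor$
bins, medians and means per category, plus the global span
$\log_{10}(v_{max}/v_{min})$.

## Synthetic fixtures: what they emulate and what they do not

The generators produce desk-scale models with the *structural* properties
the methods rely on, not biological realism:

* `make_analytic_model()` — the closed-form oracle. One bounded uptake
  ($\le U$), growth consuming `a_bio` substrate per unit $\mu$, and an
  enzyme costing `m` substrate whose dilution row couples it to uptake via
  `k_eff`. Eliminating the minimal enzyme expenditure gives
  $\mu^* = U/(a_{bio} + m U/k_{eff})$, the reference value for search and
  SLP tests ($m = 0$ is allowed as the enzyme-free limit $U/a_{bio}$).
* `make_coupled_complex_model()` — two translation products whose only
  sink is a 1:1 complex: variability analysis must return identical ranges
  for the two subunits, and either knockout is lethal.
* `make_two_pathway_model()` — an efficient respiration route versus two
  redundant product-secreting routes, for the knockout and grid-scan
  pipeline; deleting the respiration gene forces growth-coupled secretion.
* `make_multiscale_model(seed)` — all four machinery families around a
  linear uptake chain, with $k_{eff}$ log-uniform over the requested span
  (extremes pinned so the realized span equals the nominal one, base
  $10^2$ so the least efficient enzyme's proteome burden stays within the
  substrate budget across the bracket). Feasibility is guaranteed by
  construction: a target $\mu \in (0.3, 1.5)$ is drawn, the minimum-uptake
  template at that rate is computed in extended precision, and the uptake
  bound is set to exactly that requirement — so $\mu^*$ equals the target,
  the default bracket applies, and $\mu = 2$ is infeasible. The generator
  is deterministic given its seed (stored in the model metadata), restores
  the session RNG state, and re-serializes byte-identically.

Passing tests on these fixtures demonstrates the numerical machinery —
multiscale coefficients, binding machinery constraints, warm-start
behavior, degenerate coupling — on models whose ground truth is known
exactly. They say nothing about the biological fidelity of any particular
reconstruction's content: stoichiometry, lengths and rate constants are
synthetic, uptake is a single carbon-source proxy, and mRNA degradation is
not modeled.

## Numerical choices and problem sizes

Default tolerances are $10^{-15}$ (quad) and $10^{-9}$ (double); the pivot
drop tolerances are $10^{-28}$/$10^{-13}$. Degenerate inputs are handled
explicitly: fixed variables ($l = u$) are never pricing candidates,
contradictory bounds short-circuit to infeasible, zero-row and zero-column
problems are legal, and empty machinery families simply produce no rows.
The bundled fixtures are kept at 4–54 reactions so the full suite —
including 200 oracle-certified random LPs, 20 closed-form recoveries, and
repeated multiscale growth solves — runs in well under a minute; the dense
LU core is comfortable to roughly a couple thousand columns.

Known limitations: no sparse LU or Markowitz ordering, no presolve beyond
what repair provides, no interior-point alternative, no SBML import, and
the $\mu$-dependent coefficient hook is restricted to affine dependence.
The golden-section surrogate and the restoration-based step acceptance are
reconstructions where the underlying procedure is underdetermined; both are
documented above and pinned by fixed-point tests rather than by trajectory.
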