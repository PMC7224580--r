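---
title: "Mapping the parameter geography of bistability in a two-site modification cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the parameter geography of bistability in a two-site modification cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmgeo)
```

## The model

A substrate protein `S` carries two modification sites, written and erased
in a fixed order by a forward enzyme `E` and a reverse enzyme `F`, so the
substrate moves through three modforms `S0 -> S1 -> S2` and back.  Both
enzymes act distributively through an arbitrary mechanism of intermediate
complexes; at steady state all of that mechanistic detail collapses into a
handful of aggregated parameters: two catalytic-efficiency ratios
$\alpha$, $\beta$ and six non-dimensional binding parameters
$\epsilon_0, \epsilon_1, \epsilon_2$ (substrate/product binding to `E`,
scaled by $E_{tot}$) and $\phi_0, \phi_1, \phi_2$ (binding to `F`, scaled
by $F_{tot}$).  The conserved totals enter through
$\sigma = S_{tot}/E_{tot}$, $\lambda = S_{tot}/F_{tot}$ and
$\zeta = E_{tot}/F_{tot}$.

Two physical regimes are distinguished by product rebinding of the
intermediate modform.  Under *weak irreversibility* the products of the
`S1`-consuming reactions can rebind their producing enzymes
($\epsilon_2, \phi_0 > 0$; eight free parameters).  Under *strong
irreversibility* — the Michaelis–Menten-like idealisation — they cannot,
$\epsilon_2 = \phi_0 = 0$ exactly, leaving six parameters.

Eliminating every state variable in favour of the free-enzyme fractions
$u = [E]/E_{tot}$ and $v = [F]/F_{tot}$ reduces the steady state to a pair
of bivariate quartics $\Phi_1(u, v) = \Phi_2(u, v) = 0$.  The package
assembles their coefficient grids along two algebraically independent
routes: the fully expanded 24-term form (`build_system()`), and the
product form $\zeta u v\,[(1-u)(\psi_1 + u\psi_2 + v\psi_3) - \sigma u
\psi_2]$ built from the rational functions $\psi_k$
(`build_system_via_psi()`).  The two must agree to machine precision, and
a test asserts this across a thousand random parameter draws — a guard
against transcription errors that an expanded polynomial invites.  The
$\psi_k$ are stored over the monomials $\{v/u, 1, u/v\}$ with first
coefficients $\alpha/\zeta$, $\epsilon_0\alpha/\zeta$,
$\phi_0\alpha/\zeta$: this scaling is forced by dimensional consistency of
$[F]/[E] = v/(u\zeta)$ and is what makes the product route reproduce the
expanded grid for all $\zeta$, not only the $\zeta = 1$ configuration used
in the analyses.

By Bézout's theorem the pair has 16 projective complex solutions.  For
generic parameters these split into the origin $u = v = 0$ with local
intersection multiplicity 6, seven further finite solutions (five in
strong mode), and the balance at infinity.  Among the finite nonzero
solutions, either one or three are positive real: we call these cases
monostable and bistable, with the usual caveat that counting positive
steady states says nothing about their dynamical stability, which the
algebraic reduction cannot see.  The `labelled_sample` container records a
`MONOSTABLE`/`BISTABLE`/`NONGENERIC` entry per (point, $\sigma$).

## The solver

`solve_system()` finds *all* finite complex solutions deterministically,
with no path tracking:

1. **Elimination.**  The Sylvester resultant in $v$ has entries that are
   degree-$\le 4$ polynomials in $u$.  Its determinant is evaluated at
   scaled roots of unity and interpolated by an inverse DFT; real
   coefficients give the conjugate symmetry that halves the determinant
   evaluations.  The generic resultant degree is 13 (weak) or 11
   (strong), so the first attempt uses a reduced node count ($2m+2$ for a
   Sylvester matrix of size $m$); retries use the alias-safe $4m+4$.
2. **Origin multiplicity.**  The multiplicity of the $u = 0$ root of the
   resultant is read off as the number of leading coefficients lying
   within a *noise-calibrated* zero band: the coefficients above the true
   degree are pure interpolation noise and set the band's floor
   (100-fold margin).  A fixed relative threshold fails here because the
   genuine trailing coefficient can legitimately be many orders below the
   largest one.
3. **Univariate roots.**  Aberth–Ehrlich iteration, initialised from the
   Newton polygon (upper convex hull of $(j, \log|a_j|)$).  The hull
   radii matter: at $\sigma = 500$ the root magnitudes span seven
   decades and a single initial circle misses the extreme roots.
4. **Back-substitution.**  At each $u$-root both $v$-polynomials are
   rooted at their structural degrees (a coefficient is dropped only if
   it is exactly zero, e.g. in strong mode).  Trimming by a relative
   threshold is wrong here: $\Phi_2$'s leading $v$-coefficient
   $-\alpha\phi_0$ is often tiny yet exact, and it carries the system's
   large-$|v|$ solutions.
5. **Newton polish and guards.**  Every candidate pair is refined on the
   full system.  Newton is allowed to polish, not to relocate: a result
   drifting by more than 25% of its originating root's magnitude is
   discarded, which prevents pseudo-solutions in the tangent cone of the
   multiplicity-6 origin, where residuals vanish to high order.  On a
   conjugate-symmetric system complex Newton stalls with a $\sim10^{-12}$
   imaginary residue on real roots; such roots are re-polished on the
   real axis and accepted as exactly real when the real projection
   satisfies the system equally well.  Duplicates closer than $10^{-8}$
   (relative) are merged; the two $v$-polynomial sources merge at
   $10^{-4}$ within one $u$-root, where very large, poorly conditioned
   solutions agree only to a few digits.

Solution coordinates are classified as small / ambiguous / infinite /
nonzero real / nonzero non-real against the thresholds
$T_{zmin} = 10^{-25}$, $T_{zmax} = 10^{-10}$, $T_\infty = 10^{8}$
(`classifier_thresholds()`), evaluated in that order.  A point counts as
a solution of the biology — "proper" — when both coordinates are nonzero
(real or non-real) and finite; it is positive real when both coordinates
classify nonzero real with positive real parts.

A point is *generic* when the origin multiplicity is 6, the proper count
is 7 (weak) or 5 (strong), the positive-real count is 1 or 3, and no
coordinate is ambiguous.  Failing points enter a retry ladder — swapped
elimination order, then a node radius re-balanced from the first
resultant, with the ambiguity band tightened to $10^{-11}$ — capped at
two retries, after which the point is flagged `NONGENERIC`, excluded
from every estimator (numerator and denominator) and tallied in the
labelled sample.  In the $p = 1$ box the flag rate is below $10^{-3}$ at
all $\sigma$ used here; it grows in the widest boxes (see Limitations).

`certify_newton()` provides the per-solution guarantee: three Newton
steps must contract at least quadratically and the Jacobian must be
non-singular.  This is a practical contraction test, not an exact
$\alpha$-theory certificate; the origin (singular) and perturbed
non-solutions fail it.

## Sampling and volume estimation

The synthetic-data generator of every downstream stage is Independent
Logarithmic Random (ILR) sampling (`ilr_sample()`): each parameter's
log10 value is uniform on $[-p, p]$, the natural measure for parameters
whose nominal value 1 sits at the centre of $[0.1^p, 10^p]$.  The default
study conditions are the ones used throughout: $p = 1$, $\zeta = 1$,
$\lambda = \sigma$, the 15-value main $\sigma$ grid from 1 to 500
(`sigma_grid()`), weak irreversibility unless stated.  The generator
reproduces the sampling design exactly; what it cannot emulate is any
structure a *real* enzyme system would impose on the joint distribution
of the aggregated parameters, so passing tests validate the estimators
and the solver, not a biological prior over mechanisms.

The bistable volume $V_\sigma$ is the mean of the bistable indicator
under the log-uniform measure; `estimate_volume()` reports the sample
fraction with the central-limit interval $\hat V \pm z_{1-\alpha/2}
\hat\delta/\sqrt{N}$, $\hat\delta$ the sample standard deviation of the
indicator.  When no bistable point is seen the interval degenerates and
the rule-of-three bound $3/N$ is reported instead and flagged — a
convention chosen so that "zero observed" still carries quantitative
content.

`vegas_run()` enriches rare bistable sets by adaptive importance
sampling over $M = 50$ bins per axis of $[-1, 1]$ with smoothing factor
$K = 1000$.  Each iteration projects the accumulated bistable set onto
every axis, smooths the histogram as
$f_i \leftarrow \lceil K f_i / \#set \rceil + 1$ (no bin is ever empty,
which keeps a small bias toward unexplored territory), and re-partitions
the axis so every bin carries an equal share of the smoothed mass —
bins shrink where bistable density is high, and since the stratified
assignment rule $I(n, r)$ (one shared uniform $r$ per axis) gives every
bin an equal number of draws, sampling density is proportional to the
local bistable density.  Equal-mass rebinning is the load-bearing choice:
resizing bins *proportionally* to their frequencies, with the same
equal-counts assignment, would sample dense regions more thinly and
de-enrich.  VEGAS is defined for $p = 1$ boxes only; the enrichment
factor (bistable fraction among VEGAS draws over the ILR fraction)
exceeds 10 at $\sigma = 10$ already in desk-scale runs.

## Geometry of the bistable region

**Connectivity.**  The graph $G_\Delta$ joins bistable points within
Euclidean log-distance $\Delta$.  `choose_delta()` picks $\Delta$ so a
sample point has a neighbour within $\Delta$ with probability 0.99,
using the 8-ball volume $\pi^4\Delta^8/24$; the default $\Delta = 0.15$
is used everywhere.  `build_spanning_forest()` implements the queue
algorithm — BFS from unvisited points, edges only to yet-unvisited
points within $\Delta$ — over an exact KD-tree, so the component
partition equals that of the full $\Delta$-graph (asserted against a
brute-force transitive closure on small sets) while edges stay linear in
the vertex count.  The forest's edge set is not unique; only components
are contractual.  `refine_components()` tries to join non-largest
components to the largest one by solving along near-neighbour segments
subdivided at $0.98\Delta$, growing the neighbour count $K$ by the
second-largest-component rule, and stops after two consecutive
iterations without progress (random probes can fail once without
meaning the region is disconnected).  The neighbour search is exact,
which satisfies the $(1+\epsilon)$ approximate-neighbour contract at
$\epsilon = 0.001$ trivially.

**Visibility.**  The visibility ratio is the probability that the
log-space segment between two random points of the region stays inside
it; 1 for convex regions.  `estimate_visibility()` tests the $K = 10$
equally spaced *interior* points $t = j/(K+1)$ of each of $M$ sampled
pairs (the endpoints are known members), so it overestimates the true
ratio and decreases toward it as $K$ grows — both directions are
asserted on a 2-D annulus with an exact indicator.  Pairs are ordered
pairs drawn without replacement with $i \neq j$; the confidence interval
uses the finite-population correction $\sqrt{1 - M/N}$ with
$N = n^2$, dropped when $M/N < 0.01$ where it is negligible.

## Cross-$\sigma$ analyses

`threshold_scan()` labels one common sample along an ascending $\sigma$
grid and reports the smallest $\sigma$ with a bistable hit; at
$\sigma = 1$, $p = 1$, no bistable point appears even at $10^5$ points.
`blinking_summary()` counts points that are bistable at some $\sigma$
yet monostable at a larger grid value, and locates them relative to the
$\sigma$-specific largest component (outside it: `bpsc`; never entering
it later: `bpnl`).  "Asymptotically monostable" (`bpam`) is
operationalised as monostable at the grid's largest $\sigma$ — a proxy,
since no finite grid shows the $\sigma \to \infty$ limit.  Points with
any `NONGENERIC` profile entry are excluded and tallied.
`tradeoff_bound()` reports $\hat K(\sigma) = \max \epsilon_2\phi_0$ over
the bistable sample — the empirical sample maximum, deliberately not a
fitted hyperbola — quantifying the tradeoff that confines weak-mode
bistability to the region where the two rebinding parameters are not
simultaneously large.  This is what collapses the bistable share of the
box from ~20% (strong, 6-D) to ~1% (weak, 8-D) at $\sigma = 500$.

## Numerical and design choices

* $\lambda$ is stored independently of $\sigma$ although every analysis
  here sets $\lambda = \sigma$, $\zeta = 1$; the constructors default
  that way.
* Every sampling operation takes an explicit seed, runs under a locally
  seeded Mersenne–Twister and restores the caller's random state; derived
  stage seeds stay below $2^{31}$.
* Problem sizes in the shipped tests and acceptance script: $2\times10^5$
  ILR points for the volume and blinking analyses, $2\times10^4$ for the
  strong-mode volume, two VEGAS iterations of $10^5$ draws for the
  enriched $\sigma = 10$ set, $M = 500$ pairs for visibility — sizes at
  which each Monte Carlo estimate resolves its quantity to a few
  hundredths of a percentage point on a single CPU.
* Degenerate inputs: an identically zero resultant raises a
  degenerate-system error in `solve_system()` and a flag (never a fake
  count) in batch labelling; merged root clusters flag `NONGENERIC`
  rather than guessing multiplicity.

## Limitations

* Stationarity only: one versus three positive steady states; stability,
  oscillations and mixed mechanisms are out of scope.
* Certification is a Newton-contraction test, not exact $\alpha$-theory.
* In the widest boxes ($p \ge 4$) coefficient ranges stress double
  precision and the `NONGENERIC` exclusion rate grows to several percent;
  conclusions there should lean on the tallies the labeller reports.
  No arbitrary-precision escalation is attempted.
* The $\Delta$-selection formula is specific to the 8-dimensional ball.
* Connectivity and visibility are evidence about shape at the sampled
  resolution, not topological proofs; features thinner than $\Delta$ or
  of lower dimension are invisible to point sampling.
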