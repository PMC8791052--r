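---
title: "Travelling waves of tumour invasion with degenerate cross-diffusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travelling waves of tumour invasion with degenerate cross-diffusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecmwave)
```

## The model

The package studies a minimal model of tumour invasion into extracellular
matrix (ECM).  Tumour cells (density $N$) proliferate logistically and move
by diffusion that the matrix obstructs; the matrix (density $M$) is immobile
and degraded by the cells by mass action.  After nondimensionalization a
single parameter survives, the rescaled degradation rate
$\kappa = (K/\rho)\,k$:

$$\partial_t N = \partial_x\big[(1 - M)\,\partial_x N\big] + (1-N)N,
\qquad \partial_t M = -\kappa M N .$$

The diffusivity $1-M$ vanishes at maximal matrix density, so the $N$
equation is *degenerate* parabolic, and the degeneracy is *cross*-dependent:
it is controlled by the other species.  The spatially homogeneous steady
states are $(0,0)$, $(1,0)$, $(0,1)$ and a continuum $(0,\bar M)$,
$\bar M\in[0,1)$.  Invasion fronts are heteroclinic travelling waves
$N(x-ct), M(x-ct)$ from $(1,0)$ (fully invaded) to either $(0,1)$ or
$(0,\bar M)$ — the far-field matrix ahead of the tumour either is, or is
not, at maximal density, and the two cases behave differently.

## Desingularization and the shooting problem

In the wave variable $\xi = x - ct$ the profile equations are singular
where $M = 1$.  The substitution $dy/d\xi = 1/(1 - M)$ removes the
singularity and yields the regular first-order system

$$n' = p,\qquad p' = -c\,p - (1-n)\,n\,(1-m),\qquad
m' = \tfrac{\kappa}{c}\,m\,(1-m)\,n .$$

At the invaded state $(1,0,0)$ the linearization has one stable and two
unstable directions ($\lambda_2 = (-c+\sqrt{c^2+4})/2$ and
$\lambda_3 = \kappa/c$); waves must leave through the two-dimensional
unstable manifold.  Up to translation the departing orbits form a
one-parameter family indexed by $\alpha \ge 0$, the coefficient of the ECM
component in the local expansion
$n = 1 - e^{\lambda_2 y}$, $p = -\lambda_2 e^{\lambda_2 y}$,
$m = \alpha e^{\lambda_3 y}$.  Larger $\alpha$ lets the matrix grow sooner
along the orbit, and the far-field density $m_\infty(\alpha)$ reached at
$y\to+\infty$ is continuous and strictly increasing in $\alpha$.  That
monotonicity is what turns wave construction into bisection: to connect to
$(0,0,\bar m)$, bisect $\alpha$ on $m_\infty(\alpha) \lessgtr \bar m$
(`find_alpha_for_target()`); the orbit into $(0,0,1)$ sits at the supremum
$\alpha_1$ of the non-degenerate range (`find_alpha1()`).

### Launch point

The expansion above is only the leading order, so the launch must sit deep
on the manifold but not so deep that double precision erases it.  The
default places $e^{\lambda_2 y_0} = 10^{-8}$: the neglected terms are then a
relative $10^{-8}$ correction, while $n = 1 - 10^{-8}$ still carries eight
significant digits of the deviation from the equilibrium.  (Launching at,
say, $e^{-40}$ would round $n$ to exactly 1 in doubles and the orbit's
phase information would be lost.)  For large $\alpha$ the launch is pushed
deeper so the starting ECM density stays below 0.3, keeping the truncation
honest in all three components; a hard floor at $10^{-14}$ guards the
roundoff limit.  `launch_point()` enforces all three constraints.  Shifting
$y_0$ by a further $-10$ changes $m_\infty$ by under $10^{-6}$ (a test),
confirming the orbit is launch-insensitive in the admissible window.

### Classifying the fate of a shot

Each shot is integrated with `deSolve::lsodar` (adaptive, stiff-capable,
with exact event location) at tolerances `rtol = 1e-13`,
`atol = (1e-16, 1e-16, 1e-30)`.  Near-critical discrimination is
exponentially sensitive, and the tiny absolute tolerance on $m$ matters
because $m$ spans hundreds of orders of magnitude near the launch.

The delicate step is deciding whether the leading-edge tail of an orbit
keeps $n$ positive.  A naive event on $n = 0$ is *not* reliable: orbits
that lose positivity near criticality do so at amplitudes far below any
feasible event resolution (we observed apparent "crossings" at
$n\sim10^{-32}$ whose sign structure was pure integrator noise — $n$ had
simply fallen below `atol`).  Instead each orbit is integrated until $n$
reaches a fixed classification depth $n_{\text{tail}} = 10^{-12}$, where
the dynamics are linear about $(0,0,m_{\text{end}})$ and $m$ is frozen
(its remaining drift is $O(n_{\text{tail}})$), and the tail is classified
by the local spectrum:

* **transversal exit**: $p < -10^{-6}$ at the depth — a genuine finite
  crossing of $n = 0$, whose location is recorded;
* **spiral**: $c < 2\sqrt{1 - m_{\text{end}}}$ — the would-be limit is a
  stable spiral, so $n$ must oscillate through zero (no admissible wave;
  this is the mechanism behind the lower speed bound);
* otherwise the deviation is projected onto the left eigenvector of the
  slow stable mode, $s = (c + \lambda_s)\,n + p$, which annihilates the
  fast mode exactly.  A **negative** projection means the slow mode carries
  a negative coefficient, so $n$ crosses zero at some amplitude below the
  classification depth: the orbit is rejected.  A **positive** projection
  is an admissible connection with $m_\infty = m_{\text{end}}$.

The sign of the slow-mode projection is readable as long as the two decay
rates have separated by the classification depth, i.e. over roughly
$\sqrt{c^2 - 4(1-\bar m)}\cdot\Delta y \gtrsim$ a few e-folds.  As the
speed approaches $2\sqrt{1-\bar m}$ this separation collapses (degenerate
node) and the projection saturates at $+$; the practical consequence is a
**resolution floor** on how small a positivity-loss margin can be detected
— see the minimal-speed discussion below.

Orbits heading to $(0,0,1)$ approach it *algebraically*
($y\,(1-m)\to c$ and $y\,(n + p/c)\to c/\kappa$ on the critical orbit — a
testable decay law, `decay_law_check()`), so no convergence event ever
fires at a finite horizon.  Probes hovering there are classified by the
decay-law ratio $\kappa (n + p/c)/(1-m)$, which is below 1 on the wave
side and above 1 on the degenerate side and equals 1 exactly on the
critical orbit.  The working horizon is $y_{\max} = 4000$; critical orbits
returned to the user are integrated to $8\times$ that.

## Minimal wave speed

For far-field density $\bar m \in (0,1)$, waves exist exactly for speeds
$c \ge c^*_\kappa(\bar m)$, and analytically
$2\sqrt{1-\bar m} \le c^*_\kappa(\bar m) \le 2$.  `minimal_speed()` bisects
the speed on that bracket (default tolerance $10^{-3}$), with feasibility
of each probe decided by `find_alpha_for_target()`: pin the orbit with
$m_\infty = \bar m$, then ask whether its tail is admissible.

The threshold $\kappa^*(\bar m) = (1-\bar m)/\bar m$ (equivalently
$m^*(\kappa) = 1/(\kappa+1)$) separates two regimes.  Along the wave the
matrix is a function $M(n)$ of the tumour density and the wave solves a
generalized Fisher-type problem with reaction
$g(n) = (1-n)\,n\,(1-M(n))$; for $\kappa \le \kappa^*$ the reaction is
concave at the leading edge ($g''(0) < 0$, checked numerically by
`g_concavity_check()` with one-sided Richardson differences) and the
minimal speed takes the linear-spreading value $2\sqrt{1-\bar m}$.  The
package reproduces this to $\sim 0.03\%$ at $\kappa = 1$,
$\bar m \in \{0.1, 0.25, 0.4\}$.  Above the threshold a genuinely larger
minimal speed emerges: at $\kappa = 1$, $\bar m = 0.9$ ($9\kappa^*$) the
computed margin over $2\sqrt{1-\bar m}$ is $0.060$, and at
$\kappa = 10/3$, $\bar m = 0.75$ ($10\kappa^*$) the ODE value $1.0728$
agrees with the PDE-selected speed $1.074$ to $0.1\%$.

**Resolution floor.**  When $\kappa$ is only slightly supercritical
(e.g. $\kappa = 1$ with $\bar m \in \{0.6, 0.75\}$, i.e. $1.5$–$3\times$
$\kappa^*$) the inadmissibility margin lives inside the window where the
slow/fast decay rates have not separated at the classification depth, and
both the shooting route and the PDE route return speeds indistinguishable
from $2\sqrt{1-\bar m}$ at the $10^{-3}$ search resolution.  The returned
`c_star` then exceeds the lower bound only by the final half-bracket.  A
reported margin below `tol_c` should be read as "not resolved", not as a
measurement of the true margin.

## The PDE solver and front speeds

The method-of-lines discretization keeps the degenerate flux in
conservative form: face flux
$F_{i+1/2} = (1 - M_{i+1/2})\,(N_{i+1}-N_i)/\Delta x$ with the arithmetic
mean $M_{i+1/2}$ (second order; sign-preserving since $M \le 1$), zero
flux at both ends for $N$, and no spatial operator on $M$.  The discrete
diffusion operator then telescopes to zero exactly — a property the tests
assert to $10^{-12}$.  Time integration uses `deSolve::ode.1D`
(`lsodes`) at `rtol = 1e-8`, `atol = 1e-10`.  Negative densities within
$-10^{-10}$ of zero are clipped post hoc and counted (the count is kept on
the solution object); larger invariant violations abort with a pointer to
grid refinement.  Nothing in the solver is stochastic: runs are bitwise
reproducible.

Fronts are tracked at the level $N = 0.5$ by linear interpolation and the
speed is the least-squares slope of $X(t)$ over $t\in[50,100]$, a window
that excludes the initial transient of the reference initial condition
(plateau of extent $\sigma = 2$, smooth bump ramp of width $\omega = 1$,
domain $[0,200]$, $\Delta x = 0.1$).  At $\bar M = 0$ this machinery
reproduces the Fisher-type value: $\hat c = 1.9813$ at
$\Delta x = 0.1$ (the $\sim 1\%$ deficit is the well-known discrete
front-speed bias, which the self-convergence check `convergence_check()`
quantifies: $\Delta x\in\{0.2, 0.1\}$ agree within $1\%$).

### The fully degenerate far field

$\bar M = 1$ is special.  Ahead of a compactly supported tumour the
diffusivity is exactly zero, so the continuum spreading mechanism
degenerates, and the discrete front advances through grid-scale coupling
in the flux stencil.  Empirically the selected speed does **not** converge
under refinement ($0.517, 0.458, 0.415, 0.383, 0.357$ at
$\Delta x = 0.4, 0.2, 0.1, 0.05, 0.025$; $\kappa = 1$), while at each grid
the front is a clean travelling wave of constant shape.  Strikingly, that
shape agrees with the smooth ODE wave *at the speed that grid selects* to
within a few percent in sup-norm (waves exist for every $c > 0$ when
$\bar M = 1$, so there is always one to compare against).  The package
therefore treats $\bar M = 1$ speeds as scheme-dependent observables — the
grid policy is to refine ($\Delta x = 0.05$) and run the convergence check
in any quantitative use of that regime — while profile comparisons
(`compare_pde_ode()`) are meaningful at matched speed.  For
$\bar M \in [0, 1)$ none of this arises: speeds converge and match the
shooting route.

## What the synthetic inputs emulate — and what they do not

The initial-condition generator (`make_ic_variants()`) produces compactly
supported tumour profiles with matrix $M = \bar M(1-N)$ across the
interface: an established tumour edge invading intact matrix.  Variants
(shifted extent, rescaled interface, piecewise-linear ramp) emulate the
biologically irrelevant arbitrariness of the initial shape; the tests
assert the selected speed is insensitive to it (within $2\%$).  The
manufactured orbit (`manufactured_trajectory()`) pairs a logistic $n(y)$
with the exact closed-form $m(y)$; it satisfies only the $m$-equation, by
construction, and exists purely to test the quadrature and that equation's
solver-independence.  None of these emulate real tumour data: no spatial
heterogeneity of the matrix, no stochasticity, no growth of the matrix, a
single space dimension, and densities already scaled to carrying capacity.
Passing tests certify the mathematics of the model, not agreement with any
biological measurement.

## Numerical choices at a glance

| quantity | default | why |
|---|---|---|
| launch amplitude $e^{\lambda_2 y_0}$ | $10^{-8}$ | truncation $10^{-8}$ relative, $8$ digits above roundoff of $1-n$ |
| tail classification depth | $10^{-12}$ | linear regime; slow/fast separation readable |
| shot tolerances | rtol $10^{-13}$, atol $(10^{-16},10^{-16},10^{-30})$ | near-critical discrimination |
| $\alpha$-bisection | relative $10^{-12}$ | $m_\infty(\alpha)$ steepens with $\kappa$ |
| target match `tol_m` | $10^{-8}$ | well above orbit reproducibility |
| speed bisection `tol_c` | $10^{-3}$ | the scale at which speeds are compared |
| horizon $y_{\max}$ | $4000$ ($\times 8$ for critical orbits) | algebraic approach to $(0,0,1)$ |
| PDE grid / tolerances | $\Delta x = 0.1$, rtol $10^{-8}$, atol $10^{-10}$ | $1\%$ speed bias, checked by self-convergence |
| fit window | $t\in[50,100]$ | transient excluded |

Degenerate or invalid inputs error early with the offending field named:
non-positive dimensional parameters, $\bar m \ge 1$ for the tumour-free
family, $c \le 0$, ordering violations of the initial-condition shape,
non-uniform grids, too-shallow launches.

Test-suite problem sizes are scaled for a routine run: monotonicity sweeps
use $\Delta x = 0.2$, short-time invariant checks use $L = 50$ and
$t \le 20$, and the conjecture-surface checks run the
$\bar m \in \{0.25, 0.75\}$ subset; the full $\bar m$ grid behaves
identically and is reported above.

## Known limitations

* Margins of $c^*$ above $2\sqrt{1-\bar m}$ smaller than about the speed
  tolerance cannot be certified (resolution floor of the tail projection).
* `find_alpha0()` for $0 < c < 2$ returns the practical boundary between
  exiting and non-exiting shots at the probe resolution; very close to the
  spiral bound the classification inherits the same floor.
* $\bar M = 1$ PDE speeds are scheme artifacts in the sense above; only
  profile shape at matched speed is quantitative there.
* Sharp (corner) waves and weak-solution verification are out of scope:
  all constructed waves are smooth, and the PDE solver assumes enough
  regularity for the method of lines.
* For very large $\kappa$ (beyond $\sim 100$) the map
  $\alpha \mapsto m_\infty$ becomes so steep that pinning a target density
  saturates the $\alpha$-bisection; the search then falls back on the
  least-overshooting bracket end and flags nothing, but `tol_m` is
  effectively coarser.
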