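---
title: "Traveling waves of the active/inactive particle growth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves of the active/inactive particle growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Branching morphogenesis — the growth of branched epithelial organs such as
the mammary gland or kidney — has been described by stochastic models in
which *active* tips of a branching network elongate and split until they
collide with existing tissue and become irreversibly *inactive*. Averaging
such dynamics over space yields, after normalization, a two-species
reaction–diffusion system for the densities $A(x,t)$ of active and $I(x,t)$
of inactive particles:

$$A_t = A_{xx} + A - A(A+I), \qquad I_t = A(A+I) + rA,$$

with a single remaining parameter $r \ge 0$, the rate at which active
particles shed extra inactive material. Active particles diffuse and grow
logistically; every collision event converts activity into inactivity.
Inactive particles never move and never decay, so **every** state
$(A, I) = (0, K)$, $K \ge 0$, is a steady state. This continuum of
equilibria is the system's distinguishing feature relative to the scalar
FKPP equation (to which it degenerates when $I$ is absent): the outcome of
the growth process — the density of tissue left behind — is selected
dynamically, not imposed by the equation.

Simulations show self-organization: from a compact heap of active particles
on an empty background, two fronts emerge, travel at asymptotic speed
$c = 2$, and deposit a constant inactive density $I = 2$ behind them. The
package makes every ingredient of the analytic description of these fronts
executable.

## Wave coordinates and the shooting problem

In the comoving variable $z = x - ct$ a wave profile $(a, i)(z)$ satisfies
the first-order system (with $b = a'$)

$$a' = b, \qquad b' = a(a+i) - a - cb, \qquad i' = -\tfrac1c\, a(a+i+r),$$

implemented in `wave_vector_field()`. All fixed points form the line
$a = b = 0$, $i = K$; the Jacobian there (`wave_jacobian()`) has eigenvalues
$\lambda_0 = 0$ and $\lambda_\pm = -c/2 \pm \sqrt{c^2/4 + K - 1}$
(`fixed_point_eigensystem()`). The zero eigenvalue points along the line of
equilibria, so there is no flow in that direction, and the stability of each
fixed point is decided by $\lambda_\pm$ alone: unstable for $K > 1$, stable
for $K < 1$.

A bounded non-negative wave is a heteroclinic orbit from $(0,0,i_{-\infty})$
with $i_{-\infty} \in (1, 2]$ to $(0,0,i_{+\infty})$ with
$i_{+\infty} \in [0, 1)$, and the limits obey the symmetry
$i_{-\infty} + i_{+\infty} = 2$. Not every right limit is reachable at every
speed: if $c^2/4 + i_{+\infty} - 1 < 0$, the linearization at the right
limit is a spiral and the active density would oscillate through negative
values. The smallest admissible right limit at speed $c$ is the critical
density

$$i_c(c) = \max\{0,\, 1 - c^2/4\}$$

(`critical_density()`); conversely $c = 2$ is the smallest speed allowing
full invasion $i_{+\infty} = 0$ (`minimal_invasion_speed()`, computed by
bisection).

`shoot_wave(c, r, i_minus_inf)` constructs the orbit numerically. The
unstable manifold of the left fixed point is one-dimensional with direction

$$e_+ = \bigl(-\lambda_-,\; i_{-\infty}-1,\;
  \tfrac1c (r+i_{-\infty})\lambda_-/\lambda_+\bigr)$$

(`unstable_direction()`, stored exactly in this component form so the sign
structure used in the analysis stays visible; a unit-normalized copy is
available via `unit = TRUE`). The shot starts at
$(0,0,i_{-\infty}) + \varepsilon \hat e_+$ with $\varepsilon = 10^{-7}$ and
integrates with an adaptive solver (deSolve, relative tolerance $10^{-10}$,
absolute $10^{-12}$). Because the unstable manifold is one-dimensional, the
linearization error of this start is $O(\varepsilon^2)$; the test suite
verifies that the measured limits move by less than $10^{-8}$ across
$\varepsilon \in \{10^{-6}, 10^{-7}, 10^{-8}\}$.

Two numerical choices matter downstream:

* **Turning-point detection.** The first zero of $b$ (the unique maximum of
  $a$) is located by the integrator's root-finding, not by inspecting
  samples. Only the first downward crossing is meaningful; later upward
  crossings would be numerical artifacts.
* **Limit refinement.** Integration stops when $\max(|a|,|b|)$ falls below
  $10^{-10}$; the observed right limit is then refined by one application of
  the closed-form limit map at the final state, which removes the remaining
  truncation bias. In the critical case (see below) the threshold is relaxed
  to $10^{-8}$ and the span enlarged, because the tail closes only like
  $z\,e^{-cz/2}$.

The integration span is budgeted from the linear rates: waves with
$i_{-\infty}$ just above 1 emerge from the fixed point extremely slowly
($\lambda_+ \approx (i_{-\infty}-1)/c$), so the span grows like
$\log(1/\varepsilon)/\lambda_+$ rather than being fixed.

```{r, eval = FALSE}
library(fkppfronts)
w <- shoot_wave(2, 0, 1.8)
glance(w)
autoplot(w)
```

## Closed-form cross-checks

Three families of exact relations turn the orbit into a test surface.

**Integral identities.** Between any two phase-times with $b = 0$, with
$\mathcal{A}(t) = \int_{z_1}^{t} a\,dz$,

$$\int a(a+i)\,dz = \mathcal{A}(z_2) + c[a(z_2)-a(z_1)], \qquad
i(z_1) - i(z_2) = \tfrac{1+r}{c}\mathcal{A}(z_2) + a(z_2) - a(z_1),$$

plus an energy-type identity quadratic in $\mathcal{A}$
(`integral_identities()`). The endpoint terms $a(z_2)-a(z_1)$ vanish on the
full span of a heteroclinic orbit; on the half-window ending at the turning
point they are essential — dropping them breaks the mass-transfer relation
by exactly $a(z_0)$, which is easy to confirm numerically. Integrals are
evaluated by composite Simpson quadrature on a spline resampling of the
orbit (the raw trapezoidal rule on the 0.05-spaced samples would limit the
residuals to about $10^{-4}$; the identities hold to $10^{-5}$ and better).

**The limit map.** For orbits started at $(a_0, 0, i_0)$ inside the
attractor of the stable set, the right limit has the closed form

$$i_{+\infty}(a_0, i_0) = 1 - \sqrt{(i_0+a_0-1)^2 +
  \tfrac{1+r}{c^2}(a_0^2 + 2c^2 a_0)}$$

(`limit_map()`), decreasing in $a_0$, with `limit_map(0, i0) = i0`. The
value $a_0 = \alpha(i_0)$ at which it reaches $i_c$ (`alpha_threshold()`)
and the attractor bound $a^*(i_0) = \min\{\alpha(i_0), 1-i_0\}$ (`a_star()`)
bracket the admissible starts; `attractor_orbit()` confirms the map against
direct integration to $10^{-6}$ over a grid of starts. (For $c = 2$, $r = 0$,
$i_0 = 0.5$ the printed formulas give $a^*(i_0) \approx 0.47$; we note that
one published figure caption quotes $\approx 0.42$ for this configuration,
and we follow the formulas.)

**The turning point.** At the first $b = 0$ crossing the state satisfies a
quadratic relation between $a_{z_0}$, $i_{z_0}$ and $i_{-\infty}$
(`turning_point_active()`), along with $a_{z_0} + i_{z_0} \le 1$,
$i_{z_0} > 2 - i_{-\infty}$ and $a_{z_0} \le a^*(i_{z_0})$ — the hand-off
from the unstable manifold into the attractor. On computed orbits the
residual is at the integrator tolerance ($\sim 10^{-14}$).

**Tail rates.** Both tails are exponential with rates
$\mu_{\pm\infty} = -c/2 + \sqrt{c^2/4 + i_{\pm\infty} - 1}$, except the
critical wave ($i_{+\infty} = i_c$ with vanishing discriminant), whose tail
is $\propto z\,e^{-cz/2}$. `tail_rate_fit()` fits $\log a$ linearly; in the
critical case it fits $\log a - \log(z - s)$ with the offset $s$ profiled
out by least squares, because the phase origin of a computed orbit is
arbitrary — fixing $s = 0$, as a literal reading of the asymptotic form
suggests, biases the fitted rate by several percent at the spans we
integrate.

## The trapping triangle

Freezing $i(z) = i$ reduces the system to the plane:
$\bar a' = \bar b$, $\bar b' = \bar a(\bar a + i - 1) - c\bar b$
(`reduced_vector_field()`), with a stable node/spiral at the origin and a
saddle at $(1-i, 0)$. For $i \in [i_c, 1)$ the triangle $T_c(i)$
(`build_triangle()`) — spanned by the two fixed points and the intersection
of the eigenvector half-lines from each — is invariant: the flow crosses
every boundary point inward. Since $b'$ does not depend on $i'$, the full
system's $(a,b)$ dynamics agree with the reduced ones at each instant, and
after its turning point the orbit is trapped in $T_c(i_c)$; this is what
forces convergence without spiraling.

`invariance_scan()` certifies invariance numerically: each edge is sampled
(excluding a $10^{-6}$-fraction neighborhood of the two fixed-point
vertices, where the flux legitimately vanishes) and the inner product of the
field with the inward normal — computed from an enforced counterclockwise
vertex orientation, which removes any sign ambiguity — must be non-negative;
on the eigenvector edges it equals $-p^2\lambda_-^3 > 0$ exactly, which the
tests verify against the closed form. The triangles are nested, growing as
$i$ decreases (`nestedness_scan()`), and both internal angles grow as $i$
decreases. At $i = i_c$ with $c < 2$ the eigenvalues collide and the
triangle degenerates; the scan reports this status instead of a verdict,
matching the continuity argument that covers the degenerate case in the
analysis. The module checks (numerically, on grids) that
$|\lambda_-(i)|/(1-i)$ increases in $i$ and $(1-i)/|\beta_-(i)|$ decreases
in $i$ — the two monotonicities behind the nestedness.

## The PDE simulator

`run_simulation()` advances the system by the method of lines on a uniform
grid with no-flux boundaries: second-order central differences for $A_{xx}$
(there is no spatial operator on $I$), Strang splitting of a Crank–Nicolson
diffusion step (sparse LU factorized once) around a classical RK4 step of
the local reaction, $dt = 0.25\,dx$ by default. The scheme is second order
in $dx$ and $dt$, preserves every steady state $(0, K)$ exactly, and keeps
$I$ pointwise non-decreasing in time ($I_t \ge 0$). Negative values are
never clipped: negativity beyond tolerance is treated as a scheme failure
and reported. The reference configuration mirrors the self-organization
scenario: $A(x,0) = \tfrac12 e^{-x^2}$, $I(x,0) = 0$ on $x \in [0, 400]$
with a reflecting boundary at $x = 0$ (the initial data are even, so the
half-line run represents the right-moving front), integrated to $t = 150$.

Front speed is the subtle part: these are *pulled* fronts, whose speed is
selected by the linearization in the leading edge and approached only with
a $-k/t$ correction (logarithmic shift of position). `track_front()` locates
the rightmost level crossing of $A$ per snapshot and fits
$x_f(t) = ct - k\log t + d$ over the last half of the run; the plain linear
slope is also reported and visibly understates $c$ at $t = 150$ (1.989
versus 2.0003 for the reference run). `plateau_density()` averages the
final $I$ field over a window well behind the front, restricted to points
where $A$ has vanished below $10^{-6}$. `comoving_profile_compare()`
resamples a computed wave orbit onto the grid (monotone cubic interpolation
with analytic exponential tail extensions, `resample_orbit()`) and reports
the shift-optimal sup-norm discrepancy — which decreases in time as the
front converges to the critical wave.

## Spectral stability in weighted spaces

Linearizing around a wave profile $w = (a, i)$ in the comoving frame gives

$$\tilde Y_t = D\tilde Y_{zz} + c\tilde Y_z + JR(w)\tilde Y, \quad
D = \mathrm{diag}(1, 0), \quad
JR = \begin{pmatrix} 1-2a-i & -a \\ 2a+i+r & a \end{pmatrix}.$$

Because inactive particles neither move nor react back, perturbations of
$I$ persist; stability can only hold in an exponentially weighted space
$H^1_\alpha$ that discounts what is convected backward. The weight is
applied by operator similarity ($\partial_z \to \partial_z - \alpha$;
multiplying grids by $e^{\alpha z}$ would overflow over the spans used).
`assemble_weighted_operator()` discretizes with central stencils and
homogeneous Dirichlet closure for the diffusive $\tilde A$ row, and one-sided
(upwind) transport for the hyperbolic $\tilde I$ row — the sided stencil is
taken toward increasing $z$, the side the characteristics of
$+c\,\partial_z$ come from, which keeps the transport block dissipative;
a central or wrong-sided stencil pollutes the spectrum with modes of
positive real part. A periodic closure is available for validating the
assembly against the exact constant-coefficient Fourier symbols.

`compute_spectrum()` performs a dense eigendecomposition and identifies the
translational mode by maximal overlap with the weighted profile derivative.
For the critical wave at $\alpha = c/2$ the computed spectrum lies in the
left half-plane apart from that mode (margin $\approx -0.01$ on the default
grid, $n = 800$ over $z_0 \pm 60$); without the weight the spectrum reaches
into the closed right half-plane, as it must for a pulled front. Two
caveats are inherent and documented by the tests rather than hidden: the
weighted essential spectrum *touches* the origin, so the rightmost
discretized eigenvalues are continuum edge modes that drift toward 0 at the
Dirichlet rate $O(L^{-2})$ as the span $L$ grows (the stability verdict is
robust to truncation; the individual edge-mode positions are not), and at
$\alpha = c/2$ the weighted translational eigenfunction grows linearly, so
its eigenvalue carries an $O(L^{-1})$ truncation error. This module is
exploratory: it asserts properties of the discretized operator, not certified
spectral bounds.

## Scenario generators and what passing tests show

`make_bump()`, `make_attractor_start()`, `make_perturbed_wave()` and
`parameter_grid()` generate every input family the analysis uses: Gaussian
heaps (optionally two, producing two outgoing fronts), starts on the
$b = 0$ plane scaled by the attractor bound, wave profiles plus seeded,
compactly supported, exponentially enveloped perturbations, and admissible /
must-fail parameter sweeps. All generators are pure functions of their
arguments and seed; CSV round trips are lossless at double precision.

These scenarios emulate the model's *normalized, one-dimensional,
deterministic* setting. They do not emulate the underlying stochastic
branching network (no tip-level noise, no two- or three-dimensional
geometry, no finite-particle effects), so passing tests validate the
continuum analysis — wave construction, invariance, front selection,
weighted spectra — and say nothing about fluctuation-driven behavior of the
discrete model.

## Problem sizes and defaults

The choices used throughout the package (and by `scripts/acceptance.R`) are:
shooting with $\varepsilon = 10^{-7}$, tolerances $10^{-10}/10^{-12}$,
sampling step $dz = 0.05$, convergence at $10^{-10}$ (critical case:
$10^{-8}$, span auto-enlarged); PDE reference run $dx = 0.1$,
$dt = 0.25\,dx$ on $[0, 400]$ to $t = 150$ with 76 snapshots; spectra on
$z_0 \pm 60$ with $n = 800$ nodes per component. Property tests use scaled
copies of the same configurations (shorter PDE domains, $n$ of a few
hundred) chosen so every qualitative feature — front separation, plateau
formation, tail asymptotics — is still resolved.

## Known limitations

* The heteroclinic orbits are computed by shooting, which is entirely
  adequate here because the unstable manifold is one-dimensional; a
  collocation/boundary-value formulation would be needed only for
  continuation in parameters.
* The center-manifold reduction is handled implicitly (the zero eigenvalue
  direction carries no flow); no explicit coordinate transform is provided.
* The spectral module discretizes on a truncated domain with Dirichlet
  closure; eigenvalues embedded in or adjacent to the essential spectrum
  carry the truncation effects described above.
* Proof-internal bounding constants of the underlying analysis are not
  computable quantities and have no counterpart in the package.
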