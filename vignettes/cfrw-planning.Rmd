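---
title: "Collision-free workspace boundaries and multi-needle trajectory planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision-free workspace boundaries and multi-needle trajectory planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrwplan)
```

## The planning problem

Thermal ablation of a large liver tumor requires several coagulation
needles, inserted percutaneously one after another. Each needle is rigid,
so its insertion trajectory is the line segment from an entry point on the
abdominal skin to a fixed target point inside the tumor. A usable
trajectory must (i) keep a clinical safe distance $\gamma$ from every
obstacle — ribs, major vessels, and the needles already inserted — (ii)
respect the insertion-angle limits of the needle-driving robot, and
(iii) be as short as possible, because long paths amplify targeting error
under tissue deformation.

`cfrwplan` formulates this as geometry over implicit surfaces. Every
obstacle and every needle part is a posed *super-quadric*

$$f(p) = \sum_{i=1}^{3}\left(\frac{p_i}{a_i}\right)^{e_i} - c,$$

evaluated in the body's local frame, with even exponents $e_i \ge 2$
(so $f$ is polynomial, hence smooth to the third order that the boundary
criterion differentiates), scales $a_i$ in mm and a level constant $c>0$.
Ellipsoids ($e = (2,2,2)$) model vessels; a high-exponent elongated body
models the needle shaft. Since the target is fixed, a candidate
trajectory has two rotational degrees of freedom $(\theta, \varphi)$ —
polar angle from vertical and azimuth — or equivalently the point
$u = (x, y)$ where the needle axis pierces a horizontal plane $z = h$.

## The collision-free reachable workspace (CFRW)

The set of trajectories that keep distance $\ge \gamma$ from an obstacle
is the needle's collision-free reachable workspace. Its 3-D boundary is
computed layer by layer: in each plane $z = h$ the boundary is a closed
1-D curve in $u$.

Three stacked systems describe the boundary:

1. **Kinematics** (2 equations): $u$ is consistent with $(\theta,
   \varphi)$ through the target. Bounded angles are substituted as
   $\theta = \tfrac{\theta_{\max}+\theta_{\min}}{2} +
   \tfrac{\theta_{\max}-\theta_{\min}}{2}\sin w_1$ (and analogously for
   $\varphi$), so the substituted parameters are unconstrained.
2. **Barrier closest pair** (11 equations, 11 unknowns): a primal-dual
   interior-point characterisation of the closest points $a$ (on the
   obstacle) and $b$ (on the needle): six stationarity rows
   $\nabla_\eta\|a-b\|^2 + \lambda_1 \nabla f_n + \lambda_2 \nabla
   f_{obs} = 0$, two membership rows $f + s = 0$, two complementarity
   rows $\lambda_i s_i = \mu$ with barrier parameter $\mu > 0$, and one
   clearance row $\|a-b\|^2 - \gamma^2 - s_d^2 = 0$.
3. **Boundary criterion** (27 equations, 28 unknowns): the extended
   system $\tilde\Phi$ (13 rows = kinematics + closest pair), the rank
   condition $\tilde\Phi_{\tilde z}^{\mathsf T}\,\tilde\xi = 0$ for a
   unit null direction $\tilde\xi$ (13 rows), and
   $\tilde\xi^{\mathsf T}\tilde\xi = 1$.

Inside the workspace the extended system is regular and $s_d > 0$. On the
boundary the clearance slack vanishes; since $s_d$ enters only as
$s_d^2$, its Jacobian column is zero there and the Jacobian is singular —
exactly the rank condition above. The solution set of the 27-equation
criterion is therefore a 1-D curve whose $u$-projection is the boundary.

### Numerical treatment

* All first and second super-quadric derivatives are closed-form (chain
  rule through the pose). The one block of the criterion Jacobian that
  would need third derivatives, $\partial(\tilde\Phi_{\tilde
  z}^{\mathsf T}\tilde\xi)/\partial\tilde z$, is formed by forward
  differences of the *analytic* Jacobian; this only influences Newton's
  contraction rate, not the attainable residual.
* A boundary point is found by marching from a feasible interior point
  along a fixed direction, re-solving the 13-equation system by damped
  Newton with warm starts (absolute residual tolerance $10^{-10}$, at
  most 50 iterations), bracketing where the solve first fails, bisecting
  the bracket to $10^{-8}$ mm, and polishing the full 28-dimensional
  state onto the criterion curve by minimum-norm Gauss–Newton. The null
  direction is initialised from the smallest singular vector of the
  Jacobian transpose.
* The curve is then traced by pseudo-arclength continuation
  (predictor–corrector, corrector tolerance $10^{-9}$). The step is
  adapted to a target in-plane displacement of 0.5 mm, halved on
  corrector failure (at most 10 times) and grown again on fast
  convergence; tracing stops when the curve closes on its seed, leaves
  the $[-h_{\max}, h_{\max}]^2$ domain, or reaches an angle-limit fold.
* Curve seeding combines a coarse interior grid (default $5\times5$;
  finer grids found nothing extra on any test scene, and each seed costs
  a directional march) with a deterministic seed at every obstacle's
  central projection through the target onto the layer. The projection
  seed is what finds thin shadows — an inserted needle's blocked strip is
  far narrower than any reasonable grid pitch. Duplicate curves are
  removed by discrete Hausdorff distance.

### Angle limits, azimuth periodicity, and membership

The angle limits themselves bound the workspace: in a layer they cut an
annulus (or sector) around the target's vertical. This region has a
closed form, so it is built analytically rather than traced. When the
azimuth range spans the full circle, $\varphi$ is periodic and
effectively unconstrained; the sine substitution would then manufacture a
spurious fold at the range ends, through which a traced curve doubles
back on itself. In that case the implementation parameterises $\varphi$
freely (identity substitution, branch cut rebased opposite each
obstacle); the sine substitution is applied whenever the range is a
strict subset of the circle, where the fold is a genuine workspace
boundary.

Trajectory membership is decided per layer by even–odd ray casting: the
axis/layer intersection must have odd parity against the angle-limit
region (inside the reachable annulus, holes handled automatically by
parity) and must not fall inside any obstacle's closed clearance curve,
each curve tested by the same parity rule. Testing curves individually
rather than as one pooled set keeps the answer correct even when two
partial traces of the same shadow overlap — pooled parity would cancel
there; for the convex bodies used, each curve encloses a simply connected
infeasible pocket, so per-curve containment is exact. A needle is
feasible iff it passes on every obstacle and every crossed layer. If a
curve vertex lies on the test ray, the ray is rotated by a fixed
irrational angle and the test repeated; no randomness is involved.
Obstacles that pierce a layer (inserted needles) produce infeasible
strips that reach the angle-limit circle, so their traced curves are open
arcs; they are closed deterministically along a slightly inflated
angle-limit arc, on the side that a direct clearance probe shows to be
infeasible, and the angle limits are additionally checked analytically so
the inflation cannot leak feasibility.

### The barrier bias

With the printed slack convention ($f + s = 0$, $\lambda s = \mu$), the
closest-pair points sit strictly *inside* both bodies on the central
path. At a traced boundary point, $\|a - b\| = \gamma$ exactly, but the
true surface-to-surface distance is smaller by about $\mu/(2\gamma)$ per
"thick" side (≈ 0.033 mm per side at $\gamma = 1.5$ mm, $\mu = 0.1$; the
near-line needle contributes only its sub-0.05 mm radius). The bias is
linear in $\mu$, which the test suite verifies by re-tracing at
$\mu/10$. The complementarity rows $\lambda_i s_i = \mu$ also admit a
branch with both signs negative, where the pair sits slightly *outside*
the bodies and the realised clearance exceeds $\gamma$ by the same
$O(\mu)$ margin; Newton may land on either branch depending on the warm
start, so clearance checks bound $|d - \gamma|$ rather than assume a
sign. Analyses that need a tight clearance characterisation (e.g.
the closed-form cone comparison) use $\mu = 0.01$; the planning default
follows the reference setting $\mu = 0.1$.

## Optimal entry search

The entry point is the CFRW-feasible point of the parametric skin surface
$S(u, v)$ closest to the (deformation-compensated) target. The search is
the four-quadrant grid refinement: start at the parameter-domain
midpoint with intervals $L_1, L_2$ equal to half the domain; evaluate
the four quadrant centres at $\pm L_i/2$ offsets; discard infeasible
candidates (by the ray-casting membership test); keep the best feasible
incumbent; halve the intervals and recentre on it. Termination when the
sine of the angle between the trajectory and the surface normal falls to
$\delta = 10^{-5}$ (the unconstrained optimum is a perpendicular foot),
or when $\max(L_1, L_2) \le \varepsilon = 10^{-4}$. The procedure is a
local search by construction; an optional $m \times m$ multi-start is
provided but off by default. Candidates outside the parameter bounds are
skipped; equal-distance ties break to the lexicographically smallest
$(u, v)$; if all four quadrant centres are infeasible while the incumbent
is feasible, the intervals still halve around the incumbent, which
preserves convergence without abandoning a feasible point.

Skin kinds: elliptic-cylinder patch (abdominal wall), polynomial height
patch, spherical patch, and a gridded bilinear interpolant for tabulated
point clouds.

## Sequential planning

`plan_all()` iterates over the targets in insertion order: compensate the
target by the accumulated displacement from a pluggable
`DisplacementProvider` (zero by default — the deformation model is
external), build the obstacle set as anatomy plus previously inserted
needles, compute the CFRW, run the entry search, and append the inserted
needle — truncated at its skin entry point — as a rod obstacle for its
successors. Insertion order is an input (default: target order). The
whole path is deterministic: with the zero provider, re-running a plan
reproduces `plan.json` byte for byte.

## Defaults and units

| parameter | default | unit | meaning |
|---|---|---|---|
| `gamma` | 1.5 | mm | safe clearance to every obstacle |
| `mu` | 0.1 | – | barrier parameter (bias $\approx \mu/2\gamma$ per side) |
| `z_layers` | 150, 160, 170 | mm | boundary slice heights |
| `h_max` | 200 | mm | layer-domain half-width / max height |
| `delta_tol` | 1e-5 | – | entry-search normal-alignment sine |
| `eps_tol` | 1e-4 | param. units | entry-search interval floor |
| `step_u` | 0.5 | mm | continuation step in the layer plane |
| head scales | (60, 0.1, 0.1), $e=(8,2,2)$, $c=1000$ | mm | needle head super-quadric |

The printed head parameters give an axial half-extent of
$60 \cdot 1000^{1/8} \approx 142$ mm and a cross radius of
$0.1\sqrt{1000} \approx 3.2$ mm — effectively the whole inserted shaft
as one body. They are kept as defaults (and are fully configurable); the
head length constant is derived from them as the head's own axial extent
so the posed head spans exactly $[0, l]$ above the tip. `validate_scene`
flags implausible sizes without rejecting them.

## What the synthetic scenes emulate — and what they do not

`make_three_needle_scene()` reproduces the reference simulation layout at
desk scale: three collinear targets at $(0,0,0)$, $(0,-15,0)$,
$(0,-30,0)$ mm, vessel-like elongated super-quadrics between tumor and
skin, a cylindrical skin patch spanning $z \approx 150$–$180$ mm, and
the reference parameters $\gamma = 1.5$, $\mu = 0.1$, layers
$\{150, 160, 170\}$. `make_sphere_oracle_scene()` builds the one
configuration with a closed-form boundary — a sphere probed by a
near-line needle, whose CFRW boundary is the tangent cone of half-angle
$\arcsin((r+\gamma)/D)$ — and is the independent oracle for the tracer.
The near-line needle uses a rod radius of ~0.03 mm: geometrically
negligible against the 0.5 mm continuation step, while keeping the KKT
system's scales within what double-precision Newton handles comfortably.
`make_random_vessel_scene()` draws seeded vessel poses from its own
linear-congruential stream (the global RNG is untouched), restricted to
the $+x$ half-space so layer shadows stay away from the azimuth branch
cut.

These scenes are emulations, not patient data: vessels are convex
ellipsoids rather than branching trees, the skin is a smooth analytic
patch rather than a tracked point cloud, and no deformation model is
bundled. Passing tests therefore demonstrate the geometry and numerics —
clearance characterisation, oracle agreement, sequential obstacle
updates — not clinical validity on reconstructed anatomy. The original
study's in-vitro placement accuracy (2.1 ± 0.6 mm) depends on physical
hardware and is out of desk-scale reach by construction.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at the scale the method
is specified at: single boundary curves of 300–1500 continuation points,
one to three layers, one to five obstacles, and three sequential needles
for the full demo plan. Brute-force oracles (multi-start nearest-point
searches, dense feasibility grids of ~600×600 to 2000×2000 cells,
finite-difference derivative checks) are sized to finish alongside.

## Known limitations

* Convexity: the closest-pair system assumes each body is convex (true
  for the even-exponent super-quadrics used); concave anatomy must be
  approximated by unions of convex pieces, one CFRW intersection each.
* Curve topology: a clearance curve that stalls mid-trace (corrector
  underflow away from any angle fold) is closed along the angle-limit
  arc, which is only correct when the open ends actually sit near that
  arc; `end_reason` records every such case.
* The entry search is local. The multi-start option mitigates but does
  not remove this.
* Layers are horizontal planes; a trajectory that is feasible on every
  stored layer but infeasible between layers is not detected — choose
  the layer set to bracket the obstacles of interest.
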