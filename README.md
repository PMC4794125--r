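# cfrwplan

Automatic multi-needle insertion-trajectory planning for robot-assisted
thermal ablation of large liver tumors.

Large tumors need several overlapping coagulations, hence several
needles, inserted one after another through the abdominal wall. Each
trajectory is a straight line from a skin entry point to a fixed target
in the tumor, and it must (a) keep a clinical safe distance γ from ribs,
major vessels, and the needles already in place, (b) respect the
insertion-angle limits of the needle-driving robot, and (c) be as short
as possible. `cfrwplan` computes, for each needle in turn, the boundary
of its **collision-free reachable workspace (CFRW)** — the set of
trajectories through its target with clearance ≥ γ to every obstacle —
and then picks the shortest feasible trajectory on the skin surface.

## The method in brief

Obstacles and needle parts are posed **super-quadrics**
`f(p) = Σ (p_i/a_i)^{e_i} − c` with even exponents. For a needle pivoting
about its target, a candidate trajectory is identified with the point
`u = (x, y)` where its axis pierces a horizontal plane `z = h`. Three
stacked nonlinear systems characterise the workspace boundary in that
plane:

* 2 kinematic rows tying `u` to the (limit-substituted) insertion angles;
* 11 interior-point KKT rows for the closest pair `(a, b)` between the
  needle surface and the obstacle surface — stationarity, surface
  membership with slacks, barrier complementarity `λᵢsᵢ = μ`, and the
  clearance row `‖a−b‖² = γ² + s_d²`;
* a Jacobian rank condition: on the boundary the clearance slack `s_d`
  vanishes and the 13×13 Jacobian of the stacked system becomes
  singular. Appending `Φ̃_z̃ᵀ ξ̃ = 0` for a unit null direction `ξ̃`
  gives 27 equations in 28 unknowns, whose solution set is a 1-D curve.

That curve is traced by pseudo-arclength continuation (all superquadric
derivatives closed-form), one closed curve per obstacle per layer.
Trajectory feasibility is then a ray-casting parity test against the
angle-limit region and the traced curves. The optimal entry point on the
parametric skin `S(u, v)` is found by four-quadrant grid refinement of
`min ‖S(u,v) − target‖` over the feasible set, and the planner loops
over needles, adding each inserted needle (truncated at its entry point)
to the obstacle set and compensating later targets by a pluggable
displacement model.

## Worked example

The sphere-obstacle scene is the configuration with a closed-form
answer: a sphere of radius `r` a distance `D` above the target, probed
by a near-line needle, has a tangent-cone CFRW boundary of half-angle
`asin((r+γ)/D)` — a circle in each layer.

```r
library(cfrwplan)
osc <- make_sphere_oracle_scene(r = 6, D = 40, gamma = 1.5, z_layers = 150)
osc$half_angle            # 0.18862 rad
osc$circle_radius(150)    # 28.633 mm

plan <- plan_all(osc$scene)
print(plan)
#> <plan_result 'sphere-oracle-r6-D40'> 1 needle(s)
#>   needle 1: entry (-9.8643e+01, -9.1553e-04,  1.5056e+02) mm, d_min 180.000 mm, min clearance 15.89 mm
```

The traced boundary circle has mean radius 28.727 mm — the 0.09 mm
excess over the analytic 28.633 mm is the needle rod radius plus the
barrier bias, both of which the test suite bounds. The vertical
trajectory is blocked by the sphere, so the entry search walks to a
feasible point of the cylindrical skin patch
(`entry = (-98.643, -0.001, 150.564)` mm) while every radial direction
attains the same minimal length `d_min = 180` mm; the search stops when
the trajectory aligns with the surface normal (`normal_alignment`, 16
iterations). `min clearance` is the brute-force distance from the
planned needle to the sphere: 15.9 mm ≥ γ.

The three-needle demonstration (three collinear targets, three vessels,
γ = 1.5 mm, μ = 0.1, layers {150, 160, 170} mm) runs with
`plan_all(make_three_needle_scene())` in a few minutes and returns three
mutually clearing trajectories; `save_plan()` writes `plan.json` and
`boundaries.csv`, `plot_layers()` draws the layer curves.

A thin CLI wraps the same functions:

```sh
inst/cli/cfrw-plan synth --preset demo3 --out scene.json
inst/cli/cfrw-plan run --scene scene.json --gamma 1.5 --mu 0.1 --out outdir/
inst/cli/cfrw-plan trace --scene scene.json --needle 1 --z 150 --out curves.csv
```

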