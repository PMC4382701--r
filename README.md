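# pitchersim

Vertex-dynamics simulation of oriented cell division in pitcher-leaf
primordia.

Carnivorous pitcher leaves develop two regions with different growth modes:
a *hollow* region that grows bifacially like a flat blade, and a *ridge*
(keel) that protrudes from the adaxial side. Histology places the
difference in cell-division orientation — longitudinal (division plane
perpendicular to the tissue surface) in the outer three cell layers of the
hollow region, periclinal (parallel to the surface) in the adaxial L2/L3 of
the ridge. `pitchersim` is for developmental biologists and modellers who
want to test whether those division-orientation rules are *sufficient* to
produce the two morphologies in silico, and to reuse the accompanying
quantification tools.

The package implements, in a transverse 2-D section:

* **Tissue mechanics** — cells are polygons sharing vertices; massless
  vertices in a viscous medium follow η dx/dt = −∂U/∂x with

  U = (K_S/2) Σᵢ (Sᵢ − sᵢ)² + Σⱼ (K_B Lⱼ + K_R/Lⱼ) + (K_E/2) Σₖ (Lₖ − L_E)²,

  where sᵢ = Nᵢ tan(π/6) / (6 tan(π/Nᵢ)) is the edge-count-dependent target
  area, the edge term gives every wall a finite target length √(K_R/K_B),
  and the third term stiffens the outermost (cuticle) walls; integration is
  RK4 at Δt = 0.005.
* **Morphogens** u (division-promoting, sourced at the adaxial–abaxial
  epidermal junctions), v (epidermal) and w (adaxial-epidermal), diffusing
  on the cell-adjacency graph: dzᵢ/dt = A·1(source) − B zᵢ + D Σ(zⱼ − zᵢ).
* **A division clock** d(clock)/dt = P₀ + P·Hill(u; u₀, n)·Hill(S; S₀, m)
  with per-cell thresholds drawn from [0.9C, 1.1C]; epidermal cells divide
  instead when they reach five neighbouring cells, by a line through the
  midpoints of their outermost and innermost edges.
* **Orientation rules** — inner cells divide perpendicular to their long
  axis (closed-form principal axis of the vertex second moments); L2/L3
  divide parallel to the morphogen-v axis (longitudinal) or perpendicular
  to the morphogen-w axis (periclinal, forced in adaxial L2/L3 under the
  ridge preset).
* **Quantification** — division-plane angles vs the local surface tangent
  (0° periclinal, 90° longitudinal) with exact/approximate Mann–Whitney
  comparisons and circular summaries; protrusion morphometrics; and
  expression-boundary detection on smoothed intensity profiles (local
  extrema of the backward difference of a cubic smoothing-spline fit).

## Worked example

```r
library(pitchersim)

run <- run_simulation(run_config(mode = "ridge", seed = 1, max_cells = 400))
run$summary
#> # A tibble: 1 x 12
#>   n_cells n_divisions  time  n_L1  n_L2  n_L3 n_inner protrusion_height
#>     <int>       <int> <dbl> <int> <int> <int>   <int>             <dbl>
#> 1     400         294 4665.    79    79   100     142             0.625
#>   aspect_ratio adaxial_share inner_fraction classification
#>          <dbl>         <dbl>          <dbl> <chr>
#> 1         1.40         0.127          0.355 protrusion

# division-plane angles of adaxial L2/L3 cells (0 = periclinal)
ev <- tidy(run)
median(ev$angle[ev$layer %in% c("L2", "L3") & ev$side == "adaxial"])
#> [1] 11.69793

autoplot(run$tissue, fill = "identity")   # section with the adaxial keel
```

The ridge preset stacks cell layers under the adaxial epidermis: over a
third of its cells end up deeper than L3 (`inner_fraction` 0.355) while
the adaxial epidermis barely expands (`adaxial_share` 0.127), and adaxial
L2/L3 division planes are periclinal (median 11.7°).  A `mode = "hollow"`
run from the same seed inverts every signature — adaxial L2/L3 angle
median 79.0° (longitudinal), `adaxial_share` 0.523, `inner_fraction`
0.087 — bifacial blade growth lining a deep hollow. `sweep_simulations()` tabulates grids of
configurations (e.g. varying `D_u`, `A_u`, `P`, or the initial shape), and
`write_tissue()` / `write_svg_tissue()` export snapshots as CSV pairs and
SVG renderings. A thin command-line wrapper ships at
`inst/cli/pitchersim` (`init`, `simulate`, `angles`, `boundary`).

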