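# terrabed

Simulation of terraced dry riverbeds as meta-ecosystems: trait-based plant
communities competing for water and light across a chain of
runoff-connected terraces under pulsed rainfall.

Ancient stone-wall terraces cover large stretches of desert riverbeds.
Abandoned for centuries, they still intercept runoff, accumulate soil
moisture, and host self-organized plant communities — novel ecosystems
whose productivity, functional diversity, and drought resilience depend on
how rainfall is delivered and redistributed.  terrabed is a tool for
ecologists and ecohydrologists who want to explore those dependencies in a
mechanistic model: which plant strategies are filtered from a species pool
in each terrace, how communities change downstream, and how whole
riverbeds respond to drought and to changes in rainfall regime.

## The model

A riverbed of `n` terraces (`j = n` uppermost) carries the biomass
`B_ij` of `m` plant functional groups plus soil water `W_j` and surface
water `H_j` per terrace:

    dB_ij/dt = Λ_ij · W_j/(1 + aW_j) · (1 + E_i B_ij)² (1 − B_ij/K_i) B_ij − M B_ij
    dW_j/dt  = I H_j − L W_j − W_j/(1 + aW_j) · Σ_i Γ B_ij (1 + E_i B_ij)²
    dH_j/dt  = P − I H_j + D (H_{j+1} − H_j)          (j < n)
    dH_n/dt  = (1 + α(P)) P − I H_n − D H_n

with light competition `Λ_ij = Λ₀ [1 − (B_Tj − B_ij)/(B_Tj + B_R)]` and a
hillslope runoff subsidy `α(P) = α₁P²/(1 + α₂P²)` on the uppermost
terrace.  Functional groups trade maximal shoot biomass against
root-to-shoot ratio along a coordinate `χ ∈ [0, 1]`:
`K(χ) = K_min + (1−χ)^ε ΔK`, `E(χ) = E_min + χ^ε ΔE`, with `ε < 1` convex,
`ε = 1` linear, and `ε > 1` concave pools.  Rain arrives as `k` one-day
square-wave events per year in the wet half-year with `k·A·T = MAP` held
fixed.  The system is integrated with a compiled fixed-step fourth-order
Runge–Kutta scheme; community outcomes are read off the asymptotic
biomass pulse over `χ` (area = total biomass, width = functional
diversity, position = composition).  See the vignette
(`vignettes/terraced-riverbed-model.Rmd`) for parameters, units, and
numerical choices.

## Worked example

Steady-state terrace profiles for a linear pool of 100 groups under six
16.7 mm events per year:

```r
library(terrabed)
prof <- terrace_profile_experiment(epsilon = 1, k = 6, MAP = 100,
                                   m = 100, tol = 1e-5, max_years = 400)
prof$summary
#> riverbed: biomass 261.994 kg/m^2, diversity 0.3535, centroid 0.579
#>  terrace  B_total diversity  centroid          W        H
#>        1 27.01846 0.2424242 0.5854904 0.03524383 3.188846
#>        2 27.01846 0.2424242 0.5854904 0.03524391 3.188852
#>        3 27.01848 0.2424242 0.5854904 0.03524467 3.188910
#>        4 27.01863 0.2424242 0.5854906 0.03525183 3.189455
#>        5 27.01998 0.2424242 0.5854924 0.03531512 3.194262
#>        6 27.03194 0.2424242 0.5855078 0.03579214 3.230792
#>        7 27.43492 0.2525253 0.5874572 0.03854557 3.445299
#>        8 29.40736 0.2626263 0.5828067 0.04561751 4.248558
#>        9 43.02541 0.3535354 0.5467157 0.03644484 6.357130
```

The uppermost terrace (j = 9), fed by hillslope runoff, carries the most
biomass (43.0 kg/m² year-end) and the widest community (pulse width 0.354
of the trait axis); each cascade step passes on only ~11% of its surface
water, so by terrace 6 the profiles are indistinguishable (27.0 kg/m²,
width 0.242) and the composition centroid has shifted from χ ≈ 0.547
toward the root-investing end (χ ≈ 0.585).  The riverbed-level width
(0.354, the union of terrace supports) exceeds every single-terrace
width.  `drought_experiment()` and `rainfall_sweep()` drive the same model
through drought–recovery scenarios and regime comparisons at fixed mean
annual precipitation, and `plot_profiles()` / `plot_drought()` /
`plot_sweep()` render the standard panels.

A thin command-line front end over these functions ships in
`inst/cli/terrabed.R`:

```sh
Rscript inst/cli/terrabed.R steady-state --events 6 --map 100 --out-dir runs/demo
```

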