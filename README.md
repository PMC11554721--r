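# vesselgr

Coupled bio-chemo-mechanical growth and remodeling (G&R) of blood
vessels in R.

Arteries adapt to sustained changes in pressure and flow: they thicken
to restore their circumferential (hoop) stress and change caliber to
restore wall shear stress. `vesselgr` simulates this adaptation with a
homogenized constrained mixture model of the wall — elastin, four
collagen fiber families and smooth muscle, each with its own stress-free
configuration and turnover kinetics — coupled to logic-gated
intracellular signaling networks evaluated at every material point and
to continuum reaction–diffusion of the endothelium-derived messengers
nitric oxide (NO) and endothelin-1 (ET1). It is intended for
mechanobiologists and modelers who want a desk-scale, fully scripted
counterpart to 3D finite-element G&R codes: every constitutive and
evolution equation is retained; only the mechanics is reduced to an
axisymmetric thick-walled cylinder.

## Model core

For each constituent *i* the deformation gradient splits as
**F**<sub>e</sub><sup>i</sup> = **F F**<sub>g</sub><sup>−1</sup>
(**F**<sub>r</sub><sup>i</sup>)<sup>−1</sup>, with radial growth
(det **F**<sub>g</sub> = ρ₀(s)/ρ₀(0)) and isochoric fiber remodeling
driven by the scalar law

λ̇ᵣ = (ρ̇₀/ρ₀ + 1/T) · λᵣ/(2 I₄ₑ) · (∂σ/∂I₄ₑ)⁻¹ · (σ − σ_h),

so mass turnover shifts each fiber family toward its homeostatic stress
σ_h. Mass production is controlled by signaling networks of normalized
Hill activations f⁺(y) = W·B·yⁿ/((B−1)+yⁿ), B = (EC₅₀ⁿ−1)/(2EC₅₀ⁿ−1),
composed with scaled AND / OR / AND-NOT gates and run to steady state;
network outputs act through their normalized deviations Δψ = (y−y₀)/y₀
on the turnover laws. NO and ET1 satisfy quasi-steady reaction–diffusion
D∇²c = c/T across the wall with endothelial flux boundary conditions
tied to the wall-shear-stress ratio ε/(a/A)³. A staggered scheme
advances mechanics → signaling → biochemistry each 7-day step.

## Worked example

A 15% pressure step with the three-node stress-sensing network at
sensitivity 1.0:

```r
library(vesselgr)
run <- run_scenario("sensitivity_sweep",
                    overrides = list(gamma = 1.15, s_sigma = 1.0),
                    t_end_norm = 10)
print(run)
#> <gr_run> sensitivity_sweep
#>   steps: 100 (to s/T^m = 10.0), n_radial = 5
#>   final: r/A = 1.0340, h/H = 1.0869, trace/trace0 = 1.0464, wss = 0.9046
#>   ideal adaptation: a/A = 1.0000, h/H = 1.1500
```

The wall has thickened to 1.087 of its initial value, approaching the
ideal marker γ·ε^(1/3) = 1.15 that would fully restore the hoop stress;
the normalized mixture-stress trace has decayed from its post-step jump
back to within ~5% of baseline; the inner radius has drifted 3.4%
outward (this preset has no wall-shear feedback to pull it back, so wall
shear is 10% below baseline). `glance(run)` returns these as a one-row
tibble, `tidy(run)` the full per-step time series in long format, and
`autoplot(run)` the four-panel evolution plot with baselines and
ideal-adaptation markers.

Other presets (`list_scenarios()`): `angii_hypertension` (pressure step
with optional exogenous angiotensin II — accelerated adaptation with a
transient stress undershoot and a smaller adapted radius),
`ec_communication` (endothelial layer, NO/ET1 diffusion, active muscle
tone; a 10% flow step dilates the lumen toward ε^(1/3)·A ≈ 1.03·A), and
`uncoupled` (phenomenological stress-driven rates, no signaling).

A thin command-line wrapper ships at `inst/cli/vasogr`
(`vasogr list-scenarios`, `vasogr run --scenario ec_communication --set
epsilon=1.1`, `vasogr steady-state --network net.json --inputs
stress=0.6`, `vasogr prestress`).

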