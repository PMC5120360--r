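---
title: "The glioma-vasculature interplay model: methods and numerical choices"
author: "gliovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The glioma-vasculature interplay model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
assumptions behind it, and the numerical and design choices that a user or
reviewer should know about before trusting its output.

## The biological picture

Diffuse gliomas infiltrate the brain rather than growing as compact masses.
Two microenvironmental mechanisms shape that infiltration:

* **The migration/proliferation dichotomy (Go-or-Grow).** Glioma cells occupy
  mutually exclusive migratory and proliferative phenotypes and switch between
  them in response to oxygen: normoxic cells proliferate, hypoxic cells
  migrate towards better-oxygenated tissue.
* **The vascular feedback loop.** Functional vessels supply oxygen; hypoxic
  tumour cells secrete pro-angiogenic factors that recruit new vessels; and
  dense tumour tissue mechanically occludes vessels (vaso-occlusion),
  creating the hypoxia that drives further migration — the histological
  pseudopalisade pattern.

The package asks how interventions that modulate this loop — changing the
cellular oxygen-consumption rate or the occlusion rate — alter the two
clinically relevant invasion metrics, front speed and infiltration width.

## Model equations and hierarchy

The fields are glioma density $\rho(x,t)$ (cells/mm), functional vasculature
$v(x,t)\in[0,1]$ (normal tissue at $1/2$), and oxygen $\sigma(x,t)$ (nmol/mm)
on $x\in[0,L]$ with no-flux boundaries. Linear switching rates
$f_{12}(\sigma)=\lambda_2\sigma$ and $f_{21}(\sigma)=\lambda_1-\sigma$
(with $\lambda_1>\sigma_0$ so both stay positive on the physiological range),
assumed fast relative to migration and division, give the quasi-steady-state
phenotype fractions

$$\alpha(\sigma)=\frac{\lambda_1-\sigma}{(\lambda_1-\sigma)+\lambda_2\sigma},
\qquad \beta(\sigma)=1-\alpha(\sigma),$$

the migratory and proliferative shares of the total density. Summing the two
phenotype equations with Fickian diffusion of the migratory subpopulation
yields the density equation with the diffusion operator acting on the
composite field $D_\rho\,\alpha(\sigma)\,\rho$ (see "Numerical choices" for
the alternative flux form). The full system (Model III) is

$$\begin{aligned}
\partial_t\rho &= \partial_x^2\!\left[D_\rho\,\alpha(\sigma)\,\rho\right]
  + b_\rho\,\beta(\sigma)\,\rho\,(1-\rho/N),\\
\partial_t v &= D_v\,\partial_x^2 v + g_1\,M(\rho,\sigma,v)\,v(1-v) - g_2\,v\rho^n,\\
\partial_t\sigma &= D_\sigma\,\partial_x^2\sigma + h_1 v(\sigma_0-\sigma) - h_2\rho\sigma,
\end{aligned}$$

with $M=\rho\tilde H(\sigma-\hat\sigma)\,/\,(\rho\tilde H(\sigma-\hat\sigma)+Kv)$
the Michaelis–Menten activation of vessel formation by the effective
pro-angiogenic factor at quasi-steady state (hypoxic production proportional
to $\rho$, endothelial uptake proportional to $v$, decay negligible against
uptake), and $\tilde H(\xi)=1/(1+e^{\xi/\theta})$ a smoothed decreasing step.
The normalisations $D_\rho=D/\alpha(\sigma_0)$ and $b_\rho=b/\beta(\sigma_0)$
make $D$ and $b$ the *intrinsic* rates: with $\sigma\equiv\sigma_0$ the
density equation is exactly Fisher–Kolmogorov with coefficients $(D,b)$.

The hierarchy: **Model II** is Model III with $g_1=g_2=0$ (constant
vasculature $v_0$; oxygen still dynamic), appropriate where vascular
pathology is not prominent (low-grade tumours); **Model I** is Model II with
$h_2=0$ (constant oxygen $\sigma_0$), the classical Fisher–Kolmogorov model.
The solver integrates only the dynamic fields of each variant, so the
constancy of $v$ (variants I, II) and $\sigma$ (variant I) is exact, and the
package's tests verify that the variants collapse onto each other at the
parameter limits.

## Parameters

Defaults are the published physiological parameterisation:

| symbol | meaning | default | units |
|---|---|---|---|
| D | intrinsic glioma diffusion | geometric mid of [2.73e-3, 2.73e-1] | mm²/day |
| b | intrinsic glioma proliferation | geometric mid of [2.73e-4, 2.73e-2] | 1/day |
| N | tissue carrying capacity | 100 | cells/mm |
| σ₀ | physiological oxygen | 1.0 | nmol/mm |
| λ₁, λ₂ | switching parameters | 2.0, 1.0 | nmol/mm, — |
| D_σ | oxygen diffusion | 151 | mm²/day |
| h₁ | oxygen supply (vessel permeability) | 0.337 | 1/day |
| h₂ | cellular oxygen consumption | 5.73e-3 | mm/(cell·day) |
| D_v | vasculature dispersal | 5e-4 | mm²/day |
| g₁ | vessel formation rate | 0.1 | 1/day |
| σ̂ | hypoxic threshold | 0.25 | nmol/mm |
| K | half-maximal factor concentration | 1.0 | nmol/mm |
| g₂, n | vaso-occlusion rate and degree | 5e-13, 6 | cell⁻ⁿmmⁿ/day, — |
| θ | Heaviside steepness | 0.01 (= σ₀/100) | nmol/mm |
| v₀, ρ₀ | initial vasculature, seed density | 0.5, 10 (= N/10) | —, cells/mm |
| ε, γ | seed length, seed steepness | 2, 0.1 | mm |
| L, T_f | domain, horizon (single runs) | 200, 400 | mm, days |

Choices that were genuinely open, and why they were made this way:

* **h₂ and g₂ defaults** are the *baseline* levels of the published regime
  maps (h₂ = 5.73e-3 is the constant consumption level of the occlusion
  maps; g₂ = 5e-13 the lowest captioned occlusion level), not the midpoints
  of their ranges — the default parameter set should reproduce the reference
  condition against which modulations are measured. λ₂ defaults to the middle
  of its three published values.
* **Seed density ρ₀ = N/10.** The vaso-occlusion term $g_2 v\rho^n$ with
  $n=6$ only acts above roughly half carrying capacity. A seed *above* N/2
  would occlude its own vasculature at $t=0$ regardless of how slowly it
  proliferates, erasing the critical proliferation rate b⁺ below which
  tumours never become dense enough to occlude. Seeding at a tenth of
  capacity makes occlusion an emergent consequence of proliferation, which is
  the mechanism the model is built to study.
* **Heaviside realisation.** Any monotone smooth step with steepness θ works;
  the logistic form is used with θ = σ₀/100, sharp on the oxygen scale but
  resolvable by the solver. The hypoxic gate is $\tilde H(\sigma-\hat\sigma)$,
  ≈1 exactly when $\sigma<\hat\sigma$.
* **Degenerate Michaelis–Menten point.** At $\rho\tilde H = 0$ and $v = 0$
  the activation is 0/0; it is defined as 0 (no factor sources and no
  vessels means no formation), which keeps the healthy-tissue state
  $(\rho,v,\sigma)=(0,v_0,\sigma_0)$ an exact fixed point.
* **No hard density gate on occlusion.** The steep power law already makes
  occlusion negligible below N/2 at the published magnitudes (the rate at N
  is 2⁶ = 64 times the rate at N/2); an optional smooth gate
  $\tilde H(N/2-\rho)$ is available (`occlusion_gate = TRUE`) but off by
  default.

## Numerical scheme

Method of lines: 3-point central differences on a uniform grid, ghost-node
reflection at both boundaries (zero flux, second order). Time integration is
`deSolve::lsoda` — adaptive, stiff-capable, needed because oxygen diffusion
($D_\sigma/\mathrm{d}x^2 \sim 10^4$/day at dx = 0.1 mm) is fast against cell
motility. The state is interleaved per node so the internally estimated
Jacobian is banded (bandwidth ≤ 5), which keeps the implicit steps cheap.
Tolerances are rtol = 1e-6, atol = 1e-9. Runs are deterministic and
bit-reproducible for fixed inputs; the package uses no randomness anywhere.

Degenerate inputs and guards:

* Oxygen is clamped to $[0,\lambda_1-10^{-12}]$ before evaluating the switch
  fractions inside the right-hand side; an excursion beyond 1% of the field
  scale aborts with a diagnostic (instability, not roundoff).
* Output snapshots are clipped onto the physical bounds $[0,N]\times[0,1]
  \times[0,\sigma_0]$; excursions beyond 100·rtol (relative) raise an
  integration error rather than being silently clipped.
* The glioma diffusion term defaults to the composite form
  $\partial_x^2(D_\rho\alpha\rho)$ obtained by summing the phenotype
  equations; the conservative flux form
  $\partial_x(D_\rho\alpha\,\partial_x\rho)$ is available
  (`diffusion_form = "gradient"`) for sensitivity checks. The two differ by
  a $\partial_x(\rho\,\partial_x(D_\rho\alpha))$ transport term that is small
  where $\alpha$ varies slowly; measured front speeds agree within a few
  percent (tested).

## Observables and their estimators

* **Front position**: the point of most negative slope of $\rho$ (the tumour
  is seeded at the left boundary, so the invading front is the rightward,
  decreasing one), refined by quadratic interpolation around the discrete
  gradient minimum. Flat profiles raise a typed no-front error.
* **Front speed**: least-squares slope of front position over the final 25%
  of the run — more robust to output discretisation than a two-point
  difference while still measuring the developed, late-time wave. If the
  front enters the last 5% of the domain during the window the run is
  rejected (boundary contamination) rather than silently biased.
  A caveat inherited from front propagation theory: pulled fronts approach
  their asymptotic speed with a slowly decaying $O(1/t)$ (Bramson)
  correction of relative size $\approx 3/(4bt)$, so speed measurements
  intended for comparison with $2\sqrt{Db}$ must use horizons with
  $t \gg 1/b$. The package's Fisher–KPP checks run to $T_f = 2000$ days
  (correction ~1.5% at the fit window) for this reason; comparisons *between*
  runs at equal horizons (the sweep difference maps) are insensitive to it
  because the correction largely cancels.
* **Infiltration width**: distance between the 80% and 2% crossings of the
  density maximum, located by linear interpolation on the rightward monotone
  segment. Width is measured on the invading front only; with a left-seeded
  1-D tumour there is exactly one front.
* **Effective rates**: unweighted domain averages
  $D_{\mathrm{eff}}=\frac1L\int D_\rho\alpha(\sigma)\,dx$,
  $b_{\mathrm{eff}}=\frac1L\int b_\rho\beta(\sigma)\,dx$ by trapezoidal
  quadrature, which reduce exactly to $(D,b)$ at uniform physiological
  oxygen. A $\rho$-weighted variant (`rho_weighted = TRUE`) is provided for
  sensitivity analysis; the unweighted average is the default because it is
  the form the domain-length normalisation implies.

## Sweep design and threshold estimation

Regime maps run an 8×8 (or smaller) logarithmic grid over the physiological
ranges D ∈ [2.73e-3, 2.73e-1] mm²/day, b ∈ [2.73e-4, 2.73e-2] /day at two or
more levels of h₂ (Model II) or g₂ (Model III). Per-cell runs are
independent and deterministic, so execution order cannot matter; failed cells
carry typed error messages in the result, never silent defaults.

**Problem sizes.** Sweeps use dx = 0.25 mm, T_f = 1000 days, L = 300 mm.
The spatial step is justified a posteriori by the refinement tests (halving
dx moves measured speeds by well under 2% and flips no regime
classification). The horizon follows from the slowest mechanism on the map:
a tumour seeded at N/10 needs $\ln 9/b \approx 2.2/b$ days of logistic
growth to reach the N/2 occlusion threshold, i.e. ~800 days at mid-range
b — with a shorter horizon the occlusion-driven regimes simply have not
happened yet for most of the b range and the difference maps are blank.
L = 300 mm keeps the fastest fronts (~0.17 mm/day for 1000 days) clear of
the right-boundary guard.

**Classification dead zone.** A front-speed difference below 0.5% of the
cell's baseline speed counts as "no change". Threshold estimators operate on
these sign classifications, bracketing between grid values rather than
interpolating noisy differences:

* **b\*** (h₂ sweeps): in each D column, the bracket where the speed
  difference flips from positive (slow proliferators invade faster under
  higher consumption) to negative; the median bracket across columns is
  reported with its min/max spread, plus flags for no crossing or multiple
  crossings.
* **b⁺ and Λ⁺** (g₂ sweeps): b⁺ is the smallest b whose row contains a
  speed-up cell; within rows at or above b⁺ the boundary midpoint between the
  last slow-down and first speed-up cell along D is collected, and the line
  b = Λ⁺·D is fitted through the origin by least squares. Fewer than three
  boundary points raises an insufficient-resolution error rather than
  returning a two-point "fit".

The estimated thresholds are implementation-anchored: the reference work
reports them only as features of heat maps, so the package validates their
*structure* (existence, bracketing inside the captioned ranges, linearity of
the boundary within one grid cell, opposite speed/width responses on the two
sides) rather than numeric values.

## What the test conditions do and do not show

The study conditions are a clean 1-D caricature: a single smoothed tumour
seed in homogeneous, isotropically vascularised tissue, no anatomy, no
treatment, no cell-level stochasticity. Passing tests therefore demonstrate
the internal consistency of the model and solver (conservation, hierarchy
collapse, travelling-wave asymptotics, regime structure) — not agreement
with any patient data. Features of real gliomas deliberately outside scope:
2-D/3-D geometry (prior work on the continuous Go-or-Grow model found no
interface instability, so 1-D results are expected to carry over
qualitatively), explicit VEGF or multi-chemokine dynamics, convective oxygen
transport, interstitial pressure mechanics, immune involvement, and any
treatment scheduling.

Known limitations worth keeping in mind:

* The speed/width trade-off under vaso-occlusion expresses slowly: its
  width-decrease side is a weak effect that only exceeds the classification
  dead zone deep inside the speed-up wedge, so on an 8×8 map most speed-up
  cells classify as "width unchanged". Longer horizons sharpen it.
* b⁺ is horizon-dependent by construction (it reflects which tumours have
  had time to reach occluding densities), so it should be read as "critical
  proliferation rate at the stated T_f", not as a universal constant.
* The vaso-occlusion term is phenomenological; the exponent n = 6 encodes
  "collapse above half capacity" but is not mechanistically derived.
* lsoda's internal step adaptation means trajectories are reproducible for a
  fixed solver version but may differ at the tolerance level across deSolve
  versions.
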