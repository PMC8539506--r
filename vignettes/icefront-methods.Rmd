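---
title: "icefront: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{icefront: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icefront)
```

# The problem

During the freezing stage of vial lyophilization, the nucleation
temperature and the dynamics of the freezing front determine the ice
crystal sizes and hence the pore structure of the dried cake. An infrared
camera pointed at a row of vials can record each vial's whole axial
temperature profile at low cost; tracking the height of the axial
temperature maximum (`Hmax`) provides a proxy for the freezing-front
position in conduction-dominated (ON-shelf) vials, and the gradient
between `Tmax` and the bottom pixel estimates the frozen-layer gradient.
These two quantities are the inputs that one-dimensional ice-crystal-size
models need. The cake itself is characterised after drying by segmenting
pores in SEM cross-sections and comparing pore-size dispersion (variance
and interquartile range) across process conditions.

`icefront` implements this chain end-to-end with a synthetic, fully
seeded stand-in for the camera and the microscope, so every processing
stage can be validated against known ground truth.

# The freezing simulator

## Governing model

A vial is a 1-D column of `n_nodes` cells (default 32 over a 10 mm cake).
Each node carries a specific enthalpy $u$ (J/kg; zero for liquid at the
solution's equilibrium temperature $T_{eq}$) and an ice mass fraction
$f$. The caloric equation of state is

$$u(T, f) = c_{p,l}(T - T_{eq}) - f\,\Delta H_f(T), \qquad
\Delta H_f(T) = \Delta H_f(T_{eq}) - (c_{p,l} - c_{p,ice})(T_{eq} - T),$$

whose temperature derivative is the correct mixture heat capacity.
Cryoconcentration is modelled by a hyperbolic liquidus
$T_{liq}(f) = T_m - d_0/(1 - f)$ with $T_m = 273.15$ K and
$d_0 = T_m - T_{eq}$ (0.15 K for the default $T_{eq} = 273.0$ K of
5 % w/w solutions; setting $T_{eq} = 273.15$ K recovers pure water with a
flat liquidus). A node is treated as fully solid once
$f_{\max} = 1 - d_0/(d_0 + w_s)$ is reached, where $w_s$ (`sol_window_K`,
default 2 K) is the span between nominal freezing point and the
operational solidus; for pure water $f_{\max} = 1$.

The explicit enthalpy march uses harmonic-mean interface conductivities
(linear mixture $k(f)$), Robin boundaries at both ends (the boundary film
coefficient in series with the half-cell conduction, so $h \to \infty$
degenerates gracefully to a Dirichlet face), distributed side exchange
$h_{side}\,(P/A)\,(T_{env} - T)$, and a time step bounded by the
stability criterion $\Delta t \le 0.4\,\rho c_{p,ice} \Delta x^2 /
(2 k_{max} + h_{max} \Delta x)$. In the limit of a fixed cold base, no
side losses and pure-water properties the front trajectory converges to
the one-sided Stefan similarity solution within 2 % (the transcendental
condition is solved independently in the test suite).

## Nucleation

* **Adiabatic jump.** At nucleation every supercooled node jumps to its
  (depressed) equilibrium temperature and instantaneously freezes the
  fraction $f = c_{p,l}(T_{eq} - T_n)/\Delta H_f(T_n)$
  (`instant_freeze_fraction()`), i.e. the latent heat of the instantly
  frozen fraction pays exactly for the sensible reheat. With standard
  water constants this gives 3 % at 271 K and 14 % at 263 K.
* **VISF.** The vial cools toward the pre-nucleation shelf setpoint;
  once the bottom node reaches `Tn_target` a 600 s equilibration hold
  runs, then the vacuum pulse applies an evaporative heat sink to the
  upper liquid (coefficient `h_evap` = 20 W/(m^2 K) toward an effective
  sink of 230 K, penetration depth 8 mm, emulating evaporation-driven
  mixing). Nucleation fires when the top node reaches
  `visf_trigger_K` (264.5 K, a surface supercooling of ~8.5 K). At deep
  supercooling (`Tn_target` = 263 K) the whole vial is already below the
  trigger, so nucleation fires at pulse onset --- before any gradient can
  develop, which is exactly why those runs show no inversion. In a
  batch the pressure drop is chamber-wide, so `simulate_batch()`
  schedules the pulse once (probe vial) and imposes it on all vials;
  the residual spread of nucleation times comes from vial-to-vial
  heat-transfer variability (5 % lognormal) plus a short onset jitter.
* **Spontaneous.** An exponential clock (rate `spont_rate`, default
  1/300 s^-1) runs while any node is at or below `Tn_target`; each vial
  draws its own waiting time, giving the staggered, hundreds-of-seconds
  spread the camera sees.

## What the camera must see, and how 1-D gets there

Two emulation devices stand in for effects that a 1-D conduction model
cannot produce; both are explicit, seeded, and documented here because
they define the synthetic world rather than approximating a published
model.

* **ON-shelf front signature (kinetic slush).** After nucleation the
  column is a slush at ~3-14 % ice. Solidification proceeds
  *contiguously* from the cold base: nodes adjacent to the front are
  pinned to the liquidus (ACTIVE), while slush away from the front grows
  ice only at the kinetic rate `kinetic_rate * undercooling`
  (default 1e-5 /(K s)), so side cooling leaves it ~1-2 K below the
  liquidus. The warm liquidus-pinned point at the front is therefore the
  axial maximum, and `Hmax` rides the front --- the observable the whole
  method rests on. A slush node joins the active front when its
  neighbour toward the front is at least half frozen (dendrites run ahead
  of complete local solidification).
* **OFF-shelf mid-height maximum and pre-nucleation stratification.**
  Suspended vials freeze as a radial shell in reality; the camera sees a
  nearly parabolic wall profile with the maximum near mid-height. The
  1-D emulation removes heat symmetrically (bottom/top film coefficients
  24/12 W/(m^2 K)) with an exponential end-boost of the side exchange
  (`fin_gain` 2, length 2.5 mm; the glass above and below the product
  acts as a thermal fin) and treats the whole mush as equilibrium
  (liquidus-pinned), which yields the observed smooth mid-height maximum
  drifting with noise. Before nucleation, buoyancy below water's density
  maximum carries the coldest liquid to the top; a pure conduction model
  with an insulated base forces a zero gradient at the bottom face and
  cannot make the bottom pixel measurably the warmest. The simulator
  therefore relaxes the liquid column (energy-conservingly) toward a
  linear stratified profile of 0.45 K/mm with a 5 s overturn time.

## Heat-transfer defaults are calibration knobs

The study's dryer coefficients are unpublished, so the defaults were
chosen once to reproduce the qualitative observables: ON-shelf
`h_bottom` 250 W/(m^2 K) (shelf contact plus gas conduction at ambient
pressure), `h_side` 24, `h_top` 3; OFF-shelf 24/8/12; environment 3 K
above the shelf. These give a freezing interval (nucleation to all
pixels at or below 263 K) of roughly 16 min ON-shelf versus 23 min
OFF-shelf. The ordering matches the observations the package targets;
the absolute OFF-shelf duration is compressed relative to the reported
~45 min, a known limitation of the symmetric-removal emulation.

# The camera model

Rendering maps each vial's nodal field to 6 acquisition lines x 8 pixels
(pixel centres at $(p - 0.5) \cdot 1.25$ mm) by linear interpolation,
applies the graybody forward model
$T_{app} = (\epsilon T^4 + (1-\epsilon) T_{refl}^4)^{1/4}$ at
$\epsilon = 0.91$, adds i.i.d. Gaussian noise (0.3 K), and emits frames
at 0.1 fps. Neighbour-nucleation "humps" (+3.5 K decaying over 60 s on
the outermost lines) can be injected for spontaneous batches.
`correct_emissivity()` is the exact algebraic inverse (round-trip
1e-9 K); the correction strategy is pluggable since the published
correction formula is not reproduced in the source study.

Processing applies no smoothing or filtering of any kind: extrema are a
plain min/max scan per line with ties broken toward the lowest height,
then averaged extremum-first line -> vial -> batch (the order matters and
is tested against a fixture where the two orders disagree).

# Front analysis

* `track_front()` restricts `Hmax` to post-nucleation frames, computes a
  central-difference velocity over a 5-frame stencil, and labels phases
  with a two-segment least-squares fit (breakpoint minimising total SSE;
  a segment with |slope| below 0.02 mm/min is a plateau, the steeper
  segment is the linear ascent). OFF-shelf traces are refused.
* `freezing_interval()` uses the `Tmax` series (which bounds every
  pixel) and a two-frame sustained crossing of 263 K.
* `classify_inversion()` operationalizes the qualitative batch table:
  within a window the bottom pixel is LOWEST/HIGHEST if it clears every
  other pixel by `margin_K` (0.2 K) in at least 80 % of frames. Windows:
  *before* = 300 s ending at the pulse (VISF) or at nucleation; *during*
  = the last 100 s of the pulse; *after* = 300 s to 1500 s after
  nucleation, truncated once the column maximum stays below 263 K
  (gradients genuinely fade there, and including the equalised tail
  would degrade every label to UNCLEAR). The during-pulse window is
  allowed to be shorter than 5 frames --- nucleation at pulse onset is
  the deep-supercooling signature --- in which case it inherits the
  before-pulse label and the inversion verdict is NO when the bottom was
  LOWEST. Before/after windows shorter than 5 frames are an error.
* Spontaneous batches are analysed per vial and averaged after aligning
  each vial at its own detected nucleation time (`align_profiles()`);
  VISF batches nucleate together and use plain batch means.
* `detect_nucleation()` returns the first frame whose rise above a
  trailing reference exceeds `jump_K` within a 60 s forward window;
  thresholds of 2 K (VISF) and 4.5 K (spontaneous, rejecting ~3-4 K
  neighbour humps) are the pipeline defaults.

# Pore segmentation (MIA)

The segmentation chain and its defaults:

1. **Equalization**: subtract a 101 px moving-average background and
   restore the global mean exactly (charging-gradient removal).
2. **Texture PCA**: unfold 5x5 windows into a matrix (one row per
   interior pixel, columns in row-major window order), mean-centre,
   eigen-decompose the column covariance. Components are sign-fixed so
   the centre-slot loading is negative: dark pores score high. A
   shifted-image path (`mia_score_image()`) computes identical loadings
   and score images without materialising the matrix, and the two paths
   are tested for agreement.
3. **Score threshold**: `score > quantile(score, 0.8)` by default. The
   source procedure tunes this limit manually; the quantile makes the
   choice reproducible, and the default pairs with the generator's
   18 % porosity target (a deliberately coherent synthetic world: the
   green recovery test establishes the chain's internal consistency, not
   that 0.8 is right for any particular real SEM).
4. **Canny edges**: Gaussian sigma 1.5, hysteresis at 0.1/0.25 of the
   maximum gradient magnitude, 8-connected weak-edge components kept if
   they contain a strong pixel. Regions fully enclosed by edges are
   filled and unioned with the score mask (the second filter targets
   lighter pores outlined by strong gradients).
5. **Dimensional filter**: 8-connected components with area outside
   [50, 1000] px removed; the bounds are inclusive because the source
   rule removes areas *lower than* 50 or *greater than* 1000.
6. **Region properties**: pixel-count area, exposed-edge perimeter (the
   number of unit pixel edges between the component and anything else),
   centroid, equivalent diameter $d = s_{px}\sqrt{4A/\pi}$. Border
   pixels without complete windows carry no score and are background.

PCA is fitted per image (not pooled); window sizes, thresholds and Canny
parameters are all arguments with the stated defaults.

# Pore statistics

Quartiles use R's type-7 linear-interpolation rule through a single
shared implementation, variance uses the n-1 denominator, and
IQR = Q3 - Q1. `beta_qq()` pairs order statistics with scaled
Beta(1.2, 15) quantiles at plotting positions $(i - 0.5)/n$ and reports
the squared Pearson correlation of the Q-Q relation; when no scale is
supplied it is fitted by maximum likelihood with the shapes fixed, which
makes the r-squared invariant under rescaling of the data. Group
comparison is sign-based (which loading has the lower variance/IQR),
because the source reports no absolute dispersion numbers.

# The synthetic SEM world

`generate_sem_image()` throws non-overlapping ellipses (aspect 0.7-1,
area-preserving; 2 px clearance keeps pores 8-disconnected; placement in
decreasing size order, fully inside the frame) with diameters drawn from
`diameter_scale_um * Beta(1.2, 15)` until `n_pores` are placed or the
porosity target is reached. Defaults (scale 100 um, 0.43 um/px, 18 %
porosity, 2000 pores on 2100 x 2100 px) were chosen once so that the
bulk of the population lies inside the 50-1000 px analysis window and a
2000-pore population exactly fills the porosity budget. The matrix is
bright (185) with Gaussian texture (sd 10) and a row-wise charging ramp
(40 levels peak-to-peak); pores are dark (60). What a green end-to-end
test establishes: the segmentation chain recovers the quartiles of the
in-window population within 15 % and the count within 20 % on this
world. What it does not establish: performance on real SEM texture
(sputter-coating granularity, depth-of-field, wall shading), which no
synthetic stand-in of this simplicity can claim.

# Numerical choices and degenerate inputs

* Enthalpy inversion on the liquidus is a 60-iteration bisection
  (monotone, bracketed); all other state branches are closed-form.
* Extremum ties break toward the lowest height; uniform profiles return
  the lowest pixel centre for both extrema.
* `Hmax = 0` makes the frozen-layer gradient undefined (`NA` with a
  warning); traces that never reach 263 K yield `NA` intervals.
* Quantile-mode thresholds on all-`NA` borders ignore the borders.
* The text stack format stores integer centikelvin (0.01 K), below the
  camera noise floor; seeded reruns of every pipeline are byte-identical
  (manifests carry md5 sums and no timestamps).

# Known limitations

* 1-D only: radial shell freezing, view-factor radiation and real vial
  curvature are out of scope; OFF-shelf behaviour is an emulation of the
  camera observable, with a compressed absolute duration.
* The 8 px / 1.25 mm axial resolution bounds what `Hmax`-based
  quantities can achieve: front position to about one pixel and the
  frozen-layer gradient to roughly 15 % mid-cake, regardless of
  estimator quality.
* The emissivity correction is a graybody inversion with a constant
  reflected temperature; real radiometric calibration chains are not
  modelled.
* Beta-distributed equivalent diameters with independent placement are a
  convenient null model; real cakes have spatially correlated pore sizes
  across cake height.
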