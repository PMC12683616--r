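---
title: "Lightning disturbance in an individual-based forest gap model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightning disturbance in an individual-based forest gap model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lightgap` simulates a tropical forest stand as a collection of individual
trees on a voxel grid: space is discretized into 1 x 1 x 1 m cells, each
ground cell holds at most one living tree, and a 200 x 200 x 50 m domain
therefore holds at most 40,000 trees. Trees are characterized by species,
diameter at breast height (DBH), and leaf area; species are defined by leaf
mass per area, wood specific gravity, leaf %N and %P, a generalized
Michaelis-Menten DBH-height allometry

$$H(D) = \frac{a\,D^{b}}{k + D^{b}},$$

a reproductive maturity DBH, a maximum DBH, and a lightning tolerance
$\Delta_i$ (below).

Each monthly timestep runs, in order: **growth**, **stage-1 mortality**
(background + carbon starvation), **stage-2 mortality** (treefall with
secondary damage), **lightning** (optional third stage), and **recruitment**.

### Carbon balance

Top-of-canopy photosynthetic photon flux density (PPFD) is attenuated
downward through each voxel column with the Beer-Lambert law
(extinction coefficient $k_{ext} = 0.5$ by default). Crowns are umbrella
shaped: one-voxel-thick disk layers spanning the crown depth with uniform
leaf area density, capped at a leaf area index of `lai_max` (default 8) over
the crown area; canopy mass in excess of the cap is shed as litter.

Leaf-level gross photosynthesis per half-hourly slot is the minimum of a
Rubisco-limited and an RuBP-regeneration-limited rate,

$$A = \min\!\big(0.25\,V_{cmax}\,f_T\,f_D,\;
      \min(\phi\,I_\ell,\; 0.2\,J_{max}\,f_T)\big),$$

where $I_\ell$ is absorbed PPFD per unit leaf area, $\phi$ is the apparent
quantum yield (default 0.065 mol C mol photon$^{-1}$, the midpoint of the
uncertainty range 0.04-0.09), $f_T$ a mild Q10 temperature response, and
$f_D = (1 + \sqrt{VPD}/g_1)^{-1}$ a stomatal factor in the spirit of the
Medlyn optimization ($g_1 = 3.77$ kPa$^{0.5}$). The lumped factors 0.25 and
0.2 stand in for the CO$_2$-limitation terms of the full biochemical model
and put light-saturated assimilation near 10 umol m$^{-2}$ s$^{-1}$ for a
typical tropical canopy leaf. $V_{cmax}$, $J_{max}$, and leaf dark
respiration derive from area-based leaf N and P by a log-linear trait
relationship; species lacking leaf %P use the same relationship with the P
term dropped and its mean contribution folded into the intercept.

Monthly NPP is GPP minus leaf, stem (proportional to sapwood volume), and
belowground maintenance respiration (proportional to aboveground
maintenance), minus growth respiration (25% of the surplus). NPP can be
negative. Positive NPP is allocated with fixed fractions
$f_{below} + f_{wood} + f_{canopy} = 1$; above a size threshold
(`size_threshold_frac` = 0.5 of the species maximum DBH) the wood fraction
is halved, and at the maximum DBH wood growth stops; in both cases the
remainder is diverted belowground so the three increments always sum to NPP.
Wood growth updates stem volume
($V = F \tfrac{\pi}{4} (D/100)^2 H$, form factor $F = 0.6$), DBH (by Newton
inversion, never decreasing), height, crown radius
($cr = 0.5\,D^{0.6}$), and crown depth (25% of height).

The `max_dbh` trait deserves a note: with Michaelis-Menten exponents
$b < 1$ the height curve is so flat that carbon balance alone does not stop
diameter growth, and single trees otherwise grow without bound. A species
maximum DBH is standard in trait-based gap models; tables lacking the column
fall back to an allometric derivation capped at 250 cm.

### Demography

Stage-1 mortality sums a background probability, linear in wood specific
gravity (equal to $m_0/12$ per month at the softest wood, zero at
`wsg_max`), and carbon starvation: probability one once consecutive
negative-NPP months exceed the species leaf lifespan (proportional to LMA,
$12\,(LMA/100)$ months — the proportional scaling keeps the leaf
replacement cost per unit leaf area trait-neutral, which prevents the
cheapest-leaf species from excluding all others). Stage-2 treefall probability is a Hill
function of height — exactly zero at zero height, half its ceiling at the
midpoint height (30 m), saturating at `treefall_max_prob` (0.0015 per
month). A falling tree crushes trees in a corridor of length equal to its
height and half-width its crown radius along a uniform random azimuth;
crushed trees die when shorter than half the faller's height.

Recruitment fills every unoccupied ground voxel whose mean-day ground PPFD
exceeds the light-compensation threshold of a species drawn from the
seedbank (unit external seed rain per species, plus a bounded bonus for
species with at least one mature tree in the domain — bounded so abundant
species cannot monopolize recruitment); recruits start at DBH 1 cm.

## The lightning module

Cloud-to-ground flashes arrive at an areal frequency $\lambda$
(CG fl km$^{-2}$ yr$^{-1}$; 12.7 at the reference site, 95% CI 10.9-14.5).
Every ground voxel is struck independently each month with probability
$\lambda \times 10^{-6}/12$. A strike targets the tallest tree within 15 m
of the struck voxel (ties broken toward the smallest $(x, y)$ index). The
**community-level lightning risk** (CLLR) model gives every tree at distance
$r$ from the struck tree a death probability

$$P_{com}(r, D) = P_{direct}\; 10^{\,a\,\frac{70\,\mathrm{cm}}{D}\,
  \frac{r}{45\,\mathrm{m}}},$$

with $a < 0$: the direct hit ($r = 0$) dies with probability $P_{direct}$,
risk decays with distance and grows with size. A note on the sign of $a$:
the printed form of this equation carries a leading minus sign while the
calibration searches $-7 \le a \le -1$; the two are inconsistent, and we
adopt the convention above (exponent $a \cdot (70/D)(r/45)$, $a$ negative)
so that risk decays with distance over the printed search range. Trees
beyond a flashover cutoff `r_max` (default 25 m, the radius of the largest
observed damage areas) are unaffected. All lightning deaths are immediate
and the voxels become available for recruitment; sub-lethal crown damage is
not carried over.

The **species-specific lightning risk** (SSLR) model shifts the base-10
log-odds by the species tolerance $\Delta_i$:

$$\log_{10}\frac{P_i}{1 - P_i} = \log_{10}\frac{P_{com}}{1 - P_{com}}
  + \Delta_i ,$$

so $\Delta_i < 0$ is tolerant, $\Delta_i > 0$ intolerant, and unknown
tolerances default to 0 (identical to CLLR). The scaling factor
$s_i = 1/(1 + e^{-\Delta_i})$ summarizes tolerance on (0, 1) with 0.5 as
neutrality. Note the base mismatch: $s_i$ is the natural-base logistic while
the risk shift is base-10, so the interpretation of $s_i$ as "the SSLR risk
when the CLLR risk is 0.5" is exact only in base 10; both formulas are
implemented exactly as printed.

### Calibration

`calibrate_cllr()` fits $(a, P_{direct})$ to field mortality counts binned
into 5 distance and 3 DBH classes. Because an unknown fraction of
lightning-damaged trees dies later, a parameter $d \in [0, 1]$ converts the
counts into effective observed mortalities $O = killed + d \cdot damaged$
per cell (the same $d$ in every cell). The scaled residual

$$R(a, P_{direct}; d) = \sum_{r}\sum_{D}
  \frac{(M_{D,r} - O_{D,r})^2}{O_{D,r}}$$

is minimized by exhaustive search on the full lattice: 101 values of $a$
(step 0.06 on $[-7, -1]$) by 101 values of $P_{direct}$ (step 0.01 on
$[0, 1]$). Predicted mortalities $M = n_{trees} \cdot P_{com}(r_{rep},
D_{rep})$ use geometric distance midpoints (0 for the direct-hit class) and
arithmetic DBH midpoints — the bin representative is a design choice, as is
skipping (with a warning) cells with $O = 0$, which the residual cannot
scale. Exact ties break toward smaller $|a|$, then smaller $P_{direct}$.
Bias and RMSE over the 15 cells report goodness of fit.

## Uncertainty analysis and the frequency sweep

Six parameters carry the model's dominant uncertainty: $\phi$ (0.04, 0.09),
$m_0$ (0, 0.03 yr$^{-1}$), $f_{below}$ (0.1, 0.5), the allocation angle
$\theta$ ($\pi/12$, $5\pi/12$), $\lambda$ (10.9, 14.5), and $d$ (0, 1).
Because $f_{wood} + f_{canopy} = 1 - f_{below}$, the aboveground split is
sampled through $\theta = \tan^{-1}(f_{canopy}/f_{wood})$:

$$f_{wood} = (1 - f_{below})\frac{\cos\theta}{\cos\theta + \sin\theta},
 \qquad
 f_{canopy} = (1 - f_{below})\frac{\sin\theta}{\cos\theta + \sin\theta}.$$

Parameter sets are the first $n$ points of a standard Sobol' sequence
(Joe-Kuo direction numbers, Gray-code order, first point at the origin),
scaled affinely to the ranges — deterministic and prefix-stable, so a
20-member exploration is literally the prefix of the 1000-member production
design. Each ensemble member re-calibrates $(a, P_{direct})$ from its own
$d$ before running. The frequency sweep crosses 15 frequencies (9 to 23
CG fl km$^{-2}$ yr$^{-1}$) with the same parameter sets at every frequency
(15,000 runs at production scale); each manifest row carries a
deterministic seed derived from the run id, so the manifest is pure and any
row is replayable in isolation. Whether to re-use stochastic streams across
frequencies was an open choice; we use independent seeds per run.
`filter_consistent()` keeps members whose equilibrium AGB, GPP, N10, and N60
fall inside user-supplied observational intervals (the intervals come from
site data and are deliberately not bundled). `transient_lambda()` supplies a
linear monthly $\lambda(t)$ ramp for out-of-equilibrium experiments.

Outputs per run are averaged over the final 50 years: AGB (Mg ha$^{-1}$),
GPP (Mg C ha$^{-1}$ yr$^{-1}$), stem counts N10/N30/N60, strike and kill
tallies by species and size class. `tolerance_binning()` aggregates species
by $s_i$ (tolerant / neutral / intolerant) and `agb_delta_summary()` forms
the per-parameter-set AGB difference between two frequencies together with
its empirical CDF — the compositional-acclimation diagnostics.

## Synthetic inputs

The three external inputs (species traits, half-hourly meteorology, binned
lightning mortality) are not redistributable, so generators stand in for
them and are first-class, tested code:

- `gen_species()`: 27 species by default with 20% tolerant and 20%
  intolerant; the tallest species is strongly tolerant
  ($\Delta = -2$), without which compositional acclimation has nothing to
  act on. Trait covariance is injected weakly (taller stature, denser wood,
  larger maximum size) so equilibria contain emergent trees. A tenth of
  species lack leaf %P, exercising the N-only physiology route.
- `gen_forcing()`: 48 half-hourly slots x 12 months; sinusoidal daylight
  PPFD arc peaking at 1100 umol m$^{-2}$ s$^{-1}$ at noon — a multi-year
  climatological mean including cloudy slots, not a clear-sky maximum —
  with mild seasonal amplitude variation; smooth diurnal temperature and
  VPD cycles.
- `gen_binned_mortality()`: multinomial (killed / damaged / unaffected)
  draws per cell with probabilities chosen so the effective observed
  mortality at the generating $d$ is unbiased for the generating risk
  model, enabling round-trip calibration tests.

What the generators do **not** emulate: real trait covariance structure,
interannual and synoptic weather variability, spatially clustered strikes,
and observational error in the field counts. Tests passing on synthetic
data therefore validate the machinery (contracts, calibration recovery,
directional responses), not site-level predictive skill.

## Numerical choices and desk-scale experiment sizes

- Boundary rule: toroidal wrap for all spatial queries (light, treefall,
  lightning), configurable to hard edges; the torus avoids edge artifacts
  on small domains.
- Deterministic row-major voxel iteration and a single RNG stream make runs
  bit-reproducible from (config, seed); at $\lambda = 0$ the lightning stage
  consumes no random numbers, so a zero-frequency run is bit-identical to a
  lightning-disabled one.
- Distance $r$ in the risk model is measured from the struck (target) tree,
  matching how the calibration data are recorded.
- The simulation engine is C++ (Rcpp), as is conventional for
  individual-based forest models; the R operations and the engine share one
  set of inline kernels, and the test suite exercises the R surface against
  independent oracles.
- Shipped experiment sizes are desk scale by design: the directional
  frequency-response checks use a 50 x 50 m domain, 300-year runs, 20
  Sobol' parameter sets, and the sweep endpoints $\lambda \in \{9, 23\}$.
  The production-scale design (4 ha, 600 yr, 1000 sets, 15 frequencies) is
  expressed by exactly the same manifest machinery.
- At 0.25 ha the between-run demographic variance of equilibrium AGB is
  large in absolute terms — a single emergent carries on the order of
  90 Mg ha$^{-1}$ — so frequency-contrast statistics behave differently
  than on large domains. The mean AGB decline separates the two risk
  models cleanly (the community-level model loses the dominant tolerant
  emergents; the species-specific model does not), but the median total
  decline does not, because the extra community-level losses sit in a
  right tail of occasional catastrophic emergent deaths and neutral
  species partially refill the freed canopy space. Median-based contrasts
  of total biomass therefore need domains large enough that every run
  contains many strikes; tolerance-binned biomass and kills-per-strike
  are the informative desk-scale diagnostics.

## Limitations

No lianas, soil water, nutrient cycling, fire, wind disturbance, or
interannual climate variability; no sub-lethal crown damage dynamics
(lightning kills are immediate or absent); one tree per square metre with
integer voxel positions; the photosynthesis module is a contract-level
simplification of the full biochemical leaf model, with lumped CO$_2$
factors rather than explicit $C_i$ dynamics. At 0.25 ha, lightning is a
rare-event process (a handful of strikes per decade), so equilibrium
contrasts need ensembles of runs, not single realizations.
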