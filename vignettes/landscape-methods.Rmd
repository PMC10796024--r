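---
title: "Energy landscapes and transition paths for plant-pollinator networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscapes and transition paths for plant-pollinator networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

ecoscape studies bipartite plant-pollinator communities under generalized
Lotka-Volterra dynamics with saturating mutualism. With plants
$P_1,\dots,P_{N_P}$ and pollinators $A_1,\dots,A_{N_A}$,

$$
\frac{dP_i}{dt} = \alpha_i P_i - \beta_{ii} P_i^2
  - \sum_{k \ne i}\beta_{ik} P_i P_k
  + \frac{P_i \sum_l \gamma^{(A)}_{il} A_l}{1 + h \sum_l \gamma^{(A)}_{il} A_l}
  + \mu,
$$

and symmetrically for pollinators with an extra decay term $-\kappa A_j$
that models environmental degradation. The mutualistic benefit saturates
(Holling type II, handling time $h$), and the per-link strength divides a
per-capita budget $\gamma_0$ by the receiving species' degree raised to the
trade-off exponent $\delta$: $\gamma^{(A)}_{il} = \gamma_0
\varepsilon_{il} / [g^{(P)}_i]^{\delta}$. Defaults follow the standard
parameterization of this literature: $\alpha = 0.3$, $\beta_{\text{intra}}
= 1$, $\beta_{\text{inter}} = 0.01$, $\gamma_0 = 1$, $\delta = 0.5$,
$h = 0.2$, $\kappa = 1.07$.

Immigration defaults to $\mu = 0$. A positive $\mu$ is supported, but it
pins every species above a floor of order $\mu/\kappa$; with the
conventional extinction threshold of $10^{-3}$ and $\mu = 10^{-3}$ no
pollinator could ever be classified extinct, so the neglect of immigration
is the only internally consistent default.

A state in which all pollinators sit below the extinction threshold
($10^{-3}$) is the **low** state. Among coexisting stable states the one
with the largest total abundance is **high**; a non-maximal state keeping
fewer than half of the pollinators (or just one, typically the most
generalist species) is **intermediate**. Multistability scenarios are coded
H, HI, HL, HIL, IL, L, and T for two or more intermediate-like states.

## Attractors and basin weights

`find_attractors()` integrates the ODEs from random initial conditions
(uniform per species on $[0, x_{hi}]$), polishes endpoints by Newton
iteration, verifies linear stability through the analytic Jacobian, and
merges duplicates within $10^{-3}$ in the infinity norm. Basin weights
$\phi_j$ are occupancy frequencies of the starts. The default box
$x_{hi} = \max(\alpha/\beta, 3)$ probes a generous abundance range; on the
packaged fixture the low/intermediate basins occupy a negligible share of
that box, so fixture analyses use $x_{hi} = 1$ (roughly the carrying-
capacity scale), under which the three basins carry weights of about
0.52/0.33/0.14. This is a property of basin geometry, not of the dynamics:
the attractors themselves are identical under either box.

`continue_attractors()` tracks all coexisting branches across a $\kappa$
grid by Newton continuation, walking outward from the anchor $\kappa$ so
that a branch losing stability on one side of the grid is not lost on the
other. Two rescue steps handle bifurcations: a vanished branch (fold) is
re-relaxed by integration from the stale state, and a branch destabilized
by a re-viable extinct species (invasion) is reseeded at $10^{-2}$ and
relaxed over a long horizon, because invasion growth rates near the
bifurcation are of order $10^{-2}$ per unit time.

## The truncated-moment landscape

Adding isotropic white noise of intensity $d$ turns the ODEs into a
Langevin equation whose stationary density obeys a Fokker-Planck equation.
Truncating moments above second order (valid for $d \ll 1$) makes the
density around each attractor Gaussian: the mean is the fixed point and
the covariance solves the stationary Lyapunov equation
$\Sigma A^\top + A \Sigma + 2 d I = 0$ with $A$ the Jacobian at the fixed
point. The package solves this exactly through the Kronecker-product
linear system; the residual is checked to $10^{-8}$ and the covariance to
positive semi-definiteness. The global stationary density is the
$\phi$-weighted Gaussian mixture over attractors and the potential is
$U = -\ln p_{ss}$.

Basin weights are recomputed at every parameter value of a sweep rather
than smoothed across it, so the landscape at each $\kappa$ reflects that
$\kappa$ alone.

**Noise default.** The landscape functions default to $d = 0.005$. The
choice matters for resolution rather than correctness: at $d = 0.01$ the
low and intermediate components of the fixture overlap so strongly that
they merge into a single basin on the reduced grid, while at $d = 0.005$
all three basins resolve. A `d` argument exposes the sweep.

## Bipartite dimension reduction

Because plants and pollinators obey two different equation families, the
two guilds are reduced separately: the exact mixture moment formula
$\Sigma(X) = \sum_j \phi_j (\Sigma_j(X) + \mu_j(X) \mu_j(X)^\top) -
\mu(X)\mu(X)^\top$ is evaluated on the plant block and the pollinator
block, and the leading eigenvector of each becomes a projection axis:
$z_1 = w_1(P)^\top P$ (plant PC1) and $z_2 = w_1(A)^\top A$ (pollinator
PC1). Signs are fixed so the high state projects to the largest
coordinates, making landscapes comparable across parameter sets; a
projection computed at one reference parameter set can be reused across a
sweep. Each mixture component projects exactly to a bivariate Gaussian,
so the reduced potential $U(z_1, z_2) = -\ln p_z$ is evaluated in closed
form on a grid (default $200 \times 200$ spanning the projected means
$\pm 4$ projected standard deviations).

## Saddles and barrier heights

The saddle between two basins is the lowest crossing level: the smallest
$c$ for which the two minima belong to one 4-connected component of
$\{U \le c\}$. Cells are merged in increasing order of $U$ with a
union-find structure, which returns the exact grid minimax level in one
sweep (equivalent to, but cheaper than, bisection with flood fill).
Barrier heights are $BH_{si} = U_{\text{saddle}} - U_i$ and the relative
barrier height is $RBH_{ij} = BH_{sj} - BH_{si}$, antisymmetric by
construction; a positive $RBH_{ij}$ means basin $j$ is the deeper one and
the transition $i \to j$ the easier direction.

## Minimum-action paths

The Freidlin-Wentzell action
$S = \tfrac12 \int_0^T \lVert \dot x - f(x) \rVert^2 \, dt$
is discretized on $L$ nodes (default 20) with segment finite differences
and midpoint quadrature, and minimized over interior nodes by L-BFGS-B
with the analytic gradient, under the hard bound that abundances stay
non-negative. For each horizon in a geometric $T$ schedule (default 20,
50, 100, 200) the path is re-optimized after arc-length remeshing. Because
a coarse time grid can under-resolve the action at large $T$ (the
discretized functional then dips below the continuous minimum), every
candidate is re-evaluated on a four-fold refined quadrature and both the
horizon selection and the reported action use the refined value. On the
one-dimensional double well $f = x - x^3$ this recovers the gradient-flow
identity $S = 2\Delta V = 1/2$ within 2% at $L = 40$.

The forward/backward asymmetry $\Delta S_{ij} = S_{i\to j} - S_{j \to i}$
is negative when $i \to j$ is the easier direction, so $\Delta S_{ij}$
and $RBH_{ij}$ carry opposite signs under these conventions (their zero
crossings coincide); the Kramers check below therefore asserts a strong
linear relation for both, not a shared sign.

Between numerically optimized paths, the textbook inequality
"indirect (via a waypoint) action $\ge$ direct action" holds only at
matched resolution: the two-leg route effectively uses twice the nodes.
The package's tests therefore check waypoint additivity on an oracle
system and, on the fixture, the scientific content of the comparison: the
direct and via-intermediate collapse paths nearly coincide (small squared
path distance PD), while the recovery routes differ more.

## Langevin simulation and hysteresis

The Euler-Maruyama stepper (compiled; bit-reproducible under a seed) clips
abundances at zero, the discrete counterpart of the reflecting boundary of
the Fokker-Planck problem. Colored noise uses per-species AR(1) innovation
streams with lag-1 autocorrelation $\rho$ ($+0.5$ red, $-0.5$ blue by
default), variance-normalized to match the white case. Mean first passage
times are measured as the first entry into a ball around the target
attractor, by default of radius 25% of the inter-attractor distance in the
reduced coordinates; censored runs are reported, never averaged in.

Ramps move $\kappa$ linearly in time; every recorded point is labelled
with the nearest frozen-parameter attractor in reduced coordinates, using
a continuation anchored *inside* the multistable window so that every
coexisting branch is represented. A transition is a sustained residence
change (default dwell 50 time units). Collapse thresholds are the
$\kappa$ of the first exit from the high state and the first arrival in
the low state; recovery thresholds mirror them. When the route skips the
intermediate state the two thresholds of that direction coincide, which is
the honest reading of a one-stage transition.

## The early-warning engine

The early-warning signal is the RBH between the low and intermediate
states, tracked over a $\kappa$ grid with a shared projection. On each
prefix of the sequence an ordinary least-squares linear trend is removed
and the BDS statistic of the residuals is computed; the first grid point
whose p-value clears a significance level is the warning.

The BDS statistic is implemented from the correlation integrals with the
standard asymptotic variance; it reproduces the reference implementation
in statsmodels digit-for-digit. Two settings differ deliberately from
common textbook defaults, both for calibration: the proximity radius
defaults to $1.0\,\mathrm{SD}$ of the residuals (at $0.5\,\mathrm{SD}$ the
indicator matrix is so sparse that the asymptotic approximation rejects
i.i.d. Gaussian series at 9-15% instead of 5%), and the p-values over the
embedding dimensions $m \in \{2, 3\}$ are combined with a Bonferroni
factor rather than a raw minimum (the raw minimum roughly doubles the
size). With both choices the empirical size at nominal 5% is about 4-6%
and the power on the chaotic logistic map is 1.

Trajectory comparators (AR(1), variance, CV, Fano factor) are computed
per species on Gaussian-filtered Langevin trajectories (bandwidth 10% of
the series length) over rolling windows; their warning is the smallest
$\kappa$ from which the metric keeps rising to the tipping point, with a
small slack for stochastic wiggle and the requirement of a net rise (so a
flat or declining metric never warns). The comparison table takes the
median warning across species per metric, as a field practitioner
monitoring many species would.

## The synthetic fixture

The package ships a seeded generator rather than data files. The fixture
network reproduces the construction used throughout: a random 17 x 61
bipartite web (connectance 0.12, lognormal degree heterogeneity 1.2,
generator seed 31) reduced by random removal of 80% of pollinators
(removal seed 5031) to 17 plants and 13 pollinators. At $\kappa = 1.05$
it is verified tristable; by continuation the high and low states coexist
on about $[1.00, 1.035]$, all three states on about $[1.04, 1.085]$, and
only the low state above 1.09. Its intermediate state keeps exactly one
pollinator alive, the degree-8 generalist, matching the ecological
picture of a generalist-sustained transition state.

What the fixture does not emulate: empirical webs are more nested than
the lognormal-propensity generator produces; the fixture's intermediate
state folds together with the high state rather than outliving it, so the
intermediate-low bistable window that real networks can show between the
two collapse thresholds is absent here (two-stage collapse still occurs,
via noise-induced hops inside the tristable window); and interaction
weights are binarized. Passing tests on the fixture therefore validate
the machinery and the qualitative phenomena, not any quantitative claim
about a particular empirical web.

## Problem sizes and numerical settings

The shipped tests and the acceptance script use deliberately modest
problem sizes chosen for a laptop-class single core: 10 random systems
for the Lyapunov check; a 6-point $\kappa$ sweep with 24 first-passage
replicates per point for the Kramers property; 1000 replicates of length
500 for the BDS size; 1000 random parameter draws for the 2-D scan; 20
ramp replicates per direction for hysteresis; 5 seeds per noise color;
and a 30-point RBH grid for the warning comparison. Tolerances: fixed
points to $10^{-11}$ residual, accepted attractors to $10^{-8}$, Lyapunov
residuals to $10^{-8}$, merge radius $10^{-3}$, extinction threshold
$10^{-3}$.

## Known limitations

* Basin weights from multi-start sampling are binomially noisy; RBH
  sequences inherit step artifacts at small start counts (60 starts per
  grid point are used in the shipped analyses).
* The saddle search operates on the reduced two-dimensional landscape,
  as barrier heights are defined there; it is not an N-dimensional
  saddle search.
* The action optimizer is local; multi-modal path spaces (direct vs
  via-intermediate channels) are explored through explicit waypoints, a
  perturbed restart, and refined-quadrature selection, not a global
  search.
* Limit cycles are not continued; non-convergent trajectories are
  counted and excluded from basin weights with a warning count.
* The probability flux decomposition of non-equilibrium steady states is
  out of scope.
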