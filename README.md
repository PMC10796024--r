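# ecoscape

Energy landscapes, minimum-action transition paths and early-warning
signals for bipartite plant-pollinator networks.

Mutualistic communities under environmental pressure do not fail
gracefully: as the pollinator decay rate rises, the community can hold
several alternative stable states at once — a **high** state with most
species abundant, a **low** state with every pollinator extinct, and,
in between, **intermediate** states in which a handful of generalist
pollinators keep a reduced community alive. Collapse and recovery then
become stochastic barrier-crossing events with hysteresis, and the
practical question is how to see the collapse coming. ecoscape is for
theoretical ecologists and modellers who want to analyse these dynamics
quantitatively on real or synthetic interaction webs.

## The model and the quantities it computes

Species follow generalized Lotka-Volterra dynamics with saturating
(Holling type II) mutualism: for plant $i$ and pollinator $j$,

$$
\dot P_i = \alpha P_i - \beta_{ii} P_i^2 - \sum_{k\ne i}\beta_{ik}P_iP_k
 + \frac{P_i\sum_l \gamma^{(A)}_{il}A_l}{1 + h\sum_l\gamma^{(A)}_{il}A_l} + \mu,
\qquad
\dot A_j = \cdots - \kappa A_j + \cdots
$$

with per-link strengths $\gamma_{il} = \gamma_0\,\varepsilon_{il} /
g_i^{\delta}$ divided by the receiving species' degree. On top of the
deterministic analysis (attractors, basin weights, multistability
censuses under random pollinator removal, phase diagrams), the package
quantifies:

* the **quasi-potential landscape** $U = -\ln p_{ss}$ from a
  truncated-moment (Gaussian-mixture) closure of the Fokker-Planck
  equation, projected onto interpretable plant-PC1/pollinator-PC1
  coordinates, with saddle points and **barrier heights** (BH) and
  **relative barrier heights** (RBH) between basins;
* **Freidlin-Wentzell minimum-action paths** between attractors under a
  non-negativity constraint, direct or through the intermediate state,
  with the action asymmetry $\Delta S$ and the path distance PD;
* **Langevin simulations** (white, red and blue noise), mean first
  passage times, ramped-$\kappa$ collapse/recovery experiments and
  hysteresis thresholds;
* the **barrier height as an early-warning signal**: a BDS
  nonlinearity test on the detrended RBH sequence, compared against
  AR(1), variance, CV and Fano-factor warnings from filtered
  trajectories;
* a closed-form analysis of the two-dimensional mean-field reduction,
  which provably supports at most two stable states — the formal reason
  a multidimensional model is needed to see intermediate states;
* a one-at-a-time global sensitivity analysis of transition actions,
  including perturbations restricted to the one pollinator that
  survives in the intermediate state.

## Worked example

The package ships a seeded synthetic fixture: a 17 x 61 random web
reduced by an 80% random pollinator removal to 17 plants and 13
pollinators, tristable at $\kappa = 1.05$.

```r
library(ecoscape)

fx  <- fixture_tristable()
att <- find_attractors(fx$net, fx$params, n_starts = 100, seed = 1,
                       x_hi = fx$x_hi)
att
#> attractor_set: 3 stable state(s), scenario HIL
#>   [1] low          phi=0.141  alive pollinators=0   total=4.397
#>   [2] intermediate phi=0.333  alive pollinators=1   total=9.239
#>   [3] high         phi=0.525  alive pollinators=10  total=20.290
#>   (1 non-convergent start(s) excluded)
```

Three stable states coexist: a low state (all 13 pollinators below the
extinction threshold $10^{-3}$), an intermediate state in which only the
most generalist pollinator survives, and a high state; `phi` are the
basin weights from the multi-start sample. The landscape and its
barriers:

```r
mix  <- tme_landscape(att, d = 0.005)
proj <- reduce_bipartite(mix, fx$net)
red  <- reduced_landscape(mix, proj)
barrier_report(red)
#>              i            j   U_saddle      BH_i       BH_j    RBH_ij merged
#> 1          low intermediate  0.7316117  0.287938  0.7807168 0.4927788  FALSE
#> 2          low         high 11.1841628 10.740489 12.8424098 2.1019207  FALSE
#> 3 intermediate         high 11.1841628 11.233268 12.8424098 1.6091419  FALSE
```

`BH_i` is the potential rise from basin `i` to the saddle separating it
from basin `j`; `RBH_ij = BH_j - BH_i > 0` says basin `j` is the deeper
one. Here the low-intermediate barrier is tiny compared to the barriers
guarding the high state: the intermediate state lives close to the edge
of collapse, while the high state is strongly protected at these
parameters. From here, `transition_path()` and `indirect_path()` give
the most probable collapse and recovery routes, `mfpt()` their expected
waiting times, `ramp_simulation()`/`hysteresis_experiment()` the
collapse and recovery thresholds under a slowly worsening environment,
and `rbh_sequence()` + `bds_warning()` + `compare_ews()` the
early-warning comparison.

A thin command-line wrapper over the same functions is included at
`inst/cli/ecoscape.R` (subcommands `fixture`, `attractors`, `census`,
`phase`, `landscape`, `paths`, `mfpt`, `ramp`, `ews`, `reduced2d`,
`sensitivity`).

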