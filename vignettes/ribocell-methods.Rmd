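---
title: "The Ribocell model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Ribocell model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The Ribocell is a hypothetical RNA-based minimal cell: a fatty-acid
(oleic-type) vesicle whose genome consists of two ribozymes and their
complementary strands. The polymerase ribozyme $R_P$ replicates RNA by
template-directed, processive addition of activated nucleotides; the lipase
ribozyme $R_L$ converts an external precursor $P$ into membrane lipid $L$.
The cell is viable only if genome replication and membrane reproduction
stay synchronised.

The state of one vesicle is the vector
$x^T = (n_1^C, \ldots, n_N^C, n_L^\mu, V_C)$: the molecule counts of every
aqueous species in the core, the membrane lipid count, and the core water
volume. The internal chemistry is

1. reversible hybridisation $S + cS \rightleftharpoons S{\cdot}cS$ for both
   gene pairs (rates $k_{SS}$, $k_S$) — dimers and complexes are
   catalytically inactive, so the (strongly dimer-shifted) equilibrium
   controls how much catalyst is ever free;
2. transcription: a free $R_P$ binds any free monomeric template $S \in
   \{R_P, cR_P, R_L, cR_L\}$ (rate $k_{R@S}$), then adds one nucleotide at
   a time ($k_{NTP}$ per step, one by-product molecule $W$ per addition)
   through $L$ elongation intermediates $R_P@S_j$, and finally releases
   itself and the product duplex $S{\cdot}cS$ ($k_{R@SS}$). Since the
   catalyst may bind a template of its own species, that initiation channel
   is homo-bimolecular (propensity $\propto n(n-1)$);
3. lipid synthesis $P \to L_{aq}$ catalysed by free $R_L$ ($k_L$), with the
   aqueous lipid absorbed into the bilayer.

The membrane surface is $S_\mu = \alpha_L n_L^\mu / 2$ (bilayer of head
area $\alpha_L$). Vesicle shape is summarised by the *reduced surface*
$\phi = S_\mu / (36\pi V_C^2)^{1/3}$ — the ratio of the actual membrane
area to the area of the sphere wrapping the current volume. The stability
window is $(1-\varepsilon) \le \phi \le 2^{1/3}(1+\eta)$: below it the
osmotically stretched membrane ruptures (burst); at $\phi = 2^{1/3}$ the
deflated vesicle can split into two equal spherical daughters. Ties are
resolved so that exactly $2^{1/3}(1+\eta)$ divides and exactly
$1-\varepsilon$ is still stable.

The environment is a continuously stirred reservoir (CSTR): external
concentrations of precursor, the four nucleotide pools, an inert osmotic
buffer and aqueous lipid are constant; the by-product $W$ is absent
outside. Permeation of $P$ and NTPs follows $P_n S_\mu (C_n^E - C_n^C)$,
split in the stochastic engine into one influx and one efflux channel. $W$,
the buffer and all RNA are impermeable. Because $W$ is trapped, every
polymerisation step raises the internal osmolarity, pulls in water and
grows $V_C$: volume growth is coupled to metabolism only through this
*osmotic synchronisation*, and membrane growth only through $R_L$'s lipid
output. The growth control coefficient
$\gamma = (\dot V_C / V_C)/(\dot S_\mu / S_\mu)$ equals 1 exactly when the
two stay in step; sustained $\gamma > 1$ ends in a burst and $\gamma < 1$
in ever-smaller divisions.

### Lipid exchange

The bilayer exchanges lipid with the vesicle core: single-molecule uptake
at $k_{in} S_\mu [L_{aq}]$ and release at $k_{out} n_L^\mu$, which balance
at $[L]_{eq} = 2 k_{out} / (\alpha_L k_{in}) \approx 6.7\times10^{-5}$ M.
The external reservoir is assumed saturated at $[L]_{eq}$, so it
contributes to the external osmolarity but drives no net membrane flux. We
deliberately do not give the membrane separate stochastic exchange channels
against the (infinite) reservoir: at saturation such channels balance in
the mean for *every* membrane size, so they add an unbounded critical
random walk to $n_L^\mu$ — inert vesicles would then spuriously divide or
burst within days. Exchanging with the finite internal pool keeps membrane
fluctuations bounded by the pool size (~20 molecules) and makes catalysed
synthesis the only route to net membrane growth, which is the behaviour the
model is meant to study.

## Parameters

| name | default | units | role |
|------|---------|-------|------|
| `k_SS` | 8.8e6 | 1/(M s) | duplex formation, both gene pairs |
| `k_S` | 2.2e-6 | 1/s | duplex dissociation (1/k_S ≈ 5 days: the slow clock of the model) |
| `k_RatS` | 5.32e5 | 1/(M s) | polymerase–template binding |
| `k_RatSS` | 9.9e-3 | 1/s | release of polymerase + product duplex |
| `k_NTP` | 0.113 | 1/(M s) | per-nucleotide addition |
| `k_L` | 1.7e3 | 1/(M s) | precursor → lipid catalysis |
| `k_in`, `k_out` | 7.6e19, 7.6e-2 | see `?kinetic_parameters` | lipid uptake/release |
| `P_P`, `P_NTP` | 4.2e-9, 1.9e-11 | cm/s | membrane permeabilities |
| `P_W`, `P_S` | 0 | cm/s | waste and RNA are trapped |
| `P_aq` | 1.0e-3 | cm/s | water permeability |
| `alpha_L` | 0.3 | nm² | lipid head area |
| `epsilon` | 0.21 | — | osmotic tolerance (oleic acid) |
| `eta` | 0 | — | dividing tolerance |
| `v_aq` | 0.018 | L/mol | molar volume of water |

All quantities are converted once, at network compilation, into a
dm/litre/second system (1 cm/s = 0.1 dm/s, 1 nm² = 1e-16 dm²), in which
$P_n S_\mu N_A C$ is directly events/s.

External defaults are the optimal growth conditions
$[N_{ex}] = [P_{ex}] = 10^{-2}$ M and $[I_{ex}] = 0.3$ M. The four
nucleotide pools are kinetically identical and each is held at $[N_{ex}]$;
which pool an elongation step consumes is fixed by the template's random
base sequence, drawn once when the network is built (only the base
composition can matter). Both ribozymes default to 100 nt; 20 nt is the
floor below which a folded, catalytically competent structure is not
plausible.

## Deterministic engine

`run_lineage()` integrates counts (not concentrations) plus the explicit
water-flux volume equation
$\dot V_C = v_{aq} P_{aq} S_\mu (C_T^C - C_T^E)$, so that halving at
division is exact. The system is stiff — lipid-pool relaxation is on the
millisecond scale while division times are tens of days — and is handled
by `deSolve::lsodar` with root functions on $\phi - 2^{1/3}(1+\eta)$ and
$\phi - (1-\varepsilon)$; the root ends the generation as a division or a
burst, and a configurable time cap (default 500 days) flags stalled
vesicles as `timeout`. At division the contents are halved and one daughter
is followed.

Numerical choices that matter:

* tolerances default to `rtol = 1e-6`, `atol = 1e-2` molecules (volume
  `1e-26` L). Division times and compositions agree to 5 significant
  digits with rtol = 1e-7..1e-8 where those run; the tighter settings were
  rejected because they intermittently exhaust the solver's step budget on
  the millisecond lipid relaxation after a division restart.
* *support masking*: species that are unreachable from the initial support
  through the channel hypergraph (e.g. the whole lipase sector of a vesicle
  that has no lipase gene) are pinned to zero for the generation.
  Without this, solver-level noise (at the `atol` scale) seeds the empty
  gene sector and the replication autocatalysis amplifies it to
  macroscopic strand counts within ~100 simulated days. A reactant floor of
  1e-9 molecules in the rate laws backstops the same issue inside the
  reachable sector.
* a homo-bimolecular initiation uses mass action $k [R_P]^2$
  deterministically and ordered-pair counting $n(n-1)$ stochastically;
  these agree to $O(1/n)$.

Starting from an isotonic sphere (the inert buffer $B$ is set so
$C_T^C = C_T^E$ exactly, giving $\phi = 1$ to machine precision), the
lineage first swells — substrates equilibrate inward faster than the
membrane can grow, $\gamma > 1$, $\phi$ dips to ≈ 0.90 — then the division
regime establishes itself. With the default study conditions
($N_0 = 100$ dimers of each gene, $r_0 = 50$ nm) the division time
plateaus by generation ~15 at 68.3 days, independent (to < 1%) of
$N_0 \in \{1, 10, 100\}$ and of $r_0$ over 50–500 nm; the cycle-averaged
$\gamma$ is 1 to within 2%. Division times this long trace directly to the
dimer-shifted hybridisation equilibrium: free catalyst concentrations are
$\sim \sqrt{(k_S/k_{SS}) [S{\cdot}cS]}$, a few times $10^{-9}$ M.

The stationary genome composition depends on the external conditions
through one mechanism: the fraction of strands locked in elongation
complexes is the elongation time divided by the cycle time. Under
nucleotide-limited conditions ($[N_{ex}] = [P_{ex}] = 5\times10^{-4}$ M)
elongation takes tens of days, complexes hold a quarter of all polymerase
strands, and the stationary census settles at ≈ 33/33/24/10 percent for
$R_L/cR_L/R_P/cR_P$ (the two lipase fractions equal by symmetry; $cR_P$
lowest because a free $R_P$ is usually consumed as catalyst before it can
serve as template). At the optimal conditions elongation is fast, the
sequestration weakens, and the census is nearly symmetric with the same
ordering. `scan_stationary()` drives grids over external concentrations,
ribozyme lengths and the dimerisation constants; the generation-25 life
time under a 100-fold weaker $k_{SS}/k_S$ falls to 6.8–12.6 days, with the
residual spread across equal-ratio $(k_{SS}, k_S)$ pairs reflecting
whether $1/k_S$ is short enough for the duplex pool to equilibrate within
one cycle — the ratio alone determines the life time only in that regime.

## Stochastic engine

`simulate_vesicle()`/`run_population()` implement the Gillespie direct
method over the same channel table. Water flux is treated as instantaneous:
after every event $V_C$ is reset through the osmotic identity
$\sum_{aq} n_i = N_A C_T^E V_C$ (held exactly, and checked in the tests).
At division the mother's molecules are partitioned binomially per species
(dimers and complexes travel as units, the membrane and volume split in
half); `run_population()` keeps one daughter per division — chosen at
random by default — so the number of monitored entities stays constant,
and broken vesicles stay in the census as flat bilayers.
`classify_vesicle()` maps each genome census onto the protocell taxonomy
(EMPTY, INERT, SELF_PRODUCING, SELF_REPLICATING_GENOME, REDUCED_RIBOCELL,
RIBOCELL, BROKEN); strands inside dimers and complexes count as recoverable
genome, nascent partial chains do not.

### Hybrid acceleration

Exact SSA is impractical for multi-generation vesicles: the lipid
release/uptake pair alone fires ~$2 k_{out} n_L^\mu \approx 3\times10^4$
events/s against a ~20-molecule aqueous pool. `acceleration = "hybrid"`
(the default) therefore:

* Poisson-leaps the fast channels (permeation, lipid exchange, lipid
  synthesis) with a Cao-type step choice $\Delta t \le \min_i g_i/|\mu_i|$
  (and the variance analogue $g_i^2/\sigma_i^2$), where
  $g_i = \max(\epsilon n_i, \min(g_{min}, 0.1\, n_i + 1))$ with
  $\epsilon = 0.03$, $g_{min} = 10$ molecules. Abundant species change by
  at most the fraction $\epsilon$ per leap; sparse pools may move by up to
  $g_{min}$ molecules but never more than ~10% of the pool, which lets
  slow transport into half-empty pools proceed without throttling
  month-long spans to second-scale steps while keeping near-empty *fast*
  pools — where propensity staleness would bias the dynamics — at
  single-molecule resolution. The leap halves and redraws on any negative
  excursion.
* keeps every RNA channel exact: their firing times are drawn by
  accumulating the slow-set hazard across leaps, so dormancy (all
  ribozymes paired) and the abrupt activity bursts after a dissociation
  event are reproduced event-by-event.
* holds the internal aqueous lipid pool at its quasi-steady value. The
  uptake/release pair is near-critical, and sampling it as two independent
  Poisson counts would replace the bounded, anti-correlated churn with an
  unbounded random walk of the membrane count. Instead the pair is not
  sampled at all and each synthesis event's product is routed directly to
  the membrane — the exact net effect of the quasi-steady state — while
  the pool's (real-valued) occupancy still counts towards the osmotic
  balance.

With `hybrid_threshold = Inf` every channel is handled exactly and the
engine reduces to the direct method; the test suite gates the accelerator
by comparing hybrid and exact means on subsystems where exact simulation
is affordable, and by checking the SSA against the ODE at large copy
numbers.

All stochastic runs are reproducible from a single seed: the engine draws
exclusively from R's RNG, and `run_population()` derives one sub-seed per
replicate run from the master seed.

## What the default studies do and do not show

The shipped study conditions — 20–25 generation lineages; populations of
20–60 vesicles followed for 8–15 generations over 1200–1500 days, averaged
over seeded replicate runs — are desk-scale by design; the engines scale
linearly in events for larger protocols. Within them the model exhibits
the qualitative repertoire the design targets: osmotic synchronisation
with $\gamma \to 1$; death by segregation (empty and broken vesicles
accumulating, genuine ribocells a vanishing minority); reduced ribocells
as a transient class; no inert vesicles (dimers are too stable for lone
complementary strands to end up isolated); dormant phases alternating with
fast growth exactly when a free $R_L$ monomer exists; and polymerase-only
genomes marching deterministically to osmotic burst.

Caveats to keep in mind when reading quantitative outputs:

* The CSTR idealisation means burst debris and exported solutes never feed
  back on the environment; competition between vesicles is out of scope.
* Hybridisation is sequence-free (two rate constants for all duplexes),
  there is no mutation, no folding thermodynamics, no temperature
  dependence, and the membrane has no bending mechanics beyond the
  $(1-\varepsilon, 2^{1/3}(1+\eta))$ window.
* The absolute stationary vesicle size is the least constrained output: it
  balances the lipid-sector fluxes ($k_L [P_{ex}]$, $P_P$) against the
  replication sector, and scales steeply with them, while the stationary
  division time is nearly insensitive to the same fluxes (it is set by the
  hybridisation equilibrium). Conclusions that hinge on absolute size —
  e.g. the division time of a single-lipase self-producing vesicle, which
  is proportional to the membrane lipid count it must synthesise — inherit
  that sensitivity; relative and structural results (composition,
  taxonomy, synchronisation, ratio dependences) do not.
* The osmotic-burst boundary in the $[N_{ex}]$–$[P_{ex}]$ plane sits near
  $[N_{ex}] = 0.05$ M: from a 50 nm isotonic founder the swell transient
  reaches $\phi_{min} \approx 0.80$ at $[P_{ex}] = 10^{-2}$ M (marginally
  stable) and bursts for $[P_{ex}] \lesssim 2\times10^{-3}$ M — another
  consequence of the same lipid-flux sensitivity.
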