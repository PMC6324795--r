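---
title: "Simulating in-vivo-like synaptic regimes in a reduced IS3 interneuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating in-vivo-like synaptic regimes in a reduced IS3 interneuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Hippocampal CA1 interneuron-specific type 3 (IS3) cells are VIP+/CR+
interneurons that inhibit other interneurons. They cannot currently be
recorded intracellularly *in vivo*, so the synaptic input regimes they
experience there — how many excitatory and inhibitory synapses are active,
at what presynaptic rates, and how correlated they are — must be inferred by
simulation. The approach implemented here bombards a reduced
multi-compartment IS3-like model with parameterized excitatory and
inhibitory spike trains, asks which input combinations produce an
*in-vivo-like* (IVL) high-conductance state, characterizes the
excitation-inhibition (E/I) balance of those combinations, and probes
whether theta-timed (8 Hz) inputs can still recruit the cell once it is in
such a state.

`ivlsim` packages the whole pipeline: a deterministic synthetic morphology
and synapse bank, conductance-based membrane dynamics with a compiled
backward-Euler cable solver, the input generators, the IVL classifier, the
four-dimensional input sweep with pool division and clutter-based
dimensional reordering (CBDR) images, somatic voltage-clamp conductance
isolation, and the theta protocols.

## The cell model

### Morphology

The default fixture is a 221-compartment tree: 1 somatic cylinder
(10 x 10 um), a 50-compartment axon initial segment (AIS), and 170
dendritic compartments arranged as 17 unbranched dendrites of 10
compartments (60 um each, 0.5 um diameter). A compartment's
`path_distance` is the cable distance from the soma to its midpoint.
Dendritic compartments below 300 um are *proximal* (stratum radiatum,
Schaffer-collateral territory), the rest *distal* (stratum
lacunosum-moleculare, entorhinal territory).

The geometry was chosen so that the proximal/distal boundary splits the
dendritic compartments exactly 85/85. That symmetry is load-bearing: with 9
excitatory synapse slots per dendritic compartment the bank holds exactly
1530 excitatory slots, 765 per zone, so "equal numbers of proximal and
distal active synapses" is always realizable and the low/high pool boundary
at 765 synapses is exactly half the excitatory capacity. No arrangement of
10 identical unbranched dendrites can produce the 85/85 split (85 is not
divisible by 10), which is why the fixture uses 17 dendrites of 10
compartments; the number of *primary* dendrites of a real IS3 cell is
smaller, and the 17 chains are better thought of as terminal branches
flattened into a star. The tree serializes losslessly to standard SWC
(`write_swc()`/`read_swc()`).

### Channels and kinetics

Four active conductances are distributed per model variant (densities in
mS/cm^2):

| variant | G_Na,t | G_Na,p | G_Ka | G_Kdrf | layout |
|---|---|---|---|---|---|
| AType+ | 70 | 0.075 | 70 | 250 | uniform over soma and first 70 um of dendrite; persistent Na somatic only |
| AType- | 55 | 0.15 | 30 | 295 | as above, but A-type K somatic only |

The AIS is passive by default (`ais_active = FALSE` in
`assign_channels()`).

The gating kinetics are the package's own: the original reconstructed-cell
channel models are not part of this artifact, so `src/kinetics.h` implements
literature-typical fast-spiking interneuron gating (steep Golomb-style
sigmoids) and is the single place to swap them. The qualitative targets that
guided the voltage shifts were: a stable rest near the leak reversal
(-70 mV) despite the very small calibrated leak of a ~400 MOhm cell; a small
rheobase with sustained high-rate repetitive firing; and depolarization
block (DB) with shrinking spikes under strong sustained drive. Two features
deserve comment:

* The fast delayed rectifier is Kv3-like (half-activation -12.4 mV): it
  engages only during the spike. With a lower-threshold rectifier the huge
  printed density (250-295 mS/cm^2) smothers spike initiation in a cell
  whose leak is three orders of magnitude smaller.
* Transient Na carries a slow inactivation gate (tau = 600 ms) in addition
  to fast inactivation. It integrates the time spent depolarized (including
  the spikes themselves) over hundreds of milliseconds and is what turns
  sustained strong excitation into depolarization block with progressively
  shrinking spikes, while leaving sparse irregular firing untouched.

Quantitatively the model is anchored not by the kinetics but by two
calibrations (below); the kinetics only need to place the cell in the right
dynamical regime.

### Calibration

Two scalar knobs close the loop on the printed anchors:

* `calibrate_passive()` bisects the uniform leak density until the somatic
  input resistance measured by the standard protocol (-100 pA step over
  4.5-5.5 s of a 10 s noise-free run, baseline windows 0-4.5 and 5.5-10 s,
  hyperpolarized window 4.7-5.5 s to skip 200 ms of settling) equals
  388.71 MOhm (AType+) or 406.57 MOhm (AType-) within 0.05 MOhm.
* `calibrate_noise()` scales the somatic Gaussian current noise (white,
  amplitude scaled by 1/sqrt(dt) so its statistics are step-size invariant)
  until the subthreshold sigma of the membrane potential over the last 9 s
  of a no-synapse run, averaged over 5 noise seeds, equals 0.22 mV within
  0.005 mV. Because the subthreshold response is essentially linear in the
  noise amplitude, a scaled secant iteration converges in 2-3 steps.

```{r}
library(ivlsim)
model <- build_model("AType+") |>
  calibrate_passive() |>
  calibrate_noise()
glance(model)
```

### Integration

The branched cable equation is integrated by backward Euler with an exact
Hines-ordered tridiagonal solve per step (unconditionally stable for the
passive subsystem), gates by exponential relaxation toward their
voltage-dependent steady states using tabulated rates, and synapses as
event-driven double-exponential states. Default dt is 0.025 ms with
recordings at 0.1 ms. Synapses sharing a compartment and kinetics class
share one state (their dynamics are identical and conductances add), which
keeps the cost of fully bombarded scenarios flat. Spike-time events snap to
the nearest solver step. Identical seeds and configurations give
bit-identical traces; the noise generator is a self-contained xorshift64*
with Box-Muller normals, so reproducibility does not depend on R's RNG
internals.

## Synapses and inputs

Synaptic conductances follow the two-state kinetic scheme
`g(t) = weight * factor * (exp(-t/tau_d) - exp(-t/tau_r))` with the peak
normalized to `weight`. Weights grow linearly with path distance
(excitatory `0.00230814 d + 0.22016666` nS, inhibitory
`0.00469125 d + 0.2695779` nS); time constants are fixed per class
(proximal excitatory rise/decay 2.9936e-4/2.4216 ms, distal excitatory
6.1871e-4/3.1975 ms, inhibitory 0.1013/4.8216 ms everywhere); reversals are
0 mV (excitatory) and -70 mV (inhibitory). A synapse sits at its
compartment's midpoint and uses the compartment's path distance: at 60 um
resolution, sub-compartment placement is below model resolution.

The full bank holds 9 excitatory slots per dendritic compartment (1530
total) and 344 inhibitory slots spread as evenly as possible (2 per
compartment plus a third on the first four). The source description of the
per-compartment inhibitory density is internally inconsistent (2 vs 4 per
compartment); the package honors the exact totals (1530/344), which drive
every downstream range and divisibility property, and distributes the
inhibitory remainder deterministically.

Background input scenarios are defined by four parameters: excitatory rate
`f_exc` (0-30 Hz), inhibitory rate `f_inh` (0-100 Hz), active excitatory
count `n_exc` (18-1530, split equally between zones), and active inhibitory
count `n_inh` (4-344). Trains contain exactly `round(rate * duration)`
spike times drawn uniformly over the window and sorted; the resulting
inter-spike intervals are near-exponential (Poisson-like), which the test
suite checks with a Kolmogorov-Smirnov test. Common-input grouping
partitions each class's actives into groups of `k` (plus a remainder group)
that share one train; `k = 1` is fully independent input. Every stochastic
ingredient (placement, spike times, noise) draws from its own named seed
stream (`scenario_seeds()`), so any one can be re-randomized while the
others are held fixed — the noise-off controls and the representative
re-seeding procedure depend on this.

The theta protocol adds deterministic 8 Hz population trains at
quarter-cycle offsets: CA3 (27 proximal excitatory synapses) at 0 degrees,
its driven inhibitory populations (bistratified, IS1, IS2; 8 synapses each,
proximal) at 90 degrees, EC3 (27 distal excitatory synapses) at 180
degrees, and its driven inhibitory populations (neurogliaform, OLM; 8 each,
distal) at 270 degrees. One spike per population per 125 ms cycle, no
jitter: the underlying description fixes the quarter-cycle phases and the
driver relationships but not a jitter model, so the minimal deterministic
choice is used. Theta synapses are chosen deterministically, round-robin across the zone's
compartments (first slot of each compartment in id order, then second
slots, and so on), so the protocol adds no randomness of its own while
spreading each population over the arbor — concentrating a population on
one thin dendrite would locally saturate the driving force and mute the
very recruitment the protocol probes. Which inhibitory population is
CA3- versus EC3-driven is assigned by layer (proximal populations with the
proximal driver), a convention the phase structure fixes only up to that
split.

## Trace metrics and the IVL classifier

All features are computed over the last 9 s of a 10 s simulation. Spikes
are detected as upward crossings of -20 mV; a spike's begin is the start of
the last contiguous run of dV/dt >= 20 mV/ms before its peak, its end the
first return of the voltage to the begin level, and its amplitude the peak
minus the begin voltage (threshold-relative, which is what makes the 40 mV
depolarization-block cutoff meaningful for shrinking spikes). Spike samples
are cut before subthreshold statistics. The inter-spike-interval
coefficient of variation is defined as 0 with fewer than 3 spikes, and a
spikeless trace is by convention *not* in depolarization block.

The IVL metric is the conditional sum
`(mean Vm > -66.7 mV) + (sigma_Vm > 2.2 mV) + (ISICV > 0.8) -
4 * (mean spike amplitude < 40 mV)`: 3 is in-vivo-like, 0 non-in-vivo-like,
negative values are nearing depolarization block.

Spike-train spectra use Welch's method on the 1 ms-binned instantaneous
rate (spikes/s): mean-detrended, periodic-Hann-windowed segments of 2000
samples with 50% overlap. The 2000-sample segment (16 theta cycles) puts
8 Hz exactly on a frequency bin; with power-of-two segments the 8 Hz line
falls between bins and leaks asymmetrically, which can make the 16 Hz
harmonic of a perfectly periodic train appear larger than the fundamental.

## The sweep, pools, and representatives

`enumerate_grid()` reproduces the full production grid — 7 x 11 x 85 x 86
core combinations, times 2 variants and 4 common-input modes, 4,502,960
ten-second scenarios — but executing it is cluster work; desk-scale
analyses run the same machinery on coarsened grids. Scenarios are ordered
excitatory rate first, then inhibitory rate, excitatory count, inhibitory
count (the representative-search order), and each carries a seed derived
deterministically from its coordinates, so any chunk can be re-run
independently and reproduces identical records.

Pools split each parameter at its low/high boundary (rates 0-15/20-30 and
0-50/60-100 Hz; counts 18-765/783-1530 and 4-172/176-344) into 16 pools
labelled in the order (inhibitory count, excitatory count, inhibitory rate,
excitatory rate). A pool's representative is the first of its IVL
scenarios, in canonical order, that stays IVL on 10 consecutive re-seeded
repeats (fresh placement and spike-time seeds each repeat).

Two E/I balance metrics accompany every record: the normalized metric
`0.5 (n_exc/1530 + f_exc/30 - n_inh/344 - f_inh/100)` in [-1, 1], and the
cumulative-rate difference `f_exc n_exc - f_inh n_inh`.

CBDR images nest the 4-D grid into 2-D — rows stack excitatory rate (outer)
over excitatory count (inner), columns inhibitory rate over inhibitory
count — with an exact pixel-to-parameter mapping and a JSON sidecar.

## Conductance isolation and theta analyses

`isolate_conductance()` replicates the stated protocol literally: all
active conductances removed, the leak reversal set to the holding potential
in every compartment (so leak current vanishes at the clamp, rather than
being subtracted post hoc), and an ideal zero-series-resistance somatic
clamp at -70 mV (recording excitatory currents) or 0 mV (inhibitory).
Method 1 removes the opposite input class entirely; Method 2 leaves both
classes active, which is what an experimenter can do, and exposes the
space-clamp artifact: dendritic inhibition depresses the apparent
excitatory conductance toward zero. On a single compartment the two methods
agree exactly and recover the analytic kernel, which the tests use as the
oracle.

The element-wise E/I conductance ratio averages `g_exc(t)/g_inh(t)` over
samples where `g_inh` exceeds a 1e-3 nS floor (the ratio is undefined at
zeros; the excluded fraction is reported alongside). Theta-cycle averaging
splits the 9 s window into its 72 consecutive 125 ms cycles.
`estimate_theta_inputs()` implements the minimal-count search for
theta-recruiting synapse numbers (excitatory: PSD at 8 Hz above
50 spikes^2/Hz and more than 10 spikes; inhibitory, against a holding
current calibrated to sustain at least 35 Hz firing: PSD above
80 spikes^2/Hz and fewer than 240 spikes). With the package's stand-in
kinetics the resulting counts and holding currents are reference
quantities, not reproductions of the original cell's values.

## What the synthetic generator does and does not emulate

The generator reproduces the *statistical structure* of the study's inputs:
exact spike counts at the requested rates, sorted-uniform (Poisson-like)
irregularity, unique random placement with the equal zone split, shared
trains within common-input groups, and deterministic quarter-cycle theta
timing. It does not emulate rate nonstationarity, oscillatory background
modulation, short-term plasticity, synaptic failures, or NMDA-type
voltage-dependent currents — all outside scope. Passing tests therefore
demonstrate that the pipeline reproduces the study's logic and its
desk-scale anchors under these idealized inputs, not that the specific
biological IS3 cell behaves identically.

## Problem sizes and numerical choices

The package's own test and acceptance runs use desk-scale sizes chosen to
exercise every code path at full fidelity: the reduced sweep covers a
3 x 3 x 3 x 3 grid (rates 5/15/25 and 10/50/90 Hz, counts 144/720/1368 and
40/172/304) over both variants and the (9,4) and (1,1) common modes with
4 s simulations; representative searches and theta-response comparisons run
at 5-10 s. The full production grid is enumerated, never executed, in the
tests. Other defaults: dt 0.025 ms, recordings at 0.1 ms, 10 s scenario
duration with the last 9 s analyzed; calibration tolerances 0.05 MOhm and
0.005 mV; the clamp ratio floor 1e-3 nS; seeds below 2^31 everywhere.

Degenerate inputs are handled explicitly: zero-rate trains are empty;
`n mod k` leaves a remainder common-input group; a group size above the
active count collapses to a single group; a morphology without dendrites is
rejected by the bank builder; non-finite solver states abort with the time
and compartment.

## Known limitations

* The channel kinetics are stand-ins calibrated to qualitative dynamics
  plus the two printed anchors; quantities that depend on the original
  cell's exact kinetics (theta synapse-count estimates, E/I conductance
  ratios of specific representative scenarios, absolute pool counts) are
  tracked as orderings, not values.
* The fixture morphology is a star of identical unbranched dendrites; it
  reproduces the counts and zone structure of the reconstructed cell, not
  its electrotonic detail.
* Pool statistics at desk scale use dozens of scenarios per pool, not tens
  of thousands; only orderings robust at that scale are asserted.
* The sweep runs serially; records are deterministic per scenario seed, so
  chunked or parallel execution is a wrapper concern, not a correctness
  one.
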