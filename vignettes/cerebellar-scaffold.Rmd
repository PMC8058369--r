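---
title: "The cerebscaffold model: assumptions, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cerebscaffold model: assumptions, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what the model is, which constants come from the published circuit
description, which were calibrated by us and how, and where the numerical
scheme makes choices a user should know about.

## The circuit

The package reconstructs a cerebellar cortical column following the
scaffolding approach: cell placement, structural connectivity, and the
dynamical simulation are three independent stages with plain-text
interchange formats between them, so any stage can be replaced. The
reference column is 400 × 400 × 900 µm³ — x is the transversal direction
parallel fibers run along, y sagittal, z vertical — and contains 7,070
mossy-fiber (MF) terminals, 88,158 granule cells (GrC), 219 Golgi cells
(GoC), 69 Purkinje cells (PC), 603 stellate (SC) and 603 basket cells (BC),
12 deep-cerebellar-nuclei cells (DCN), and one inferior-olive (IO) cell.
Counts scale linearly with footprint area, so wider columns (e.g.
800 × 800 µm) are generated by the same code path.

All neurons are conductance-based leaky integrate-and-fire units,

$$C_m \frac{du_i}{dt} = -g_L (u_i - E_L) + I_e + I_{syn}(u_i, t),$$

firing when $u_i \ge V_{th}$, resetting to $V_r$, and remaining clamped
there for the refractory period. Synapses are exponential-decay
conductances: a presynaptic spike arriving through a connection of weight
$w_{ij}$ after delay $d_{ij}$ makes the target's excitatory or inhibitory
conductance jump by $w_{ij}$ nS, and each conductance decays with its
type-specific time constant. Per-type constants are in `lif_params()`.
Units are mutually consistent as pF, nS, mV, pA, ms (nS·mV = pA and
pA·ms/pF = mV). The leak conductance column is read in nS, the only
interpretation under which $C_m / g_L$ is a membrane time constant in ms.
MFs and the IO are not integrated: they are inhomogeneous Poisson spike
sources on the 1 ms grid.

Reversal potentials are not part of the per-type table; we use the standard
AMPA/GABA-A values $E_{exc} = 0$ mV, $E_{inh} = -80$ mV
(`reversal_potentials()`, configurable — results do depend on them).

## Placement

Cells are placed uniformly at random inside their layer's slab (deep-nuclei
region below the cortex, granular layer, Purkinje monolayer, molecular
layer; boundaries configurable in `volume_spec()`). Purkinje somata sit on
a jittered near-square grid at the monolayer midplane (±5 µm in z), which
guarantees a monolayer without modelling packing. MF "positions" are
glomerular terminal positions in the granular layer; the IO cell has no
position (it is a pure spike source). Uniform placement is a deliberate
simplification: all downstream statistics used here depend on layer
densities, not on sphere-packing detail. The default layer boundaries
(deep nuclei [0, 600), granular [600, 750), PC layer [750, 760), molecular
[760, 900) µm) approximate murine laminar proportions within the 900 µm
column.

## Connectivity and its calibration

Sixteen projections connect the populations (`connection_rules()`), each
stored as a CSR matrix over postsynaptic cells with one scalar weight (nS)
and delay (an integer number of milliseconds, ≥ the 1 ms exchange
interval). Weights and delays are the published values for every
projection. The convergence geometry is not published, and is therefore
the package's calibration layer:

* **Parallel fibers** run the full transversal extent: a GrC contacts a PC
  iff $|y_{GrC} - y_{PC}| \le h$. The one quantitative anchor is the
  printed mean PF→PC convergence of 29,196 synapses per PC. For uniformly
  placed cells the expected band coverage including edge truncation is
  $(2h - h^2/L)/L$ with $L = 400$ µm; solving
  $(2h - h^2/L)/L \cdot 88{,}158 = 29{,}196$ gives $h = 72.9$ µm, which we
  ship as the default (a no-edge-correction estimate, $h \approx 66$ µm,
  under-produces the anchor by ~8%). The realized mean is within about 2%
  of the anchor across seeds.
* **Fixed in-degrees** realize the remaining projections (each target draws
  k partners within a radius, a sagittal band, or a vertical cylinder for
  ascending axons). Defaults: MF→GrC 4 (within 60 µm), MF→GoC 35,
  GoC→GrC 4, GoC→GoC 10, AA→GoC 20, PF→GoC 400, SC↔SC and BC↔BC 4,
  PF→SC/BC 300, SC→PC and BC→PC 22, AA→PC 3, PC→DCN all 69, MF→DCN 4,500.
  The orders of magnitude follow standard cerebellar anatomy; the exact
  values were tuned, once, so that the two built-in experiments land on
  their published operating points (next sections). Two cases deserve
  comment: taking *every* GrC inside the 30 µm ascending-axon cylinder
  (~1,500 cells) at the published 75 nS (AA→PC) or 20 nS (AA→GoC) weight
  would saturate the targets, so the cylinder rule draws a small fixed
  in-degree instead; and a small MF→DCN convergence cannot reach the
  ~105 Hz nuclear rates of the OKR experiment at the published 0.006 nS
  weight, so DCN cells sample broadly from the MF population.

`build_connectivity()` is deterministic per seed, enforces at most one
synapse per (pre, post) pair per rule, and errors when a fixed in-degree
exceeds the available presynaptic pool (miniature fixtures instead truncate
with a warning).

## Numerics

* Forward Euler with $\Delta t = 0.1$ ms for both the membrane equation and
  the conductance decay (one method throughout); spike exchange,
  synaptic-delay bookkeeping, Poisson sources, and plasticity run on a 1 ms
  grid. Within an exchange step the order is: draw source spikes → deliver
  matured delayed batches → ten Euler substeps with threshold detection →
  enqueue new spikes → plasticity update → record. The ordering matters at
  1 ms granularity and is fixed.
* Spikes are detected with $u \ge V_{th}$ (boundary fires), time-stamped at
  0.1 ms resolution, but delivered on the 1 ms grid: a spike in substeps
  $[k, k+10)$ ms is exchanged as if fired at ms $k$.
* Refractory units are clamped at $V_r$; their synaptic conductances keep
  evolving; integration resumes when the timer (an integer number of
  substeps) expires. No unit can fire twice within its refractory period.
* Initialization: $u(0) = E_L$ per type, zero conductances, no
  refractoriness. Protocols that need a steady state include their own
  background period.
* Randomness is counter-based: every (seed, stream, step) triple maps to an
  independent substream, so regenerating any step gives identical draws
  regardless of evaluation order, and whole runs are bit-reproducible for a
  fixed master seed. Placement and connectivity consume seeds separately
  from the source streams.
* Divergence (a non-finite membrane potential) halts with the neuron index
  and time.
* Spike records are flushed to disk every 50 ms when a file sink is given;
  analyses are invariant to the flush interval.

The hot loops — the Euler substeps over all neurons, CSR scatter of spikes
onto conductances, and the per-synapse weight update — are implemented in
C++ (Rcpp). Pure-R implementations of the same per-operation contracts
ship alongside and the test suite checks the two paths against each other
on miniature circuits.

## Plasticity

Every PF→PC synapse carries a dimensionless factor $w$ (delivered
conductance = $w \times 0.02$ nS), updated once per millisecond:

$$w \leftarrow w + \lambda_{LTP} (w_{init} - w) \cdot L_j
      - \lambda_{LTD} \, w \, CF(t) \sum_{\Delta t = 0}^{50} PF_j(t - \Delta t)$$

with $\lambda_{LTP} = 0.001$/ms, $\lambda_{LTD} = 0.01$, $w_{init} = 1$, a
51-bin eligibility window (spikes 0–50 ms before the CF spike count, one
count per 1-ms bin), and a clamp at zero as a numerical guard. The CF
signal is the IO cell's spike train, shared by all PCs; CF spikes inject no
synaptic current (their only effect is plasticity), and the ascending-axon
pathway is not plastic.

The gating factor $L_j$ is the one place the package implements two
variants. With $L_j \equiv 1$ (the default of `plasticity_params()`), LTP
relaxes every weight toward $w_{init}$ every millisecond — the literal
per-ms recursion, whose LTP-only closed form
$w(t) = w_{init} - (w_{init} - w_0)\,0.999^t$ the tests verify to float
precision. But this gives a 1 s recovery time constant: any LTD imprinted
during a 2 s trial is ~86% forgotten by the trial's end, weights reach a
stationary within-trial cycle after a handful of trials, and no gradual
multi-trial learning is possible — we verified this in simulation. The
physiological description of this LTP is potentiation caused by
*presynaptic activity alone*, i.e. $L_j = PF_j(t)$: a granule cell firing
at 20–40 Hz then gates LTP on only a few percent of the milliseconds,
recovery slows ~30-fold, and depression accumulates across tens to
hundreds of trials. The OKR protocol therefore defaults to the gated
variant (`plasticity_params(ltp_gated = TRUE)`); both are available
everywhere.

## The two experiments

**Burst response.** 1 Hz Poisson background on all MFs for 1,000 ms, with
150 Hz superimposed (rates add) for 50 ms from t = 300 ms on the MFs within
140 µm of the footprint centre; 10 repetitions from a fresh state; mean ±
SD firing rates per population over the pre-burst, burst and post-burst
periods. At the reference density the 140 µm disc captures ~2,700 MFs. The
qualitative contract — every cortical population accelerates during the
burst — holds across seeds at fixture scale.

**OKR gain adaptation.** Each 2 s trial drives all MFs with a raised-cosine
rate $r(t) = (r_{max}/2)(1 - \cos 2\pi t/T)$ sweeping 0→30 Hz, and the IO
with the same waveform sweeping 0→3 Hz, in phase (retinal-slip error grows
with stimulus velocity; the phase offset is configurable). Trials repeat —
300 by default — with full state carry-over (no reset between trials), and
each trial's PC and DCN population rates are binned at 100 ms and fitted
with a cosine $a + b\cos(2\pi(t-\phi)/T)$ by linear least squares; the
fitted trough is $a - |b|$ and the peak $a + |b|$.

The published experiment states that its parameters were adjusted relative
to the structural tables, without printing the adjusted values; its
reported operating points are a trial-1 PC trough near 60 Hz with the PC
modulating in anti-phase to the drive, a DCN peak near 105 Hz in phase
with the drive, and learning end-points of 24 Hz (PC trough) and 124 Hz
(DCN) after 300 trials. Three observations fix our protocol-level
adjustments (`okr_defaults()`, all configurable):

* A PC driven only by the tabulated 600 pA endogenous current cannot exceed
  ~36 Hz without synaptic excitation, while anti-phase modulation requires
  molecular-layer inhibition to dominate — which pushes the cell *below*
  that ceiling at the drive's peak. A 60 Hz trough in anti-phase is
  therefore unreachable with the printed current; the OKR protocol raises
  the PC endogenous current to 2,100 pA, consistent with the vigorous
  simple-spike pacemaking of Purkinje cells in vivo.
* With the printed 0.0075 nS PC→DCN weight the entire Purkinje population
  contributes under 0.5 nS of inhibition — the nuclei would be essentially
  blind to Purkinje learning. The protocol uses 0.15 nS so that the
  60 → 24 Hz Purkinje change translates into a measurable nuclear gain
  increase.
* A tonic 15 Hz MF background is superimposed on the sinusoid (spontaneous
  mossy-fiber discharge, well within the physiological range). It supplies
  the tonic parallel-fiber drive that keeps the Purkinje trough near 60 Hz
  and gives LTD a substrate at every phase of the cycle.

These three constants and the molecular-layer convergences above were
calibrated once against the trial-1 anchors and then frozen; with them the
full-scale model produces a trial-1 PC cosine trough of ~60 Hz (anti-phase)
and a DCN peak of ~105 Hz (in phase) across seeds.

## Miniature fixtures

`scaffold_fixture(scale)` shrinks counts by `scale` and the footprint area
by the same factor (extents by √scale), preserving layer densities and all
16 rule types. Convergences that cannot be met in a miniature population
are truncated; to keep the *dynamics* comparable, each truncated rule's
weight is scaled up by the ratio of reference to realized in-degree, the
standard down-scaling practice of preserving aggregate synaptic conductance
per target. Protocol-level weight adjustments are expressed at reference
scale and applied multiplicatively so they compose with this compensation.

What fixtures show and do not show: population rates, phase relations and
the direction of learning effects track the reference model well down to a
few thousand cells; the *share* of Purkinje drive carried by plastic
parallel-fiber synapses shrinks at very small scales (few-percent scale),
so learning-magnitude checks use a 1/5-scale circuit, while structural and
engine contracts use 1/100–1/50 scale. Fixtures also inherit everything
the placement model abstracts away: no packing geometry, no microzones, no
anatomical curvature — conclusions about those features cannot be drawn
from these tests, nor from the reference model itself.

## Problem sizes in the shipped checks

The test suite exercises unit contracts at 1/100–1/50 scale (seconds
each), the learning check at 1/5 scale with 30 trials and a 10× LTD rate
across three seeds, and single full-scale runs for the connectome anchor
and the trial-1 OKR operating points. `scripts/acceptance.R` rebuilds the
reference model and one 2-s OKR trial from scratch. The full 300-trial
reference-scale protocol (~300 × 40 s of compute) is supported
(`okr_protocol_spec(n_trials = 300)`) but is an overnight run rather than
part of the default checks.

## Known limitations

* Point-neuron LIF dynamics and static exponential synapses; no dendritic
  structure, no Hodgkin–Huxley channels, no stochastic release.
* MFs and the IO are Poisson abstractions; one IO cell drives one CF signal
  shared by all PCs (per-PC climbing fibers would be a configuration
  extension).
* No gap junctions, no nucleo-olivary inhibitory loop, and no oculomotor
  plant: OKR "gain" is read out as PC/DCN rate changes, not as eye
  movement.
* Placement is uniform-within-layer; connectivity realizes published
  weights/delays but calibrated convergences — the connectome is
  statistically, not anatomically, faithful.
* The synaptic-weight resolution of the printed tables is kept verbatim in
  the structural connectome; experiment-specific departures are confined to
  the protocol objects and documented above.
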