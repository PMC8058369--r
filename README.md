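# cerebscaffold

A scaffold model of the cerebellar microcircuit as a tested, configurable
spiking-network simulator in R. The package builds the circuit in three
independent stages — stochastic **cell placement** in a layered 3-D cortical
column, geometric **structural connectivity** stored as per-projection
compressed sparse row (CSR) matrices, and a clock-driven **simulation
engine** for conductance-based leaky integrate-and-fire dynamics — and adds
bidirectional plasticity at parallel fiber–Purkinje cell synapses. It is
aimed at computational neuroscientists who want a desk-scale, fully
reproducible cerebellar circuit: every stage can be replaced (placements and
connectomes can be imported from plain-text files), every run is
deterministic given a seed, and miniature fixtures make the whole pipeline
testable in seconds.

## The model

All neurons (granule, Golgi, stellate, basket, Purkinje and deep-nuclei
cells; 89,664 at the reference 400 × 400 × 900 µm³ volume, plus 7,070 mossy
fibers and one inferior-olive cell as Poisson spike sources) are
conductance-based LIF units

```
C_m du_i/dt = −g_L (u_i − E_L) + I_e + I_syn(u_i, t)
u_i ≥ V_th  ⇒  spike; u_i ← V_r for Δt_ref
```

with exponential-decay conductance synapses

```
I_syn = −Σ_x g_x (u_i − E_x),   τ_x dg_x/dt = −g_x + Σ_f Σ_j w_ij δ(t − t_j^(f) − d_ij)
```

integrated by forward Euler at Δt = 0.1 ms, with spike exchange and
synaptic delays on a 1 ms grid. Parallel fiber → Purkinje cell synapses
carry a dimensionless plastic factor updated every millisecond,

```
w ← w + λ_LTP (w_init − w) − λ_LTD · w · CF(t) · Σ_{Δt=0..50} PF_j(t − Δt)
```

so that climbing-fiber (CF) activity conjunct with recent parallel-fiber
spikes produces LTD, and parallel-fiber activity alone relaxes the weight
back toward `w_init` (LTP). Two built-in experiments drive the circuit: a
focal 150 Hz mossy-fiber burst over a 1 Hz background (population rate
tables over pre/burst/post periods), and 300-trial optokinetic-response
(OKR) gain adaptation under sinusoidal 0–30 Hz mossy-fiber and 0–3 Hz
inferior-olive drive, with trial-wise 100-ms-binned rates and cosine fits.

## Worked example

A 1/20-scale miniature scaffold (~4,800 cells; weights rescaled so every
cell keeps its reference-scale aggregate synaptic drive):

```r
library(cerebscaffold)
fx <- scaffold_fixture(0.05, seed = 1)
#> <cereb_model> scale 1, 4838 cells, 16 connection rules

burst <- run_burst_protocol(fx, burst_protocol_spec(repetitions = 3), seed = 1)
tidyr::pivot_wider(burst$rates[, 1:3], names_from = period, values_from = mean_hz)
#>   cell_type   pre burst  post
#> 1 BC        23.8  240.  26.1
#> 2 DCN       30    180   33.8
#> 3 GoC        7.98 124.   7.83
#> 4 GrC        3.64 108.   4.03
#> 5 PC        18.1   35.6 17.6
#> 6 SC        25.6  250.  28.3
```

Granule cells are nearly silent under 1 Hz background (no endogenous
current) and jump to ~108 Hz during the 50 ms burst; every cortical
population transiently accelerates, and rates return to baseline afterwards.

```r
okr <- run_okr_protocol(fx, okr_protocol_spec(n_trials = 2), seed = 1)
okr$fits
#>   trial cell_type offset amplitude  phase    min   max
#> 1     1 PC          78.7      7.66   99.7  71.0   86.3
#> 2     1 DCN         41.5     52.5  1031.  -11.0   94.0
#> 3     2 PC          76.3      7.39   12.7  68.9   83.7
#> 4     2 DCN         43       53.0  1025.   -9.96  96.0
```

The cosine fits show the two hallmark phase relations: the Purkinje-cell
modulation peaks near phase 0/2000 ms — opposite to the mossy-fiber drive,
which peaks at 1000 ms — while the deep-nuclei cells follow the drive in
phase (~1030 ms). `autoplot(okr)` draws the fitted learning curves;
`autoplot(res$spikes)` draws population rasters.

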