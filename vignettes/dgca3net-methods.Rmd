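---
title: "Modeling discharge transitions in a DG-CA3 micro-network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling discharge transitions in a DG-CA3 micro-network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dgca3net` simulates a minimal hippocampal circuit of six conductance-based
cells spanning the dentate gyrus (granule cell `G`, two-compartment mossy
cell `MS`/`MD`, GABAergic interneuron `DI`) and CA3 (pyramidal cell `P`,
fast-spiking interneuron `I`, O-LM cell `O`).  The circuit is wired as a
feed-forward mossy-fiber pathway (granule to mossy to pyramidal) embedded
in local feedback inhibition, plus a single CA3-to-DG *backprojection*
whose placement is the central experimental variable:

* **mode A** (`"mossy_soma"`): the pyramidal cell excites the mossy soma —
  a glutamatergic, regeneratively excitatory feedback loop;
* **mode B** (`"dg_interneuron"`): the pyramidal cell excites the DG
  interneuron — functionally an inhibitory feedback onto DG.

Each cell follows Hodgkin-Huxley-type kinetics, `C dV/dt = -sum(I_ion) +
I_ext - I_syn`, with gating variables obeying first-order kinetics in the
usual `alpha/beta` or `x_inf/tau` form.  The templates are:

* granule cell: Traub-Miles Na/K-DR/leak kinetics (type-I excitability);
* DG and CA3 interneurons: the Wang-Buzsaki fast-spiking template
  (instantaneous Na activation, rate scale `phi = 5`);
* pyramidal cell: a reduced CA1-type model with instantaneous Na
  activation, inactivating Na, a comparatively weak delayed rectifier, an
  A-current, a persistent Na current and a slow M-like K current
  (`tau_z = 75` ms).  This combination matters: it gives the cell three
  accessible firing modes — tonic spiking, burst discharges, and
  depolarization block — which is exactly the repertoire the seizure
  transition requires.  The Traub and Wang-Buzsaki templates were tried
  first and cannot express the burst/block regimes under the conductance
  drive used here;
* O-LM cell: Traub-Miles backbone plus an h-current and a strong M-type
  adaptation current.  The adaptation keeps its rate in the slow (about
  5-12 Hz) range characteristic of O-LM cells regardless of how hard the
  pyramidal cell drives it;
* mossy cell: the two-compartment Pinsky-Rinzel model (soma: Na, K-DR;
  dendrite: Ca, K-C, K-AHP; coupling conductance `g_c`, somatic area
  fraction `p = 0.5`), with its native rate functions shifted so rest sits
  near -60 mV.

Synapses use the first-order kinetic scheme `ds/dt = alpha T(V_pre) (1-s)
- beta s` with a sigmoidal transmitter drive `T` (midpoint +2 mV, slope
5 mV).  Receptor defaults: AMPA decays in ~2 ms, GABA_A in ~7 ms and NMDA
rises in ~2 ms and decays in ~100 ms; reversal potentials 0 mV
(AMPA/NMDA) and -75 mV (GABA_A).  The NMDA conductance is scaled by the
standard magnesium block `B(V) = 1/(1 + exp(-0.062 V) [Mg]/3.57)` with
1 mM magnesium, which makes the NMDA current-voltage relation J-shaped
and is the source of the regenerative depolarization that drives the
pyramidal cell across its regime boundaries.

## Parameters that matter, and why these defaults

**Conductance scale.** The three experimentally swept conductances
(`g_nmda_p`, `g_p_ms`, `g_p_di`) are specified on a relative scale with
magnitudes of order 1e-4 to 1e-1.  Taken literally as mS/cm2 such values
are dynamically inert for cells whose intrinsic conductances are of order
1-100 mS/cm2.  The package therefore carries one global factor,
`syn_gain` (default 200), converting the relative scale into conductance
density; every synaptic edge, including the unswept intra-network
couplings, is multiplied by it.  `syn_gain` was calibrated once, so that
the tonic-to-bursting bifurcation of the pyramidal cell falls near
`g_nmda_p = 0.002` on the relative scale, and then frozen.

**External drive.** Every cell receives the same constant stimulus
current (`i_ext`, default 0.35 uA/cm2), scaled per cell kind (mossy 3x —
its capacitance ratio; pyramidal 3.5x — rheobase matching; all others
1x).  A literally identical current density cannot make six heterogeneous
cell models tonically active at once, which is the baseline condition of
the study (all DG cells spiking); the per-kind factors restore that
condition while keeping a single tunable stimulus.  The defaults make the
granule cell fire near 22 Hz, the DG interneuron near 28 Hz, the mossy
cell near 17 Hz and the pyramidal cell near 17-20 Hz at the weakest
coupling.

**Calibrated deviations from canonical cell parameters.** The mossy cell
uses `gCa = 7` (canonical 10), `gKahp = 0.4` (canonical 0.8), `gLs = gLd
= 0.15` (canonical 0.1) and a leak reversal of -65 mV.  The first three
move the cell from low-rate rhythmic bursting into tonic spiking near 17
Hz, the baseline discharge the network needs; the hyperpolarized leak
silences the model's spontaneous bursting at zero drive so that an
undriven network is quiescent (the canonical parameterization is
recovered — and tested — via `cell_overrides`).  The pyramidal cell's
`gK = 9`, `gNaP = 0.08` place its burst onset at the desired position of
the NMDA sweep while leaving a tonic "preictal" corridor below it.

## The three experiment families

* `preset_nmda_sweep()`: mode-A network with a weak backprojection
  (`g_p_ms = 1e-4`), sweeping `g_nmda_p` log-spaced over [5e-4, 0.1].
  As the NMDA conductance grows the pyramidal cell passes from slow tonic
  spiking (interictal; dominant frequency near 17 Hz, inter-spike
  intervals tens of ms), through faster tonic spiking (preictal), into
  burst discharges with quiescent gaps (seizure onset) and ultimately
  toward depolarization block, where amplitude and dominant frequency
  collapse.
* `preset_glut_backprojection()`: mode A, `g_nmda_p = 0.001`, `g_p_ms`
  linear over [1e-4, 0.01].  The excitatory feedback accelerates the
  mossy cell toward a low-gamma plateau and the whole DG follows.
* `preset_gaba_backprojection()`: mode B, `g_nmda_p = 0.001`, `g_p_di`
  linear over [0.001, 0.1].  Driving the DG interneuron suppresses the
  mossy cell: its median ISI lengthens beyond a critical conductance and
  the granule cell drifts mildly downward.

## Analysis battery

Spike times are upward threshold crossings (-20 mV) with a 2-ms
refractory guard, detected at full integration resolution.  Interspike
intervals feed the ISI-versus-parameter bifurcation scans.  Spectra are
Welch averages of 1-s Hann windows with 50% overlap, linearly detrended
per segment and zero-padded to bins finer than 0.25 Hz; the *dominant
frequency* is the argmax of power over 1-100 Hz with ties broken toward
the lower frequency (the resolution suffices to separate dominant
frequencies ~1 Hz apart).  The spectrogram applies the same periodogram
on sliding 1-s windows with 90% overlap.  The zero-lag linear correlation
is the mean product of standardized samples — identical to the Pearson
coefficient at lag zero, which the test suite verifies against `cor()`.
The first 200 ms of every record are discarded before analysis unless a
scenario prescribes an explicit window.

Two operational definitions deserve note:

* **Burst structure** (`is_bursting()`): an ISI sequence is
  burst-structured when at least three intervals are shorter than 15 ms
  and some interval exceeds three times the median intra-burst interval.
  This operationalizes "small bursts separated by long ISIs" and drives
  both the regime classifier and the bifurcation-point detector.
* **ISI-lengthening critical point** (`isi_lengthening_point()`): the
  default estimator fits a two-segment changepoint model to the median
  ISI versus the swept conductance and reports the first grid value of
  the higher segment.  A fixed-margin rule ("first exceeds baseline by
  x%") is available but proved brittle to the margin choice; the
  changepoint fit needs no margin and is the shipped default.

Regime labels: burst-structured windows are `seizure_onset`; tonic
windows with a dominant frequency at or above 28 Hz are `preictal`
(the fast-spiking corridor just below the bursting boundary); tonic
windows with median ISI in the 20-50 ms band below that are
`interictal`; anything else is `unclassified`.

## Numerical choices

Integration is fixed-step classical Runge-Kutta (RK4), default step
0.01 ms, with gating variables clamped to [0,1] and calcium to
non-negative values after each step.  Initial conditions are
deterministic: every voltage starts at its leak reversal, gates at their
steady state for that voltage, synapses closed — so identical
configurations reproduce results bitwise.  Removable singularities of the
rate expressions (`x/(exp(x)-1)` forms) are evaluated by their series
expansion within 1e-4 of the singular voltage.  Integration aborts with
an informative error if any voltage leaves +/-200 mV or becomes
non-finite.  Traces are recorded at 0.05 ms (20 kHz), comfortably above
the 1-100 Hz analysis band; spike times retain full step resolution.
Step-halving changes any 1-s isolated-cell trace by well under 1 mV RMS
and moves network spike times by under 0.5 ms over the windows tested.

## What the tests do and do not show

The test suite exercises the machinery on synthetic inputs with known
answers (sinusoids, constructed spike trains, hand-computed correlations,
closed-form synaptic decay) and checks the scientific properties of the
model itself (gate boundedness, resting stability, decoupled-limit
independence, step-refinement convergence, canonical Pinsky-Rinzel
bursting, NMDA J-shaped current-voltage relation).  The quantitative
acceptance checks run the three experiment families at reduced size —
8-s simulations on 10-12-point grids, versus the 10-s, 20-point protocol
of `scripts/acceptance.R` — which keeps the default test run fast while
probing the same regime structure.  Passing them shows the shipped
parameterization reproduces the transition anatomy of this particular
six-cell model; it says nothing about real hippocampal tissue, in which
cell populations, heterogeneity, and slower processes (accumulating ionic
gradients, plasticity) shape seizure dynamics.

## Known limitations

* The detailed cell equations of the source network are reconstructed
  from the cited model lineages rather than transcribed; quantities tied
  to precise parameter values (the preictal dominant frequency, the exact
  spectral content at seizure onset, the mode-A pyramidal plateau) shift
  accordingly, while regime structure, boundaries and correlation
  patterns are robust.
* One cell per role: no population averaging, no heterogeneity, no
  stochastic channel noise — every run is deterministic.
* The backprojection is a single edge; mixed or plastic backprojections
  are out of scope.
* The spectral pipeline reads dominant frequencies from membrane voltage
  directly (no LFP forward model); for a quiescent cell the dominant
  frequency reflects subthreshold ripple rather than firing.
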