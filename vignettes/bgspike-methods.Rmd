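---
title: "Model and methods: a spiking basal-ganglia network for probabilistic learning under medication and DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`bgspike` simulates action selection in the basal ganglia (BG) with a
spiking network model and uses it to run the probabilistic learning task
(PLT) under healthy, Parkinsonian (untreated and medicated) and
subthalamic deep-brain-stimulation (DBS) conditions.  The model has four
interacting parts:

1. **Spiking lattices.**  The subthalamic nucleus (STN), external
   pallidum (GPe) and internal pallidum (GPi) are each a square lattice
   (50 x 50 by default) of two-variable Izhikevich neurons
   $$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$
   with the reset $v \ge 30\,\mathrm{mV} \Rightarrow v \leftarrow c,\;
   u \leftarrow u + d$.  STN and GPe are coupled one-to-one (STN
   excites GPe with weight $w_{sg} = 0.91$; GPe inhibits STN with
   $w_{gs} = 18$) and each nucleus has lateral connections within a
   disc of radius $r_s = 1.4$ (STN) and $r_g = 1.6$ (GPe), the radii
   that keep the loop desynchronized in the healthy condition.  GPi
   receives convergent glutamatergic input from the topographically
   aligned STN disc (radius 1.6, weight $w_{STN \to GPi}$ per
   afferent: 1.5 healthy / 2 Parkinsonian) and one-to-one GABAergic
   input from D1 striatal neurons ($w_{Str \to D1}$, 4 healthy / 3
   Parkinsonian).  The convergence keeps the output stage sensitive
   to local STN rate and timing — single dispersed afferents are
   averaged away at the GPi membrane — which both the indirect
   pathway and the stimulation effects depend on.

2. **Striatal drive.**  D1- and D2-expressing medium spiny neurons are
   Poisson spike sources in the 2-40 Hz range.  Each of the six task
   choices (cards A-F) owns one D1 and one D2 cortico-striatal weight;
   on every trial the two presented cards drive the two lattice halves
   at rates read off their weights (see *Rate normalization* below).

3. **Dopamine and plasticity.**  After each rewarded (+1) or punished
   (-1) selection the temporal-difference error
   $\delta = Re - w^{D1}_{sel}$ plays the role of phasic dopamine:
   $\Delta w^{D1} = \eta\,\delta$, $\Delta w^{D2} = -\eta\,\delta$
   with $\eta = 0.1$, applied to the selected card.  Condition
   policies transform $\delta$ first: the untreated Parkinsonian state
   clamps it at a ceiling of $-0.1$ (loss of dopaminergic neurons);
   L-DOPA adds $+2$ to the clamped value on both channels; a dopamine
   agonist adds it on the D2 channel only.  DBS runs use the
   Parkinsonian clamp and weight set.

4. **Decision race.**  GPi is the output: for each choice $k$ the
   normalized, *reversed* firing
   $f_k = (f_{max} - f'_k)/f_{max}$ (cumulative mean rate of that
   choice's GPi half against the busiest single neuron) feeds a
   mutual-inhibition race
   $\dot z_1 = -z_1 + f_1 - z_2$ (and symmetrically), and the first
   integrator across the 0.25 threshold is the selected action; the
   crossing time is the reaction time (RT).  Lower GPi activity means
   a higher drive, so the less-inhibited-striatum/more-inhibited-GPi
   choice wins.

# The task

Training presents the fixed pairs AB / CD / EF (reward probabilities
0.8/0.2, 0.7/0.3, 0.6/0.4) forty times each in shuffled order — 120
trials with feedback.  Testing presents all 15 pairs of the six cards
20 times each with frozen weights and no feedback.  Performance
measures follow the task's standard definitions: binned training
accuracy (five bins of eight presentations), a-priori selection
probabilities and their per-pair difference (DRE), per-pair testing
accuracy, choose-A / avoid-B percentages over the novel A- and
B-containing pairs, RT summaries by conflict (high conflict = both
cards on the same side of probability 0.5) and correctness, and a
least-squares fit of testing accuracy against DRE whose goodness R is
the correlation between fitted and observed values.

```{r, eval = FALSE}
library(bgspike)
cond <- bg_condition("normal", shape = 10L)
res <- run_condition(cond, plt_task(), seeds = 1:10)
res$summary$final_bin_accuracy
res$summary$choose_A_pct
mean_rt(res, "LC", TRUE)
```

# Design choices

The published description of this model family fixes the synaptic
weight values, the task, the learning rule and the race equations, but
leaves several numerical choices open.  The package's choices, and the
reasons for them, are:

**Integration.**  Forward Euler with `dt = 0.5` ms, one update per
step, voltage and recovery advanced simultaneously from the previous
state, reset applied after the update.  This is the standard scheme for
Izhikevich lattices; the step is exposed in the configuration.

**Neuron parameters.**  STN uses a slow-recovery, burst-capable set
(`a = 0.005, b = 0.265, c = -65, d = 2`); GPe and GPi use a
fast-spiking set (`a = 0.1, b = 0.2, c = -65, d = 2`).  These match the
firing phenotypes the nuclei are known for.

**Synapses.**  Current-based single-exponential traces: a presynaptic
spike adds the connection weight (pA) to the target's trace, which
decays with 5 ms (glutamatergic) or 10 ms (GABAergic) time constants;
inhibitory classes enter the current sum with negative sign.  Lateral
coupling within STN (excitatory) and GPe (inhibitory) uses small
per-neighbour weights (0.5) distinct from the one-to-one loop weights
$w_{sg}/w_{gs}$; we read the published values of the latter as the
STN<->GPe loop weights because their magnitudes (18 for GPe->STN) match
the strong pallido-subthalamic inhibition they are motivated by.

**Baseline currents and population heterogeneity.**  Each neuron
receives a tonic background current (STN 6, GPe 5.5, GPi 1.4 pA)
jittered uniformly by +/-40% per neuron and redrawn at each trial
onset.  The heterogeneity keeps the cumulative GPi rate distribution
dispersed — which the reversed-rate normalization $f_k$ requires,
since a perfectly homogeneous lattice drives $f' / f_{max} \to 1$ and
stalls the race — and it is the main source of trial-to-trial decision
variability, standing in for the background-state fluctuations of real
populations.  The GPi baseline sits just below rheobase so GPi firing
is gated by STN spikes and striatal D1 inhibition, making both the
direct and the indirect pathway effective at the output.  These values
(together with the race constant below) were calibrated once, on the
healthy condition only, to the healthy condition's published training
accuracy, choose-A percentage, accuracy-DRE linearity and low-conflict
RT; all other conditions differ from the healthy configuration only by
their published parameter changes.

**Rate normalization.**  The six cards' weights are mapped linearly
onto 2-40 Hz using their running minimum and maximum, with a floor of
2 weight units (the scale of the +/-1 reward) on the normalization
span: when the weights lie closer together than the floor the map has
a fixed gain of 19 Hz per weight unit about the running midpoint.
Without the floor, noise-level differences between rarely-selected
cards' stale initial weights are stretched across the full rate band,
which locks the testing accuracy of lose-lose pairs at 0 or 1 per run
and destroys the linear accuracy-DRE relation this model family is
known for.  The degenerate all-equal case maps to the midpoint 21 Hz.

**Side assignment.**  The alphabetically first card of a pair always
drives the upper lattice half.  A per-trial random assignment is
available (`side_assignment = "random"`), but the canonical mapping is
the default because the electrode-position effects are spatial: a
fixed electrode can only produce card-specific biases if the card-to-
lattice mapping is stable across trials.  In unstimulated conditions
the assignment is immaterial by symmetry.

**DBS pulses.**  The 130 Hz monophasic train has nominal 100 us
pulses, shorter than the integration step; each pulse is delivered on
a single step.  By default the nominal amplitude is applied for the
whole step (`pulse_mode = "full_amplitude"`).  A charge-preserving
alternative (`"charge_equivalent"`, amplitude scaled by
`pulse_width / dt`) is available but is not the default because the
resulting brief kick is fully absorbed by the STN neurons' slow
recovery variable: stimulated and unstimulated halves then fire at
identical rates and stimulation has no downstream effect at all,
inconsistent with the strong electrode-position effects this model
family exhibits.
Electrode centre and spread are expressed on the reference 50 x 50
lattice and rescale proportionally at other lattice sizes.  DBS is
active throughout each trial.

**Race calibration.**  The race equations are written in units of
their own time constant, which the model maps onto milliseconds with a
single constant `race$tau_ms` (default 2600 ms), the only bridge
between network time and the behavioural RT scale; it was fixed
together with the baseline currents on the healthy condition's
low-conflict RT and is inherited unchanged by every other condition.
Negative integrator values are clipped at zero (flag available for the
literal equations); trials that do not cross the threshold within
`t_max = 3000` ms are censored: the larger integrator is taken as the
choice, and the trial is excluded from RT averages (included, flagged,
in the logs).

**Credit assignment.**  The update is applied to the selected card
only.  The literal both-presented-cards reading would add the same
increment to both cards of a pair on every trial, leaving their
difference — the learnable quantity — untouched, so it cannot produce
discrimination learning; it remains available as
`update_mask = "input"`.

**Inter-trial reset.**  All neuronal state (v, u, traces, race
integrators, cumulative GPi counts) is reset at each trial onset.

# What the simulations do and do not show

The synthetic task generator reproduces the study conditions exactly:
Bernoulli rewards at the published probabilities, 120 training and 300
testing trials, condition presets with the published weight, clamp and
stimulation parameters.  Passing ensembles therefore show that the
mechanisms — dopamine-gated two-channel plasticity, pathway-weight
changes, spatially selective stimulation — produce the published
behavioural patterns in this network.  They do not validate the model
against new empirical data, and several quantities the publication
leaves unspecified (neuron parameters, synaptic kinetics, the race
time mapping, ensemble sizes) are this package's own choices, so
absolute agreement is only meaningful to within ensemble variability.

Reported ensembles in the package's tests use 10 x 10 lattices (the
behaviour of interest is carried by half-lattice rate differences and
survives down-scaling, with electrode geometry rescaled
proportionally) and 5-10 seeds; the examples in the README use the
same sizes.  The full 50 x 50 geometry runs unchanged through the same API
(`shape = 50L`) at roughly 25x the cost.

# Known limitations

* The hyper-direct (cortex->STN) pathway and the GPe->GPi projection
  are deliberately absent, as in the source model.
* Striatal neurons are Poisson sources, not spiking neurons; dopamine
  acts only through the TD error, not on membrane excitability.
* The published zero-variance RTs (e.g. "1620 +/- 0") are not
  reproduced exactly; with Poisson input and heterogeneous baselines
  our RT distributions have small but nonzero spread.
* Censoring interacts with slow conditions: in strongly lesioned
  configurations a substantial fraction of trials reach the horizon,
  and their exclusion from RT averages biases those averages toward
  the faster trials.
* One documented deviation from a literal reading of the update rule
  and one from pure running-min/max rate normalization are described
  above; both have config flags restoring the literal behaviour.
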