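# bgspike

A spiking network model of the basal ganglia for studying probabilistic
reward/punishment learning, dopaminergic medication, and subthalamic
deep brain stimulation (DBS).

## The science

The basal ganglia select actions: cortical candidates drive the
striatum, whose D1 (direct, GPi-inhibiting) and D2 (indirect, via
GPe and STN) projection pathways compete to release or hold the
inhibitory output of the internal pallidum (GPi).  Phasic dopamine —
modelled here as the temporal-difference (TD) error
`delta = Re - V` of each outcome — gates plasticity at the
cortico-striatal synapses with opposite signs on the two pathways:

```
dw_D1 =  eta * delta        dw_D2 = -eta * delta       (eta = 0.1)
```

Parkinson's disease removes the dopamine signal (`delta` clamped at a
ceiling of -0.1), L-DOPA adds a medication term (+2) on both pathways,
a dopamine agonist adds it on the D2 pathway only, and STN-DBS injects
a 130 Hz Gaussian current field into the STN lattice, part of which
may reach GPe antidromically.

The network is three 2-D lattices of Izhikevich neurons

```
dv/dt = 0.04 v^2 + 5 v + 140 - u + I      du/dt = a (b v - u)
v >= 30 mV  =>  v <- c,  u <- u + d
```

for STN, GPe and GPi, with one-to-one STN<->GPe coupling
(w_sg = 0.91 excitatory, w_gs = 18 inhibitory), lateral discs of
radius r_s = 1.4 / r_g = 1.6, Poisson striatal input at 2-40 Hz whose
rate encodes the learned weights, and a mutual-inhibition race over
the normalized, reversed GPi firing

```
f_k = (f_max - f'_k) / f_max
dz1/dt = -z1 + f1 - z2       dz2/dt = -z2 + f2 - z1
```

whose first threshold crossing (0.25) gives the selected action and
the reaction time.

The experiment harness runs the probabilistic learning task: training
on the pairs AB / CD / EF (reward probabilities 80/20, 70/30, 60/40;
40 presentations each), then testing on all 15 pairs, 20 presentations
each, with frozen weights.  Reported measures: binned training
accuracy, difference in reward expectation (DRE), per-pair testing
accuracy, choose-A / avoid-B percentages, reaction times by conflict,
and the linear fit of testing accuracy on DRE.

## Worked example

Train and test the healthy model on a 10 x 10 lattice (the reduced
geometry used throughout the test suite; `shape = 50L` gives the full
model) over a 5-seed ensemble:

```r
library(bgspike)

cond <- bg_condition("normal", shape = 10L)
res  <- run_condition(cond, plt_task(), seeds = 1:5)
res
```

```
<bg_results> normal (5 seeds)
  final-bin training accuracy: A=0.93 C=0.80 E=0.55
  choose-A 87.2%, avoid-B 53.0%
  LC-correct RT 1597 ms, HC-correct RT 1696 ms
  accuracy~DRE linear fit R = 0.69
```

By the last training bin the model picks the 80%-rewarded card A on
~93% of AB trials but stays near chance on the hard 60/40 pair EF; at
test it chooses the best card A on ~87% of novel presentations; high
conflict decisions (win-win or lose-lose pairs) take longer than low
conflict ones.  Swap the preset for `"pd_off"`, `"pd_on_ldopa"`,
`"pd_on_daa"` or `"dbs"` to reproduce the lesioned, medicated and
stimulated variants, e.g.:

```r
run_condition(bg_condition("dbs", shape = 10L,
                           overrides = list(dbs = list(position_preset = "pos1"))),
              seeds = 1:5)
```

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/bgspike simulate --preset normal --seeds 1:10 --shape 10 --out results/
Rscript inst/cli/bgspike sweep --vary position --preset dbs --out results/
Rscript inst/cli/bgspike report --dir results/
```

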