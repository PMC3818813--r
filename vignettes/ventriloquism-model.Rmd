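---
title: "A two-layer firing-rate model of the ventriloquism effect and aftereffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer firing-rate model of the ventriloquism effect and aftereffect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ventnet` simulates the interaction of two cortical maps of firing-rate
neurons:

* a **visual layer** of 180 neurons, one per degree of azimuth;
* an **auditory layer** of 180 x 40 neurons, jointly coding azimuth (one
  neuron per degree) and tone frequency (five neurons per octave, eight
  octaves).

Each neuron obeys first-order dynamics with a logistic output nonlinearity,

$$\tau_y \frac{dy}{dt} = -y + F(u), \qquad
  F(u) = \frac{1}{1 + e^{-s(u - \theta)}},$$

with a common time constant $\tau_y = 3$ ms, slope $s = 0.6$ and centre
$\theta = 12$ for every neuron. Activities are normalized to the maximal
rate, so $y \in (0, 1)$. The net input $u$ of a neuron sums three terms:

1. **External input** — the stimulus filtered by the neuron's receptive
   field: a circular Gaussian of the azimuth distance for the visual layer
   ($\sigma_p^v = 4$), a separable circular Gaussian of azimuth and
   frequency distance for the auditory layer
   ($\sigma_p^a = 30$, $\sigma_f^a = 14$), peaking at the stimulus
   intensity ($E_0^v$, $E_0^a$, arbitrary units). Both grid dimensions are
   rings: distance is `circular_distance()`, which avoids border effects.
2. **Lateral input** — a Mexican-hat kernel, the difference of a narrow,
   strong excitatory Gaussian and a broad, weaker inhibitory Gaussian
   (stored separately because plasticity treats them separately;
   self-connections are removed from both). In the auditory layer the
   kernel is a separable product over azimuth and frequency.
3. **Cross-modal input** — fixed excitatory coupling between the layers,
   aligned by azimuth: every auditory neuron at azimuth $i$ receives
   $W_{av}\, y_i^v$, and the visual neuron at $i$ receives
   $W_{va} \sum_j y^a_{ij}$. $W_{va} \approx W_{av} / N_f^a$ balances the
   40-to-1 convergence.

The defaults of `network_config()` are the model's basal parameter set;
any value can be overridden by argument or through a YAML file.

## Decoding

Perceived stimulus locations are read out with the barycenter (population
vector on linear indices): $z = \sum_i y_i\, i / \sum_i y_i$ (degrees).
Two conventions deserve a note:

* **Resting-background floor.** A logistic neuron is never exactly silent:
  with zero input its rate is $F(0) \approx 7.5\times 10^{-4}$. Summed over
  thousands of unstimulated neurons, this background drags a literal
  activity-weighted mean toward the grid midpoint (89.5°), producing a
  spurious bias of a few tenths of a degree — enough to corrupt perceptual
  shifts of a few degrees, and to break the exact symmetry argument that a
  unimodal tone must be decoded at its own azimuth. `barycenter_auditory()`
  and friends therefore zero activity below 1% of the layer maximum before
  decoding (`floor_frac = 0.01`; set 0 for the literal mean). With the
  floor, the decoded position of an untrained unimodal response is exact
  by symmetry — the property every aftereffect baseline rests on.
* **Linear, not circular, mean.** All protocol stimuli live at 80–100°,
  far from the wrap seam; a warning is emitted if more than 1% of the
  decoded mass sits within 5 indices of the seam.

## Numerical integration

The explicit Euler scheme `y <- y + (dt / tau_y) * (-y + F(u))` is used
with `dt = 1` ms. The steady states that all measurements are taken at are
fixed points $y = F(u)$ and hence independent of `dt` (the test suite
checks that halving `dt` moves converged activities by less than
`10 * steady_tol`); `dt = 1` ms also makes one integration step coincide
with the millisecond "simulation steps" at which activation snapshots are
conventionally displayed, and keeps the 1000-step adaptation protocol at a
practical runtime. Steady state is declared when the largest per-step
activity change drops below `steady_tol = 1e-6`. Untrained-network runs
converge within ~60–120 ms of simulated time, but test tones presented to
an *adapted* network can relax very slowly (several hundred ms): the
response first forms at the tone position and then gradually recruits the
strip of neurons whose incoming synapses were potentiated during
adaptation. The integration cap is therefore generous (`t_max = 2000` ms);
hitting the cap flags the returned state and warns — results from
non-converged runs are never reported silently, and a truncated run here
is not a harmless detail: stopping a weak-adaptation test at 200 ms
roughly halves the measured aftereffect.

## Plasticity

During adaptation the lateral synapses of both layers follow a
threshold-gated Hebbian potentiation rule, applied after every Euler step
(1000 steps in the standard protocol, stimuli held constant, starting from
the null state):

$$\Delta L_{ex}[q,p] = \alpha_{ex0}\,(L_{max} - L_{ex}[q,p])\; y_p\,
   [y_q - \theta_{post}]^+,\qquad
  \Delta L_{in}[q,p] = -\alpha_{in0}\, L_{in}[q,p]\; y_p\,
   [y_q - \theta_{post}]^+ .$$

Excitatory weights saturate at $L_{max}$ (the basal kernel amplitude) and
inhibitory weights cannot cross zero, because the learning factors vanish
there. After each step the incoming weights of every postsynaptic neuron
are renormalized, separately per component, to their basal sums — the
population-normalization constraint that forces competition: when some
incoming excitatory synapses grow, the rest must shrink. With
$\theta_{post} = 0.5$ only neurons above half-maximal activity gate
plasticity on; during bimodal adaptation that is essentially the strip of
auditory neurons captured by the visual stimulus, so the strip's incoming
weights from the (sub-threshold but active) neurons at the true sound
position are the ones that potentiate. Learning is active from the first
step; no warm-up period is used, since the transient (~25 ms) is a small
fraction of the 1000-step exposure.

Design notes, where the formulation left room:

* "1000 steps" is read as 1000 integration steps with one Hebbian +
  normalization application per step.
* The deltas are computed from the activities *after* the step they follow,
  and normalization acts on `L + delta` — the order the normalization rule
  is written in.
* The visual layer uses the same rules with the frequency dimension absent;
  its own $L^v_{max}$ and basal sums play the corresponding roles.
* Self-entries are excluded from delta computation and from normalization
  sums, and stay exactly zero forever.
* Frequency is treated as circular, like azimuth, because the circular
  distance is defined once for every grid dimension. Biologically a
  tonotopic ring is odd (the lowest and highest octaves are not
  neighbours), but none of the standard protocols places stimuli closer
  than three octaves to the frequency "seam", and the kernels there are
  narrow; treating the dimension as a line would change results only in
  the outermost octaves.

## Weight storage: compact vs dense

The auditory layer has 7200 neurons, so a literal pair of weight matrices
holds $2 \times 7200^2 \approx 10^8$ entries. The package's default
`"compact"` representation exploits two exact structural facts: untrained
weights are separable circulant kernels (lateral input is then two small
matrix products, plus a rank-style correction that removes the
self-connection), and learning can only ever modify the incoming rows of
neurons that crossed $\theta_{post}$ (a few hundred in practice). Only
those rows are materialized densely. This is an exact reformulation, not a
truncation; the test suite verifies compact-vs-dense agreement to 1e-10 on
a 60 x 20 grid through basal input, full adaptation and post-adaptation
testing. The `"dense"` representation remains available and is the
reference (oracle) implementation for small grids.

## Protocols

* `ventriloquism_sweep()` — bimodal steady states, learning off, over
  disparity x intensity; decodes both shifts. The canonical configuration
  (flash at 100°, tone at 80°/1.1 kHz) yields an auditory shift of ~4.8°
  at $E_0^a = 17$ and ~3.7° at $E_0^a = 20$ — weaker tones are captured
  more strongly, because the high-intensity response adds a broad
  activity mass near the true sound position that anchors the barycenter.
  The visual shift stays below 0.1° (0.5° across the whole sweep):
  capture is asymmetric.
* `adapt_network()` + `aftereffect_experiment()` — the aftereffect
  protocol: adapt for 1000 steps, then decode unimodal test tones at the
  adaptation position, learning off, across test frequencies and
  intensities. `generalization_matrix()` crosses adaptation and test
  intensities and summarizes each curve by its *generalization bandwidth*
  (octave distance at which the aftereffect first falls below a 0.5°
  floor — a summary this package defines, since the spread of the curves
  is otherwise only described verbally).
* `azimuth_tuning()`, `frequency_tuning()`, `fra()` — response properties
  of single neurons, probed by independent steady-state runs per stimulus
  (not a single sweep), with `half_max_width()` (one-sided, peak to
  half-peak, linearly interpolated; a two-sided variant is available) and
  the four-band frequency-response-area discretization at 25/50/75% of
  peak.

## What the simulations show (and what they do not)

All inputs are generated internally; there is no randomness anywhere, and
repeated runs are bit-identical. Computed behaviour at the basal
parameters, as exercised by the test suite and the acceptance script:

* ventriloquism shifts of 4.8°/3.7° at intensities 17/20 with negligible
  visual shift;
* an aftereffect that appears at the adaptation frequency and, with rising
  intensity, generalizes across octaves, with the test intensity — not the
  adaptation intensity — controlling the generalization range;
* aftereffects at the adaptation frequency of ~1.68° after adapting at
  intensity 17 and ~2.57° at 18; no generalization beyond the adaptation
  frequency at 17, roughly one octave of generalization at 18, and a
  residual two-octave aftereffect that grows from near zero (0.19°) after
  adapting at 19 to clearly present (1.41°) at 20 — the small-intensity
  window across which generalization switches on;
* azimuthal tuning whose peak and half-max width grow with intensity
  (one-sided width 21.4° at intensity 10 vs 26.9° at 25, a 5.5° increase),
  a ~60–70° responsive region at moderate floors, and frequency tuning
  broader than 1–2 octaves that widens with intensity in the FRA bands.

Values at the edges of these regimes — the two-octave aftereffect right at
the generalization onset, and anything gated by `theta_post` at the lowest
adapting intensity — are sensitive at the percent level to the activity
reached during adaptation, so small numerical choices (integration step
during the transient, convergence tolerance) move them by far more than
they move the robust quantities above. The acceptance script reports the
computed values exactly as the simulations produce them.

The model is functional, not anatomical: "proximal" neurons are
functionally proximal, and the spatial map need not exist topographically
in cortex. Cross-modal weights are fixed (only lateral synapses learn),
there is no decay or forgetting term, no noise, and no calibration of the
arbitrary intensity units to physical sound levels.

## Worked example

```{r}
library(ventnet)
cfg <- network_config()
syn <- basal_synapses(cfg)

# immediate ventriloquism effect
stim <- stimulus(visual_azimuth = 100, auditory_azimuth = 80,
                 auditory_freq_hz = 1100, auditory_intensity = 20)
st <- run_to_steady_state(syn, stim, cfg)
decode_locations(st, stim)
autoplot(st)

# aftereffect after adapting at intensity 18
ae <- aftereffect_experiment(syn, cfg, adapt_intensity = 18)
autoplot(ae)
```

Problem sizes used by the tests: unit tests run on a 60 x 20 synthetic
grid with proportionally scaled kernels (fast, qualitatively faithful,
quantitatively not comparable to the full network); the acceptance-level
tests and `scripts/acceptance.R` run the full 180 x 40 network with three
1000-step adaptations, a 42-cell ventriloquism sweep and 2 x 180 tuning
probes.
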