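---
title: "An oscillatory semantic network model of bilingual word learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An oscillatory semantic network model of bilingual word learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bilexnet` simulates a two-layer neural-mass model of semantic memory in
which *objects* live in feature maps and *words* live in a lexical sheet,
with the two tied together by learned synapses and a decision gate.

### Feature network

The feature network consists of $F$ square topographic maps ($F = 4$ maps
of $20 \times 20$ units in the reference configuration). Each unit is a
Wilson-Cowan oscillator: a coupled excitatory/inhibitory pair

$$
\tau_x \dot x = -x + H_x(g_{ee}x - g_{ie}y + P), \qquad
\tau_y \dot y = -y + H_y(g_{ei}x - g_{ii}y),
$$

where $P$ collects lateral, inter-area, word-feedback and external drive.
The activation $H$ is a logistic rescaled so that $H(0) = 0$ exactly and
$\sup H = 1$, then clamped at zero; this gives a genuinely silent rest
state and keeps activities in $[0,1]$. The default gains
($\tau_x = 2.6$ ms, $\tau_y = 5.3$ ms, $g_{ee} = 20$, $g_{ie} = 32.5$,
$g_{ei} = 25$, $g_{ii} = 0$, thresholds $2.5/4$, slopes $2/2$) place each
unit in a regime with

* a stable silent rest state at zero input, and
* a limit cycle in the gamma band under suprathreshold constant drive,
  with no amplitude death for summed drives up to roughly 13 -- the
  largest total a unit sees when external input, lateral excitation,
  inter-area synapses and word feedback stack.

`oscillator_params()` *verifies this regime by simulation at construction
time* and refuses parameter sets that are silent-unstable or fall outside
a 20--30 ms period at the reference drive.

Within each map, fixed lateral connectivity follows a Mexican-hat
(difference-of-Gaussians) profile -- excitation of radius 1 grid unit,
broader inhibition of radius 3, truncated at three inhibitory radii, no
self-connection, hard map boundaries. A point stimulus therefore ignites
a compact *activation bubble* whose units oscillate in synchrony, and the
inhibitory surround keeps one bubble from invading the rest of the map.
Fixtures place object features at least 3 units from map edges so
boundary truncation does not distort bubbles.

### Lexical sheet and interneurons

Words are units on an $M_1 \times M_2$ sheet ($40 \times 40$ by default)
with first-order dynamics and a plain logistic activation
($\vartheta = 2.5$, slope $2$). The net input of a word unit is

$$
u^L_{ij} = I^L_{ij} + V^F_{ij} - G^L (1 - z^L) - C^L_{ij} - I^{Bias}_{ij},
$$

the sum of external linguistic input, feature drive through the learned
feature-to-word synapses, gating inhibition withdrawn when the decision
gate output $z^L$ switches to 1, learned competition from the
interneurons of rival words, and a nonnegative top-down bias. Each word
unit drives one paired inhibitory interneuron whose only input is that
word's own activity.

Parameter choices that matter:

* **Gate strength** $G^L = 16$: chosen above the largest feature drive a
  fully trained word receives (peak $\approx 12$ in the reference
  configuration), so feature activity alone can never activate a word
  while the gate is closed. This inequality is asserted in the tests.
* **External word input** $I^L = G^L + \vartheta + 5/p = 21$: the
  "sufficiently high to overcome the inhibition" requirement made
  constructive -- it guarantees suprathreshold drive even under full
  gating.
* **Top-down bias** uses the same magnitude as $G^L$ and targets every
  word of the non-target language.
* **Lexical time constant** $\tau^L = 2$ ms: small enough that a word
  driven by the oscillating object representation follows the gamma
  rhythm with a phase lag below 2 ms (a first-order unit lags by
  $\arctan(2\pi f \tau)/2\pi f$, which at 30--40 Hz stays under 2 ms only
  for $\tau \lesssim 2.5$ ms). The interneuron time constant is five
  lexical time constants, so competition builds over cycles rather than
  chopping them; its steep activation (midpoint 0.5, slope 6) makes an
  externally saturated word a much stronger competitor than an
  internally evoked, oscillating one -- the asymmetry behind
  winner-take-all suppression versus coexistence.

The sheet units that are not declared words receive identical input
(gating only), so the simulator tracks them exactly with a single
background trajectory; tests assert this background stays below 0.05.

### Decision gate

The decision network opens ($z^L = 1$) only when every feature map shows
*exactly one* bubble continuously for a persistence interval (75 ms,
three gamma cycles). Because raw gamma activity dips below any threshold
each cycle, bubble detection operates on a sliding-window maximum of each
unit's activity (window 30 ms, at least one gamma period); this is the
instrument that makes "continuity of object perception" satisfiable by an
oscillating representation. Bubbles are maximal 4-connected components
above half-maximum activity (0.5, matching the sigmoid midpoint); any
violation resets the validity timer and closes the gate immediately.

### Three-phase Hebbian curriculum

All four trainable synapse groups start at zero and share one
soft-bounded Hebbian rule applied every 5 ms of simulated co-activity:

$$
\Delta W = \beta \left(1 - W/W_{max}\right) \cdot \text{post} \cdot \text{pre},
$$

clipped to $[0, W_{max}]$. The multiplicative factor is the simplest form
whose effective learning rate tapers to zero at saturation, and it makes
the constant-co-activation recurrence analyzable
($W_n = W_{max}(1 - (1 - \beta/W_{max})^n)$), which the tests exploit as
a closed-form oracle. Activities below a floor of 0.05 contribute
nothing: the lexical logistic has a nonzero baseline
($H(-\vartheta p) \approx 0.007$), and without the floor an untrained
word would slowly acquire weights from baseline activity alone,
contradicting the required zero-weight conservation for units never
co-active with a word. With the floor, that conservation is exact.

* **Phase i** presents each object (all features) alone and trains the
  inter-area feature synapses; within-area entries are structurally
  absent. Both directions learn independently and become symmetric under
  symmetric co-activation (asserted to within 1%). Afterwards any
  single-feature cue re-creates all bubbles (pattern completion).
* **Phase ii** presents the object together with its L1 word and trains
  feature-to-word and word-to-feature synapses in both directions; the
  word then evokes the object and vice versa.
* **Phase iii** presents the L1 word together with the new L2 word. L1
  retrieves the object; the L2 word's synapses to and from the feature
  maps grow, and the interneuron-to-word competition synapses grow
  between the two words (both words and hence both interneurons are
  active). Competition learning is restricted to cross-word entries: a
  word never learns inhibition from its own interneuron, which would
  contradict the sustained activity of externally stimulated words.
  Although the printed update rules of the source model cover only the
  feature-to-word and competition groups in this phase, the
  word-to-feature direction must also be trained -- without it the L2
  word could never evoke the object, the phase's defining outcome -- so
  the mirrored rule is applied there as well.

Proficiency is *measured*, not scheduled: after each phase-iii epoch the
ratio of the L2 word's feature-synapse norm to the L1 word's defines the
checkpoints -- `weak` at the first crossing of 0.3, `strong` at 0.9 --
so the experiment grid is robust to learning-rate choices.

## Scenario classification

Each scenario (stimulus x proficiency, plus the biased word-production
cases) reports a per-area bubble census, the dominant frequency of the
mean bubble activity (Hann-windowed, detrended, zero-padded spectrum over
the post-gate window), and one summary per word: the mean, over the
measurement window, of a 30-ms sliding-window maximum of the word's
activity. The windowed maximum -- the same instrument the decision gate
uses -- rates an oscillating word by the level its bursts reach; a plain
time average of a gamma-oscillating word hovers near half its burst
height and cannot be compared against qualitative "active/suppressed"
descriptions. Classification is `active` above 0.5 and `negligible`
below 0.1; the band between is reported loudly as `indeterminate` rather
than rounded to the nearer class, so threshold drift cannot silently
flip an outcome.

## Synthetic profiles

`generate_fixture("paper2010")` reproduces the reference configuration:
4 feature areas of 20 x 20 oscillators, a 40 x 40 lexical sheet, one
object (features at map position (10, 10), a package choice -- the
source figures do not print object coordinates), an L1 word at lexical
position (5, 5) and an L2 word at (20, 30). Stimuli are Gaussian bumps
(amplitude 3, spread 1 grid unit). On this profile the trained network
reproduces the full qualitative outcome grid: an untrained L2 word
evokes nothing; a weakly trained L2 word retrieves all four features
*and* co-activates L1, phase-locked to the object; a strongly trained L2
word retrieves the object while suppressing L1; L1 is autonomous at
every stage; an object evokes L1 only at low proficiency but both words
(conflict) at high proficiency; and a top-down bias on L1 yields
L2-only production, more active at high proficiency.

`generate_fixture("mini")` (2 areas of 8 x 8, 12 x 12 sheet) exists for
fast tests and carries its own weight ceilings, because feature-to-word
drive scales with bubble size. At this scale the margin between
"co-activate the rival word" and "suppress the rival word" at the weak
checkpoint becomes too narrow to satisfy both simultaneously, so the
mini-based tests assert the mechanisms (gating, binding, autonomy,
bias resolution, monotone acquisition) and the reference-scale suite
asserts the complete outcome grid.

What the generator does *not* emulate: multiple simultaneous objects
(the time-division segmentation of the underlying object-recognition
model is out of scope here), phoneme-level input (word input abstracts
the phoneme-to-lemma stage as a constant drive), feature extraction from
real sensory data, synaptic decay, or more than two languages. Passing
tests therefore demonstrate the internal consistency of the model under
its stated idealizations, not fidelity to empirical recordings.

## Numerical choices

* Explicit Euler at `dt = 0.05` ms (configurable; an error is raised if
  `dt` exceeds one tenth of the smallest time constant). Halving `dt`
  shifts the measured spectral peak by about 0.1 Hz, far below the 2 Hz
  acceptance band for convergence.
* Traces are recorded every 0.5 ms; at 40 Hz this still oversamples the
  rhythm fifty-fold while keeping scenario outputs compact.
* Spectral estimates remove the mean, apply a Hann window, zero-pad
  eightfold, and search 5--200 Hz; the post-gate measurement window
  (>= 250 ms at the default scenario length) gives a raw resolution
  better than 4 Hz, refined by padding. Flat traces report 0 Hz with
  zero power instead of a spurious peak.
* Phase lags come from the cross-correlation maximum with parabolic
  interpolation, wrapped into half a period; non-oscillatory inputs
  yield `NA` with a warning rather than a meaningless number.
* Coordinates are 1-based `(row, col)` in all configs and outputs,
  0-based only inside the compiled engine.
* The model contains no stochastic element; identical runs are
  bit-identical, which the test suite asserts.

## Problem sizes

The reference profile trains 8 object presentations, 12 L1
presentations, and as many phase-iii epochs as the proficiency ratio
requires (typically 9--11), each presentation 350 ms of simulated time;
scenarios run 600 ms. The full curriculum plus the 11-scenario grid
completes in well under a minute of wall time, and the mini profile runs
its whole curriculum in about a second.

## Known limitations

* The oscillator parameter set is one tuned representative of the gamma
  regime, not a fit to published values (the source model defers its
  oscillator constants to earlier work); only the regime itself is
  load-bearing, and the construction-time check enforces it.
* Whether the lexical layer should read the oscillator's excitatory
  sub-unit or a combination of both sub-units is not specified by the
  source; the package assumes the excitatory sub-unit and exposes
  `feature_output = "mean_pair"` as an alternative.
* Word-production conflict at high proficiency is resolved only by the
  external bias input; no autonomous control system is modeled.
* The mini profile's weak checkpoint cannot reproduce the L1
  co-activation and L2 suppression contrasts simultaneously (see above);
  use the reference profile for quantitative claims.
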