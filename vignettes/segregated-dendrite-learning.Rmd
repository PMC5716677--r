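---
title: "Deep learning with segregated dendrites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep learning with segregated dendrites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendritenet)
```

## The model

`dendritenet` simulates and trains spiking networks whose hidden neurons are
three-compartment units: a **basal** dendrite integrating bottom-up input, an
**apical** dendrite integrating top-down feedback, and a soma. The point of
the architecture is credit assignment without weight transport: feedback
about the output layer's error reaches each hidden neuron through its own
fixed synapses onto the apical compartment, which is electrotonically
segregated from the soma, so feedforward processing and the learning signal
coexist in one neuron without a separate feedback pathway.

Dendritic potentials are instantaneous weighted sums of filtered presynaptic
spike trains,

$$V^{b}_i(t) = \sum_j W_{ij}\, s_j(t) + b_i, \qquad
  V^{a}_i(t) = \sum_j Y_{ij}\, s^{\mathrm{out}}_j(t),$$

where each spike train is convolved with the unit-integral kernel
$\kappa(t) = (e^{-t/\tau_L} - e^{-t/\tau_s})\,\Theta(t)/(\tau_L - \tau_s)$
($\tau_s = 3$ ms, $\tau_L = 10$ ms). Somatic voltages relax toward
conductance-weighted mixtures of their dendritic drives,

$$\tau \dot V_i = (V_R - V_i)
  + \tfrac{g_b}{g_l}(V^{b}_i - V_i)
  + \tfrac{g_a}{g_l}(V^{a}_i - V_i),$$

with $\tau = C_m/g_l = 10$ ms, and units fire as Poisson processes at rate
$\phi_i = \phi_{\max}\,\sigma(V_i)$ with the logistic $\sigma$. Output-layer
neurons are two-compartment versions of the same dynamics (conductance
$g_d$) plus a somatic teaching current that, in the target phase, clamps the
correct unit toward the excitatory reversal ($E_E = 8$) and all others
toward the inhibitory reversal ($E_I = -8$).

All voltages are dimensionless values on the model's native scale (rest 0,
dendritic initialisation range $[-6, 12]$). Rates are kept in **spikes/ms**
internally ($\phi_{\max} = 0.2$, i.e. 200 Hz): filtered spike trains and
firing rates then live on the same scale, which the firing-rate lemma (below)
requires, and it fixes the gradient scaling factors at $P_0 = 20/\phi_{\max}
= 100$ and $P_1 = 20/\phi_{\max}^2 = 500$. Hz appears only in reports.

## Phases, plateau potentials and the learning rules

Each training example drives the input layer as Poisson units with rates
proportional to pixel intensity. The network then undergoes a **forward
phase** (teaching current off) and a **target phase** (teaching current on),
each lasting 50 ms plus a Wald(mean 2 ms, shape 1) extra, sampled
independently per phase. Time averages within a phase exclude the first
$\Delta t_s = 30$ ms so the dynamics settle first. At the end of each phase,
every hidden neuron computes a **plateau potential**: the sigmoid of its
time-averaged apical voltage over the post-settle window,
$\alpha^f_i$ and $\alpha^t_i$. Plateaus are pure credit-assignment
quantities; they never feed back into the voltage dynamics.

Targets and losses:

* output: $\phi^{1*} = \bar\phi^{1,t}$ (target-phase average rates), with
  $L_1 = \lVert \phi^{1*} - \phi_{\max}\sigma(\bar V^{1,f}) \rVert_2^2$;
* hidden: $\phi^{0*} = \bar\phi^{0,f} + \alpha^t - \alpha^f$, with
  $L_0 = \lVert \phi^{0*} - \phi_{\max}\sigma(\bar V^{0,f}) \rVert_2^2$,
  which is approximately $\lVert \alpha^t - \alpha^f \rVert_2^2$ when rates
  sit in the sigmoid's linear region.

At the end of every target phase the weights take one gradient-descent step,
$W \leftarrow W - \eta P \, \partial L/\partial W$, with

$$\partial L_1/\partial W^1 =
  -k_d\,\phi_{\max}(\phi^{1*} - \phi_{\max}\sigma(\bar V^{1,f}))\,
  \sigma'(\bar V^{1,f}) \circ \bar s^{0,f},
\qquad
\partial L_0/\partial W^0 =
  -k_b\,(\alpha^t - \alpha^f)\,\phi_{\max}\sigma'(\bar V^{0,f})
  \circ \bar s^{\mathrm{in},f},$$

where $k_d = g_d/(g_l + g_d)$ and $k_b = g_b/(g_l + g_b + g_a)$ are the
steady-state dendro-somatic attenuation factors. The hidden rule is
spatially local: it uses only the neuron's own plateaus, its mean forward
voltage and its presynaptic traces. Targets are treated as constants under
differentiation — learning shapes the forward phase to reproduce the target
phase, never the other way round.

**Gradient convention.** The reported losses are full squared norms, while
the update formulas above are the exact gradients of the corresponding
*half*-squared errors (the factor 2 is folded into the learning rate, as
usual for delta rules). The package keeps both conventions deliberately:
`losses()` reports $\lVert\cdot\rVert_2^2$, and the gradient operations are
validated against central-difference derivatives of
$\tfrac12\lVert\cdot\rVert_2^2$ to better than $10^{-6}$ relative error.

With several hidden layers, every hidden layer receives feedback directly
from the output layer through its own fixed random matrix, so no backward
pass through intermediate layers exists. Hidden targets default to the
forward-phase baseline $\bar\phi^{k,f} + \alpha^t - \alpha^f$; a
`target_baseline = "target"` switch selects the variant that baselines on
the target-phase average instead. With total apical segregation
($g_a = 0$) the two coincide in expectation; we default to the forward
baseline because it keeps the loss interpretation ("move the forward phase
toward the target phase") exact.

Feedback-weight variants reproduce the published manipulations: `random`
(fixed uniform draw with the same $[-6, 12]$ dendritic calibration as the
feedforward weights — the assumption that feedback uses the same
initialisation is ours), `sparse` (80% of entries zeroed, survivors
multiplied by five), `symmetric` ($Y = W^{1\top}$, refreshed after every
update), and `symmetric_noise` ($Y = W^{1\top} + E$). The published
description of the noise is "a normal distribution with variance
$\sigma = 0.05$"; since the symbol is $\sigma$, we read 0.05 as the standard
deviation (a `noise_as = "variance"` option gives the other reading), and we
draw $E$ once at construction so the perturbation is a fixed offset from the
moving symmetric target.

## Integration and numerical choices

* Forward Euler with $dt = 1$ ms ($dt \le \tau/5$ enforced); per step the
  update order is dendritic potentials → somatic potentials → spikes,
  layers bottom-to-top, so each layer sees the input layer's current-step
  traces and the output layer's previous-step feedback.
* Synaptic filtering uses two exponential accumulators per source (decay
  $e^{-dt/\tau_L}$, $e^{-dt/\tau_s}$) rather than stored spike times;
  equality with direct convolution is a tested property ($<10^{-9}$).
* Phase durations are continuous draws rounded to whole steps; the plateau
  "integral" is the arithmetic mean of per-step apical voltages over the
  window.
* In the stochastic-plateau variant each neuron's plateau time is drawn from
  a folded normal ($\mu = 0, \sigma^2 = 3$) truncated at 5 ms before phase
  end, and its 30 ms averaging window may reach back into the settle period
  (but never before the phase start) — the published description does not
  resolve this boundary, so we allow it.
* The teaching current is scaled by $1/g_l$ by default (`teach_scale =
  "inverse_leak"`), putting it on the same ratio units as the dendritic
  terms; taken literally, a unit conductance could not saturate the clamped
  unit. With the scaling, the clamped unit settles at $V = 4.706$ (99.1% of
  $\phi_{\max}$) and the silenced units below 1% of $\phi_{\max}$.
* Classification reads out the output unit with the greatest time-averaged
  somatic potential over a 500 ms forward phase; ties break to the lowest
  index. Trials start from rest; each phase's averages exclude the settle
  window exactly.
* One global R RNG stream drives everything (initialisation, shuffles, phase
  lengths, plateau times, spikes) in a documented order, so a run is a pure
  function of its seed; the compiled engine consumes the same stream as the
  pure-R reference simulator and is tested to match it.

## Validation machinery

**Firing-rate lemma.** The time-averaged filtered spike train estimates the
mean rate once the window is long relative to the bound
$2\tau_L^2\tau_s^2\bar{\phi^2}/((\tau_L-\tau_s)^2(\tau_L+\tau_s))$ — about
0.001 at the simulation parameters, far below the 50 ms minimum phase.
`lemma1_mc_check()` verifies this by simulation. Its default includes a
100 ms burn-in so the filter is stationary, mirroring how the network takes
averages after a settle period mid-stream; a cold-started window
(`burn_in = 0`) instead shows the lemma's edge deficit, about
$(\tau_L+\tau_s)/\Delta t$ in relative terms.

**Backpropagation oracle.** `backprop_oracle_update()` computes the
hidden-layer gradient that exact backpropagation through the deterministic
rate model $\phi_{\max}\sigma(k_d W^1 \phi_{\max}\sigma(k_b W^0 x + b^0) +
b^1)$ would prescribe (no explicit update formula is published for it; we
define it as this exact gradient and verify it by finite differences). The
angle between the local and oracle updates is computed on weight matrices
only (biases excluded, row-major flattening) and smoothed with a trailing
100-presentation window. Independent high-dimensional vectors sit at
$90^\circ$; sustained angles below $90^\circ$ indicate the local rule points
with backpropagation. The first $\sim$200 presentations start near
orthogonality before alignment develops, so windows straddling them sit at
$\approx 90^\circ$.

**Loss coordination.** Per-class Pearson correlation between per-image $L_0$
and $L_1$, against a control that re-pairs $L_0$ with $L_1$ by permutation
within the class.

**Jacobian eigenvalue monitor.** With $\beta(x) = \phi_{\max}\sigma(k_d W^1
x)$ and $\gamma(x) = \sigma(Y x)$, coordination between the layers' losses
is guaranteed while $\mu$, the largest eigenvalue of $(I - J_\beta
J_\gamma)^\top (I - J_\beta J_\gamma)$, is below 1.
`jacobian_product_eigenvalue()` evaluates the Jacobians at the elementwise
mean activity of the last 100 training examples (one documented reading of
"mean Jacobian matrices"; averaging per-example Jacobians gives the same
qualitative picture) and includes the output bias in the operating point, so
$J_\beta$ is the Jacobian of the network's actual forward transform at its
actual working voltages — without the bias the monitored quantity grows even
as the losses coordinate, which marks that reading as the wrong one. On the
scaled-down task $\mu$ starts an order of magnitude above 1 and decreases
steadily as training proceeds; reaching $\mu < 1$ takes substantially more
than the 2,000 updates of one scaled-down epoch (the behaviour reported on
the full 60,000-image task developed within its much longer first epoch).

## The synthetic task

`synthetic_dataset()` generates class-structured grayscale intensity
vectors: per class a fixed smooth random prototype in $[0,1]$ (smoothed
Gaussian noise, min-max rescaled), plus i.i.d. Gaussian pixel noise, clipped
to $[0,1]$. It emulates what the learning problem needs from image data —
bounded intensities encodable as Poisson rates, within-class variability
around a stable class structure, guaranteed class separability (a one-pass
nearest-class-mean classifier on the training draw must reach at least 95%
accuracy, or generation aborts). It deliberately does **not** emulate 2-D
spatial structure, stroke-like features, multimodal within-class styles,
heavy-tailed pixel statistics or label noise. Clipping at the intensity
boundaries slightly biases class means at extreme pixels, which the
generator's distribution-recovery test accounts for by checking interior
pixels.

Two consequences of this design are worth stating plainly. Because the
classes are unimodal Gaussian blobs around linearly separable prototypes, a
shallow delta-rule network is already near-optimal on the task: at the
default settings every architecture reaches (near-)zero test error within a
few epochs, so the synthetic task validates the *mechanism* — that the
network learns, that local updates align with backpropagation, that hidden
and output losses coordinate — and not the comparative, asymptotic
advantages of depth or of particular feedback structures, which on the full
image benchmark emerge over tens of 60,000-image epochs. The
`class_contrast` parameter (prototypes shrunk toward their common
background) exposes harder regimes; there the scaled training horizon sits
inside the learning transient, where the shallow network (which has no
credit-assignment machinery to develop) leads the deep local learner, the
mirror image of the asymptotic ordering.

The validation profile used throughout the tests and the acceptance script
is 10 classes, 64 inputs, 200 training and 100 test examples per class,
noise sd 0.08, networks 64-100-10 (one hidden layer), 64-10 (shallow) and
64-100-20-10 (two hidden), with up to 3 epochs and 5 seeds for the
depth/feedback comparisons — sizes that keep a full validation run on a
laptop-class machine. Learning rates follow the published depth-specific
values (0.19 shallow; 0.21/0.21 one hidden; 0.23/0.23/0.12 two hidden),
taken as given.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
train_data <- synthetic_dataset(n_classes = 10, input_dim = 64,
                                n_per_class = 200, noise_sd = 0.08)
test_data <- synthetic_dataset(n_classes = 10, input_dim = 64,
                               n_per_class = 100, noise_sd = 0.08,
                               check_separability = FALSE,
                               prototypes = train_data$prototypes)
net <- dendrite_network(64, hidden = 100, n_classes = 10)
fit <- train(net, train_data, epochs = 3, test_data = test_data,
             track_angle = TRUE)
tidy(fit)              # per-epoch test error, losses, eigenvalue monitor
plot_update_angles(fit)
loss_correlation(dplyr::filter(fit$presentations, epoch == 2))
```

## Known limitations

* Poisson spiking without refractoriness or bursts; the burst-based
  molecular-memory mechanism sketched alongside the published model is
  excluded by design, as is learning on the feedback weights.
* No convolution/pooling, momentum, dropout or mini-batches — training is
  strictly on-line, matching the published protocol.
* The backprop-angle comparison supports one hidden layer (the published
  comparison's scope).
* The Jacobian monitor is a 10-dimensional eigenvalue of a learned
  quantity; at desk scale it certifies the *trend* toward the coordination
  condition rather than its attainment (see above).
* t-SNE embeddings of hidden activity are out of scope; the package exposes
  the activity matrices for external embedding tools instead.
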