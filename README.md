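# dendritenet

Deep learning with segregated dendrites: an R package that simulates and
trains spiking neural networks whose hidden neurons receive bottom-up input
in **basal** dendritic compartments and top-down feedback in electrotonically
segregated **apical** compartments, and that learn with local,
plateau-potential-driven weight updates — solving the credit assignment
problem without the "weight transport" that backpropagation requires.

It is aimed at computational neuroscientists and students of biologically
plausible learning who want a compact, fully reproducible implementation of
the multi-compartment learning algorithm together with the analyses used to
validate it.

## The model in brief

Hidden-layer neurons integrate filtered presynaptic spike trains
(double-exponential kernel, τ_s = 3 ms, τ_L = 10 ms) in their dendrites and
relax somatically as leaky integrators,

    τ dV/dt = (V_R − V) + (g_b/g_l)(V_b − V) + (g_a/g_l)(V_a − V),

firing as Poisson processes at rate φ_max·σ(V). Training alternates a
**forward phase** (no teaching signal) and a **target phase** in which a
conductance-based teaching current clamps the correct output unit to its
maximal rate and silences the rest. At each phase end every hidden neuron
computes a **plateau potential** α = σ(mean apical voltage), and weights
update by gradient descent on local losses:

    ΔW¹ ∝ k_d φ_max (φ¹* − φ_max σ(V̄¹f)) σ′(V̄¹f) ∘ s̄⁰f        (output)
    ΔW⁰ ∝ k_b (αᵗ − αᶠ) φ_max σ′(V̄⁰f) ∘ s̄ⁱⁿf                  (hidden)

with attenuation factors k_d = g_d/(g_l+g_d), k_b = g_b/(g_l+g_b+g_a). The
feedback weights Y are fixed (random by default; sparse, symmetric and
noisy-symmetric variants are built in), yet the hidden updates come to align
with explicit backpropagation — the package ships the backprop oracle, the
update-angle analysis, the hidden/output loss-coordination analysis, and the
Jacobian-product eigenvalue monitor used to check the alignment condition,
plus a Monte-Carlo check that time-averaged filtered spike trains estimate
firing rates.

Everything runs on a built-in synthetic dataset generator (class-structured
intensity vectors in [0,1]); MNIST IDX files are read natively when a local
copy is available, but nothing is downloaded.

## Worked example

Train a one-hidden-layer network (64-100-10) on the synthetic task and look
at the standard analyses:

```r
library(dendritenet)
set.seed(1)

train_data <- synthetic_dataset(n_classes = 10, input_dim = 64,
                                n_per_class = 200, noise_sd = 0.08)
test_data  <- synthetic_dataset(n_classes = 10, input_dim = 64,
                                n_per_class = 100, noise_sd = 0.08,
                                prototypes = train_data$prototypes,
                                check_separability = FALSE)

net <- dendrite_network(input_dim = 64, hidden = 100, n_classes = 10)
fit <- train(net, train_data, epochs = 3, test_data = test_data)
tidy(fit)
```

```
# A tibble: 4 × 5
  epoch test_error mean_loss_output mean_loss_hidden jacobian_mu
  <int>      <dbl>            <dbl>            <dbl>       <dbl>
1     0         90         NA                 NA           NA
2     1          0          0.0242             1.44         1.75
3     2          0          0.00524            0.837        1.57
4     3          0          0.00240            0.676        1.25
```

The `test_error` column is the percentage of held-out examples whose
500 ms forward phase put the highest average somatic potential on the wrong
output unit: the untrained network (epoch 0) sits at the 90% chance level
and a single epoch of local plateau-driven updates solves this (deliberately
easy) task; the `class_contrast` argument of `synthetic_dataset()` exposes
harder regimes. `mean_loss_output` is the mean
squared distance between forward-phase output rates and the teaching-imposed
targets (spikes/ms scale); `jacobian_mu` is the eigenvalue monitor of the
feedforward/feedback alignment condition (it decreases toward 1 as the
network *learns to assign credit*). `plot_update_angles(fit)` (after
training with `track_angle = TRUE`) shows the angle between the local hidden
updates and the backpropagation oracle falling below 90°, and
`loss_correlation(subset(fit$presentations, epoch == 2))` gives the
per-class correlation between hidden and output losses against a
shuffled-pairing control.

A command-line front end is installed with the package
(`exec/dendritenet`): `dendritenet train --dataset synthetic --epochs 3`,
`dendritenet grid --feedback sparse`, `dendritenet analyze --what lemma1`,
etc.

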