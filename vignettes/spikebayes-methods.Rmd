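---
title: "Frequentist and Bayesian learning rules for spiking networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequentist and Bayesian learning rules for spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikebayes)
```

# The neuron and network model

`spikebayes` simulates layered feedforward networks of discrete-time
spike-response-model (SRM) neurons. Neuron $i$ emits a binary spike
$s_{i,t} = \Theta(u_{i,t} - \vartheta)$ when its membrane potential reaches
the threshold $\vartheta$; the potential is a weighted sum of filtered
pre-synaptic activity minus a refractory trace of its own spikes,

$$u_{i,t} = \sum_{j} w_{ij}\,(\alpha * s_j)_t - (\beta * s_i)_t ,$$

with the alpha-function synaptic kernel
$\alpha_t = e^{-t/\tau_{\mathrm{mem}}} - e^{-t/\tau_{\mathrm{syn}}}$ and the
exponentially decaying refractory kernel of magnitude $e^{-t/\tau_{\mathrm{ref}}}$.
This is the standard discrete-time leaky integrate-and-fire model written as
a filter network; both kernels admit exact one-step autoregressive updates
(two exponential accumulators for $\alpha$, one for the refractory trace),
which is what `step_filters()` implements and `alpha_kernel()` /
`beta_kernel()` verify against.

Three conventions are fixed deliberately:

* **Inclusive threshold.** $\Theta(0) = 1$: a neuron at exactly threshold
  fires. Any tie-break is arbitrary; this one is documented and tested.
* **Strict causality.** Convolutions use only strictly past spikes: a spike
  at step $t$ first influences any potential at $t+1$. The $\alpha$ kernel
  vanishes at lag zero, so feeding the current step's pre-synaptic spikes into
  the accumulators realizes this automatically and avoids an instantaneous
  self-reset.
* **Refractory sign.** The self-feedback term is *subtracted* as a positive
  decaying trace of the neuron's own spikes, i.e., it hyperpolarizes. This is
  the standard refractory mechanism; writing the kernel with a negative sign
  and subtracting it again would instead produce runaway self-excitation.

Defaults are $\tau_{\mathrm{mem}} = 20$, $\tau_{\mathrm{syn}} = 5$,
$\tau_{\mathrm{ref}} = 10$ steps, with $\vartheta = 1$ for real-valued
weights, $\vartheta = \sqrt{\text{fan-in}}$ for binary $\pm 1$ weights, and
$\vartheta = 64$ offered for fixed-point emulation. The time constants are
package choices (the underlying model family does not prescribe them); all
are configurable through `filter_params()` and `layered_srm()`.

# Local losses and the three-factor surrogate gradient

Every trainable layer $l$ owns a fixed random read-out matrix
$B^{(l)} \in \mathbb{R}^{C\times |l|}$ (i.i.d. standard normal, generated
once from `readout_seed`, never trained). At each step the layer is scored
by the cross-entropy between the one-hot target and
$\mathrm{Softmax}(B^{(l)} s^{(l)}_t)$ (`local_loss()`), and learns only from
that local signal: gradients never propagate across layers or across time,
and the pre-synaptic trace is treated as a constant. The weight gradient
factorizes into the three-factor form

$$\frac{\partial L_t}{\partial w_{ij}} = e_{i,t}\cdot
\sigma'(u_{i,t}-\vartheta)\cdot (\alpha * s_j)_t ,$$

where $e_{i,t}$ is the analytic derivative of the local loss with respect to
the layer's spikes (`error_signal()`), the sigmoid derivative replaces the
zero-almost-everywhere threshold derivative (`post_sensitivity()`, slope 1
by default), and the pre-synaptic trace is available from the forward state.
Updates are applied online, once per time-step, from batch-averaged
gradients; each mini-batch element runs as an independent network replica.

The gradient checks replace $\Theta$ by $\sigma$ throughout
(`srm_forward(..., relaxed = TRUE)`) and compare accumulated three-factor
gradients against central finite differences of each layer's relaxed local
loss. The oracle network disables the refractory feedback: with it, a
neuron's own past spikes re-enter its potential, a dependence the local rule
deliberately ignores; without it, the per-layer loss is an exact function of
that layer's weights and the comparison is meaningful to machine precision.

Binary synapses train with the straight-through estimator: real latent
weights receive the SGD update evaluated at the binarized weights, and the
forward weights are always $\mathrm{sign}(w^r)$ with
$\mathrm{sign}(0) = +1$. The forward pass never sees a non-binary weight.

# Bayesian learning as information risk minimization

Both Bayesian learners minimize the variational free energy
$F(q) = E_q[L_D(w)] + \rho\,\mathrm{KL}(q \| p)$ over a mean-field family,
using natural-gradient ("Bayesian learning rule") updates. $\rho$
interpolates between pure empirical risk ($\rho = 0$) and pure prior
adherence; the unconstrained minimizer is the Gibbs posterior
$p(w)e^{-L_D(w)/\rho}$ (normalized), which `gibbs_free_energy()` enumerates
on small problems as the lower bound every factorized solution must respect.

**Gaussian posterior (real-valued synapses).** Each weight has mean $m$ and
precision $p$. Per update, weights are sampled from the current posterior
(one shared sample across the mini-batch per Monte-Carlo draw; `n_mc = 1` by
default), surrogate gradients are computed at the sample, and

$$p \leftarrow (1-\eta\rho)p + \eta\,(\overline{g^2} + \rho p_0),\qquad
m \leftarrow m - \eta\, p^{-1}(\bar g - \rho p_0 (m_0 - m)),$$

precision first, mean second (the mean update uses the advanced precision).
The square sits inside the per-example average. `eta * rho < 1` is enforced
so the precision update remains a convex combination, and precisions are
floored at `p_floor = 1e-6` against numerical collapse. The growing
precision of well-constrained synapses shrinks their effective step size —
the same stabilizing role that metaplasticity counters play in the
biologically inspired rule below.

Two initialization choices matter in practice and are package decisions:
the posterior *means* start at a standard random weight initialization
rather than at the prior mean (an all-zero spiking network is silent, emits
no gradient structure, and cannot bootstrap), while precisions start at the
prior's. The per-epoch free-energy trace uses sampled dataset losses plus
the closed-form Gaussian KL.

**Bernoulli posterior (binary synapses).** Each weight holds a logit $w^r$
with $P(w{=}+1) = \sigma(2w^r)$ and mean $\mu = \tanh(w^r)$. Training
samples *relaxed* weights $w = \tanh((w^r + \delta)/\tau)$ with logistic
noise $\delta$ (the Gumbel-softmax reparameterization for two categories),
runs the network forward with those real-valued weights (the spiking
dynamics stay binary), and converts the surrogate gradient through the
chain-rule multiplier $(1-w^2)/(\tau(1-\tanh^2 w^r))$ before the logit
update $w^r \leftarrow (1-\eta\rho)w^r - \eta(\bar g_\mu - \rho w_0^r)$.
Inference always uses hard $\pm 1$ samples (`hard_sample()`), the
$\tau \to 0$ limit with $\mathrm{sign}(0) = +1$.

The estimator is unbiased only as $\tau \to 0$, where its variance diverges;
$\tau = 1$ is the training default and smaller values are used where
fidelity to the exact gradient matters (the enumeration checks run at
$\tau = 0.05$–$0.5$). Two numerical safeguards are built in and tested:
the multiplier is defined as zero when the relaxed sample saturates exactly
(avoiding 0/0), and logits are clipped at $\pm 10$ after every update —
probabilities within $2\times 10^{-9}$ of 0 or 1, so the clip is
behaviorally inert, but it removes the heavy-tailed kicks the multiplier
produces at saturated logits.

# Continual learning

A task stream presents labeled datasets sequentially; task boundaries are
known during training, task identity is never used at test time (a single
read-out over all classes serves every task). Four trainers share this
protocol:

* **Plain sequential SGD** (`train_ewc()` with `alpha = 0`, no coresets):
  the catastrophic-forgetting baseline.
* **EWC with coresets**: the quadratic penalty
  $\alpha \sum_k (w - w^{(k)})^\top \mathrm{diag}(F^{(k)}) (w - w^{(k)})$
  anchors weights to each completed task's solution, weighted by the
  summed-squared-gradient Fisher diagonal (`fim_diag()`).
* **Biologically inspired rule** (`train_continual_bio()`): per-synapse
  metaplasticity counters $\nu$ grow when pre- and post-synaptic rates both
  exceed a threshold and damp updates by $e^{-|\nu w|}$; a reference weight
  tracks the current weight and pulls it back when the post-synaptic neuron
  is active (heterosynaptic drift). The error signal reuses the same local
  read-out error as the gradient rules — the rule's original formulation
  delegates this signal, and the local error is the natural instantiation
  here.
* **Bayesian continual learning**: task $k$ minimizes the free energy with
  the *previous posterior as prior* (the handoff is bit-identical and
  tested), plus replayed coresets.

Coresets are class-balanced uniform random subsets (round-half-up per
class). The continual objective adds one *mean* loss term per coreset, so
each past task carries the same weight as the current one regardless of
sizes; with uniform mini-batches over a pooled dataset this is realized by
upsampling each coreset to the current training-set size. Plain
proportional pooling was evaluated and gives past tasks only a ~10% share
of the gradient signal, which is not the stated objective and retains
noticeably less.

# Prediction and calibration

Predictive probabilities average the softmax of the read-out layer's
projected spikes over time; Bayesian predictions additionally average over
$N_S$ posterior draws (default 10), either redrawn per input (*ensemble*)
or drawn once and reused (*committee*). Both modes share one sampling law,
so their expected predictions coincide; their realized gap shrinks as
$N_S$ grows, which the test suite checks at $N_S \in \{1, 10, 100\}$.
Argmax ties break toward the lowest class index.

Reliability analysis bins confidences into $M = 10$ half-open intervals
$((m-1)/M,\, m/M]$; the expected calibration error is the count-weighted
mean absolute gap between per-bin confidence and accuracy. Empty bins stay
in the report with zero weight. A four-example hand-worked case pins the
binning and ECE arithmetic exactly, and a synthetic self-consistent
decision set (correctness drawn Bernoulli(confidence), $n = 10^5$) must
produce ECE below 0.01.

# Encoders and synthetic tasks

Population encoding gives each input dimension `n_units_per_dim` neurons
with Gaussian tuning curves, centers evenly spaced on $[0,1]$ and width
defaulting to the center spacing; spikes are i.i.d. Bernoulli per step at
the tuning-curve rate. (The probabilistic sampling, the Gaussian form, and
the width are package choices; deterministic thresholded rates would be an
equally defensible instantiation.) Inputs are min–max rescaled with
statistics frozen on the training set. Out-of-range inputs are rejected by
default; the out-of-distribution evaluation pipeline instead *clips* them
to the covered range — the saturation behavior of bounded tuning curves —
because with narrow curves a far-away point would otherwise encode to
silence and force every predictor to the same uniform output, leaving
nothing to compare. Rate encoding maps values in $[0,1]$ directly to
per-step Bernoulli rates.

The spike-template stream stands in for split-class image benchmarks at
desk scale: each class owns a fixed binary template raster, examples are
bit-flipped copies, and tasks present the classes in consecutive pairs. In
`"orthogonal"` mode the (neuron, time) cells are partitioned among classes,
making templates exactly orthogonal while every neuron still serves several
classes — the sharing that makes catastrophic forgetting possible at all.
(Disjoint *neuron blocks* were evaluated and trivially prevent forgetting,
because gradient updates are gated by pre-synaptic activity.)

The two-moons generator uses the common parametrization
(moon 0: $(\cos\theta, \sin\theta)$; moon 1:
$(1-\cos\theta,\, 0.5-\sin\theta)$, $\theta \sim U[0,\pi]$) with isotropic
Gaussian noise, 200 points per class and $\sigma = 0.1$ by default.

# Study problem sizes

The bundled experiments are sized to run in minutes on one CPU core:

* `experiment_two_moons_uncertainty()`: 200 training / 500 held-out points
  per class, 10 encoding neurons per dimension over $T = 50$ steps, one
  hidden layer of 64, 15 epochs; Bayesian learner at $\rho = 0.01$,
  $\eta = 0.2$; far field = grid points on $[-4,4]^2$ more than 3 away from
  every training point.
* `experiment_continual_contrast()`: 4 classes in 2 tasks, 32 neurons
  $\times$ 20 steps templates, 40 training / 20 test examples per class,
  hidden layer of 50, 15 epochs per task, 3 repeats; coresets of 10%
  (Bayesian) and 7.5% (EWC).

$\rho$ and the learning rates are not prescribed by the model family; the
values above were chosen once, during development, as the middle of the
range in which the Bayesian learner both fits the data and retains
measurable posterior spread.

# What the synthetic benchmarks do and do not show

The template stream has stationary, noiseless class structure with
i.i.d. bit flips; the two moons are a two-dimensional toy. Passing the
bundled checks demonstrates that the learning rules optimize their stated
objectives, that the Bayesian rules retain prior tasks and withhold
confidence off-distribution, and that the calibration arithmetic is exact —
it does not demonstrate performance on event-camera data, large networks,
or hardware-constrained arithmetic, all of which are out of scope here.

Known limitations worth stating plainly:

* On an essentially separable task (two moons at $\sigma = 0.1$) both
  learners are *under*-confident on held-out data, because the
  time-averaged softmax includes the network's silent warm-up steps. In
  that regime ECE reduces to accuracy minus mean confidence, so posterior
  averaging — which necessarily lowers confidence — cannot deliver a lower
  held-out ECE than the frequentist point estimate, even while it delivers
  the intended, and observed, confidence reduction far from the data. The
  calibration advantage of Bayesian averaging is a claim about regimes with
  real epistemic error, not about separable toys.
* Mean-field Gaussian VI with single-sample natural-gradient updates leaves
  the precision near its prior value when per-step gradients are small;
  posterior contraction is driven by the accumulated squared-gradient
  signal, not guaranteed.
* The Gumbel-softmax gradient trades bias (large $\tau$) against variance
  (small $\tau$); the enumeration checks quantify where the trade sits on
  small problems only.

# Reproducibility

Every stochastic component threads an integer seed: generators, encoders,
initializations, trainers, and posterior sampling. Checkpoints (JSON),
metric traces (JSON/CSV), and stream manifests (YAML) carry the resolved
configuration and seed needed to regenerate them, and the test suite
asserts bit-identical re-runs for the trainers and generators.
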