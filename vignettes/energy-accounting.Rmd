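---
title: "Energy accounting for synaptic plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy accounting for synaptic plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastenergy)
```

## The problem

Biological learning is metabolically expensive: changing a synapse costs
energy, and a network trained by backpropagation changes *every* synapse on
*every* trial. `plastenergy` simulates single-hidden-layer perceptrons
trained by per-sample SGD while keeping an exact account of the plasticity
energy, and implements the restriction strategies — fixed masks, coordinated
plastic subnetworks, competitive top-k selection, and two-compartment
synaptic caching — that reduce that cost while preserving learning.

## The energy model

For applied weight changes $\Delta w_{ij}(t)$ the cost family is

$$M_\alpha = \sum_{i,j,t} |\Delta w_{ij}(t)|^\alpha ,$$

with two members of primary interest:

* $M_0$ (limit $\alpha \to 0$): the **number of non-zero updates**,
  implemented as a direct count with an exact-zero test. This is the natural
  cost model when initiating any change dominates (tag setting, or memory
  writes in hardware).
* $M_1$ ($\alpha = 1$): the **accumulated absolute weight change**, the
  natural model when the amount of change dominates (e.g. protein
  synthesis).

The model assumes spatial and temporal independence of synaptic costs (the
total is a plain sum over synapses and steps) and, by default, equal cost
for potentiation and depression. A potentiation-only variant charges only
$\Delta w > 0$; on a standard run it accumulates close to half of the full
$M_1$, because training is dominated by weights wandering up and down.

Because inputs are zero-meaned (see below), the update
$\Delta w = -\epsilon\,\delta\,x$ is non-zero for essentially every synapse
on every sample, so for unrestricted training $M_0$ equals the synapse count
times the number of sample presentations *exactly* — an identity the test
suite asserts literally.

## Network and training

The network is `n_in`–`N_h`–`n_out`, all-to-all, with biases treated as
synapses from a constant-1 input (they are masked and charged like any
other synapse; their share of the energy is a fraction of a percent).
Hidden units use a leaky rectifier ($g(x)=x$ for $x \ge 0$, $\beta x$
otherwise, $\beta = 0.1$) so that no hidden unit silences its outgoing
plasticity; outputs are linear and trained on mean squared error against
one-hot targets ($\delta^{\rm out} = y - t$), because cross-entropy with
softmax only vanishes at diverging weights and is therefore energy-inefficient.
Both a plain-ReLU and a softmax/cross-entropy variant are available as
configuration switches for robustness checks.

Defaults (all overridable in `training_config()`):

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.01 | fixed SGD rate; compromise at which $M_0$ and $M_1$ can be compared on one run |
| `init_sd` | 0.01 | sd of Gaussian weight initialisation |
| `criterion_accuracy` | 0.95 | validation accuracy stopping criterion |
| `eval_every` | 1000 | presentations between validation checks |
| $\beta$ | 0.1 | leak slope of the hidden activation |

Updates are applied after every sample (no batching — biologically, batching
would require storing updates across trials), in a fresh uniform shuffle per
epoch. Everything is deterministic given the config seed.

## Restriction strategies

`strategy_spec()` declares which proposed updates survive:

* **dropconnect** — fresh Bernoulli mask per trial (with a per-class
  persistent variant). Included as a control; it slows learning without
  saving energy.
* **fixed synapse mask** — Bernoulli($f_0$) over input-layer and
  Bernoulli($f_1$) over output-layer synapses, drawn once. The optimal
  densities follow from a counting argument: criterion learning needs about
  $\mu$ (default 100) plastic input→hidden→output *paths*; random masks
  leave $f_0 f_1 N_h$ of them, while energy is proportional to the plastic
  synapse count $m(f_0,f_1) = n_{\rm in} N_h f_0 + n_{\rm out} N_h f_1$.
  Minimising $m$ under the path constraint gives
  $f_1^* = \min\!\big(1, \sqrt{\mu n_{\rm in}/(N_h n_{\rm out})}\big)$,
  $f_0^* = \mu/(N_h f_1^*)$ (`optimal_fractions()`). The printed source
  for the $f_1^* < 1$ boundary is garbled; the re-derivation in
  `?mask_problem` gives $\mu n_{\rm in}/n_{\rm out} = 7840 \approx 8000$
  for the defaults, consistent with the quoted magnitude, and the closed
  form is verified against dense grid search in the tests.
* **fixed neuron mask** — freeze the back-propagated error outside a fixed
  subset of hidden units; input-layer plasticity is restricted to that
  subset, the output layer stays fully plastic.
* **subnet** — coordinated plasticity: incoming *and* outgoing synapses of
  the subset are the only plastic ones, so plastic synapses form paths.
  The energy per iteration then depends only on the subnet size, not on the
  embedding network size (asserted exactly, per iteration, in the
  acceptance suite).
* **top-k** — competitive selection recomputed every trial: keep the
  $\lceil k \rceil$ largest-|Δw| proposed input-layer updates (per layer or
  per neuron); the output layer always updates. Unlike a fixed mask this
  does not pin the support: the inverse Simpson index
  $q = 1/(N\sum_i p_i^2)$ of the realised update distribution stays well
  above $k/N$. Exploratory variants select whole neurons by error or
  activity magnitude instead; they are off by default.

## Synaptic caching

`cache_state()` splits each weight into a persistent component and a
decaying transient component (effective weight = sum). Per sample the order
is fixed: decay by $(1-\lambda)$ → add the restricted deltas → consolidate
every entry with $|w^{\rm trans}| \ge \theta$ (move into $w^{\rm pers}$,
charge one $M_0$ event and $|w^{\rm trans}|$ of $M_1$, reset) → charge the
maintenance cost $c\sum_i |w^{\rm trans}_i|$. Defaults: $\lambda = 10^{-3}$
per presentation, $c = 0.01$. The decay-first order is a deliberate choice
the source leaves open: it makes $\theta = 0$ *bit-identical* to vanilla
training, which anchors the ledger identities. Consolidation is per-synapse
(threshold on the individual transient magnitude), and caching composes with
any restriction strategy — under a subnet, both compartments are restricted.

## The synthetic data world

`make_synthetic()` draws one Gaussian prototype per class (sd
`prototype_scale`) and adds i.i.d. Gaussian noise, then zero-means per
feature with the training means (validation data is shifted by the *train*
means, standard practice). Defaults — 784 features, 10 classes, 2000
training samples, prototype scale 1, noise sd 0.5 — emulate the geometry of
zero-meaned MNIST and are calibrated so a 30-hidden-unit network reaches
the 95% criterion within a few epochs, which the suite asserts.

What the generator does *not* emulate: MNIST's manifold structure,
pixel correlations, and class overlap. Consequences worth being explicit
about:

* The default task is easy; criterion runs typically stop at the first
  1000-sample evaluation. The subnet size-independence acceptance check is
  therefore dominated by the exact per-iteration energy identity rather
  than by learning-time variation.
* The empirical MNIST speed-up of larger networks ($T \propto N_h^{-0.249}$)
  is not robust on Gaussian prototypes; the speed/masking trade-off is
  tested as a sign constraint on fitted slopes (masked slope ≥ unmasked),
  on a harder parameterisation of the generator (80 features, 8 classes,
  noise sd 2.8) chosen before the assertions were frozen.
* A green synthetic suite establishes the *mechanics* (identities,
  equivalences, closed forms, qualitative contrasts), not the MNIST point
  estimates; `scripts/mnist_experiments.R` reproduces those given the
  manually downloaded IDX files.

## Numerical choices

* **Top-k tie-break**: stable order on (|Δw| descending, flat index
  ascending) — deterministic and keeps the kept-count exact under ties.
* **Exact-zero test** for $M_0$: no tolerance; zero-meaning makes
  accidental zeros measure-zero.
* **$M_0$ under caching** counts consolidation events only, and only for
  non-zero transfers (so $\theta = 0$ reproduces the vanilla count).
* **Divergence** (non-finite activations or proposals, e.g. at excessive
  learning rates) flags the run (`diverged = TRUE`) instead of throwing.
* **Fast path**: for `full`/`subnet`/`fixed_neuron_mask` the loop updates
  only the plastic rows, with float-for-float the same operations as the
  generic chain; a parity test asserts bit-identical weights and ledgers.
* **Accuracy ties** break toward the lowest output index.
* Power-law fits are OLS on logs; $r^2$ is computed directly (a perfect fit
  returns 1 rather than warning).

## Limitations

* Single hidden layer, plain SGD only (no ADAM, batching, regularisation —
  deliberately, matching the modelling scope).
* The energy model ignores signalling costs and any spatial/temporal
  interaction between synaptic modifications.
* The mask theory predicts proportional shape, not absolute energy; its
  constant must be fitted to one empirical point.
* Cortex-scale extrapolations (`extrapolate_ratio()`) inherit the fitted
  exponents and assume the power law continues far outside the simulated
  range.

## A worked call

```{r}
ds <- make_synthetic(synthetic_spec(seed = 1))
rec <- train_to_criterion(ds$train, ds$valid, n_hidden = 100,
                          config = training_config(seed = 1),
                          strategy = strategy_spec("subnet", subnet_size = 30))
rec
```

The theory table and the cortex-scale ratios:

```{r}
mask_theory_table(c(100, 1000, 10000))
extrapolate_ratio(0.75)$nearest_decade
extrapolate_ratio(0.43)$one_sig_fig
```
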