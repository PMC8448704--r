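---
title: "A combined competitive, attractor and backprojection network of neocortical pyramidal cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A combined competitive, attractor and backprojection network of neocortical pyramidal cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabnet)
```

## The question the model addresses

A neocortical pyramidal cell receives three anatomically distinct classes of
excitatory input: forward afferents from the previous cortical area, recurrent
collaterals from neighbouring pyramidal cells of the same population, and
backprojections from higher areas terminating on the apical dendrite.  Each
class is classically associated with a different computation — forward inputs
with competitive categorisation of what arrives from below, recurrent
collaterals with attractor short-term memory, and backprojections with
top-down recall and attentional biasing.  `cabnet` simulates all three on a
*single* population of binary-rate neurons, with the *same* associative
learning rule at every synapse and a *single* weight normalization applied
across each neuron's whole dendrite, and asks whether the three functions can
coexist without interfering.

## The model

The population has $N$ neurons (default 100).  Each neuron $i$ carries three
blocks of non-negative synaptic weights: forward
$w^{\mathrm{comp}}_{ik}$, recurrent $w^{\mathrm{rec}}_{il}$ and
backprojection $w^{\mathrm{bp}}_{im}$, each block with $n_{\mathrm{syn}}$
synapses (default $n_{\mathrm{syn}} = N = 100$, i.e. full connectivity), so a
dendrite has $3 n_{\mathrm{syn}} = 300$ weights.

**Activation.**  For presynaptic rate vectors $x^{\mathrm{comp}}$,
$x^{\mathrm{rec}}$, $x^{\mathrm{bp}}$ the activation is the scaled weighted
sum

$$h_i \;=\; g^{\mathrm{comp}} \sum_k \hat{x}^{\mathrm{comp}}_k
w^{\mathrm{comp}}_{ik} \;+\; g^{\mathrm{rec}} \sum_l \hat{x}^{\mathrm{rec}}_l
w^{\mathrm{rec}}_{il} \;+\; g^{\mathrm{bp}} \sum_m \hat{x}^{\mathrm{bp}}_m
w^{\mathrm{bp}}_{im},$$

where $\hat{x} = x / \sum_j x_j$ denotes the input vector scaled to unit
total rate and the fixed scale factors default to $g^{\mathrm{comp}} = 1$,
$g^{\mathrm{rec}} = g^{\mathrm{bp}} = 0.1$: the weaker gains let the forward
input dominate while learning, yet suffice to sustain a memory state or drive
recall once the forward input is absent.

**Output.**  A threshold binary activation function stands in for the
population's inhibitory interneurons: the $\max(1,
\mathrm{round}(a\,N))$ neurons with the highest activation fire at rate 1 and
the rest at 0, where $a$ is the output sparseness (default $0.01$, a single
winner).  Ties break toward the lowest neuron index, and if no activation is
positive no neuron fires.

**Learning.**  Every synapse uses the same associative rule,
$\delta w_{ij} = \alpha\, y_i\, \hat{x}_j$, with class-specific rates
$\alpha^{\mathrm{comp}} = 0.1$, $\alpha^{\mathrm{rec}} = 0.03$,
$\alpha^{\mathrm{bp}} = 0.1$.  After the increments of a presentation, each
modified neuron's *whole* dendritic weight vector — all 300 weights across
the three blocks — is renormalized to unit total strength.  The
renormalization silently weakens the inactive synapses of neurons that fired
(heterosynaptic depression), which is what lets a competitive neuron abandon
its random initial preferences in favour of the inputs it wins.

**Initialisation.**  All weights are drawn uniform on $[0,1]$ and each
dendrite is normalized to unit total strength, so all neurons start with the
same synaptic resource and competition is fair.  Non-negative patterns and
rates keep every weight $\ge 0$ forever.

**Training.**  For each of 5 epochs, the 28 (forward, backprojection)
pattern pairs are presented once in a fresh random permutation.  A
presentation settles the rates from the two external inputs (rates start at
zero, so with the default single settling pass the recurrent collaterals do
not influence the presented pattern's rates), then applies the Hebbian
update, with the settled rates serving both as the postsynaptic rates $y$
and as the recurrent presynaptic rates — recurrent learning is therefore
autoassociative, the substrate of the attractor.

## The training patterns

`make_shifted_patterns()` builds the forward set: 28 binary patterns over
100 input lines, each with 20 active lines, consecutive patterns shifted by
3 lines so neighbours share 17 active lines (positions are taken modulo 100,
which preserves both the active count and the 17-line overlap at the end of
the set).  The patterns are highly correlated by design — the mean absolute
pairwise Pearson correlation is $13/42 \approx 0.31$ — so the interesting
question is whether the network can map them to (nearly) orthogonal outputs
while keeping similar patterns together.  `make_orthogonal_patterns()`
builds the backprojection cues: 28 pairwise disjoint patterns of 3 active
lines each.  `make_random_patterns()` generates random binary sets of a
given sparseness for exploration.

## Normalization conventions

Two conventions define the normalization, both taken from classical
competitive-learning practice (Rumelhart & Zipser 1985; see also Oja 1982
for the related multiplicative formulation):

* **Input scaling.**  Presynaptic vectors enter the activation and the
  learning rule scaled to unit total rate ($\hat{x} = x/\sum x$).  A forward
  pattern (20 active lines), a recurrent rate vector (1 active neuron at the
  default sparseness) and a cue (3 active lines) then deliver the same total
  drive per unit scale factor, and each class's total Hebbian increment per
  presentation is exactly its learning rate.
* **Weight budget.**  The normalization conserves each dendrite's *total*
  synaptic strength ($\sum_j w_{ij} = 1$), i.e. the budget is the summed
  efficacy the dendrite can support.

The budget choice matters and was examined quantitatively.  Under a
Euclidean budget ($\sum_j w_{ij}^2 = 1$) with binary inputs and the default
learning rates, the learned self-recurrent weight of a category neuron
converges to roughly $\alpha^{\mathrm{rec}}$ divided by the norm of the mean
increment, about $0.08$ — reliably *below* the largest initial random
recurrent weight among the $\sim$95 untrained neurons (about $0.1$), so the
short-term memory collapses onto an untrained neuron as soon as the input is
removed; the sparse backprojection channel loses the same competition and
recall fails.  Under the total-strength budget the increments of the sparse
channels survive normalization with an order-of-magnitude margin over the
random background, and all three functions coexist.  The package therefore
uses the total-strength budget throughout; `dendrite_norms()` exposes it and
the test suite asserts its conservation to $10^{-10}$ after every update.

Normalization is applied after every presentation by default;
`network_params(normalize = "epoch")` defers it to the end of each epoch,
which was evaluated and rejected as the default (category formation
degrades: the within-epoch accumulation lets early winners capture too many
patterns).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `N` | 100 | output neurons |
| `nSyn` | `N` | synapses per input class per neuron |
| `gComp`, `gRec`, `gBp` | 1, 0.1, 0.1 | fixed scale factors of the three input classes (dimensionless) |
| `alphaComp`, `alphaRec`, `alphaBp` | 0.1, 0.03, 0.1 | Hebbian learning rates (dimensionless; increments per presentation on the unit-rate scale) |
| `sparseness` | 0.01 | fraction of output neurons firing (0.01 → single winner) |
| `epochs` | 5 | training epochs |
| `settleIters` | 1 | settling passes per presentation |
| `seed` | 1 | default RNG seed |

The recurrent learning rate is lower than the other two because its
presynaptic vector (a single winner) is maximally concentrated: at equal
rates the self-synapse would swallow the dendrite's budget and distort the
forward competition.

## Test protocols

`run_experiment()` trains a fresh network and runs the three tests with
frozen weights:

1. **Categorisation** — each forward pattern alone (`test_forward()`).
   Outputs are grouped by exact binary identity; the report records the
   number of categories, whether each category occupies a contiguous
   (wrap-aware) run of the pattern order, and the mean absolute pairwise
   correlation of the distinct output vectors.
2. **Short-term memory** — from each forward-driven output the network runs
   free for 10 (and, as an extended check, 100) iterations with no external
   input (`run_attractor()`); stability means the rates never change.
3. **Recall** — each backprojection cue alone (`recall()`); a cue is correct
   when it reproduces the forward-driven output exactly.

`category_statistics()` repeats this over seeds, `robustness_sweep()` maps
where in parameter space the network still *operates well* (defined here as:
recall perfect, attractor stable, and 3–6 categories — the band that
tolerates the run-to-run 4-versus-5 category variation), and
`attention_experiment()` probes biased competition: ambiguous stimuli built
as the element-wise maximum of two category exemplars are presented weakly,
with and without a weak cue, and the report counts how often the cued
category wins.  The ambiguous-mixture construction is this package's probe
design: it is the minimal stimulus with two plausible winners.

## What the defaults produce

At the defaults, across seeded runs: the 28 correlated inputs collapse to
usually 4 (sometimes 5) orthogonal single-winner categories with contiguous
membership; the mean absolute correlation between distinct outputs is
$1/99 \approx 0.01$ (against $0.31$ for the inputs); every forward-driven
state persists unchanged through 100 free-running iterations; and the cues
recall 26–28 of the 28 outputs exactly, perfectly in most runs.  The test
suite pins these outcomes over seeds 0–19, and `scripts/acceptance.R`
recomputes them from scratch.

## Numerical choices and degenerate inputs

* $m = \mathrm{round}(a N)$ winners, with a minimum of one whenever
  $a > 0$; an all-zero activation vector yields all-zero rates rather than
  forced winners.
* Ties in the threshold break toward the lowest neuron index, for
  determinism; with continuous random weights ties have measure zero.
* Category identity is exact binary vector equality, not a similarity
  threshold — with single winners the two notions coincide.
* All randomness flows from integer seeds: the weight draw and the
  epoch permutations use separate derived seeds (`seed` and `seed + 1`), so
  a pipeline is bit-reproducible and generators never disturb the caller's
  RNG stream.
* Degenerate pattern sets (constant rows) are rejected where a correlation
  is requested; regimes that can silence the output entirely (e.g.
  `gBp = 0` during recall) report `NA` correlations rather than fail.

## What the generators do and do not emulate

The built-in pattern sets are idealised: binary rates, exactly equal active
counts, noise-free presentations, and full connectivity.  Passing the tests
therefore shows that the three computations coexist under one learning rule
and one normalization — the question the model isolates — not that they
survive graded firing rates, diluted connectivity, input noise, or realistic
synapse counts.  Explicit inhibitory circuitry is abstracted into the fixed
sparseness of the threshold function, and the capacity questions (how many
categories or memories such a population can hold) are outside the model's
scope.

## Known limitations

* **Boundary drift.**  With the default learning rate the category
  boundaries keep moving slightly during the final epoch, so a
  category-edge pattern occasionally ends up recalled as its neighbouring
  category: single runs score 26–28 of 28 correct cues, not always 28.
  This is intrinsic to online competitive learning at
  $\alpha^{\mathrm{comp}} = 0.1$ (higher rates overwrite earlier learning);
  the run-to-run spread is reported rather than hidden.
* The number of categories fluctuates between 3 and 6 across seeds (modally
  4); exact counts depend on the random initial weights.
* Rates are binary; no membrane dynamics, noise injection, or synaptic
  bounds other than non-negativity plus the normalization are modelled.

## Problem sizes used by the shipped checks

The test suite and acceptance script use the full default network
($N = 100$, 28 pattern pairs, 5 epochs) — single runs take well under a
second — with 20 seeded repetitions for the category statistics and 5 per
point for the parameter-tolerance endpoints, sizes chosen to make the
stochastic claims stable while keeping a complete run of the suite around a
minute.

## References

* Rumelhart, D. E. & Zipser, D. (1985) Feature discovery by competitive
  learning. *Cognitive Science* 9, 75–112.
* Oja, E. (1982) A simplified neuron model as a principal component
  analyzer. *Journal of Mathematical Biology* 15, 267–273.
* Hopfield, J. J. (1982) Neural networks and physical systems with emergent
  collective computational abilities. *PNAS* 79, 2554–2558.
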